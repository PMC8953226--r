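## Off-gas sensor dynamics: identification, forward smearing,
## deconvolution, and gas-phase mole balancing into volumetric rates.
##
## The sensor train (tubing, foam trap, measurement cell) is modelled
## as a single lumped mixing chamber: a pure transport delay followed
## by a first-order lag with time constant tau.

#' First-order-plus-delay sensor model
#'
#' @param delay transport delay, s (>= 0).
#' @param time_constant first-order lag time constant tau, s (>= 0).
#' @return an object of class `sensor_model`.
#' @export
sensor_model <- function(delay = 0, time_constant = 0) {
  if (delay < 0 || time_constant < 0)
    stop("delay and time_constant must be non-negative")
  structure(list(delay = delay, time_constant = time_constant),
            class = "sensor_model")
}

assert_uniform_grid <- function(time) {
  if (length(time) < 2) stop("need at least two samples")
  dts <- diff(time)
  if (any(dts <= 0)) stop("time must be strictly increasing")
  if (diff(range(dts)) > 1e-6 * mean(dts))
    stop("time grid must be uniform")
  mean(dts)
}

#' Forward-simulate sensor smearing of a true signal
#'
#' Applies the delay (rounded to the nearest grid step) and the exact
#' discrete solution of the first-order lag for piecewise-linear
#' input (first-order hold): with a = exp(-dt/tau) and
#' c = (tau/dt) (1 - a),
#' y_k = a y_(k-1) + (1 - a) x_(k-1) + (1 - c) (x_k - x_(k-1)),
#' which reproduces the continuous-time response exactly for signals
#' linear between samples (no half-step phase lag). The filter is
#' initialized at the first input value (sensor equilibrated with the
#' pre-existing signal). tau = 0 reduces to the identity (plus delay).
#'
#' @param time uniform sampling grid, s.
#' @param signal true (reactor-side) signal values.
#' @param model a [sensor_model()].
#' @return numeric vector of the measured (smeared) signal.
#' @export
convolve_sensor <- function(time, signal, model) {
  dt <- assert_uniform_grid(time)
  n <- length(signal)
  shift <- as.integer(round(model$delay / dt))
  x <- if (shift > 0)
    c(rep(signal[1], shift), signal[seq_len(n - shift)])
  else signal
  if (model$time_constant <= 0) return(x)
  a <- exp(-dt / model$time_constant)
  cc <- model$time_constant / dt * (1 - a)
  ## forcing term of the exact piecewise-linear-input solution
  u <- c(x[1] * (1 - a),
         (1 - a) * x[-n] + (1 - cc) * diff(x))
  as.numeric(stats::filter(u, filter = a, method = "recursive",
                           init = x[1]))
}

## Moving local quadratic (Savitzky-Golay degree-2) derivative on a
## uniform grid; one-sided fits at the ends. window must be odd >= 3.
smoothed_derivative <- function(y, dt, window) {
  n <- length(y)
  if (window %% 2 != 1 || window < 3) stop("window must be odd, >= 3")
  if (window > n) stop("smoothing window larger than the series")
  half <- (window - 1) %/% 2
  dy <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    idx <- lo:hi
    tt <- (idx - i) * dt
    deg <- min(2, length(idx) - 1)
    X <- stats::poly(tt, degree = deg, raw = TRUE, simple = TRUE)
    fit <- stats::lm.fit(cbind(1, X), y[idx])
    ## derivative at tt = 0 is the linear coefficient
    dy[i] <- fit$coefficients[2]
  }
  dy
}

#' Deconvolve a measured off-gas signal
#'
#' Inverts the first-order-plus-delay sensor model. Two inversion
#' methods are available:
#' \describe{
#'   \item{`"smoothed_derivative"`}{the continuous-time inverse
#'     x(t) = y(t + delay) + tau * dy/dt(t + delay), with the
#'     derivative taken on a locally smoothed signal (moving quadratic
#'     polynomial filter; one-sided fits at the series ends). Robust
#'     to noise, but a centered derivative has zero gain at the
#'     Nyquist frequency, so features on the scale of the sampling
#'     interval are attenuated.}
#'   \item{`"exact"`}{algebraic forward-substitution inverse of the
#'     discrete first-order-hold filter applied by
#'     [convolve_sensor()]; reconstructs noiseless signals exactly
#'     (including steps) but amplifies measurement noise near the
#'     Nyquist frequency, so it should be paired with ensemble or
#'     cycle averaging (see [cycle_waveform()]).}
#' }
#' The tail uncovered by the delay shift is held at the last
#' reconstructed value.
#'
#' The default 3-point window is the shortest admissible
#' regularization; at 1-min logging it keeps the filter support
#' (3 min) close to the duration of the shortest process phase so
#' cycle extrema are not clipped more than necessary.
#'
#' @param time uniform sampling grid, s.
#' @param measured measured (smeared) signal.
#' @param model a [sensor_model()].
#' @param smoothing_window odd number of points (>= 3) for the
#'   derivative regularization.
#' @param method inversion method, see above.
#' @param noise_gain_warn warn if tau/dt exceeds this factor (noise
#'   amplification bound); never an error.
#' @return numeric vector of the reconstructed true signal.
#' @export
deconvolve_signal <- function(time, measured, model,
                              smoothing_window = 3,
                              method = c("smoothed_derivative",
                                         "exact"),
                              noise_gain_warn = 20) {
  method <- match.arg(method)
  dt <- assert_uniform_grid(time)
  n <- length(measured)
  tau <- model$time_constant
  if (tau / dt > noise_gain_warn)
    warning(sprintf(
      "tau/dt = %.1f amplifies measurement noise strongly; %s",
      tau / dt, "consider a wider smoothing window"))
  shift <- as.integer(round(model$delay / dt))
  y <- if (shift > 0) c(measured[(shift + 1):n],
                        rep(measured[n], shift)) else measured
  if (tau <= 0) return(y)
  if (method == "exact") {
    a <- exp(-dt / tau)
    cc <- tau / dt * (1 - a)
    x <- numeric(n)
    x[1] <- y[1]
    for (k in 2:n)
      x[k] <- (y[k] - a * y[k - 1] - (cc - a) * x[k - 1]) / (1 - cc)
  } else {
    dy <- smoothed_derivative(y, dt, smoothing_window)
    x <- y + tau * dy
  }
  if (shift > 0) x[(n - shift + 1):n] <- x[n - shift]
  x
}

#' Identify a sensor model from a step experiment
#'
#' The delay is the time from the applied step to the first sample
#' departing from the pre-step baseline by more than 3x the baseline
#' noise (standard deviation of the pre-step samples; an absolute
#' floor of 1e-9 times the response span covers noiseless records).
#' The time constant is then fit by least squares to the step
#' response of the first-order-hold discretization used by
#' [convolve_sensor()],
#' y(t) = y0 + dy * (1 - C exp(-(t - delay - t0)/tau)) with
#' C = (tau/dt)(1 - exp(-dt/tau)), jointly with a small continuous
#' time-origin refinement t0 (|t0| on the order of one sample), so
#' identification is exactly self-consistent with the forward model.
#'
#' @param time sample times, s (uniform grid).
#' @param response measured step response.
#' @param step_time time at which the step was applied, s.
#' @return a [sensor_model()] with attributes `y0`, `amplitude`,
#'   `rmse`.
#' @export
identify_sensor_model <- function(time, response, step_time) {
  dt <- assert_uniform_grid(time)
  pre <- response[time < step_time]
  if (length(pre) < 2) stop("no pre-step baseline present")
  y0 <- mean(pre)
  span <- diff(range(response))
  if (span <= 0) stop("no detectable step in the response")
  noise <- max(stats::sd(pre), 1e-9 * span)
  post_idx <- which(time >= step_time)
  beyond <- abs(response[post_idx] - y0) > 3 * noise
  ## sustained departure: three consecutive samples beyond threshold,
  ## so an isolated noise excursion cannot trigger detection
  run3 <- beyond & c(beyond[-1], FALSE) & c(beyond[-(1:2)], FALSE, FALSE)
  if (!any(run3)) stop("no detectable step in the response")
  ## first departing sample: the lagged response is already nonzero at
  ## the sample where the delayed step arrives
  delay <- max(time[post_idx[which(run3)[1]]] - step_time, 0)

  fit_idx <- which(time >= step_time + delay - dt / 2)
  tt <- time[fit_idx] - (step_time + delay)
  yy <- response[fit_idx]
  dy0 <- mean(utils::tail(yy, max(3, length(yy) %/% 10))) - y0
  sse <- function(tau, t0 = 0) {
    tau <- max(tau, 1e-12)
    cc <- tau / dt * (1 - exp(-dt / tau))
    pred <- y0 + dy0 * (1 - cc * exp(-pmax(tt - t0, 0) / tau))
    sum((yy - pred)^2)
  }
  span_t <- max(tt[length(tt)], dt)
  opt1 <- stats::optimize(function(tau) sse(tau),
                          interval = c(dt / 50, span_t), tol = 1e-10)
  opt <- stats::optim(c(opt1$minimum, 0),
                      function(p) sse(p[1], p[2]),
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-12))
  tau <- if (sse(1e-12) <= opt$value) 0 else opt$par[1]
  rmse <- sqrt(min(sse(1e-12), opt$value) / length(yy))
  out <- sensor_model(delay = delay, time_constant = tau)
  attr(out, "y0") <- y0
  attr(out, "amplitude") <- dy0
  attr(out, "rmse") <- rmse
  out
}

#' Volumetric gas transfer rates from off-gas mole fractions
#'
#' Uses the inert-gas balance to obtain the outlet flow,
#' F_out = F_in (1 - yO2_in - yCO2_in)/(1 - yO2_out - yCO2_out),
#' then Q_O2 = (F_in yO2_in - F_out yO2_out) / (V_m V) (positive =
#' consumption) and Q_CO2 = (F_out yCO2_out - F_in yCO2_in) / (V_m V)
#' (positive = production), converted to mmol per liter broth per hour.
#'
#' @param y_o2,y_co2 outlet mole fractions (vectors).
#' @param gas_flow_in inlet gas flow, normal liters per minute.
#' @param volume broth volume, L.
#' @param inlet_o2,inlet_co2 inlet mole fractions (ambient air
#'   defaults).
#' @param molar_volume molar gas volume at normal conditions, NL/mol.
#' @return data frame with columns `q_o2` and `q_co2`, mmol/L/h.
#' @export
gas_transfer_rates <- function(y_o2, y_co2, gas_flow_in, volume,
                               inlet_o2 = 0.2095, inlet_co2 = 0.0004,
                               molar_volume = MOLAR_VOLUME_NL) {
  inert_in <- 1 - inlet_o2 - inlet_co2
  inert_out <- 1 - y_o2 - y_co2
  if (any(inert_out <= 0))
    stop("outlet inert fraction must be positive")
  f_out <- gas_flow_in * inert_in / inert_out        # NL/min
  ## NL/min -> mmol/h: / molar_volume * 60 * 1000
  to_mmol_h <- 60 * 1000 / molar_volume
  q_o2 <- (gas_flow_in * inlet_o2 - f_out * y_o2) * to_mmol_h / volume
  q_co2 <- (f_out * y_co2 - gas_flow_in * inlet_co2) * to_mmol_h / volume
  data.frame(q_o2 = q_o2, q_co2 = q_co2)
}

## Inverse of gas_transfer_rates: outlet mole fractions that a given
## pair of volumetric rates produces. Used by the synthetic generator.
rates_to_fractions <- function(q_o2, q_co2, gas_flow_in, volume,
                               inlet_o2 = 0.2095, inlet_co2 = 0.0004,
                               molar_volume = MOLAR_VOLUME_NL) {
  to_mol_min <- 1 / molar_volume                    # NL/min -> mol/min
  n_o2_in <- gas_flow_in * inlet_o2 * to_mol_min
  n_co2_in <- gas_flow_in * inlet_co2 * to_mol_min
  n_inert <- gas_flow_in * (1 - inlet_o2 - inlet_co2) * to_mol_min
  ## mmol/L/h -> mol/min over the whole broth volume
  r_o2 <- q_o2 * volume / 1000 / 60
  r_co2 <- q_co2 * volume / 1000 / 60
  n_o2_out <- n_o2_in - r_o2
  n_co2_out <- n_co2_in + r_co2
  if (any(n_o2_out < 0)) stop("oxygen demand exceeds supply")
  tot <- n_o2_out + n_co2_out + n_inert
  data.frame(y_o2 = n_o2_out / tot, y_co2 = n_co2_out / tot)
}
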