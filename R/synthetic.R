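## Seeded synthetic stimulus-response datasets with known ground truth.
##
## The generator emulates the study design: a glucose-limited chemostat
## at D = 0.1 1/h (1.7 L, 22.5 g/L glucose feed) run at a reference
## steady state, perturbed once by a 2-min feed stop, then driven into
## a dynamic steady state by repeated 2-min-off / 7-min-on cycles.
## Gas-phase observables are derived stoichiometrically from the
## simulated uptake, smeared by the sensor model and noised; metabolite
## panels relax by piecewise first-order kinetics with optional damped
## overshoot (the AMP/ADP/IMP shape) and are emitted as triplicates.

#' Default per-metabolite relaxation specifications
#'
#' Columns: `metabolite`, `steady` and `famine` levels (umol/gDMB),
#' `tau_decay` and `tau_recovery` (min), `overshoot` (amplitude above
#' steady, umol/gDMB; 0 = none) and `tau_overshoot` (min). Adenylate
#' and nicotinamide levels follow published steady-state pool sizes;
#' the remaining central-carbon levels are order-of-magnitude
#' synthetic placeholders chosen to reproduce the qualitative
#' decay / delayed-recovery / overshoot shapes.
#'
#' @return data frame of relaxation parameters.
#' @export
default_metabolite_specs <- function() {
  spec <- read.csv(textConnection(
"metabolite,steady,famine,tau_decay,tau_recovery,overshoot,tau_overshoot
G6P,2.0,0.5,0.5,1.0,0,1
Hex6P,1.0,0.3,0.5,1.0,0,1
T6P,0.30,0.12,0.7,1.5,0.15,1.5
FBP,0.36,0.14,0.6,2.5,0,1
PG23,0.50,0.45,1.0,1.0,0,1
PEP,0.60,0.55,1.0,1.0,0,1
PYR,0.40,0.15,0.6,1.2,0,1
PGA6,0.10,0.03,0.6,3.0,0,1
P5P,0.30,0.10,0.6,3.0,0,1
CIT_ISOCIT,2.0,1.9,1.5,1.5,0,1
AKG,0.80,0.20,0.6,2.5,0,1
UDP_glucose,0.70,0.60,1.5,1.5,0,1
trehalose,30,28,3.0,3.0,0,1
glycogen,80,76,3.0,3.0,0,1
ATP,8.12,3.56,0.9,2.0,0,1
ADP,1.30,0.90,0.4,1.5,0.60,1.8
AMP,0.30,0.30,0.5,1.0,0.87,1.8
IMP,0.05,0.05,0.5,1.0,0.12,2.0
INO,0.10,0.08,0.5,1.5,0.05,2.5
HYX,0.05,0.04,0.5,1.5,0.02,2.5
NAD,3.53,3.53,1.0,1.0,0,1
NADH,0.17,0.10,0.8,3.0,0,1
NADP,0.158,0.120,0.8,2.0,0,1
NADPH,0.202,0.202,1.0,1.0,0,1
"), stringsAsFactors = FALSE)
  spec
}

#' Scenario specification for the synthetic SRE generator
#'
#' Defaults reproduce the study operating point; every component can
#' be overridden.
#'
#' @param reactor a [reactor_params()].
#' @param schedule_ds intermittent [feed_schedule()] of the dynamic
#'   steady state.
#' @param kinetics a [kinetic_params()].
#' @param sensor_o2,sensor_co2 [sensor_model()]s; defaults emulate the
#'   long sensor train (apparent time constant 120 s, delay 180 s).
#' @param noise named list of relative standard deviations per channel
#'   (`gas`, `metabolite`, `feed`, `biomass`); all >= 0.
#' @param metabolite_specs data frame as
#'   [default_metabolite_specs()].
#' @param replicates number of biological replicates (>= 1).
#' @param rs_hours,post_minutes,ds_cycles durations of the reference
#'   steady-state phase (h), the tracked post-single-famine window
#'   (min) and the number of 9-min DS cycles (default 333, i.e. five
#'   residence times at D = 0.1 per hour, the operation time after
#'   which the dynamic steady state is sampled).
#' @param seed integer random seed; fixed seed implies bit-identical
#'   output.
#' @return an object of class `sre_scenario`.
#' @export
sre_scenario <- function(reactor = reactor_params(),
                         schedule_ds = feed_schedule("intermittent"),
                         kinetics = kinetic_params(),
                         sensor_o2 = sensor_model(delay = 180,
                                                  time_constant = 120),
                         sensor_co2 = sensor_model(delay = 180,
                                                   time_constant = 120),
                         noise = list(gas = 0.002, metabolite = 0.05,
                                      feed = 0.005, biomass = 0.01),
                         metabolite_specs = default_metabolite_specs(),
                         replicates = 3,
                         rs_hours = 1, post_minutes = 30,
                         ds_cycles = 333,
                         seed = 1) {
  stopifnot(replicates >= 1)
  if (any(unlist(noise) < 0)) stop("noise sds must be >= 0")
  structure(list(reactor = reactor, schedule_ds = schedule_ds,
                 kinetics = kinetics, sensor_o2 = sensor_o2,
                 sensor_co2 = sensor_co2, noise = noise,
                 metabolite_specs = metabolite_specs,
                 replicates = replicates, rs_hours = rs_hours,
                 post_minutes = post_minutes, ds_cycles = ds_cycles,
                 seed = as.integer(seed)),
            class = "sre_scenario")
}

## Stoichiometric gas rates implied by the simulated uptake: all
## non-assimilated glucose carbon leaves as CO2 and oxygen closes the
## electron balance, so carbon, nitrogen and available-electron
## recoveries are exactly 100% by construction.
stoichiometric_gas <- function(q_s, biomass, kinetics,
                               biomass_comp = yeast_biomass_composition()) {
  m_x <- cmol_mass(biomass_comp)
  ## mmol biomass C formed per mmol glucose taken up
  cmol_per_glc <- kinetics$yield_xs * GLUCOSE_MOLAR_MASS / m_x
  q_co2 <- (6 - cmol_per_glc) * q_s                 # mmol/gDMB/h
  q_o2 <- (4 * 6 - biomass_comp$gamma * cmol_per_glc) / 4 * q_s
  q_nh3 <- biomass_comp$N * cmol_per_glc * q_s
  list(q_o2_vol = q_o2 * biomass, q_co2_vol = q_co2 * biomass,
       q_nh3 = q_nh3, cmol_per_glc = cmol_per_glc)
}

relaxation_curve <- function(t_min, steady, famine, tau_decay,
                             tau_recovery, overshoot, tau_overshoot,
                             off_min = 2) {
  x <- numeric(length(t_min))
  fam <- t_min <= off_min
  x[fam] <- famine + (steady - famine) * exp(-t_min[fam] / tau_decay)
  x_off <- famine + (steady - famine) * exp(-off_min / tau_decay)
  u <- t_min[!fam] - off_min
  x[!fam] <- steady + (x_off - steady) * exp(-u / tau_recovery)
  if (overshoot != 0) {
    ## damped excursion anchored at famine onset: peaks at
    ## t = tau_overshoot (the AMP/ADP/IMP transient shape)
    shape <- (t_min / tau_overshoot) * exp(1 - t_min / tau_overshoot)
    x <- x + overshoot * shape
  }
  pmax(x, 0)
}

#' Generate a complete synthetic stimulus-response dataset
#'
#' Runs the chemostat simulator through the three experimental phases
#' (reference steady state, single 2-min feed stop with tracked
#' recovery, intermittent dynamic steady state), derives the
#' stoichiometrically consistent true gas transfer rates, applies
#' sensor smearing and measurement noise at 1-min logging, and builds
#' replicated metabolite panels for the adapted (DS) famine cycle.
#'
#' @param scenario an [sre_scenario()].
#' @param dt simulator time step, s.
#' @return list of class `sre_dataset` with elements
#'   \describe{
#'     \item{trajectory}{full state trajectory with a `phase` column
#'       (`rs`, `post`, `ds`).}
#'     \item{gas}{1-min off-gas record: `time_s`, `phase`, measured
#'       `y_o2`, `y_co2`.}
#'     \item{panel}{tidy replicate metabolite panel
#'       (`sample_time_min`, `metabolite`, `replicate`,
#'       `value_umol_gDMB`).}
#'     \item{process}{per-phase replicate process measurements
#'       (feed rate, biomass, residual glucose).}
#'     \item{truth}{ground-truth record: the scenario, the noiseless
#'       volumetric rate series (`q_o2_vol`, `q_co2_vol`, mmol/L/h),
#'       true dilution rates and steady-state values, and the
#'       noiseless panel means.}
#'   }
#' @export
generate_sre_dataset <- function(scenario, dt = 1) {
  sc <- scenario
  set.seed(sc$seed)
  reactor <- sc$reactor; kin <- sc$kinetics
  d_cont <- reactor$base_feed_rate * 60 /
    (reactor$working_volume * 1000)
  ss <- monod_steady_state(d_cont, kin, reactor$feed_glucose)
  cont <- feed_schedule("continuous")

  ## phase (i): reference steady state
  rs <- simulate_chemostat(reactor, cont, kin,
                           init = c(glucose = ss$glucose,
                                    biomass = ss$biomass),
                           duration = sc$rs_hours, dt = dt)
  ## phase (ii): one 2-min feed stop, then the previous feed again
  off_min <- sc$schedule_ds$off_duration
  post_total <- off_min + sc$post_minutes
  single <- feed_schedule("intermittent", cycle_period = post_total,
                          off_duration = off_min,
                          on_rate = reactor$base_feed_rate)
  post <- simulate_chemostat(reactor, single, kin,
                             init = c(glucose = utils::tail(rs$glucose_umol_L, 1),
                                      biomass = utils::tail(rs$biomass_g_L, 1)),
                             duration = post_total / 60, dt = dt)
  ## phase (iii): intermittent cycles to the dynamic steady state
  ds_hours <- sc$ds_cycles * sc$schedule_ds$cycle_period / 60
  ds <- simulate_chemostat(reactor, sc$schedule_ds, kin,
                           init = c(glucose = utils::tail(post$glucose_umol_L, 1),
                                    biomass = utils::tail(post$biomass_g_L, 1)),
                           duration = ds_hours, dt = dt)

  shift_time <- function(tr, offset, phase) {
    tr$time_s <- tr$time_s + offset
    tr$phase <- phase
    tr
  }
  t1 <- utils::tail(rs$time_s, 1)
  t2 <- t1 + utils::tail(post$time_s, 1)
  traj <- rbind(shift_time(rs, 0, "rs"),
                shift_time(post[-1, ], t1, "post"),
                shift_time(ds[-1, ], t2, "ds"))

  ## true volumetric gas rates along the trajectory
  q_s <- kin$q_max * traj$glucose_umol_L /
    (kin$K_M + traj$glucose_umol_L)
  gas_true <- stoichiometric_gas(q_s, traj$biomass_g_L, kin)

  ## 1-min logging grid
  grid <- traj$time_s %% 60 == 0
  tg <- traj$time_s[grid]
  frac_true <- rates_to_fractions(gas_true$q_o2_vol[grid],
                                  gas_true$q_co2_vol[grid],
                                  reactor$gas_flow_in,
                                  reactor$working_volume)
  y_o2_m <- convolve_sensor(tg, frac_true$y_o2, sc$sensor_o2)
  y_co2_m <- convolve_sensor(tg, frac_true$y_co2, sc$sensor_co2)
  rel_noise <- function(x, sd) {
    if (sd <= 0) return(x)
    pmax(x * (1 + stats::rnorm(length(x), 0, sd)), 0)
  }
  gas <- data.frame(time_s = tg, phase = traj$phase[grid],
                    y_o2 = rel_noise(y_o2_m, sc$noise$gas),
                    y_co2 = rel_noise(y_co2_m, sc$noise$gas))

  ## per-phase replicate process measurements
  phases <- c("rs", "ds")
  proc <- do.call(rbind, lapply(phases, function(ph) {
    sched <- if (ph == "rs") cont else sc$schedule_ds
    rate <- if (ph == "rs") reactor$base_feed_rate else sched$on_rate
    sel <- traj$phase == ph
    x_true <- mean(traj$biomass_g_L[sel])
    res_true <- mean(traj$glucose_umol_L[sel]) *
      GLUCOSE_MOLAR_MASS / 1e6                       # g/L
    nh3_true <- mean(gas_true$q_nh3[sel]) * x_true   # mmol/L/h
    data.frame(
      phase = ph, replicate = seq_len(sc$replicates),
      feed_rate_ml_min = rel_noise(rep(rate, sc$replicates),
                                   sc$noise$feed),
      biomass_g_L = rel_noise(rep(x_true, sc$replicates),
                              sc$noise$biomass),
      residual_glucose_g_L = res_true,
      ammonia_mmol_L_h = rel_noise(rep(nh3_true, sc$replicates),
                                   sc$noise$feed),
      stringsAsFactors = FALSE)
  }))

  ## metabolite panel over one adapted famine cycle
  times <- c(0, 0.5, 1, 1.5, 2, 2.5, 3, 4, 5, 7, 9)
  specs <- sc$metabolite_specs
  true_panel <- do.call(rbind, lapply(seq_len(nrow(specs)), function(i) {
    s <- specs[i, ]
    data.frame(sample_time_min = times, metabolite = s$metabolite,
               value = relaxation_curve(times, s$steady, s$famine,
                                        s$tau_decay, s$tau_recovery,
                                        s$overshoot, s$tau_overshoot,
                                        off_min = off_min),
               stringsAsFactors = FALSE)
  }))
  panel <- do.call(rbind, lapply(seq_len(sc$replicates), function(r) {
    data.frame(sample_time_min = true_panel$sample_time_min,
               metabolite = true_panel$metabolite,
               replicate = r,
               value_umol_gDMB = rel_noise(true_panel$value,
                                           sc$noise$metabolite),
               stringsAsFactors = FALSE)
  }))

  structure(list(
    trajectory = traj, gas = gas, panel = panel, process = proc,
    truth = list(
      scenario = sc,
      d_continuous = d_cont,
      d_cycle_avg = average_dilution(sc$schedule_ds, reactor),
      steady_state = ss,
      q_o2_vol = data.frame(time_s = traj$time_s,
                            value = gas_true$q_o2_vol),
      q_co2_vol = data.frame(time_s = traj$time_s,
                             value = gas_true$q_co2_vol),
      q_nh3_specific = gas_true$q_nh3,
      panel_true = true_panel)
  ), class = "sre_dataset")
}

#' Write a synthetic dataset bundle as delimited text files
#'
#' Emits `trajectory.csv`, `gas.csv`, `metabolites.csv`, `process.csv`
#' and `ground_truth.csv` (the noiseless panel means) into `dir`.
#'
#' @param dataset an `sre_dataset` from [generate_sre_dataset()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_sre_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(dataset$trajectory,
                   file.path(dir, "trajectory.csv"), row.names = FALSE)
  utils::write.csv(dataset$gas, file.path(dir, "gas.csv"),
                   row.names = FALSE)
  utils::write.csv(dataset$panel, file.path(dir, "metabolites.csv"),
                   row.names = FALSE)
  utils::write.csv(dataset$process, file.path(dir, "process.csv"),
                   row.names = FALSE)
  utils::write.csv(dataset$truth$panel_true,
                   file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Generate a synthetic sensor step experiment
#'
#' A unit step applied after a baseline window, smeared by the sensor
#' model, with optional additive Gaussian noise — the input for
#' [identify_sensor_model()] round trips.
#'
#' @param model a [sensor_model()].
#' @param noise_sd additive noise standard deviation (response units).
#' @param seed integer seed for the noise.
#' @param dt sampling interval, s.
#' @param baseline_s pre-step baseline duration, s.
#' @param span_tau response duration after the step, in multiples of
#'   the time constant (minimum 5).
#' @return data frame `time_s`, `response`; attribute `step_time`.
#' @export
make_step_experiment <- function(model, noise_sd = 0, seed = 1,
                                 dt = 1, baseline_s = 120,
                                 span_tau = 8) {
  set.seed(seed)
  span_tau <- max(span_tau, 5)
  total <- baseline_s + model$delay +
    span_tau * max(model$time_constant, 10 * dt)
  time <- seq(0, total, by = dt)
  x <- as.numeric(time >= baseline_s)
  y <- convolve_sensor(time, x, model)
  if (noise_sd > 0) y <- y + stats::rnorm(length(y), 0, noise_sd)
  out <- data.frame(time_s = time, response = y)
  attr(out, "step_time") <- baseline_s
  out
}
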