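## Biomass-specific rates, yields, elemental recoveries, ATP demand
## and steady-state comparisons.
##
## Sign convention: uptake rates (glucose, oxygen, ammonia) are stored
## as positive magnitudes; reports render them with a leading minus
## (-q_glucose) as is customary in phenotype tables.

#' Elemental composition of a flow compound
#'
#' @param C,H,O,N atoms per formula unit.
#' @return list with the formula and the degree of reduction per C-mol.
#' @export
elemental_composition <- function(C, H, O, N = 0) {
  list(C = C, H = H, O = O, N = N,
       gamma = if (C > 0) degree_of_reduction(C, H, O, N) else NA_real_)
}

#' Default biomass composition: CH1.8O0.5N0.2 per C-mol
#'
#' Standard yeast C-mol formula; molar mass 24.63 g per C-mol
#' (ash-free), i.e. about 0.041 mol C per g dry matter.
#' @return an [elemental_composition()].
#' @export
yeast_biomass_composition <- function() {
  elemental_composition(C = 1, H = 1.8, O = 0.5, N = 0.2)
}

cmol_mass <- function(comp) {
  (12.011 * comp$C + 1.008 * comp$H + 15.999 * comp$O +
     14.007 * comp$N) / comp$C
}

#' Cycle-averaged dilution rate of a feed schedule
#'
#' @param schedule a [feed_schedule()].
#' @param params a [reactor_params()].
#' @return dilution rate D, 1/h.
#' @export
#' @examples
#' average_dilution(feed_schedule("continuous"), reactor_params())
#' average_dilution(feed_schedule("intermittent"), reactor_params())
average_dilution <- function(schedule, params) {
  mean_rate <- if (schedule$mode == "continuous") {
    params$base_feed_rate
  } else {
    on_time <- schedule$cycle_period - schedule$off_duration
    schedule$on_rate * on_time / schedule$cycle_period
  }
  mean_rate * 60 / (params$working_volume * 1000)   # mL/h / mL -> 1/h
}

#' Intermittent on-rate required to match a continuous feed rate
#'
#' For a duty cycle of `on_duration / cycle_period` the pump must run
#' faster by the inverse duty cycle to conserve the average feed.
#'
#' @param continuous_rate continuous-feed pump rate, mL/min.
#' @param cycle_period,off_duration cycle timing, min.
#' @return required on-rate, mL/min.
#' @export
#' @examples
#' required_on_rate(2.83, 9, 2)   # ~3.64 mL/min
required_on_rate <- function(continuous_rate, cycle_period,
                             off_duration) {
  duty <- (cycle_period - off_duration) / cycle_period
  if (duty <= 0) stop("on duration must be positive")
  continuous_rate / duty
}

#' Biomass-specific rates and yields from process measurements
#'
#' @param D dilution rate, 1/h.
#' @param biomass steady-state biomass concentration, gDMB/L.
#' @param feed_glucose feed glucose, g/L.
#' @param residual_glucose residual glucose in the broth, g/L.
#' @param q_o2_vol,q_co2_vol volumetric gas rates (e.g. from
#'   [gas_transfer_rates()]), mmol/L/h; positive magnitudes.
#' @param q_nh3_vol volumetric ammonia uptake, mmol/L/h (optional).
#' @param q_other_c_vol volumetric leakage of other carbon,
#'   mmolC/L/h (optional).
#' @return a `phenotype_record` list with fields `D`, `Y_xs`,
#'   `q_glucose`, `q_oxygen`, `q_co2`, `q_ammonia`, `q_other_carbon`
#'   (all specific rates in mmol/gDMB/h, positive magnitudes) and
#'   `Y_o2_glucose` (mol/mol).
#' @export
specific_rates <- function(D, biomass, feed_glucose,
                           residual_glucose = 0,
                           q_o2_vol = NA_real_, q_co2_vol = NA_real_,
                           q_nh3_vol = NA_real_,
                           q_other_c_vol = NA_real_) {
  if (biomass <= 0) stop("biomass must be positive")
  if (D < 0 || feed_glucose < 0 || residual_glucose < 0)
    stop("flows must be non-negative")
  m_glc <- GLUCOSE_MOLAR_MASS / 1000     # g per mmol
  q_glc <- D * (feed_glucose - residual_glucose) / (biomass * m_glc)
  y_xs <- biomass * D / (D * (feed_glucose - residual_glucose))
  rec <- list(
    D = D,
    Y_xs = y_xs,
    q_glucose = q_glc,
    q_oxygen = q_o2_vol / biomass,
    q_co2 = q_co2_vol / biomass,
    q_ammonia = q_nh3_vol / biomass,
    q_other_carbon = q_other_c_vol / biomass,
    Y_o2_glucose = if (is.na(q_o2_vol)) NA_real_
                   else (q_o2_vol / biomass) / q_glc
  )
  class(rec) <- "phenotype_record"
  rec
}

#' Carbon, nitrogen and available-electron recoveries
#'
#' Recovery = accounted output over input, in percent:
#' \itemize{
#'  \item carbon: (q_CO2 + biomass C + other C) / (6 q_glucose)
#'  \item nitrogen: biomass N / q_ammonia
#'  \item available electrons: (gamma_X * biomass C-mol +
#'        4 * q_O2) / (gamma_glc * 6 * q_glucose), with gamma_glc = 4
#'        and 4 electrons accepted per O2.
#' }
#' Biomass formation enters as D / M_Cmol in mmol C per gDMB per h.
#'
#' @param record a `phenotype_record` from [specific_rates()].
#' @param biomass_comp biomass elemental composition per C-mol
#'   (default [yeast_biomass_composition()]).
#' @param gamma_glucose degree of reduction of glucose per C-mol.
#' @return list with `carbon`, `nitrogen`, `ave` recoveries in percent.
#' @export
recoveries <- function(record,
                       biomass_comp = yeast_biomass_composition(),
                       gamma_glucose = 4) {
  q_glc <- record$q_glucose
  if (!is.finite(q_glc) || q_glc <= 0)
    stop("record must contain a positive glucose uptake rate")
  m_x <- cmol_mass(biomass_comp)
  r_x <- record$D * 1000 / m_x                # mmol C-mol/gDMB/h
  q_other <- record$q_other_carbon
  if (is.na(q_other)) q_other <- 0
  carbon_in <- 6 * q_glc
  carbon_out <- record$q_co2 + r_x + q_other
  nitrogen_in <- record$q_ammonia
  nitrogen_out <- biomass_comp$N * r_x
  ave_in <- gamma_glucose * 6 * q_glc
  ave_out <- biomass_comp$gamma * r_x + 4 * record$q_oxygen
  list(carbon = 100 * carbon_out / carbon_in,
       nitrogen = if (is.na(nitrogen_in)) NA_real_
                  else 100 * nitrogen_out / nitrogen_in,
       ave = 100 * ave_out / ave_in)
}

#' Specific ATP turnover estimate for respiratory metabolism
#'
#' q_ATP = slp_per_glucose * q_glucose + 2 * (P/O) * q_oxygen:
#' substrate-level phosphorylation (default 2 ATP per glucose through
#' glycolysis) plus oxidative phosphorylation with the given P/O ratio
#' per oxygen atom (2 atoms per O2). Both coefficients are assumptions,
#' not measurements, and are returned alongside the estimate.
#'
#' @param q_glucose,q_oxygen specific uptake magnitudes, mmol/gDMB/h.
#' @param p_o_ratio ATP per oxygen atom in oxidative phosphorylation.
#' @param slp_per_glucose ATP per glucose from substrate-level
#'   phosphorylation.
#' @return list with `q_atp` (mmol ATP/gDMB/h), and the formula and
#'   assumptions used.
#' @export
qatp_estimate <- function(q_glucose, q_oxygen, p_o_ratio = 1.08,
                          slp_per_glucose = 2) {
  if (q_glucose < 0 || q_oxygen < 0) stop("rates must be non-negative")
  q_atp <- slp_per_glucose * q_glucose + 2 * p_o_ratio * q_oxygen
  list(q_atp = q_atp,
       formula = "q_ATP = slp_per_glucose * q_glucose + 2 * P/O * q_oxygen",
       p_o_ratio = p_o_ratio, slp_per_glucose = slp_per_glucose)
}

#' Expected biomass-yield effect of a storage-carbon change
#'
#' A reduction of intracellular storage carbohydrate pools by
#' `delta_storage_c` mol C per gDMB corresponds to a fractional change
#' in the biomass/substrate yield of `delta_storage_c / biomass_c`.
#'
#' @param delta_storage_c storage-carbon change, molC/gDMB.
#' @param biomass_c biomass carbon content, molC/gDMB (default 0.04).
#' @return fractional yield change (0.04 means 4%).
#' @export
storage_carbon_yield_effect <- function(delta_storage_c,
                                        biomass_c = 0.04) {
  if (biomass_c <= 0) stop("biomass_c must be positive")
  delta_storage_c / biomass_c
}

#' Reconstruct replicate values from mean, sd and n
#'
#' For n = 3 the deterministic set {m - s, m, m + s} matches the mean
#' and the sample standard deviation exactly. For general n, a
#' standardized symmetric design is scaled to the requested moments.
#'
#' @param mean,sd summary statistics (sd is the sample sd).
#' @param n number of replicates (>= 2).
#' @return numeric vector of length `n` with the requested sample
#'   moments.
#' @export
replicates_from_moments <- function(mean, sd, n = 3) {
  if (n < 2) stop("n must be >= 2")
  if (sd < 0) stop("sd must be non-negative")
  base <- seq(-1, 1, length.out = n)
  base <- base - base[ceiling(n / 2)] * 0   # symmetric, mean zero
  s <- stats::sd(base)
  mean + if (s > 0) base / s * sd else rep(0, n)
}

#' Welch two-sample comparison of replicate groups
#'
#' Two-sided Welch t-test with Satterthwaite degrees of freedom,
#' plus the percent change of group b relative to group a. Changes
#' with p > 0.05 are labelled "n.s.".
#'
#' @param a,b numeric vectors of replicate values (n >= 2 each).
#' @return list with `p_value`, `percent_change`, `significant`,
#'   `label` (formatted percent or "n.s.").
#' @export
welch_compare <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop("need at least two replicates per group")
  ma <- mean(a); mb <- mean(b)
  va <- stats::var(a); vb <- stats::var(b)
  na <- length(a); nb <- length(b)
  se2 <- va / na + vb / nb
  if (se2 == 0) {
    p <- if (ma == mb) 1 else 0
  } else {
    tstat <- (ma - mb) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    p <- 2 * stats::pt(-abs(tstat), df)
  }
  change <- (mb - ma) / ma * 100
  sig <- p <= 0.05
  list(p_value = p, percent_change = change, significant = sig,
       label = if (sig) sprintf("%+.1f", change) else "n.s.")
}
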