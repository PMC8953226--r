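test_that("continuous feed dilution rate matches the operating point", {
  d <- average_dilution(feed_schedule("continuous"), rp)
  expect_equal(d, 2.83 * 60 / 1700)
  expect_equal(d, 0.0999, tolerance = 1e-3)
})

test_that("simulator reproduces the closed-form Monod steady state", {
  k <- kinetic_params(q_max = 2.0, K_M = 100, yield_xs = 0.5)
  ## closed form: q_req = D/(Y*M) -> Cs* = K_M q_req/(q_max - q_req)
  D <- 0.1
  q_req <- D / (0.5 * 0.18016)
  cs_star <- 100 * q_req / (2.0 - q_req)
  expect_equal(cs_star, 124.7, tolerance = 1e-3)
  ss <- monod_steady_state(D, k, feed_glucose = 22.5)
  expect_equal(ss$glucose, cs_star, tolerance = 1e-12)

  ## long simulation converges to it from a perturbed start
  r <- reactor_params(base_feed_rate = D * 1700 / 60)
  tr <- simulate_chemostat(r, feed_schedule("continuous"), k,
                           init = c(glucose = 1.5 * cs_star,
                                    biomass = ss$biomass),
                           duration = 10, dt = 1)
  expect_lt(abs(utils::tail(tr$glucose_umol_L, 1) - cs_star) / cs_star,
            0.005)
  expect_lt(abs(utils::tail(tr$biomass_g_L, 1) - ss$biomass) /
              ss$biomass, 0.005)
})

test_that("glucose stays constant with no uptake and no feed", {
  k <- kinetic_params(q_max = 1e-12, K_M = 100, yield_xs = 0.5)
  ## intermittent schedule that is off for almost the whole short run
  sch <- feed_schedule("intermittent", cycle_period = 60,
                       off_duration = 59, on_rate = 2.83)
  tr <- simulate_chemostat(rp, sch, k,
                           init = c(glucose = 80, biomass = 5),
                           duration = 50 / 60, dt = 1)
  expect_equal(max(abs(tr$glucose_umol_L - 80)), 0, tolerance = 1e-6)
})

test_that("simulator conserves carbon when maintenance is zero", {
  ## feed glucose carbon = effluent + biomass carbon + CO2-implied
  ## carbon (1 - yield share), integrated over the run
  k <- kinetic_params()
  tr <- simulate_chemostat(rp, feed_schedule("continuous"), k,
                           duration = 2, dt = 1)
  dt_h <- 1 / 3600
  d <- rp$base_feed_rate * 60 / (rp$working_volume * 1000)
  cs_feed <- rp$feed_glucose / 180.16 * 1e6
  ## left-endpoint integrals over the grid intervals
  int <- function(v) sum(utils::head(v, -1)) * dt_h
  q_s <- k$q_max * tr$glucose_umol_L / (k$K_M + tr$glucose_umol_L)
  m_x <- 24.626
  cmol_per_glc <- k$yield_xs * 180.16 / m_x
  t_h <- utils::tail(tr$time_s, 1) / 3600
  glc_in <- d * cs_feed * t_h * 6                       # umolC/L
  glc_out <- int(d * tr$glucose_umol_L) * 6
  uptake <- int(q_s * tr$biomass_g_L * 1000)            # umol/L
  bio_c <- uptake * cmol_per_glc
  co2_c <- uptake * (6 - cmol_per_glc)
  accum <- (utils::tail(tr$glucose_umol_L, 1) -
              tr$glucose_umol_L[1]) * 6
  expect_equal(glc_in, glc_out + bio_c + co2_c + accum,
               tolerance = 1e-3)
})

test_that("regime classification follows the thresholds, boundaries inclusive to limitation", {
  expect_equal(classify_regime(300, kp), "overflow")
  expect_equal(classify_regime(30, kp), "starvation")
  expect_equal(classify_regime(c(207, 53, 100), kp),
               rep("limitation", 3))
  expect_error(classify_regime(-1, kp), "non-negative")
})

test_that("regime residence is left-endpoint time-weighted and sums to one", {
  ## square wave: 58 s of 100 s below the starvation threshold
  t <- 0:100
  g <- c(rep(10, 58), rep(100, 43))
  fr <- regime_residence(t, g, kp)
  expect_equal(unname(fr["starvation"]), 0.58)
  expect_equal(sum(fr), 1, tolerance = 1e-12)

  fr2 <- regime_residence(c(0, 50, 100), c(100, 100, 100), kp)
  expect_equal(unname(fr2["limitation"]), 1)

  expect_error(regime_residence(c(0, 2, 1), c(1, 2, 3), kp),
               "increasing")
})

test_that("intermittent-run residence fractions match the event timing", {
  ## event-timing oracle: glucose falls below the starvation threshold
  ## a computable time after feed-off and recovers after feed-on; the
  ## residence fractions must agree with threshold crossings of the
  ## trajectory itself within one grid step per crossing
  tr <- simulate_chemostat(rp, feed_schedule("intermittent"), kp,
                           duration = 0.9, dt = 1)
  fr <- regime_residence(tr$time_s, tr$glucose_umol_L, kp)
  below <- tr$glucose_umol_L < kp$starvation_threshold
  frac_below <- mean(below[-length(below)])
  expect_equal(unname(fr["starvation"]), frac_below,
               tolerance = 2 / nrow(tr))
  expect_equal(sum(fr), 1, tolerance = 1e-12)
})

test_that("residence fractions move monotonically with the starvation threshold", {
  tr <- simulate_chemostat(rp, feed_schedule("intermittent"), kp,
                           duration = 0.9, dt = 1)
  starv <- vapply(c(20, 53, 90, 150), function(th) {
    k2 <- kinetic_params(starvation_threshold = th)
    regime_residence(tr$time_s, tr$glucose_umol_L, k2)[["starvation"]]
  }, numeric(1))
  expect_true(all(diff(starv) >= 0))
  expect_gt(starv[4], starv[1])
})

test_that("semilog slope recovers decay constants", {
  t <- 0:200
  g <- 150 * exp(-0.02 * t)
  s <- semilog_slope(t, g)
  expect_equal(s$slope_per_s, 0.02, tolerance = 1e-12)
  expect_equal(s$slope_per_min, 1.2, tolerance = 1e-12)
  expect_equal(s$r_squared, 1)

  ## 2% multiplicative noise, n = 120
  set.seed(42)
  t2 <- 0:119
  g2 <- 150 * exp(-0.02 * t2) * (1 + rnorm(120, 0, 0.02))
  s2 <- semilog_slope(t2, g2)
  expect_lt(abs(s2$slope_per_s - 0.02) / 0.02, 0.10)

  s3 <- semilog_slope(t, rep(5, length(t)))
  expect_equal(s3$slope_per_s, 0)

  expect_error(semilog_slope(t, g - 150), "positive")
  expect_error(semilog_slope(0:1, c(1, 2)), "3 points")
})

test_that("deep-limitation depletion slope approaches q_max X / K_M", {
  ## with the feed off and Cs << K_M the balance is first order with
  ## volumetric constant q_max X / K_M (plus the vanishing outflow)
  k <- kinetic_params()
  sch <- feed_schedule("intermittent", cycle_period = 30,
                       off_duration = 29, on_rate = 0.01)
  x0 <- 11.1
  tr <- simulate_chemostat(rp, sch, k,
                           init = c(glucose = 50, biomass = x0),
                           duration = 4 / 60, dt = 1,
                           freeze_biomass = TRUE)
  sel <- tr$glucose_umol_L > 0 & tr$glucose_umol_L < k$K_M / 20 &
    tr$time_s <= 240
  s <- semilog_slope(tr$time_s[sel], tr$glucose_umol_L[sel])
  k_theory <- k$q_max * x0 * 1000 / k$K_M / 3600   # per s
  expect_lt(abs(s$slope_per_s - k_theory) / k_theory, 0.05)
})

test_that("minimum glucose follows uptake scaling and feed state", {
  ## monotone decay: the minimum is the last value
  t <- 0:100
  tr_df <- data.frame(time_s = t, glucose_umol_L = 100 * exp(-0.01 * t))
  m <- minimum_glucose(tr_df)
  expect_equal(m$glucose, 100 * exp(-1))
  expect_equal(m$time_s, 100)

  ## 2-min feed-off: uptake scaled to 60% leaves a higher minimum
  ## than full kinetics, both below the starting level
  sch <- feed_schedule("intermittent", cycle_period = 9,
                       off_duration = 2, on_rate = 3.64)
  run_min <- function(scale) {
    k2 <- kinetic_params(q_max = kp$q_max * scale)
    tr <- simulate_chemostat(rp, sch, k2,
                             init = c(glucose = 150, biomass = 11.1),
                             duration = 2 / 60, dt = 1,
                             freeze_biomass = TRUE)
    minimum_glucose(tr, window = c(0, 120))$glucose
  }
  m_full <- run_min(1)
  m_60 <- run_min(0.6)
  expect_lt(m_60, 150)
  expect_gt(m_60, m_full)

  ## feed never off at steady state: minimum equals the steady value
  ss <- monod_steady_state(average_dilution(feed_schedule("continuous"),
                                            rp), kp, 22.5)
  tr_ss <- simulate_chemostat(rp, feed_schedule("continuous"), kp,
                              duration = 0.2, dt = 1)
  expect_equal(minimum_glucose(tr_ss)$glucose, ss$glucose,
               tolerance = 1e-4)
  expect_error(minimum_glucose(tr_ss, window = c(1e6, 2e6)), "window")
})

test_that("parameter constructors validate their invariants", {
  expect_error(reactor_params(working_volume = -1), "positive")
  expect_error(feed_schedule("intermittent", cycle_period = 2,
                             off_duration = 3), "shorter")
  expect_error(feed_schedule("intermittent", on_rate = 0), "on_rate")
  expect_error(kinetic_params(yield_xs = 1.2), "yield")
  expect_error(kinetic_params(starvation_threshold = 300), "below")
  expect_error(simulate_chemostat(rp, feed_schedule("continuous"),
                                  kp, duration = 1, dt = -1),
               "dt")
  ## schedule events finer than dt
  expect_error(simulate_chemostat(rp, feed_schedule("intermittent"),
                                  kp, duration = 0.5, dt = 7),
               "multiples of dt")
})
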