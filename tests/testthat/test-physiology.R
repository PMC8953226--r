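test_that("specific rates reproduce the steady-state arithmetic", {
  ## q_glucose = D / (Y_xs * M_glc) when residual glucose ~ 0
  rec <- specific_rates(D = 0.101, biomass = 0.494 * 22.5,
                        feed_glucose = 22.5, residual_glucose = 0,
                        q_o2_vol = 2.52 * 0.494 * 22.5,
                        q_co2_vol = 2.71 * 0.494 * 22.5)
  expect_equal(rec$q_glucose, 0.101 / (0.494 * 0.18016),
               tolerance = 1e-12)
  expect_equal(rec$q_glucose, 1.13, tolerance = 0.005)
  expect_equal(rec$Y_xs, 0.494, tolerance = 1e-12)
  ## oxygen yield on glucose
  expect_equal(rec$Y_o2_glucose, 2.52 / rec$q_glucose,
               tolerance = 1e-12)
  expect_equal(2.52 / 1.13, 2.23, tolerance = 1e-3)

  ## zero gas consumption
  rec0 <- specific_rates(D = 0.1, biomass = 10, feed_glucose = 22.5,
                         q_o2_vol = 0, q_co2_vol = 0)
  expect_equal(rec0$Y_o2_glucose, 0)

  expect_error(specific_rates(D = 0.1, biomass = 0,
                              feed_glucose = 22.5), "biomass")
  expect_error(specific_rates(D = -0.1, biomass = 1,
                              feed_glucose = 22.5), "non-negative")
})

test_that("self-consistency: q_glucose * Y_xs * M_glc = D at zero residual", {
  for (d in c(0.05, 0.1, 0.2)) {
    rec <- specific_rates(D = d, biomass = 9, feed_glucose = 20)
    expect_equal(rec$q_glucose * rec$Y_xs * 0.18016, d,
                 tolerance = 1e-12)
  }
})

test_that("degree of reduction arithmetic", {
  expect_equal(degree_of_reduction(1, 2, 1, 0), 4)    # glucose C-mol
  expect_equal(degree_of_reduction(1, 1.8, 0.5, 0.2), 4.2)
  expect_equal(degree_of_reduction(1, 4, 0, 0), 8)    # methane
})

test_that("recoveries close exactly on a stoichiometric flow set and respond to losses", {
  ## construct conservation: fraction f of glucose carbon to biomass,
  ## the rest to CO2; oxygen closes the electron balance; ammonia
  ## supplies exactly the biomass nitrogen
  comp <- yeast_biomass_composition()
  m_x <- (12.011 + 1.8 * 1.008 + 0.5 * 15.999 + 0.2 * 14.007)
  q_glc <- 1.2
  d <- 0.1
  r_x <- d * 1000 / m_x
  q_co2 <- 6 * q_glc - r_x
  q_o2 <- (4 * 6 * q_glc - comp$gamma * r_x) / 4
  q_nh3 <- 0.2 * r_x
  x <- 10
  rec <- specific_rates(D = d, biomass = x,
                        feed_glucose = q_glc * x * 0.18016 / d,
                        q_o2_vol = q_o2 * x, q_co2_vol = q_co2 * x,
                        q_nh3_vol = q_nh3 * x)
  bal <- recoveries(rec)
  expect_equal(bal$carbon, 100, tolerance = 1e-9)
  expect_equal(bal$nitrogen, 100, tolerance = 1e-9)
  expect_equal(bal$ave, 100, tolerance = 1e-9)

  ## dropping 5% of the CO2 lowers carbon recovery by the CO2 share
  rec2 <- specific_rates(D = d, biomass = x,
                         feed_glucose = q_glc * x * 0.18016 / d,
                         q_o2_vol = q_o2 * x,
                         q_co2_vol = 0.95 * q_co2 * x,
                         q_nh3_vol = q_nh3 * x)
  bal2 <- recoveries(rec2)
  expect_equal(bal2$carbon, 100 - 5 * q_co2 / (6 * q_glc),
               tolerance = 1e-9)

  ## available-electron recovery invariant under rescaling all flows
  ## (tripled dilution, feed supply and gas flows at fixed biomass)
  rec3 <- specific_rates(D = d * 3, biomass = x,
                         feed_glucose = q_glc * x * 0.18016 / d,
                         q_o2_vol = q_o2 * x * 3,
                         q_co2_vol = q_co2 * x * 3,
                         q_nh3_vol = q_nh3 * x * 3)
  expect_equal(recoveries(rec3)$ave, bal$ave, tolerance = 1e-9)
  expect_equal(recoveries(rec3)$carbon, bal$carbon, tolerance = 1e-9)
})

test_that("ATP demand estimate follows the disclosed formula", {
  ## reference steady-state rates
  rs <- qatp_estimate(1.13, 2.52)
  expect_equal(rs$q_atp, 2 * 1.13 + 2 * 1.08 * 2.52, tolerance = 1e-12)
  expect_equal(rs$q_atp, 7.70, tolerance = 1e-3)
  ## dynamic steady-state rates and the relative increase
  ds <- qatp_estimate(1.12, 2.63)
  expect_equal(ds$q_atp, 7.92, tolerance = 1e-3)
  expect_equal((ds$q_atp / rs$q_atp - 1) * 100, 2.9, tolerance = 0.1)
  ## no oxygen: substrate-level phosphorylation only
  expect_equal(qatp_estimate(1.5, 0)$q_atp, 3.0)
  expect_error(qatp_estimate(-1, 1), "non-negative")
})

test_that("storage-carbon yield effect is the linear carbon ratio", {
  expect_equal(storage_carbon_yield_effect(0.0016, 0.04), 0.04)
  expect_equal(storage_carbon_yield_effect(0), 0)
  expect_equal(storage_carbon_yield_effect(0.002),
               2 * storage_carbon_yield_effect(0.001))
  expect_error(storage_carbon_yield_effect(1, 0), "positive")
})

test_that("moment-matched replicate reconstruction is exact", {
  r <- replicates_from_moments(2.23, 0.03, 3)
  expect_equal(mean(r), 2.23)
  expect_equal(sd(r), 0.03)
  r5 <- replicates_from_moments(10, 1.7, 5)
  expect_equal(mean(r5), 10)
  expect_equal(sd(r5), 1.7)
  expect_equal(replicates_from_moments(4, 0, 3), rep(4, 3))
})

test_that("Welch comparison matches the reference implementation", {
  ## identical groups
  w0 <- welch_compare(c(1, 2, 3), c(1, 2, 3))
  expect_equal(w0$p_value, 1)
  expect_equal(w0$percent_change, 0)
  expect_equal(w0$label, "n.s.")

  ## reconstructed oxygen-yield replicates: +4.9% between steady states
  a <- replicates_from_moments(2.23, 0.03, 3)
  b <- replicates_from_moments(2.34, 0.03, 3)
  w <- welch_compare(a, b)
  expect_equal(w$percent_change, (2.34 - 2.23) / 2.23 * 100)
  expect_equal(round(w$percent_change, 1), 4.9)
  expect_true(w$significant)

  ## extreme separation
  wx <- welch_compare(rnorm(5), rnorm(5) + 100)
  expect_lt(wx$p_value, 1e-3)

  ## 100 random group pairs against stats::t.test
  set.seed(11)
  for (i in 1:100) {
    na <- sample(2:8, 1); nb <- sample(2:8, 1)
    a <- rnorm(na, sd = runif(1, 0.1, 2))
    b <- rnorm(nb, mean = runif(1, -1, 1), sd = runif(1, 0.1, 2))
    w <- welch_compare(a, b)
    ref <- stats::t.test(a, b, var.equal = FALSE)
    expect_equal(w$p_value, ref$p.value, tolerance = 1e-10)
  }

  expect_error(welch_compare(1, c(1, 2)), "two replicates")
})

test_that("cycle-averaged dilution matches the operating schedules", {
  ## 7 of 9 minutes at 3.64 mL/min in 1.7 L
  d_int <- average_dilution(feed_schedule("intermittent"), rp)
  expect_equal(d_int, 3.64 * 7 / 9 * 60 / 1700)
  expect_equal(d_int, 0.1, tolerance = 2e-3)
  ## continuous reference
  d_cont <- average_dilution(feed_schedule("continuous"), rp)
  expect_equal(d_cont, 0.1, tolerance = 2e-3)
  ## the two agree within a percent (the schedule preserves D)
  expect_equal(d_int, d_cont, tolerance = 0.01)
  ## required on-rate to hold the continuous rate over the duty cycle
  expect_equal(required_on_rate(2.83, 9, 2), 2.83 * 9 / 7)
  expect_equal(required_on_rate(2.83, 9, 2), 3.64, tolerance = 1e-3)
})
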