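test_that("AMPA waveform is peak-normalized with the analytic peak time", {
  p <- list(tau1 = 2, tau2 = 10, weight = 0.5)
  expect_equal(ampa_g(0, p), 0)
  tstar <- ampa_peak_time(2, 10)
  expect_equal(ampa_g(tstar, p), 0.5)
  expect_lt(ampa_g(tstar - 0.5, p), 0.5)
  expect_lt(ampa_g(tstar + 0.5, p), 0.5)
  expect_lt(ampa_g(200, p), 1e-8)
  expect_equal(ampa_g(-1, p), 0)
  expect_error(ampa_g(1, list(tau1 = 5, tau2 = 2, weight = 1)),
               "tau2 > tau1")
})

test_that("NMDA waveform normalizes and the Mg block follows the sigmoid", {
  p <- nmda_defaults(weight = 1)
  expect_equal(nmda_g(0, -65, p), 0, tolerance = 1e-12)
  # Mg = 0: block factor is 1; waveform peaks at exactly the weight
  p0 <- nmda_defaults(weight = 1, mg = 0)
  tg <- seq(0, 20 * p0$tau3, by = 0.01)
  expect_equal(max(nmda_g(tg, -65, p0)), 1, tolerance = 1e-6)
  # block factor at 0 mV, 1 mM: 1 / (1 + 1/3.57)
  expect_equal(mg_block(0, 1), 1 / (1 + 1 / 3.57))
  # monotone increasing in voltage
  v <- seq(-90, 40, by = 1)
  expect_true(all(diff(mg_block(v, 1)) > 0))
  expect_equal(mg_block(v, 0), rep(1, length(v)))
})

test_that("NMDA peak normalizer matches limits and scaling laws", {
  # near-double-exponential limit (w -> 1): analytic peak of
  # exp(-t/tau3) - exp(-t/tau1)
  p <- list(tau1 = 1, tau2 = 50, tau3 = 100, w = 1 - 1e-9)
  tstar <- ampa_peak_time(1, 100)
  analytic <- exp(-tstar / 100) - exp(-tstar / 1)
  expect_equal(nmda_peak_normalizer(p), analytic, tolerance = 1e-6)
  # dense-grid maximum equals the normalizer for random valid parameters
  set.seed(4)
  for (i in 1:100) {
    taus <- sort(stats::runif(3, 0.5, 300))
    if (diff(taus)[1] < 1e-3 || diff(taus)[2] < 1e-3) next
    pp <- list(tau1 = taus[1], tau2 = taus[2], tau3 = taus[3],
               w = stats::runif(1, 0.05, 0.95))
    tg <- seq(0, 10 * pp$tau3, length.out = 400001)
    num <- pp$w * exp(-tg / pp$tau3) + (1 - pp$w) * exp(-tg / pp$tau2) -
      exp(-tg / pp$tau1)
    expect_equal(nmda_peak_normalizer(pp), max(num), tolerance = 1e-6)
  }
  # scaling all taus leaves the normalizer unchanged
  p1 <- list(tau1 = 2, tau2 = 30, tau3 = 120, w = 0.6)
  p2 <- list(tau1 = 6, tau2 = 90, tau3 = 360, w = 0.6)
  expect_equal(nmda_peak_normalizer(p1), nmda_peak_normalizer(p2),
               tolerance = 1e-9)
  expect_error(nmda_peak_normalizer(list(tau1 = 5, tau2 = 2, tau3 = 10,
                                         w = 0.5)), "tau3 > tau2")
})

test_that("EPSP measurement handles geometry and degenerate traces", {
  # triangular bump: 10 ms rise to 1 mV, 30 ms fall -> HHW 20 ms
  t <- seq(0, 40, by = 0.1)
  v <- ifelse(t <= 10, t / 10, pmax(1 - (t - 10) / 30, 0)) - 65
  m <- measure_epsp(t, v)
  expect_equal(m$peak_mv, 1)
  expect_equal(m$hhw_ms, 20, tolerance = 0.01)
  expect_error(measure_epsp(t, rep(-65, length(t))), "flat")
  expect_error(measure_epsp(t, -65 + t / 40), "crossing")
})

test_that("calibration reproduces its targets and is monotone", {
  expect_equal(calibrate_synapse(0, 40)$ampa$weight, 0)
  k1 <- calibrate_synapse(0.3, 40.9, layer = "radiatum")
  expect_lt(abs(k1$achieved$peak_mv - 0.3) / 0.3, 0.02)
  expect_lt(abs(k1$achieved$hhw_ms - 40.9) / 40.9, 0.02)
  k2 <- calibrate_synapse(0.6, 40.9, layer = "radiatum")
  expect_gt(k2$ampa$weight, k1$ampa$weight)
  expect_error(calibrate_synapse(0.3, 1), "not bracketed")
})
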