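test_that("base-rate calibration has the right limits", {
  expect_equal(calibrate_base_rate(0), 0)
  # vanishing refractory period: plain Poisson, base = target
  expect_equal(calibrate_base_rate(5, 1e-4), 5, tolerance = 1e-3)
  b <- calibrate_base_rate(5, 35)
  expect_gt(b, 5)
  expect_error(calibrate_base_rate(2000, 35), "ceiling")
  expect_error(renewal_params(-1), ">= 0")
})

test_that("renewal sources realize their target rates", {
  # ~25k spikes: the 2% band sits ~4 standard errors out
  r <- renewal_raster(1000, ec_source_params(), 5000, seed = 101)
  expect_lt(abs(mean_rate(r) - 5) / 5, 0.02)
  r2 <- renewal_raster(3000, dg_surrogate_params(), 5000, seed = 102)
  expect_lt(abs(mean_rate(r2) - 0.62) / 0.62, 0.03)
  expect_length(generate_renewal_train(renewal_params(0), 1000), 0)
})

test_that("the refractory period leaves its signature on the ISIs", {
  isis <- unlist(lapply(1:400, function(i) {
    diff(generate_renewal_train(ec_source_params(), 5000,
                                seed = 1000 + i))
  }))
  expect_gt(length(isis), 5000)
  # deficit of short ISIs: not exponential (KS rejects plain Poisson)
  ks <- stats::ks.test(isis, "pexp", 1 / mean(isis))
  expect_lt(ks$p.value, 0.01)
  frac_short <- mean(isis < 35)
  frac_short_exp <- stats::pexp(35, 1 / mean(isis))
  expect_lt(frac_short, frac_short_exp)
  # refractoriness regularizes: ISI CV below 1
  expect_lt(stats::sd(isis) / mean(isis), 1)
})

test_that("per-neuron substreams make rasters order-independent", {
  a <- renewal_raster(5, ec_source_params(), 2000, seed = 9)
  b <- renewal_raster(5, ec_source_params(), 2000, seed = 9)
  expect_identical(a$trains, b$trains)
  # a raster over ids 3..4 reproduces the tail of the id 0..4 raster
  c2 <- renewal_raster(2, ec_source_params(), 2000, seed = 9, ids = 3:4)
  expect_identical(c2$trains, a$trains[4:5])
})

test_that("binarization clips, is idempotent, and respects bin edges", {
  r <- spike_raster(list(c(0.4, 0.6), numeric(0), c(2.0, 3.5)), 5,
                    population = "CA3")
  b <- bin_spikes(r)
  expect_equal(b$n_bins, 5)
  expect_equal(b$x[1, ], c(1L, 0L, 0L, 0L, 0L))  # two spikes clip to 1
  expect_equal(b$x[2, ], rep(0L, 5))
  expect_equal(b$sigma[2], 0)
  expect_equal(b$x[3, ], c(0L, 0L, 1L, 1L, 0L))
  # row sums equal spike counts when no bin holds 2 spikes
  r5 <- renewal_raster(20, ec_source_params(), 5000, seed = 77)
  b5 <- bin_spikes(r5)
  n_sp <- lengths(r5$trains)
  collisions <- n_sp - rowSums(b5$x)
  expect_true(all(collisions >= 0))
  expect_lt(sum(collisions), sum(n_sp) * 0.02)
  expect_error(bin_spikes(r, bin_ms = 0), "> 0")
})
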