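test_that("an empty network with no drive stays silent", {
  toy <- make_toy_network(0, 3, "LPP")
  ras <- simulate_network(toy$connectome, list(), toy$layout,
                          sim_config(duration = 300),
                          kinetics = ref_kinetics())
  expect_equal(sum(lengths(ras$trains)), 0)
})

test_that("a single perforant-path spike evokes the calibrated EPSP", {
  toy <- make_toy_network(1, 1, "LPP", "single", separation_mm = 1)
  src <- spike_raster(list(500), 1500, population = "EC", ids = 0L)
  cfg <- sim_config(duration = 1500, record_cells = 0L, record_every = 4L)
  ras <- simulate_network(toy$connectome, list(EC = src), toy$layout, cfg,
                          presets = "weakly_adapting",
                          kinetics = ref_kinetics())
  expect_equal(sum(lengths(ras$trains)), 0)  # subthreshold
  v <- attr(ras, "v")
  tt <- attr(ras, "t_rec")
  keep <- tt > 400
  m <- measure_epsp(tt[keep], v[keep, 1],
                    baseline_end_ms = 500 + compute_delay(1, "LPP"))
  expect_lt(abs(m$peak_mv - 0.30) / 0.30, 0.03)
})

test_that("simulation output is deterministic bit-for-bit", {
  toy <- make_toy_network(5, 5, "MF", "single", separation_mm = 1,
                          weight = 5)
  src <- renewal_raster(5, renewal_params(2, 35), 1000, seed = 3,
                        population = "DG")
  cfg <- sim_config(duration = 1000)
  a <- simulate_network(toy$connectome, list(DG = src), toy$layout, cfg,
                        kinetics = ref_kinetics())
  b <- simulate_network(toy$connectome, list(DG = src), toy$layout, cfg,
                        kinetics = ref_kinetics())
  expect_identical(a$trains, b$trains)
})

test_that("zero weight scaling is equivalent to removing the pathway", {
  toy <- make_toy_network(4, 4, "MF", "single", separation_mm = 1,
                          weight = 5)
  src <- renewal_raster(4, renewal_params(3, 35), 800, seed = 6,
                        population = "DG")
  cfg <- sim_config(duration = 800)
  silenced <- scale_weights(toy$connectome, "MF", 0)
  r0 <- simulate_network(silenced, list(DG = src), toy$layout, cfg,
                         kinetics = ref_kinetics())
  removed <- toy$connectome
  removed$edges <- removed$edges[0, ]
  r1 <- simulate_network(removed, list(DG = src), toy$layout, cfg,
                         kinetics = ref_kinetics())
  expect_identical(r0$trains, r1$trains)
  expect_equal(sum(lengths(r0$trains)), 0)
})

test_that("halving dt moves response spikes by less than 0.5 ms", {
  toy <- make_toy_network(10, 10, "MF", "single", separation_mm = 1,
                          weight = 5)
  src <- spike_raster(rep(list(100), 10), 400, population = "DG",
                      ids = 0:9)
  r1 <- simulate_network(toy$connectome, list(DG = src), toy$layout,
                         sim_config(duration = 400, dt = 0.025),
                         kinetics = ref_kinetics())
  r2 <- simulate_network(toy$connectome, list(DG = src), toy$layout,
                         sim_config(duration = 400, dt = 0.0125),
                         kinetics = ref_kinetics())
  expect_equal(lengths(r1$trains), lengths(r2$trains))
  d <- abs(unlist(r1$trains) - unlist(r2$trains))
  expect_true(all(d < 0.5))
})

test_that("shared input correlates downstream spiking at zero lag", {
  toy <- make_toy_network(1, 2, "MF", "fan", separation_mm = 1,
                          weight = 5)
  src <- renewal_raster(1, renewal_params(4, 35), 5000, seed = 8,
                        population = "DG")
  ras <- simulate_network(toy$connectome, list(DG = src), toy$layout,
                          sim_config(duration = 5000),
                          kinetics = ref_kinetics())
  b <- bin_spikes(ras)
  expect_true(all(b$sigma > 0))
  r <- normalized_xcorr(b$x[1, ], b$x[2, ], 5)
  expect_gt(max(r$value), 0)
})
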