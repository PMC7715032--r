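test_that("zero-cluster fixtures are pure background", {
  lay <- build_layout(0, 200, 0, seed = 23)
  spec <- cluster_spec(n_clusters = 0, background_rate = 2,
                       duration = 5000)
  cr <- make_cluster_raster(spec, lay, seed = 24)
  expect_equal(nrow(cr$events), 0)
  rates <- lengths(cr$raster$trains) / 5
  ref <- renewal_raster(200, renewal_params(2, 35), 5000, seed = 25)
  p <- suppressWarnings(
    stats::ks.test(rates, lengths(ref$trains) / 5)$p.value)
  expect_gt(p, 0.01)
})

test_that("cluster fixtures are reproducible with ground truth", {
  lay <- build_layout(0, 150, 0, seed = 26)
  spec <- cluster_spec(n_clusters = 2, events_per_cluster = 10)
  a <- make_cluster_raster(spec, lay, seed = 27)
  b <- make_cluster_raster(spec, lay, seed = 27)
  expect_identical(a$raster$trains, b$raster$trains)
  expect_identical(a$events, b$events)
  expect_equal(nrow(a$events), 20)
  expect_true(all(c("cluster", "time_ms", "center_long",
                    "center_trans") %in% names(a$events)))
})

test_that("full participation without jitter maximizes in-cluster synchrony", {
  lay <- build_layout(0, 80, 0, seed = 28)
  dgp <- layout_population(lay, "DG")
  spec <- cluster_spec(n_clusters = 1, events_per_cluster = 15,
                       spatial_sd = 0.4, jitter_sd = 0, participation = 1,
                       background_rate = 1, duration = 5000,
                       centers = matrix(c(5, 0.75), 1))
  cr <- make_cluster_raster(spec, lay, seed = 29)
  b <- bin_spikes(cr$raster)
  d2 <- (dgp$longitudinal - 5)^2 + (dgp$transverse - 0.75)^2
  ord <- order(d2)
  inside <- ord[1:2]                       # the two cells at the center
  outside <- rev(ord)[b$sigma[rev(ord)] > 0][1:6]  # far, active cells
  outside <- outside[!is.na(outside)]
  expect_gte(length(outside), 2)
  xc0 <- function(i, j) {
    r <- normalized_xcorr(b$x[i, ], b$x[j, ], 0)
    r$value[r$lag == 0]
  }
  in_val <- xc0(inside[1], inside[2])
  out_vals <- utils::combn(outside[1:min(6, length(outside))], 2,
                           function(ij) xc0(ij[1], ij[2]))
  expect_gt(in_val, max(out_vals))
})

test_that("toy networks wire exactly as requested", {
  toy <- make_toy_network(1, 1, "MF", "single", separation_mm = 2.7)
  expect_equal(nrow(toy$connectome$edges), 1)
  expect_equal(toy$connectome$edges$delay_ms, 10)  # 2.7 mm / 0.27 m/s
  expect_equal(toy$connectome$edges$layer, "lucidum")
  empty <- make_toy_network(0, 0, "MF")
  expect_equal(nrow(empty$connectome$edges), 0)
  fan <- make_toy_network(1, 3, "ASSOC", "fan")
  expect_equal(nrow(fan$connectome$edges), 3)
  expect_equal(unique(fan$connectome$edges$pre_id), 0)
  expect_equal(fan$connectome$edges$layer,
               rep("radiatum", 3))
})
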