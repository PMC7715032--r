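test_that("normalized_xcorr equals a brute-force oracle to 1e-12", {
  set.seed(12)
  worst <- 0
  for (i in 1:100) {
    N <- sample(50:200, 1)
    x <- stats::rbinom(N, 1, stats::runif(1, 0.05, 0.4))
    y <- stats::rbinom(N, 1, stats::runif(1, 0.05, 0.4))
    if (sum(x) %in% c(0, N) || sum(y) %in% c(0, N)) next
    K <- sample(3:15, 1)
    worst <- max(worst,
                 max(abs(normalized_xcorr(x, y, K)$value -
                           brute_xcorr(x, y, K))))
  }
  expect_lt(worst, 1e-12)
})

test_that("autocorrelation is 1 at lag 0 and hand examples check out", {
  set.seed(3)
  x <- stats::rbinom(300, 1, 0.2)
  a <- normalized_xcorr(x, x, 10)
  expect_equal(a$value[a$lag == 0], 1)
  # x = [1,0,0,0], y = [0,1,0,0]: value at lag +1 is 11/9 = 1.2222
  r <- normalized_xcorr(c(1, 0, 0, 0), c(0, 1, 0, 0), 2)
  expect_equal(r$value[r$lag == 1], 11 / 9, tolerance = 1e-12)
  expect_equal(r$overlap, c(2, 3, 4, 3, 2))
  expect_error(normalized_xcorr(rep(0, 10), x[1:10], 2), "degenerate")
})

test_that("shifting a train shifts the correlation peak exactly", {
  set.seed(9)
  x <- stats::rbinom(500, 1, 0.15)
  for (k in c(3, 7)) {
    y <- c(rep(0, k), x[1:(500 - k)])
    r <- normalized_xcorr(x, y, 20)
    expect_equal(r$lag[which.max(r$value)], k)
  }
})

test_that("maps are point-symmetric with correct single-pair entries", {
  lay <- build_layout(0, 0, 40, seed = 13)
  ca3 <- layout_population(lay, "CA3")
  set.seed(14)
  trains <- lapply(1:40, function(i) sort(stats::runif(30, 0, 3000)))
  # make neurons 1 and 2 fire identically
  trains[[2]] <- trains[[1]]
  ras <- spike_raster(trains, 3000, population = "CA3")
  m <- accumulate_map(ras, lay, max_lag_ms = 20)
  # array-flip symmetry (continuous positions: no bin-edge ties)
  v <- m$value
  vf <- v[rev(seq_len(dim(v)[1])), rev(seq_len(dim(v)[2])),
          rev(seq_len(dim(v)[3]))]
  expect_identical(v, vf)
  expect_identical(m$count, m$count[rev(seq_len(nrow(m$count))),
                                    rev(seq_len(ncol(m$count)))])
  # the coincident pair contributes correlation 1 at lag 0 in its bin
  dl <- ca3$longitudinal[2] - ca3$longitudinal[1]
  dtr <- ca3$transverse[2] - ca3$transverse[1]
  bi <- floor(dl / 0.1) + length(m$d_long) / 2 + 1
  bj <- floor(dtr / 0.1) + length(m$d_trans) / 2 + 1
  pair_vals <- m$value[bi, bj, m$lag_ms == 0] * m$count[bi, bj]
  expect_gte(pair_vals, 1 - 1e-9)  # >= the coincident pair's 1
})

test_that("null maps stay centered and below the analytic bound", {
  lay <- build_layout(0, 0, 150, seed = 15)
  ras <- renewal_raster(150, ec_source_params(), 5000, seed = 16,
                        population = "CA3")
  m <- accumulate_map(ras, lay, max_lag_ms = 40)
  expect_lt(abs(mean(m$value, na.rm = TRUE)), 1e-3)
  nb <- map_noise_bound(m)
  expect_equal(sum(abs(m$value) > nb$bound, na.rm = TRUE), 0)
  expect_lt(peak_correlation(m), max(nb$bound, na.rm = TRUE))
})

test_that("local maps admit pairs by section membership", {
  lay <- build_layout(0, 0, 60, seed = 17)
  ras <- renewal_raster(60, renewal_params(8, 35), 2000, seed = 18,
                        population = "CA3")
  grid <- section_grid(2)
  memb <- section_membership(lay, grid)
  key <- "middle.CA3b"
  lm <- local_map(ras, lay, "middle", "CA3b", grid = grid,
                  max_lag_ms = 10)
  gm <- accumulate_map(ras, lay, max_lag_ms = 10)
  in_sec <- memb[, key]
  n_in <- sum(in_sec)
  n_out <- sum(!in_sec)
  # pairs with >= 1 member inside: total - pairs entirely outside
  expected_pairs <- choose(60, 2) - choose(n_out, 2)
  expect_equal(lm$n_pairs, expected_pairs)
  expect_lt(lm$n_pairs, gm$n_pairs)
  # a neuron in two sections contributes to both local maps
  memb_rows <- rowSums(memb[, startsWith(colnames(memb), "middle"),
                            drop = FALSE])
  expect_error(local_map(ras, lay, "middle", "XX"), "unknown section")
})

test_that("cross-sections slice correctly and threshold at 30%", {
  lay <- build_layout(0, 0, 50, seed = 19)
  ras <- renewal_raster(50, renewal_params(6, 35), 2000, seed = 20,
                        population = "CA3")
  m <- accumulate_map(ras, lay, max_lag_ms = 10)
  sl <- cross_section(m, "longitudinal-temporal", at = 0)
  k <- length(m$d_trans) / 2 + 1
  expect_equal(unclass(sl)[, ], m$value[, k, ], ignore_attr = TRUE)
  th <- cross_section(m, "longitudinal-temporal", at = 0,
                      threshold = 0.30)
  mx <- max(abs(sl), na.rm = TRUE)
  nz <- !is.na(th) & th != 0
  expect_true(all(abs(th[nz]) >= 0.30 * mx))
  zeroed <- !is.na(sl) & abs(sl) < 0.30 * mx
  expect_true(all(th[zeroed] == 0))
  sl2 <- cross_section(m, "longitudinal-transverse", at = 0)
  expect_equal(unclass(sl2)[, ], m$value[, , m$lag_ms == 0],
               ignore_attr = TRUE)
  expect_error(cross_section(m, "longitudinal-transverse", at = 1e6),
               "out of range")
})

test_that("population lag detects imposed delays", {
  lay <- build_layout(0, 100, 100, seed = 21)
  dgp <- layout_population(lay, "DG")
  ca3p <- layout_population(lay, "CA3")
  set.seed(22)
  base <- lapply(1:100, function(i) sort(stats::runif(40, 0, 2900)))
  dg <- spike_raster(base, 3000, population = "DG", ids = dgp$id)
  # CA3 mirrors DG at matched longitudinal positions, delayed 12 ms
  nn <- vapply(ca3p$longitudinal, function(l)
    which.min(abs(dgp$longitudinal - l)), integer(1))
  ca3 <- spike_raster(lapply(nn, function(i) base[[i]] + 12), 3000,
                      population = "CA3", ids = ca3p$id)
  r <- population_lag(dg, ca3, lay)
  expect_equal(r$lag_ms, 12)
})
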