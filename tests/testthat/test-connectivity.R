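test_that("synapse budgets reproduce the published input counts", {
  expect_equal(synapse_budget(1)[["lacunosum_distal"]], 1658L)
  expect_equal(synapse_budget(1)[["lacunosum_proximal"]], 1105L)
  expect_equal(synapse_budget(0)[["lacunosum_distal"]], 0L)
  expect_equal(synapse_budget(0)[["lacunosum_proximal"]], 0L)
  expect_equal(synapse_budget(0)[["radiatum"]], 11241L)
  expect_equal(synapse_budget(0)[["oriens"]], 7147L)
  expect_equal(synapse_budget(1)[["radiatum"]], 11281L)
  expect_equal(synapse_budget(1)[["oriens"]], 17893L)
  # counts are density x interpolated length (radiatum proximal length
  # back-solves to ~3,114 um at 3.61 synapses/um)
  ref <- ca3_budget_reference()
  expect_equal(ref$length_proximal[["radiatum"]], 11241 / 3.61)
  expect_equal(synapse_budget(0)[["radiatum"]],
               round(3.61 * ref$length_proximal[["radiatum"]]))
  expect_error(synapse_budget(1.5), "\\[0, 1\\]")
})

test_that("perforant-path fields are topographic, normalized Gaussians", {
  # span read as +/- 2 sd: extent 1.25 mm -> sd 0.3125 mm
  f <- pp_field_for(5, extent_mm = 1.25)
  expect_equal(f$sd, 0.3125)
  # topographic monotonicity of field centers
  centers <- vapply(c(1, 3, 5, 7, 9),
                    function(l) pp_field_for(l)$center, numeric(1))
  expect_true(all(diff(centers) > 0))
  # truncated density integrates to 1 over the target domain
  g <- seq(0, 10, length.out = 20001)
  dens <- gaussian_field_density(pp_field_for(0.3), g)
  # trapezoid rule (the truncated density steps at the domain edge)
  integ <- sum((dens[-1] + dens[-length(dens)]) / 2) * (g[2] - g[1])
  expect_equal(integ, 1, tolerance = 1e-3)
  expect_error(pp_field_for(5, extent_mm = 0), "> 0")
})

test_that("postsynaptic sampling meets budgets and follows the weights", {
  expect_length(sample_inputs_postsynaptic(c(1, 2), 0), 0)
  expect_error(sample_inputs_postsynaptic(c(0, 0), 5), "all-zero")
  draws <- sample_inputs_postsynaptic(c(0.75, 0.25), 1e4, seed = 5)
  expect_length(draws, 1e4)
  f1 <- mean(draws == 1)
  se <- sqrt(0.75 * 0.25 / 1e4)
  expect_lt(abs(f1 - 0.75), 3 * se)
  # probability-zero candidates are never drawn
  draws2 <- sample_inputs_postsynaptic(c(1, 0, 2), 5000, seed = 6)
  expect_false(any(draws2 == 2))
})

test_that("fiber trajectories start on level, deviate temporal-ward", {
  p0 <- mf_trajectory(5, noise_sd = 0)
  expect_equal(p0$longitudinal[1], 5)
  # deterministic without noise
  expect_identical(p0, mf_trajectory(5, noise_sd = 0))
  # distal deviation is toward the temporal pole (negative)
  expect_lte(p0$longitudinal[length(p0$longitudinal)] - 5, -0.4)
  expect_true(all(diff(p0$arc) > 0))
  # mean over noisy fibers matches the noiseless path pointwise
  reps <- sapply(1:300, function(s)
    mf_trajectory(5, noise_sd = 0.05, seed = s)$longitudinal)
  se <- apply(reps, 1, stats::sd) / sqrt(ncol(reps))
  dev <- abs(rowMeans(reps) - p0$longitudinal)
  expect_true(all(dev <= 3 * pmax(se, 1e-9) + 1e-9))
})

test_that("Poisson synapse placement matches the region means", {
  # zero-length path places nothing
  p <- mf_trajectory(5, noise_sd = 0)
  p$transverse <- p$transverse[1]
  p$longitudinal <- p$longitudinal[1]
  p$arc <- 0
  expect_equal(nrow(mf_place_synapses(p)), 0)
  # 1.62 mm inside CA3c: counts Poisson with mean 10
  straight <- structure(list(transverse = seq(0, 0.5, length.out = 50),
                             longitudinal = rep(5, 50),
                             arc = seq(0, 1.62, length.out = 50),
                             blade = "suprapyramidal",
                             origin_longitudinal = 5),
                        class = "ca3net_mf_path")
  grid_c <- section_grid(2)
  counts <- vapply(1:600, function(s)
    nrow(mf_place_synapses(straight, grid = grid_c, seed = s)),
    numeric(1))
  expect_lt(abs(mean(counts) - 10), 3 * sqrt(10 / 600))
  # dispersion consistent with Poisson (variance ~ mean)
  disp <- stats::var(counts) / mean(counts)
  expect_gt(disp, 0.8)
  expect_lt(disp, 1.25)
})

test_that("inter-synapse distances recover 162/223/345 um per region", {
  set.seed(20)
  len <- c(CA3c = 0, CA3b = 0, CA3a = 0)
  cnt <- c(CA3c = 0, CA3b = 0, CA3a = 0)
  grid <- section_grid(2)
  for (f in 1:1000) {
    tr <- mf_trajectory(stats::runif(1, 2, 8), noise_sd = 0.05)
    mid <- (tr$transverse[-1] + tr$transverse[-length(tr$transverse)]) / 2
    reg <- transverse_column(mid, grid)
    ds <- diff(tr$arc)
    for (r in names(len)) len[r] <- len[r] + sum(ds[reg == r])
    syn <- mf_place_synapses(tr, grid = grid)
    tb <- table(factor(syn$region, levels = names(cnt)))
    cnt <- cnt + as.integer(tb)
  }
  est <- len / cnt * 1000
  expect_lt(abs(est[["CA3c"]] - 162) / 162, 0.05)
  expect_lt(abs(est[["CA3b"]] - 223) / 223, 0.05)
  expect_lt(abs(est[["CA3a"]] - 345) / 345, 0.05)
})

test_that("capture assignment respects radius, drops, and blade rules", {
  lay <- build_layout(0, 0, 3, seed = 1)
  ca3 <- layout_population(lay, "CA3")
  # a synapse on top of cell 0 with a tiny radius picks cell 0 surely
  syn <- data.frame(arc = 0.5, transverse = ca3$transverse[1],
                    longitudinal = ca3$longitudinal[1],
                    region = "CA3c", layer = "lucidum")
  res <- mf_assign_post(syn, lay, capture_radius = 1e-4, seed = 2)
  expect_equal(res$post_id, ca3$id[1])
  expect_equal(res$dropped, 0)
  # far away: dropped and counted
  syn2 <- transform(syn, transverse = ca3$transverse[1] + 1)
  res2 <- mf_assign_post(syn2, lay, capture_radius = 1e-4, seed = 2)
  expect_true(is.na(res2$post_id))
  expect_equal(res2$dropped, 1)
  expect_error(mf_assign_post(syn, lay, capture_radius = 0), "> 0")
  # infrapyramidal-origin fibers: proximal oriens within CA3c only
  tr <- mf_trajectory(5, blade = "infrapyramidal", noise_sd = 0)
  syn3 <- mf_place_synapses(tr, seed = 3)
  expect_true(all(syn3$layer[syn3$region == "CA3c"] == "oriens_proximal"))
  expect_true(all(syn3$layer[syn3$region != "CA3c"] == "lucidum"))
  tr_s <- mf_trajectory(5, blade = "suprapyramidal", noise_sd = 0)
  expect_true(all(mf_place_synapses(tr_s, seed = 3)$layer == "lucidum"))
})

test_that("skew-Gaussian fields reduce, shift, and normalize correctly", {
  sym <- list(location = c(5, 1), scale = c(2, 0.6), alpha = c(0, 0))
  u <- seq(0, 10, by = 0.25)
  expect_equal(skew_gaussian_density(u, 1, sym),
               stats::dnorm(u, 5, 2) * stats::dnorm(1, 1, 0.6),
               tolerance = 1e-12)
  # positive skew shifts the mode toward positive offsets
  sk <- list(location = c(5, 1), scale = c(2, 0.6), alpha = c(3, 0))
  gl <- seq(0, 10, by = 0.001)
  mode_l <- gl[which.max(skew_gaussian_density(gl, 1, sk))]
  expect_gt(mode_l, 5)
  # integrates to 1 over the plane
  h <- 0.02
  g1 <- seq(-15, 25, by = h)
  g2 <- seq(-10, 12, by = h)
  tot <- sum(outer(g1, g2, function(a, b)
    skew_gaussian_density(a, b, sk))) * h * h
  expect_equal(tot, 1, tolerance = 1e-6)
  expect_error(
    skew_gaussian_density(0, 0, list(location = c(0, 0),
                                     scale = c(0, 1), alpha = c(0, 0))),
    "> 0")
})

test_that("associational parameter interpolation is bilinear", {
  grid <- assoc_param_grid()
  # node identity
  f <- assoc_field_for(grid$node_long[1], grid$node_trans[1], grid)
  expect_equal(f$alpha[1], grid$alpha_long[1])
  expect_equal(f$scale[1], grid$scale_long[1])
  # midpoint between two nodes averages their parameters
  g2 <- grid
  g2$scale_long <- seq(1, 9, length.out = 9)
  n1 <- which(g2$node_long == 2.5 & g2$node_trans == g2$node_trans[1])
  n2 <- which(g2$node_long == 5.0 & g2$node_trans == g2$node_trans[1])
  mid <- assoc_field_for(3.75, g2$node_trans[1], g2)
  expect_equal(mid$scale[1],
               (g2$scale_long[n1] + g2$scale_long[n2]) / 2)
  expect_error(assoc_field_for(5, 1, grid[1:3, ]), "malformed")
})

test_that("conduction delays are linear at the pathway velocities", {
  expect_equal(compute_delay(1.0, "PP"), 3.125)
  expect_equal(compute_delay(2.7, "MF"), 10)
  expect_equal(compute_delay(0, "ASSOC"), 0)
  expect_equal(compute_delay(2, "ASSOC"), 2 / 0.39)
  lens <- seq(0, 5, by = 0.5)
  expect_equal(compute_delay(lens, "MF"), lens / 0.27)
  expect_error(compute_delay(1, "XX"), "unknown")
  expect_error(compute_delay(-1, "MF"), ">= 0")
})

test_that("connectome generation conserves budgets and reproduces", {
  lay <- build_layout(200, 300, 120, seed = 8)
  cc <- connectome_config(budget_fraction = 0.01)
  conn <- build_connectome(lay, cc, seed = 9)
  expect_identical(conn$edges, build_connectome(lay, cc, seed = 9)$edges)
  ca3 <- layout_population(lay, "CA3")
  tf <- ca3$transverse / attr(lay, "geometry")$CA3[["transverse"]]
  for (i in seq_len(nrow(ca3))) {
    b <- synapse_budget(tf[i], fraction = 0.01)
    e <- conn$edges[conn$edges$post_id == ca3$id[i], ]
    expect_equal(sum(e$pathway == "LPP"), b[["lacunosum_distal"]])
    expect_equal(sum(e$pathway == "MPP"), b[["lacunosum_proximal"]])
    expect_equal(sum(e$pathway == "ASSOC"),
                 b[["radiatum"]] + b[["oriens"]])
  }
  expect_true(all(conn$edges$delay_ms >= 0))
  # pathway-layer consistency
  expect_true(all(conn$edges$layer[conn$edges$pathway == "LPP"] ==
                    "lacunosum_distal"))
  expect_true(all(conn$edges$layer[conn$edges$pathway == "MF"] %in%
                    c("lucidum", "oriens_proximal")))
  # disabling all pathways yields an empty connectome
  conn0 <- build_connectome(lay, connectome_config(pathways = character(0)),
                            seed = 1)
  expect_equal(nrow(conn0$edges), 0)
})

test_that("weight scaling is per-pathway and non-destructive", {
  lay <- build_layout(50, 80, 40, seed = 2)
  conn <- build_connectome(lay, connectome_config(budget_fraction = 0.003),
                           seed = 3)
  s5 <- scale_weights(conn, "MF", 5)
  mf <- conn$edges$pathway == "MF"
  expect_equal(s5$edges$weight[mf], conn$edges$weight[mf] * 5)
  expect_equal(s5$edges$weight[!mf], conn$edges$weight[!mf])
  expect_identical(scale_weights(conn, "ASSOC", 1)$edges, conn$edges)
  expect_true(all(scale_weights(conn, "PP", 0)$edges$weight[
    conn$edges$pathway %in% c("LPP", "MPP")] == 0))
  expect_error(scale_weights(conn, "MF", -1), ">= 0")
})
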