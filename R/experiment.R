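#' Named experiment configuration
#'
#' The circuit configurations studied with this model are named by the
#' projections they include: `PP-CA3` (entorhinal perforant path only),
#' `rMF-CA3` / `wcMF-CA3` (mossy fibers only, driven by the random
#' renewal dentate surrogate or by weakly correlated dentate activity),
#' `PP-rMF-CA3` / `PP-wcMF-CA3` (both feedforward projections), the full
#' `PP-wcMF-A-CA3` (adds the recurrent associational system), and
#' `PP-DG` (the upstream entorhinal-dentate stage by itself).
#'
#' @param model one of the configuration names above.
#' @param scale population fraction in (0, 1]; in-degree budgets scale
#'   with it and postsynaptically budgeted weights are compensated by
#'   the inverse factor. The mossy-fiber pathway keeps the 30 um capture
#'   radius and instead subsamples the dentate fiber population (see
#'   [mf_fiber_fraction()]) so the expected MF in-degree stays at its
#'   full-scale value.
#' @param pathway_scale named multipliers (`LPP`, `MPP`, `MF`, `ASSOC`)
#'   applied on top of the calibrated weights (1 = experimentally
#'   constrained strength).
#' @param duration simulated time, ms.
#' @param seed master seed; all stage seeds derive from it.
#' @param dg_mode for wcMF models: `"simulate"` runs the entorhinal to
#'   dentate stage explicitly; `"cluster"` substitutes a planted-cluster
#'   fixture raster with matched mean rate (fast, used for desk-scale
#'   analyses).
#' @param max_lag_ms time-lag range of the correlation maps.
#' @param dg_pp_weight perforant-path weight multiplier for the
#'   simulated dentate stage; the default `0.088 / scale` anchors the
#'   granule population near its reference 0.62 Hz mean rate (the
#'   granule stage is threshold-like, so the anchoring is approximate
#'   away from the calibration scale; check `mean_rate()` of the
#'   dentate raster).
#' @return list of class `"ca3net_experiment_config"`.
#' @export
experiment_config <- function(model = c("PP-CA3", "rMF-CA3", "wcMF-CA3",
                                        "PP-rMF-CA3", "PP-wcMF-CA3",
                                        "PP-wcMF-A-CA3", "PP-DG"),
                              scale = 0.02,
                              pathway_scale = c(LPP = 1, MPP = 1,
                                                MF = 1, ASSOC = 1),
                              duration = 3000, seed = 1L,
                              dg_mode = c("cluster", "simulate"),
                              max_lag_ms = 200, dg_pp_weight = NULL) {
  model <- match.arg(model)
  dg_mode <- match.arg(dg_mode)
  if (scale <= 0 || scale > 1) stop("scale must be in (0, 1]",
                                    call. = FALSE)
  if (is.null(dg_pp_weight)) dg_pp_weight <- 0.088 / scale
  structure(list(model = model, scale = scale,
                 pathway_scale = pathway_scale, duration = duration,
                 seed = as.integer(seed), dg_mode = dg_mode,
                 max_lag_ms = max_lag_ms, dg_pp_weight = dg_pp_weight),
            class = "ca3net_experiment_config")
}

model_pathways <- function(model) {
  switch(model,
         "PP-CA3" = c("LPP", "MPP"),
         "rMF-CA3" = "MF",
         "wcMF-CA3" = "MF",
         "PP-rMF-CA3" = c("LPP", "MPP", "MF"),
         "PP-wcMF-CA3" = c("LPP", "MPP", "MF"),
         "PP-wcMF-A-CA3" = c("LPP", "MPP", "MF", "ASSOC"),
         "PP-DG" = c("LPP", "MPP"))
}

# Entorhinal -> dentate wiring with the same Gaussian terminal-field
# machinery; per-granule-cell budget defaults to 3,000 entorhinal inputs
# at full scale, split between the divisions.
build_pp_dg_connectome <- function(layout, scale = 1, pp_extent = 1.25,
                                   ec_lateral_fraction = 0.5,
                                   budget_full = 3000, weight = 1,
                                   seed = 1L) {
  geom <- attr(layout, "geometry")
  dg <- layout_population(layout, "DG")
  ec <- layout_population(layout, "EC")
  restore <- local_rng(seed)
  on.exit(restore(), add = TRUE)
  lateral <- stats::runif(nrow(ec)) < ec_lateral_fraction
  sd <- pp_extent / 4
  budget <- round(budget_full * scale / 2)
  parts <- list()
  for (div in c("LPP", "MPP")) {
    pre <- ec[if (div == "LPP") lateral else !lateral, , drop = FALSE]
    centers <- pre$longitudinal / geom$EC[["longitudinal"]] *
      geom$DG[["longitudinal"]]
    mass <- stats::pnorm(geom$DG[["longitudinal"]], centers, sd) -
      stats::pnorm(0, centers, sd)
    layer <- if (div == "LPP") "lacunosum_distal" else "lacunosum_proximal"
    out <- vector("list", nrow(dg))
    for (i in seq_len(nrow(dg))) {
      w <- stats::dnorm(dg$longitudinal[i], centers, sd) / mass
      if (sum(w) <= 0 || budget == 0) next
      draw <- sample.int(length(w), budget, replace = TRUE, prob = w)
      plen <- sqrt((centers[draw] - dg$longitudinal[i])^2 +
                     dg$transverse[i]^2)
      out[[i]] <- data.frame(pre_pop = "EC", pre_id = pre$id[draw],
                             post_id = dg$id[i], pathway = div,
                             layer = layer,
                             delay_ms = compute_delay(plen, div),
                             weight = weight, stringsAsFactors = FALSE)
    }
    parts[[div]] <- do.call(rbind, c(out[!vapply(out, is.null,
                                                 logical(1))],
                                     make.row.names = FALSE))
  }
  edges <- do.call(rbind, c(parts, make.row.names = FALSE))
  structure(list(edges = edges, mf_dropped = 0L, seed = as.integer(seed),
                 config = NULL,
                 summary = stats::aggregate(
                   list(n_edges = edges$pre_id),
                   by = list(pathway = edges$pathway), FUN = length)),
            class = "ca3net_connectome")
}

#' Run one named experiment configuration
#'
#' Wires exactly the pathways implied by the model name, generates the
#' input rasters (entorhinal renewal sources at 5 Hz; for rMF models the
#' 0.62 Hz renewal dentate surrogate; for wcMF models either the
#' simulated entorhinal-dentate stage or a rate-matched clustered
#' fixture), simulates the CA3 population, and computes the global map,
#' the nine local maps, and a peak-correlation summary table with pair
#' counts and noise bounds.
#'
#' @param config an [experiment_config()].
#' @param out_dir optional directory: when given, the layout, connectome,
#'   rasters and summary are written there (tab-separated text).
#' @return list (artifact bundle) with `layout`, `connectome`, `sources`,
#'   `raster`, `global_map`, `local_maps`, `summary`, `config`.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  s <- config$scale
  seed <- config$seed
  pathways <- model_pathways(config$model)
  # scale-down: postsynaptic budgets scale with s (weights compensated by
  # 1/s); the mossy-fiber pathway instead keeps the 30 um capture radius
  # and unit weights, subsampling the dentate fiber population so the
  # expected MF in-degree stays at its full-scale value
  f_dg <- if (grepl("MF", config$model) && config$dg_mode == "cluster") {
    mf_fiber_fraction(s)
  } else s
  lay <- build_layout(round(112000 * s), round(120000 * f_dg),
                      round(25000 * s), seed = substream_seed(seed, 1))
  wcomp <- 1 / s
  wsc <- c(LPP = unname(config$pathway_scale["LPP"] * wcomp),
           MPP = unname(config$pathway_scale["MPP"] * wcomp),
           MF = unname(config$pathway_scale["MF"]),
           ASSOC = unname(config$pathway_scale["ASSOC"] * wcomp))
  if (config$model == "PP-DG") {
    conn <- build_pp_dg_connectome(lay, scale = s,
                                   weight = config$dg_pp_weight,
                                   seed = substream_seed(seed, 2))
    ec <- renewal_raster(round(112000 * s), ec_source_params(),
                         config$duration,
                         seed = substream_seed(seed, 3),
                         population = "EC")
    ras <- simulate_network(conn, list(EC = ec), lay,
                            sim_config(duration = config$duration,
                                       seed = seed),
                            target = "DG", presets = "granule",
                            kinetics = dg_kinetics())
    gm <- accumulate_map(ras, lay, max_lag_ms = config$max_lag_ms)
    bundle <- list(layout = lay, connectome = conn,
                   sources = list(EC = ec), raster = ras,
                   global_map = gm, local_maps = NULL,
                   summary = data.frame(scope = "global",
                                        peak = peak_correlation(gm),
                                        n_pairs = gm$n_pairs),
                   config = config)
    return(finish_bundle(bundle, out_dir))
  }
  cc <- connectome_config(pathways = pathways,
                          budget_fraction = s, weight_scale = wsc)
  conn <- build_connectome(lay, cc, seed = substream_seed(seed, 2))
  sources <- list()
  if (any(c("LPP", "MPP") %in% pathways)) {
    sources$EC <- renewal_raster(round(112000 * s), ec_source_params(),
                                 config$duration,
                                 seed = substream_seed(seed, 3),
                                 population = "EC")
  }
  if ("MF" %in% pathways) {
    sources$DG <- make_dg_source(config, lay, seed)
  }
  ras <- simulate_network(conn, sources, lay,
                          sim_config(duration = config$duration,
                                     seed = seed),
                          target = "CA3")
  gm <- try(accumulate_map(ras, lay, max_lag_ms = config$max_lag_ms),
            silent = TRUE)
  grid <- section_grid(attr(lay, "geometry")$CA3[["transverse"]])
  locals <- list()
  if (inherits(gm, "try-error")) {
    # too little activity for a map (tiny scales); report what ran
    return(finish_bundle(list(layout = lay, connectome = conn,
                              sources = sources, raster = ras,
                              global_map = NULL, local_maps = locals,
                              summary = data.frame(
                                scope = "global", peak = NA_real_,
                                n_pairs = 0L, noise_bound = NA_real_),
                              config = config), out_dir))
  }
  summ <- data.frame(scope = "global", peak = peak_correlation(gm),
                     n_pairs = gm$n_pairs,
                     noise_bound = max(map_noise_bound(gm)$bound,
                                       na.rm = TRUE))
  for (r in names(grid$long_centers)) {
    for (co in c("CA3c", "CA3b", "CA3a")) {
      lm <- try(local_map(ras, lay, r, co, grid = grid,
                          max_lag_ms = config$max_lag_ms), silent = TRUE)
      if (inherits(lm, "try-error")) next
      key <- paste(r, co, sep = ".")
      locals[[key]] <- lm
      summ <- rbind(summ, data.frame(
        scope = key, peak = peak_correlation(lm), n_pairs = lm$n_pairs,
        noise_bound = max(map_noise_bound(lm)$bound, na.rm = TRUE)))
    }
  }
  bundle <- list(layout = lay, connectome = conn, sources = sources,
                 raster = ras, global_map = gm, local_maps = locals,
                 summary = summ, config = config)
  finish_bundle(bundle, out_dir)
}

# Dentate source: renewal surrogate (rMF) or weakly correlated activity
# (wcMF) via the simulated PP-DG stage or a rate-matched cluster fixture.
make_dg_source <- function(config, lay, seed) {
  n_dg <- nrow(layout_population(lay, "DG"))
  if (grepl("rMF", config$model)) {
    return(renewal_raster(n_dg, dg_surrogate_params(), config$duration,
                          seed = substream_seed(seed, 4),
                          population = "DG"))
  }
  if (config$dg_mode == "simulate") {
    sub <- experiment_config("PP-DG", scale = config$scale,
                             duration = config$duration, seed = seed)
    return(run_experiment(sub)$raster)
  }
  make_dg_cluster_source(config, lay, seed)
}

make_dg_cluster_source <- function(config, lay, seed) {
  # clustered fixture with matched mean rate: 0.62 Hz total split
  # between background and planted events
  spec <- cluster_spec(n_clusters = 4, events_per_cluster =
                         max(3L, round(config$duration / 250)),
                       spatial_sd = 0.5, jitter_sd = 2,
                       participation = 0.6, background_rate = 0.3,
                       duration = config$duration)
  make_cluster_raster(spec, lay, population = "DG",
                      seed = substream_seed(seed, 4))$raster
}

# Granule-cell synaptic kinetics: the entorhinal-granule unitary EPSP is
# not a published constraint of this model; a small somatic EPSP target
# keeps granule firing sparse (calibrated once per session).
dg_kinetics <- function(peak_mv = 0.1, hhw_ms = 40) {
  key <- sprintf("dgkin_%g_%g", peak_mv, hhw_ms)
  if (!is.null(.ca3net_cache[[key]])) return(.ca3net_cache[[key]])
  gp <- cell_preset("granule")
  out <- list(
    lacunosum_distal = calibrate_synapse(peak_mv, hhw_ms,
                                         layer = "lacunosum_distal",
                                         preset = gp),
    lacunosum_proximal = calibrate_synapse(peak_mv, hhw_ms,
                                           layer = "lacunosum_proximal",
                                           preset = gp))
  .ca3net_cache[[key]] <- out
  out
}

finish_bundle <- function(bundle, out_dir) {
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_layout(bundle$layout, file.path(out_dir, "layout.tsv"))
    write_connectome(bundle$connectome,
                     file.path(out_dir, "connectome.tsv"))
    write_raster(bundle$raster, file.path(out_dir, "raster.tsv"))
    for (p in names(bundle$sources)) {
      write_raster(bundle$sources[[p]],
                   file.path(out_dir, paste0("source_", p, ".tsv")))
    }
    utils::write.table(bundle$summary,
                       file.path(out_dir, "summary.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  bundle
}
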