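#' Connectome generation configuration
#'
#' @param pathways subset of `c("LPP", "MPP", "MF", "ASSOC")` to generate.
#' @param pp_extent perforant-path terminal-field span, mm (1-1.5).
#' @param ec_lateral_fraction fraction of EC cells labelled lateral
#'   (LPP origin); the rest are medial (MPP origin).
#' @param topo_map monotone map on normalized longitudinal position used
#'   for the entorhinal projection (identity by default; the quantitative
#'   entorhinal-dentate map is consumed as configuration).
#' @param budget_fraction scale factor applied to the per-layer budgets
#'   (scaled-down experiments use the population fraction here).
#' @param weight_scale named per-pathway synaptic weight multipliers
#'   (1 = experimentally constrained strength).
#' @param capture_radius mossy-fiber capture radius, mm.
#' @param mf_noise_sd control-point jitter for fiber trajectories, mm.
#' @param mf_control mossy-fiber trajectory control points.
#' @param assoc_grid associational skew-field parameter grid.
#' @param mf_region_means inter-synapse distance means, mm.
#' @return list of class `"ca3net_connectome_config"`.
#' @export
connectome_config <- function(pathways = c("LPP", "MPP", "MF", "ASSOC"),
                              pp_extent = 1.25,
                              ec_lateral_fraction = 0.5,
                              topo_map = identity,
                              budget_fraction = 1,
                              weight_scale = c(LPP = 1, MPP = 1, MF = 1,
                                               ASSOC = 1),
                              capture_radius = 0.03,
                              mf_noise_sd = 0.05,
                              mf_control = NULL,
                              assoc_grid = NULL,
                              mf_region_means = NULL) {
  stopifnot(all(pathways %in% c("LPP", "MPP", "MF", "ASSOC")))
  if (pp_extent <= 0) stop("pp_extent must be > 0", call. = FALSE)
  if (is.null(mf_region_means)) {
    mf_region_means <- c(CA3c = 0.162, CA3b = 0.223, CA3a = 0.345)
  }
  structure(list(pathways = pathways, pp_extent = pp_extent,
                 ec_lateral_fraction = ec_lateral_fraction,
                 topo_map = topo_map, budget_fraction = budget_fraction,
                 weight_scale = weight_scale,
                 capture_radius = capture_radius,
                 mf_noise_sd = mf_noise_sd, mf_control = mf_control,
                 assoc_grid = assoc_grid,
                 mf_region_means = mf_region_means),
            class = "ca3net_connectome_config")
}

# Pathway -> target layer (one compartment per layer, see cell models).
pathway_layer <- c(LPP = "lacunosum_distal", MPP = "lacunosum_proximal",
                   ASSOC_RAD = "radiatum", ASSOC_OR = "oriens",
                   MF = "lucidum", MF_INFRA = "oriens_proximal")

empty_edges <- function() {
  data.frame(pre_pop = character(0), pre_id = integer(0),
             post_id = integer(0), pathway = character(0),
             layer = character(0), delay_ms = numeric(0),
             weight = numeric(0), stringsAsFactors = FALSE)
}

#' Generate the full stochastic connectome for a layout
#'
#' Orchestrates all enabled pathways. The perforant-path divisions (LPP,
#' MPP) and the associational system are budgeted postsynaptically: for
#' every CA3 cell, presynaptic partners are drawn with probability
#' proportional to their terminal-field density at the cell until the
#' layer budget is met (with replacement; repeats are multi-synapse
#' contacts). Mossy fibers are generated presynaptically: one trajectory
#' per granule cell, Poisson synapse placement along the fiber with
#' region-dependent means, and 30 um postsynaptic capture. Every edge
#' carries its conduction delay.
#'
#' @param layout a [build_layout()] result.
#' @param config a [connectome_config()].
#' @param seed integer seed; generation is reproducible bit-for-bit.
#' @return object of class `"ca3net_connectome"`: list with `edges`
#'   (data.frame: `pre_pop`, `pre_id`, `post_id`, `pathway`, `layer`,
#'   `delay_ms`, `weight`), `mf_dropped` (synapses with no cell in
#'   capture range), `seed`, `config` and a per-pathway `summary`.
#' @export
build_connectome <- function(layout, config = connectome_config(),
                             seed = 1L) {
  geom <- attr(layout, "geometry")
  ca3 <- layout_population(layout, "CA3")
  parts <- list()
  mf_dropped <- 0L
  restore <- local_rng(seed)
  on.exit(restore(), add = TRUE)

  if (any(c("LPP", "MPP") %in% config$pathways) && nrow(ca3)) {
    ec <- layout_population(layout, "EC")
    if (nrow(ec)) {
      lateral <- stats::runif(nrow(ec)) < config$ec_lateral_fraction
      for (div in intersect(c("LPP", "MPP"), config$pathways)) {
        pre <- ec[if (div == "LPP") lateral else !lateral, , drop = FALSE]
        parts[[div]] <- build_pp_edges(pre, ca3, geom, config, div)
      }
    }
  }
  if ("MF" %in% config$pathways && nrow(ca3)) {
    dg <- layout_population(layout, "DG")
    if (nrow(dg)) {
      mf <- build_mf_edges(dg, ca3, geom, config)
      parts[["MF"]] <- mf$edges
      mf_dropped <- mf$dropped
    }
  }
  if ("ASSOC" %in% config$pathways && nrow(ca3) > 1) {
    parts[["ASSOC"]] <- build_assoc_edges(ca3, geom, config)
  }
  edges <- if (length(parts)) do.call(rbind, c(parts, make.row.names = FALSE))
  else empty_edges()
  rownames(edges) <- NULL
  summ <- if (nrow(edges)) {
    stats::aggregate(list(n_edges = edges$pre_id),
                     by = list(pathway = edges$pathway), FUN = length)
  } else data.frame(pathway = character(0), n_edges = integer(0))
  structure(list(edges = edges, mf_dropped = mf_dropped,
                 seed = as.integer(seed), config = config, summary = summ),
            class = "ca3net_connectome")
}

# Perforant-path division (LPP or MPP): postsynaptic budgeted sampling.
build_pp_edges <- function(pre, ca3, geom, config, division) {
  layer <- pathway_layer[[division]]
  budget_layer <- if (division == "LPP") "lacunosum_distal"
  else "lacunosum_proximal"
  centers <- config$topo_map(pre$longitudinal /
                               geom$EC[["longitudinal"]]) *
    geom$CA3[["longitudinal"]]
  sd <- config$pp_extent / 4
  mass <- stats::pnorm(geom$CA3[["longitudinal"]], centers, sd) -
    stats::pnorm(0, centers, sd)
  tfrac <- ca3$transverse / geom$CA3[["transverse"]]
  out <- vector("list", nrow(ca3))
  w_mult <- config$weight_scale[[division]]
  # candidates restricted to a +/- 8 sd window around the cell (beyond
  # which the Gaussian field carries no appreciable mass)
  ord <- order(centers)
  centers_s <- centers[ord]
  for (i in seq_len(nrow(ca3))) {
    budget <- synapse_budget(tfrac[i],
                             fraction = config$budget_fraction)[[budget_layer]]
    if (budget == 0L) next
    win <- findInterval(ca3$longitudinal[i] + c(-8, 8) * sd, centers_s)
    cand <- ord[max(1L, win[1]):min(length(ord), max(win[2], 1L))]
    w <- stats::dnorm(ca3$longitudinal[i], centers[cand], sd) / mass[cand]
    if (sum(w) <= 0) {
      # fall back to the full candidate set (isolated geometries)
      cand <- seq_along(centers)
      w <- stats::dnorm(ca3$longitudinal[i], centers, sd) / mass
    }
    if (sum(w) <= 0) {
      stop("no admissible presynaptic candidate for CA3 cell ",
           ca3$id[i], call. = FALSE)
    }
    draw <- cand[sample.int(length(w), budget, replace = TRUE, prob = w)]
    # path length: sheet distance from the mapped entry point (at the
    # proximal border) to the cell
    plen <- sqrt((centers[draw] - ca3$longitudinal[i])^2 +
                   ca3$transverse[i]^2)
    out[[i]] <- data.frame(pre_pop = "EC", pre_id = pre$id[draw],
                           post_id = ca3$id[i], pathway = division,
                           layer = layer,
                           delay_ms = compute_delay(plen, division),
                           weight = w_mult, stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty_edges())
  do.call(rbind, c(out, make.row.names = FALSE))
}

# Batched mossy-fiber generation: shared spline basis, vectorized Poisson
# placement, spatial-hash capture.
build_mf_edges <- function(dg, ca3, geom, config) {
  control <- config$mf_control
  if (is.null(control)) {
    control <- mf_control_points(geom$CA3[["transverse"]])
  }
  long_ext <- geom$CA3[["longitudinal"]]
  n_grid <- 80L
  gx <- seq(0, max(control$transverse), length.out = n_grid)
  B <- mf_spline_basis(control, gx)
  nf <- nrow(dg)
  k <- nrow(control)
  eps <- matrix(stats::rnorm(nf * k, 0, config$mf_noise_sd), nf, k)
  base <- as.numeric(B %*% control$deviation)
  # fiber x grid matrix of longitudinal coordinates
  Y <- matrix(dg$longitudinal, nf, n_grid) +
    matrix(base, nf, n_grid, byrow = TRUE) + eps %*% t(B)
  # unclamped: off-sheet synapses find no postsynaptic cell (see
  # mf_trajectory)
  dx <- diff(gx)
  DY <- Y[, -1L, drop = FALSE] - Y[, -n_grid, drop = FALSE]
  DS <- sqrt(matrix(dx^2, nf, n_grid - 1L, byrow = TRUE) + DY^2)
  mid_x <- (gx[-1L] + gx[-n_grid]) / 2
  region <- transverse_column(mid_x, section_grid(geom$CA3[["transverse"]]))
  mean_seg <- config$mf_region_means[region]
  counts <- stats::rpois(length(DS),
                         as.numeric(DS) / rep(mean_seg, each = nf))
  dim(counts) <- dim(DS)
  tot <- sum(counts)
  if (tot == 0L) return(list(edges = empty_edges(), dropped = 0L))
  fib <- rep.int(rep.int(seq_len(nf), ncol(counts)), as.numeric(counts))
  seg <- rep.int(rep(seq_len(ncol(counts)), each = nf), as.numeric(counts))
  u <- stats::runif(tot)
  sx <- gx[seg] + u * dx[seg]
  sy <- Y[cbind(fib, seg)] + u * DY[cbind(fib, seg)]
  ARC <- cbind(0, t(apply(DS, 1L, cumsum)))
  arc <- ARC[cbind(fib, seg)] + u * DS[cbind(fib, seg)]
  idx <- capture_assign_cpp(sx, sy, ca3$transverse, ca3$longitudinal,
                            config$capture_radius)
  keep <- idx >= 0L
  dropped <- sum(!keep)
  if (!any(keep)) return(list(edges = empty_edges(), dropped = dropped))
  reg_s <- region[seg[keep]]
  infra <- dg$blade[fib[keep]] == "infrapyramidal"
  layer <- ifelse(infra & reg_s == "CA3c", "oriens_proximal", "lucidum")
  edges <- data.frame(pre_pop = "DG", pre_id = dg$id[fib[keep]],
                      post_id = ca3$id[idx[keep] + 1L], pathway = "MF",
                      layer = layer,
                      delay_ms = compute_delay(arc[keep], "MF"),
                      weight = config$weight_scale[["MF"]],
                      stringsAsFactors = FALSE)
  list(edges = edges, dropped = dropped)
}

# Associational system: postsynaptic budgeted sampling from interpolated
# skew-Gaussian fields (one field per presynaptic CA3 cell).
build_assoc_edges <- function(ca3, geom, config) {
  grid <- config$assoc_grid
  if (is.null(grid)) {
    grid <- assoc_param_grid(structure(list(CA3 = geom$CA3),
                                       class = "ca3net_geometry"))
  }
  n <- nrow(ca3)
  par_names <- c("dloc_long", "dloc_trans", "scale_long", "scale_trans",
                 "alpha_long", "alpha_trans", "amplitude")
  P <- vapply(seq_len(n), function(j) {
    f <- assoc_field_for(ca3$longitudinal[j], ca3$transverse[j], grid)
    c(f$location, f$scale, f$alpha, f$amplitude)
  }, numeric(7))
  loc_l <- P[1, ]; loc_t <- P[2, ]
  sc_l <- P[3, ]; sc_t <- P[4, ]
  al_l <- P[5, ]; al_t <- P[6, ]
  amp <- P[7, ]
  # per-presynaptic-cell truncation mass over the CA3 sheet (product of
  # per-axis truncated skew-normal masses, midpoint quadrature)
  mass_axis <- function(loc, sc, al, ext) {
    ng <- 201L
    g <- seq(0, ext, length.out = ng)
    mid <- (g[-1L] + g[-ng]) / 2
    h <- ext / (ng - 1L)
    vapply(seq_along(loc), function(j) {
      z <- (mid - loc[j]) / sc[j]
      sum(2 / sc[j] * stats::dnorm(z) * stats::pnorm(al[j] * z)) * h
    }, numeric(1))
  }
  mass <- mass_axis(loc_l, sc_l, al_l, geom$CA3[["longitudinal"]]) *
    mass_axis(loc_t, sc_t, al_t, geom$CA3[["transverse"]])
  mass[mass <= 0] <- NA
  tfrac <- ca3$transverse / geom$CA3[["transverse"]]
  w_mult <- config$weight_scale[["ASSOC"]]
  out <- vector("list", n)
  for (i in seq_len(n)) {
    z_l <- (ca3$longitudinal[i] - loc_l) / sc_l
    z_t <- (ca3$transverse[i] - loc_t) / sc_t
    w <- amp / mass *
      (2 / sc_l) * stats::dnorm(z_l) * stats::pnorm(al_l * z_l) *
      (2 / sc_t) * stats::dnorm(z_t) * stats::pnorm(al_t * z_t)
    w[i] <- 0  # no autapses
    w[is.na(w)] <- 0
    bud <- synapse_budget(tfrac[i], fraction = config$budget_fraction)
    res <- list()
    for (lay in c("radiatum", "oriens")) {
      b <- bud[[lay]]
      if (b == 0L) next
      if (sum(w) <= 0) stop("all-zero associational probabilities",
                            call. = FALSE)
      draw <- sample.int(n, b, replace = TRUE, prob = w)
      plen <- sqrt((ca3$longitudinal[draw] - ca3$longitudinal[i])^2 +
                     (ca3$transverse[draw] - ca3$transverse[i])^2)
      res[[lay]] <- data.frame(pre_pop = "CA3", pre_id = ca3$id[draw],
                               post_id = ca3$id[i], pathway = "ASSOC",
                               layer = lay,
                               delay_ms = compute_delay(plen, "ASSOC"),
                               weight = w_mult, stringsAsFactors = FALSE)
    }
    if (length(res)) out[[i]] <- do.call(rbind, c(res,
                                                  make.row.names = FALSE))
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty_edges())
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Scale the synaptic weights of one pathway
#'
#' Returns a copy of the connectome with the selected pathway's weights
#' multiplied by `factor`; other pathways are untouched and the input is
#' not modified. Factor 0 silences the pathway.
#'
#' @param connectome a [build_connectome()] result.
#' @param pathway one of `"LPP"`, `"MPP"`, `"MF"`, `"ASSOC"` (or `"PP"`
#'   for both perforant-path divisions).
#' @param factor non-negative multiplier (1 = experimentally constrained
#'   strength).
#' @return a new `"ca3net_connectome"`.
#' @export
scale_weights <- function(connectome, pathway, factor) {
  if (factor < 0) stop("factor must be >= 0", call. = FALSE)
  target <- if (pathway == "PP") c("LPP", "MPP")
  else if (pathway %in% c("LPP", "MPP", "MF", "ASSOC")) pathway
  else stop("unknown pathway: ", pathway, call. = FALSE)
  sel <- connectome$edges$pathway %in% target
  connectome$edges$weight[sel] <- connectome$edges$weight[sel] * factor
  connectome
}

#' Per-pathway in-degree table
#' @param connectome a [build_connectome()] result.
#' @return data.frame with `post_id`, `pathway`, `in_degree`.
#' @export
in_degree <- function(connectome) {
  e <- connectome$edges
  if (!nrow(e)) {
    return(data.frame(post_id = integer(0), pathway = character(0),
                      in_degree = integer(0)))
  }
  out <- stats::aggregate(list(in_degree = e$pre_id),
                          by = list(post_id = e$post_id,
                                    pathway = e$pathway), FUN = length)
  out[order(out$pathway, out$post_id), , drop = FALSE]
}

#' @export
print.ca3net_connectome <- function(x, ...) {
  cat("<ca3net_connectome> ", nrow(x$edges), " edges, seed ", x$seed,
      "\n", sep = "")
  if (nrow(x$summary)) {
    for (i in seq_len(nrow(x$summary))) {
      cat("  ", x$summary$pathway[i], ": ", x$summary$n_edges[i],
          " edges\n", sep = "")
    }
  }
  if (x$mf_dropped > 0) cat("  (", x$mf_dropped,
                            " MF synapses dropped: no cell in range)\n",
                            sep = "")
  invisible(x)
}

#' Dentate fiber fraction for scaled-down mossy-fiber generation
#'
#' When only a fraction of the CA3 population is modelled, the 30 um
#' capture rule thins mossy-fiber synapses naturally (a synapse whose
#' postsynaptic cell is not modelled finds no cell in range and is
#' dropped). Because each captured synapse is shared among fewer
#' candidate cells, the per-cell in-degree would inflate; subsampling
#' the dentate fiber population by this fraction keeps the expected
#' mossy-fiber in-degree at its full-scale value while leaving the
#' capture radius -- and therefore the local geometry of fiber
#' sampling -- unchanged.
#'
#' @param ca3_fraction modelled fraction of the CA3 population.
#' @param geometry sheet geometry (CA3 extents set the cell density).
#' @param capture_radius capture radius, mm.
#' @param n_ca3_full,n_dg_full full-scale population sizes.
#' @return fraction of the dentate fiber population to generate.
#' @export
mf_fiber_fraction <- function(ca3_fraction,
                              geometry = default_geometry(),
                              capture_radius = 0.03,
                              n_ca3_full = 25000, n_dg_full = 120000) {
  area <- geometry$CA3[["longitudinal"]] * geometry$CA3[["transverse"]]
  per_syn <- function(n) {
    lam <- n / area * pi * capture_radius^2
    (1 - exp(-lam)) / n   # P(assigned to one given cell)
  }
  f <- per_syn(n_ca3_full) / per_syn(round(n_ca3_full * ca3_fraction))
  min(f, 1)
}
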