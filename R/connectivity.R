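#' Layer-wise synaptic densities and dendritic lengths (reference values)
#'
#' Input budgets per CA3 pyramidal cell are products of layer synaptic
#' density (synapses/um) and total dendritic length in that layer (um).
#' Densities: lacunosum distal (lateral entorhinal, LEC) 0.63, lacunosum
#' proximal (medial entorhinal, MEC) 0.63, radiatum (associational) 3.61,
#' oriens (associational) 3.15 synapses/um. Dendritic lengths vary along
#' the transverse axis; the proximal and distal values are implied by the
#' published proximal/distal input counts (0 / 1,658 LEC; 0 / 1,105 MEC;
#' 11,241 / 11,281 radiatum; 7,147 / 17,893 oriens) and interpolate
#' linearly in between.
#'
#' @format list with `density` (synapses/um) and `length_proximal`,
#'   `length_distal` (um), each named by layer
#'   (`lacunosum_distal`, `lacunosum_proximal`, `radiatum`, `oriens`).
#' @export
ca3_budget_reference <- function() {
  density <- c(lacunosum_distal = 0.63, lacunosum_proximal = 0.63,
               radiatum = 3.61, oriens = 3.15)
  counts_prox <- c(lacunosum_distal = 0, lacunosum_proximal = 0,
                   radiatum = 11241, oriens = 7147)
  counts_dist <- c(lacunosum_distal = 1658, lacunosum_proximal = 1105,
                   radiatum = 11281, oriens = 17893)
  list(density = density,
       length_proximal = counts_prox / density,
       length_distal = counts_dist / density)
}

#' Per-layer synapse budget of a CA3 pyramidal cell
#'
#' @param transverse_fraction position along the transverse axis in
#'   `[0, 1]` (0 = proximal CA3c border, 1 = distal CA3a tip).
#' @param reference densities and lengths, see [ca3_budget_reference()];
#'   replaceable for sensitivity analyses.
#' @param fraction global budget scale factor (used by scaled-down
#'   experiments); budgets are rounded after scaling.
#' @return named integer vector of input counts per layer. The proximal
#'   extreme receives 0 lacunosum (perforant-path) inputs.
#' @examples
#' synapse_budget(1)["lacunosum_distal"]  # 1658
#' synapse_budget(0)[c("radiatum", "oriens")]  # 11241, 7147
#' @export
synapse_budget <- function(transverse_fraction,
                           reference = ca3_budget_reference(),
                           fraction = 1) {
  f <- transverse_fraction
  if (is.na(f) || f < 0 || f > 1) {
    stop("transverse_fraction must be in [0, 1]", call. = FALSE)
  }
  if (any(reference$density < 0) || any(reference$length_proximal < 0) ||
      any(reference$length_distal < 0)) {
    stop("densities and lengths must be >= 0", call. = FALSE)
  }
  len <- reference$length_proximal +
    f * (reference$length_distal - reference$length_proximal)
  cnt <- round(reference$density * len * fraction)
  storage.mode(cnt) <- "integer"
  cnt
}

#' Perforant-path Gaussian terminal field of an entorhinal cell
#'
#' The terminal field of a perforant-path axon extends 1-1.5 mm along the
#' longitudinal axis of the target subfield; the span is read as the
#' approximately 95% mass (+/- 2 sd) of a Gaussian, so the longitudinal sd
#' is `extent_mm / 4`. The field is centered at the image of the cell's
#' longitudinal position under the topographic map and truncated and
#' renormalized at the sheet edges. The transverse profile is uniform
#' across the target span (the published topography is longitudinal;
#' transverse structure enters through the budget gradient).
#'
#' @param ec_longitudinal,ec_extent longitudinal position of the EC cell
#'   (mm) and the EC longitudinal extent.
#' @param target_extent longitudinal extent of the target sheet (mm).
#' @param extent_mm terminal-field span (mm), default 1.25.
#' @param topo_map monotone map from normalized EC longitudinal position
#'   in `[0, 1]` to normalized target position; default identity (the
#'   quantitative entorhinal-dentate map is consumed as configuration).
#' @return list of class `"ca3net_gaussian_field"` with `center` (mm in
#'   target frame), `sd` (mm), `domain` and truncation `mass`
#'   (the untruncated probability mass inside the domain).
#' @export
pp_field_for <- function(ec_longitudinal, ec_extent = 10,
                         target_extent = 10, extent_mm = 1.25,
                         topo_map = identity) {
  if (extent_mm <= 0) stop("extent_mm must be > 0", call. = FALSE)
  center <- topo_map(ec_longitudinal / ec_extent) * target_extent
  sd <- extent_mm / 4
  mass <- stats::pnorm(target_extent, center, sd) -
    stats::pnorm(0, center, sd)
  structure(list(center = center, sd = sd,
                 domain = c(0, target_extent), mass = mass),
            class = "ca3net_gaussian_field")
}

#' Density of a truncated Gaussian terminal field
#'
#' @param field a [pp_field_for()] result.
#' @param longitudinal positions (mm) in the target frame.
#' @return density values renormalized so the field integrates to 1 over
#'   its truncation domain (0 outside).
#' @export
gaussian_field_density <- function(field, longitudinal) {
  d <- stats::dnorm(longitudinal, field$center, field$sd) / field$mass
  d[longitudinal < field$domain[1] | longitudinal > field$domain[2]] <- 0
  d
}

#' Draw presynaptic partners for one postsynaptic cell
#'
#' Postsynaptically budgeted pathways select presynaptic neurons with
#' probability proportional to the value of their terminal field at the
#' postsynaptic cell, with replacement, until the budget is met; repeat
#' draws represent multi-synapse contacts and are recorded as separate
#' edges.
#'
#' @param probabilities non-negative candidate weights (renormalized
#'   internally).
#' @param budget number of edges to draw (>= 0).
#' @param seed optional integer seed.
#' @return integer vector of candidate indices of length `budget`.
#' @export
sample_inputs_postsynaptic <- function(probabilities, budget, seed = NULL) {
  if (budget == 0) return(integer(0))
  if (any(probabilities < 0)) stop("probabilities must be >= 0",
                                   call. = FALSE)
  if (sum(probabilities) <= 0) {
    stop("budget > 0 with all-zero candidate probabilities", call. = FALSE)
  }
  restore <- if (!is.null(seed)) local_rng(seed) else NULL
  out <- sample.int(length(probabilities), budget, replace = TRUE,
                    prob = probabilities)
  if (!is.null(restore)) restore()
  out
}

#' Default mossy-fiber trajectory control points
#'
#' Deviation of the fiber from its longitudinal level of origin as a
#' function of normalized transverse position. Fibers run transversely
#' through CA3c and CA3b (zero deviation) and turn toward the temporal
#' pole (negative deviation in the septal-positive convention) within
#' CA3a. The published trajectory data are not tabulated numerically, so
#' these control points are documented package defaults.
#'
#' @param ca3_trans CA3 transverse extent (mm).
#' @param temporal_deviation magnitude of the temporal-ward deviation at
#'   the distal tip (mm), default 0.5. The default is chosen so the
#'   arc-length stretch of the CA3a bend keeps the per-area synapse
#'   density decreasing from CA3c to CA3a, consistent with the reported
#'   inter-synapse distance gradient.
#' @return data.frame with columns `transverse` (mm) and `deviation` (mm).
#' @export
mf_control_points <- function(ca3_trans = 2, temporal_deviation = 0.5) {
  data.frame(
    transverse = ca3_trans * c(0, 0.25, 0.5, 2 / 3, 0.8, 0.92, 1),
    deviation = c(0, 0, 0, 0, -0.25, -0.6, -1) * temporal_deviation
  )
}

# Linear operator mapping control-point deviations to deviations on a
# fine transverse grid via natural cubic spline interpolation. Shared by
# all fibers, so batched generation is a matrix product.
mf_spline_basis <- function(control, grid_x) {
  k <- nrow(control)
  B <- matrix(0, length(grid_x), k)
  for (j in seq_len(k)) {
    e <- numeric(k)
    e[j] <- 1
    B[, j] <- stats::spline(control$transverse, e, xout = grid_x,
                            method = "natural")$y
  }
  B
}

#' Mossy-fiber trajectory of one granule cell
#'
#' The fiber starts at the CA3c entry point at the granule cell's
#' longitudinal level and follows the deviation-versus-transverse cubic
#' spline; Gaussian jitter with sd `noise_sd` is applied to the control
#' points (so the expected path equals the noiseless spline). Paths may
#' leave the sheet at the temporal edge; synapses placed there are
#' dropped at the capture stage because no postsynaptic cell is in
#' range.
#'
#' @param origin_longitudinal granule-cell longitudinal position (mm).
#' @param blade `"suprapyramidal"` or `"infrapyramidal"`; carried on the
#'   path for target-layer rules.
#' @param control control points, see [mf_control_points()].
#' @param noise_sd control-point jitter sd (mm), default 0.05.
#' @param ca3_geom CA3 extents `c(longitudinal, transverse)` (mm).
#' @param n_vertices polyline resolution.
#' @param seed optional integer seed.
#' @return list of class `"ca3net_mf_path"`: `transverse`, `longitudinal`
#'   vertex coordinates (mm), cumulative `arc` length (mm), `blade`,
#'   `origin_longitudinal`.
#' @export
mf_trajectory <- function(origin_longitudinal, blade = "suprapyramidal",
                          control = mf_control_points(),
                          noise_sd = 0.05,
                          ca3_geom = c(longitudinal = 10, transverse = 2),
                          n_vertices = 80, seed = NULL) {
  restore <- if (!is.null(seed)) local_rng(seed) else NULL
  gx <- seq(0, max(control$transverse), length.out = n_vertices)
  dev <- control$deviation
  if (noise_sd > 0) dev <- dev + stats::rnorm(nrow(control), 0, noise_sd)
  y <- origin_longitudinal + stats::spline(control$transverse, dev,
                                           xout = gx,
                                           method = "natural")$y
  if (!is.null(restore)) restore()
  # paths are not clamped at the sheet edges: a fiber whose temporal-ward
  # deviation carries it off the sheet simply places synapses where no
  # postsynaptic cell can capture them (clamping would pile fibers up on
  # the edge and artificially inflate in-degrees there)
  arc <- c(0, cumsum(sqrt(diff(gx)^2 + diff(y)^2)))
  structure(list(transverse = gx, longitudinal = y, arc = arc,
                 blade = blade,
                 origin_longitudinal = origin_longitudinal),
            class = "ca3net_mf_path")
}

#' Region-dependent inter-synapse means for mossy fibers
#'
#' Mean inter-synapse distances along the fiber: 162 um in CA3c, 223 um
#' in CA3b, 345 um in CA3a.
#' @return named numeric vector, mm.
#' @export
mf_region_means <- function() {
  c(CA3c = 0.162, CA3b = 0.223, CA3a = 0.345)
}

#' Place synapses along a mossy-fiber path
#'
#' Synapse locations follow an inhomogeneous Poisson process along arc
#' length with rate `1 / mean(region)`, the region being determined by
#' the transverse coordinate at each arc position; within each polyline
#' segment the rate is constant, so counts are Poisson and positions
#' uniform per segment.
#'
#' @param path a [mf_trajectory()] result.
#' @param region_means named inter-synapse means (mm), see
#'   [mf_region_means()].
#' @param grid transverse [section_grid()] used to delimit CA3c/b/a.
#' @param seed optional integer seed.
#' @return data.frame with `arc` (mm along the fiber), `transverse`,
#'   `longitudinal` (mm), `region`, and `layer` (`"oriens_proximal"` for
#'   CA3c synapses of infrapyramidal-origin fibers, `"lucidum"`
#'   otherwise), sorted by arc position.
#' @export
mf_place_synapses <- function(path, region_means = mf_region_means(),
                              grid = section_grid(max(path$transverse)),
                              seed = NULL) {
  if (any(region_means <= 0)) stop("region means must be > 0",
                                   call. = FALSE)
  restore <- if (!is.null(seed)) local_rng(seed) else NULL
  nseg <- length(path$arc) - 1L
  if (nseg < 1L || max(path$arc) == 0) {
    if (!is.null(restore)) restore()
    return(mf_synapse_frame(numeric(0), numeric(0), numeric(0),
                            character(0), path$blade, grid))
  }
  mid_x <- (path$transverse[-1] + path$transverse[-(nseg + 1L)]) / 2
  region <- transverse_column(mid_x, grid)
  ds <- diff(path$arc)
  counts <- stats::rpois(nseg, ds / region_means[region])
  seg <- rep.int(seq_len(nseg), counts)
  u <- stats::runif(length(seg))
  if (!is.null(restore)) restore()
  arc <- path$arc[seg] + u * ds[seg]
  tx <- path$transverse[seg] + u * diff(path$transverse)[seg]
  ly <- path$longitudinal[seg] + u * diff(path$longitudinal)[seg]
  ord <- order(arc)
  mf_synapse_frame(arc[ord], tx[ord], ly[ord], region[seg][ord],
                   path$blade, grid)
}

mf_synapse_frame <- function(arc, tx, ly, region, blade, grid) {
  layer <- ifelse(blade == "infrapyramidal" & region == "CA3c",
                  "oriens_proximal", "lucidum")
  data.frame(arc = arc, transverse = tx, longitudinal = ly,
             region = region, layer = layer, stringsAsFactors = FALSE)
}

#' Assign mossy-fiber synapses to postsynaptic CA3 cells
#'
#' Each synapse is assigned to one CA3 pyramidal cell chosen uniformly
#' among cells within `capture_radius` (sheet distance, default 30 um); a
#' synapse with no cell in range is dropped and counted.
#'
#' @param synapses data.frame from [mf_place_synapses()] (needs
#'   `transverse`, `longitudinal`, `arc`, `layer`).
#' @param layout a [build_layout()] result (its CA3 population is used).
#' @param capture_radius capture radius, mm (default 0.03 = 30 um).
#' @param seed optional integer seed.
#' @return list with `post_id` (CA3 ids, `NA` for dropped synapses),
#'   `dropped` (count), and the input `synapses` columns.
#' @export
mf_assign_post <- function(synapses, layout, capture_radius = 0.03,
                           seed = NULL) {
  if (capture_radius <= 0) stop("capture_radius must be > 0", call. = FALSE)
  ca3 <- layout_population(layout, "CA3")
  restore <- if (!is.null(seed)) local_rng(seed) else NULL
  idx <- capture_assign_cpp(synapses$transverse, synapses$longitudinal,
                            ca3$transverse, ca3$longitudinal,
                            capture_radius)
  if (!is.null(restore)) restore()
  post <- ifelse(idx < 0L, NA_integer_, ca3$id[idx + 1L])
  list(post_id = post, dropped = sum(idx < 0L), synapses = synapses)
}

#' Two-dimensional skew-Gaussian density
#'
#' Product of two one-dimensional skew-normal densities,
#' \deqn{f(z) = \frac{2}{\omega}\phi(z)\Phi(\alpha z), \quad
#'   z = (u - \xi)/\omega,} one per sheet axis. With both skews zero the
#' density reduces to a symmetric 2D Gaussian. Integrates to 1 over the
#' plane before truncation.
#'
#' @param u_long,u_trans evaluation coordinates (mm), vectorized.
#' @param params list with `location` (length 2: longitudinal,
#'   transverse), `scale` (> 0, length 2), `alpha` (length 2).
#' @return density values (non-negative).
#' @export
skew_gaussian_density <- function(u_long, u_trans, params) {
  if (any(params$scale <= 0)) stop("scales must be > 0", call. = FALSE)
  z1 <- (u_long - params$location[1]) / params$scale[1]
  z2 <- (u_trans - params$location[2]) / params$scale[2]
  (2 / params$scale[1]) * stats::dnorm(z1) * stats::pnorm(params$alpha[1] * z1) *
    (2 / params$scale[2]) * stats::dnorm(z2) * stats::pnorm(params$alpha[2] * z2)
}

#' Default associational skew-field parameter grid
#'
#' Nine parameter sets on the 3 x 3 injection grid (septal/middle/temporal
#' x CA3c/CA3b/CA3a). The published fits are not tabulated, so these are
#' qualitative placeholders shipped as configuration: fields elongated
#' along the longitudinal axis and skewed away from the injection site.
#'
#' @param geometry sheet geometry, see [default_geometry()].
#' @return data.frame, one row per grid node, with node coordinates
#'   (`node_long`, `node_trans`, mm) and field parameters
#'   (`dloc_long`, `dloc_trans` location offsets from the injection site,
#'   `scale_long`, `scale_trans`, `alpha_long`, `alpha_trans`,
#'   `amplitude`).
#' @export
assoc_param_grid <- function(geometry = default_geometry()) {
  ext <- geometry$CA3
  nodes <- expand.grid(
    node_long = ext[["longitudinal"]] * c(0.75, 0.5, 0.25),
    node_trans = ext[["transverse"]] * c(1 / 6, 3 / 6, 5 / 6)
  )
  row_alpha <- rep(c(-2, 0, 2), 3)         # septal rows skew temporal-ward
  col_alpha <- rep(c(2, 0, -2), each = 3)  # CA3c nodes skew distal-ward
  data.frame(nodes,
             dloc_long = 0, dloc_trans = 0,
             scale_long = 2.0, scale_trans = 0.6,
             alpha_long = row_alpha, alpha_trans = col_alpha,
             amplitude = 1)
}

# 1D linear interpolation weights with extrapolation off the grid ends.
interp1_weights <- function(nodes, x) {
  nodes_s <- sort(unique(nodes))
  i <- findInterval(x, nodes_s, all.inside = TRUE)
  x0 <- nodes_s[i]; x1 <- nodes_s[i + 1]
  t <- (x - x0) / (x1 - x0)
  list(lo = x0, hi = x1, t = t)
}

#' Associational terminal field for a CA3 cell
#'
#' Skew-field parameters are interpolated bilinearly in (longitudinal,
#' transverse) between the 3 x 3 grid nodes and extrapolated linearly
#' outside; the node values are returned unchanged at the nodes.
#'
#' @param longitudinal,transverse CA3 cell position (mm).
#' @param grid parameter grid, see [assoc_param_grid()].
#' @return list with `location` (absolute mm), `scale`, `alpha`,
#'   `amplitude`; class `"ca3net_skew_field"`.
#' @export
assoc_field_for <- function(longitudinal, transverse,
                            grid = assoc_param_grid()) {
  need <- c("node_long", "node_trans", "dloc_long", "dloc_trans",
            "scale_long", "scale_trans", "alpha_long", "alpha_trans",
            "amplitude")
  if (!all(need %in% names(grid)) || nrow(grid) != 9L) {
    stop("malformed associational parameter grid", call. = FALSE)
  }
  wl <- interp1_weights(grid$node_long, longitudinal)
  wt <- interp1_weights(grid$node_trans, transverse)
  interp_par <- function(col) {
    val <- function(nl, nt) {
      grid[[col]][grid$node_long == nl & grid$node_trans == nt]
    }
    v00 <- val(wl$lo, wt$lo); v10 <- val(wl$hi, wt$lo)
    v01 <- val(wl$lo, wt$hi); v11 <- val(wl$hi, wt$hi)
    (1 - wl$t) * ((1 - wt$t) * v00 + wt$t * v01) +
      wl$t * ((1 - wt$t) * v10 + wt$t * v11)
  }
  structure(list(
    location = c(longitudinal + interp_par("dloc_long"),
                 transverse + interp_par("dloc_trans")),
    scale = c(interp_par("scale_long"), interp_par("scale_trans")),
    alpha = c(interp_par("alpha_long"), interp_par("alpha_trans")),
    amplitude = interp_par("amplitude")
  ), class = "ca3net_skew_field")
}

#' Conduction delay from path length
#'
#' Axons are represented as propagation delays: path length divided by
#' the pathway conduction velocity (perforant path 0.32 m/s, mossy fibers
#' 0.27 m/s, associational 0.39 m/s). Path length is Euclidean sheet
#' distance for perforant-path and associational edges and arc length
#' along the fiber for mossy-fiber edges.
#'
#' @param path_length_mm path length, mm (>= 0), vectorized.
#' @param pathway one of `"LPP"`, `"MPP"`, `"PP"`, `"MF"`, `"ASSOC"`.
#' @return delay in ms.
#' @examples
#' compute_delay(1.0, "PP")   # 3.125 ms
#' compute_delay(2.7, "MF")   # 10 ms
#' @export
compute_delay <- function(path_length_mm, pathway) {
  v <- c(LPP = 0.32, MPP = 0.32, PP = 0.32, MF = 0.27, ASSOC = 0.39)
  if (!pathway %in% names(v)) stop("unknown pathway: ", pathway,
                                   call. = FALSE)
  if (any(path_length_mm < 0)) stop("path length must be >= 0",
                                    call. = FALSE)
  path_length_mm / v[[pathway]]  # mm / (mm/ms)
}
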