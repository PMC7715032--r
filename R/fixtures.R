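#' Specification for a planted-cluster raster fixture
#'
#' Emulates spatially and temporally dense regions of co-activity
#' ("clusters") with known ground truth, so the correlation pipeline can
#' be validated without running network simulations: on top of
#' independent background renewal spiking, each cluster event makes
#' nearby neurons (Gaussian spatial participation around the cluster
#' center) fire once near the event time (Gaussian temporal jitter).
#'
#' @param n_clusters number of cluster centers.
#' @param events_per_cluster planted events per cluster.
#' @param spatial_sd spatial extent (Gaussian sd) of a cluster, mm.
#' @param jitter_sd temporal jitter sd of participating spikes, ms.
#' @param participation probability that an in-field neuron joins an
#'   event (the Gaussian spatial profile multiplies this).
#' @param background_rate background renewal rate, Hz.
#' @param duration raster duration, ms.
#' @param centers optional matrix of cluster centers (longitudinal,
#'   transverse); drawn uniformly over the sheet when `NULL`.
#' @param roaming when `TRUE`, every event draws a fresh center
#'   uniformly over the sheet instead of reusing its cluster's center;
#'   this emulates upstream activity whose dense regions appear at
#'   varying locations (as when random input is spatially organized by
#'   topographic feedforward wiring) and keeps long-run firing rates
#'   spatially homogeneous.
#' @return list of class `"ca3net_cluster_spec"`.
#' @export
cluster_spec <- function(n_clusters = 3, events_per_cluster = 20,
                         spatial_sd = 0.5, jitter_sd = 2,
                         participation = 0.6, background_rate = 0.5,
                         duration = 5000, centers = NULL,
                         roaming = FALSE) {
  if (spatial_sd <= 0 || jitter_sd < 0) stop("invalid sds", call. = FALSE)
  if (participation < 0 || participation > 1) {
    stop("participation must be in [0, 1]", call. = FALSE)
  }
  structure(list(n_clusters = n_clusters,
                 events_per_cluster = events_per_cluster,
                 spatial_sd = spatial_sd, jitter_sd = jitter_sd,
                 participation = participation,
                 background_rate = background_rate,
                 duration = duration, centers = centers,
                 roaming = isTRUE(roaming)),
            class = "ca3net_cluster_spec")
}

#' Generate a raster with planted spatial cluster structure
#'
#' @param spec a [cluster_spec()].
#' @param layout a [build_layout()] result.
#' @param population population to draw neurons from (default `"DG"`).
#' @param seed integer seed (reproducible).
#' @return list with `raster` (a [spike_raster()]) and `events`
#'   (ground-truth table: `cluster`, `time_ms`, `center_long`,
#'   `center_trans`).
#' @export
make_cluster_raster <- function(spec, layout, population = "DG",
                                seed = 1L) {
  pop <- layout_population(layout, population)
  n <- nrow(pop)
  restore <- local_rng(seed)
  on.exit(restore(), add = TRUE)
  geom <- attr(layout, "geometry")[[population]]
  centers <- spec$centers
  if (is.null(centers) && spec$n_clusters > 0) {
    centers <- cbind(stats::runif(spec$n_clusters, 0,
                                  geom[["longitudinal"]]),
                     stats::runif(spec$n_clusters, 0,
                                  geom[["transverse"]]))
  }
  # background renewal spiking
  bg <- if (spec$background_rate > 0) {
    par <- renewal_params(spec$background_rate, 35)
    lapply(seq_len(n), function(i)
      generate_renewal_train(par, spec$duration))
  } else rep(list(numeric(0)), n)
  events <- data.frame(cluster = integer(0), time_ms = numeric(0),
                       center_long = numeric(0), center_trans = numeric(0))
  if (spec$n_clusters > 0 && spec$events_per_cluster > 0) {
    for (k in seq_len(spec$n_clusters)) {
      times <- sort(stats::runif(spec$events_per_cluster,
                                 5 * spec$jitter_sd,
                                 spec$duration - 5 * spec$jitter_sd))
      for (tt in times) {
        ctr <- if (spec$roaming) {
          c(stats::runif(1, 0, geom[["longitudinal"]]),
            stats::runif(1, 0, geom[["transverse"]]))
        } else centers[k, ]
        events <- rbind(events, data.frame(
          cluster = k, time_ms = tt,
          center_long = ctr[1], center_trans = ctr[2]))
        d2 <- (pop$longitudinal - ctr[1])^2 +
          (pop$transverse - ctr[2])^2
        p_join <- spec$participation *
          exp(-d2 / (2 * spec$spatial_sd^2))
        join <- which(stats::runif(n) < p_join)
        if (!length(join)) next
        sp <- tt + stats::rnorm(length(join), 0, spec$jitter_sd)
        sp <- pmin(pmax(sp, 0), spec$duration - 1e-6)
        for (q in seq_along(join)) {
          bg[[join[q]]] <- c(bg[[join[q]]], sp[q])
        }
      }
    }
  }
  bg <- lapply(bg, function(x) sort(unique(x)))
  list(raster = spike_raster(bg, spec$duration, population = population,
                             ids = pop$id),
       events = events)
}

#' Minimal toy networks for engine and calibration tests
#'
#' Builds tiny layouts and connectomes with exactly known structure:
#' single-synapse pairs, feedforward chains, or shared-input fans.
#'
#' @param n_pre,n_post population sizes.
#' @param pathway pathway label for the edges (`"LPP"`, `"MPP"`, `"MF"`,
#'   `"ASSOC"`).
#' @param wiring `"single"` (pre i -> post i), `"fan"` (pre 1 -> every
#'   post), or `"all"` (every pre -> every post).
#' @param separation_mm sheet distance between a connected pre/post pair
#'   (sets the delay through the pathway conduction velocity; for mossy
#'   fibers it is read as arc length along the fiber).
#' @param weight edge weight multiplier.
#' @param seed layout seed.
#' @return list with `layout` and `connectome`.
#' @export
make_toy_network <- function(n_pre, n_post, pathway = "MF",
                             wiring = c("single", "fan", "all"),
                             separation_mm = 1, weight = 1, seed = 1L) {
  wiring <- match.arg(wiring)
  pre_pop <- switch(pathway, LPP = "EC", MPP = "EC", MF = "DG",
                    ASSOC = "CA3",
                    stop("unknown pathway: ", pathway, call. = FALSE))
  layer <- switch(pathway, LPP = "lacunosum_distal",
                  MPP = "lacunosum_proximal", MF = "lucidum",
                  ASSOC = "radiatum")
  n_ec <- if (pre_pop == "EC") n_pre else 0
  n_dg <- if (pre_pop == "DG") n_pre else 0
  n_ca3 <- n_post + if (pre_pop == "CA3") n_pre else 0
  lay <- build_layout(n_ec, n_dg, n_ca3, seed = seed)
  if (n_pre == 0 || n_post == 0) {
    return(list(layout = lay,
                connectome = structure(
                  list(edges = empty_edges(), mf_dropped = 0L,
                       seed = as.integer(seed),
                       config = NULL,
                       summary = data.frame(pathway = character(0),
                                            n_edges = integer(0))),
                  class = "ca3net_connectome")))
  }
  pre_ids <- seq_len(n_pre) - 1L
  post_offset <- if (pre_pop == "CA3") n_pre else 0L
  post_ids <- seq_len(n_post) - 1L + post_offset
  pairs <- switch(wiring,
    single = data.frame(pre = pre_ids,
                        post = rep(post_ids,
                                   length.out = n_pre)),
    fan = data.frame(pre = pre_ids[1], post = post_ids),
    all = expand.grid(pre = pre_ids, post = post_ids))
  edges <- data.frame(pre_pop = pre_pop, pre_id = pairs$pre,
                      post_id = pairs$post, pathway = pathway,
                      layer = layer,
                      delay_ms = compute_delay(separation_mm, pathway),
                      weight = weight, stringsAsFactors = FALSE)
  conn <- structure(list(edges = edges, mf_dropped = 0L,
                         seed = as.integer(seed), config = NULL,
                         summary = data.frame(pathway = pathway,
                                              n_edges = nrow(edges))),
                    class = "ca3net_connectome")
  list(layout = lay, connectome = conn)
}
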