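#' Simulation configuration
#'
#' @param dt integration step, ms (default 0.025).
#' @param duration simulated time, ms (default 5000).
#' @param threshold somatic spike-detection threshold, mV (default -10,
#'   upward crossings).
#' @param lockout refractory deduplication window for threshold
#'   crossings, ms.
#' @param seed integer seed (recorded; the network integration itself is
#'   deterministic given connectome and sources).
#' @param record_cells integer ids of cells whose somatic voltage to
#'   record (empty = none).
#' @param record_every record every k-th step.
#' @return list of class `"ca3net_sim_config"`.
#' @export
sim_config <- function(dt = 0.025, duration = 5000, threshold = -10,
                       lockout = 2, seed = 1L, record_cells = integer(0),
                       record_every = 40L) {
  if (dt <= 0 || duration < 0) stop("invalid dt/duration", call. = FALSE)
  structure(list(dt = dt, duration = duration, threshold = threshold,
                 lockout = lockout, seed = as.integer(seed),
                 record_cells = as.integer(record_cells),
                 record_every = as.integer(record_every)),
            class = "ca3net_sim_config")
}

# Flatten a calibration result list into the kinetics records consumed
# by the C++ engine, one per layer.
kinetics_table <- function(kinetics) {
  lapply(kinetics, function(k) {
    list(ampa_tau1 = k$ampa$tau1, ampa_tau2 = k$ampa$tau2,
         ampa_g = k$ampa$weight,
         ampa_norm = exp(-ampa_peak_time(k$ampa$tau1, k$ampa$tau2) /
                           k$ampa$tau2) -
           exp(-ampa_peak_time(k$ampa$tau1, k$ampa$tau2) / k$ampa$tau1),
         nmda_tau1 = k$nmda$tau1, nmda_tau2 = k$nmda$tau2,
         nmda_tau3 = k$nmda$tau3, nmda_w = k$nmda$w,
         nmda_g = k$nmda$weight, nmda_norm = k$nmda$normalizer,
         mg = k$nmda$mg)
  })
}

#' Simulate the network defined by a connectome
#'
#' Integrates the conductance-based target population at fixed step `dt`,
#' delivering every presynaptic spike through its edge after the edge's
#' conduction delay; each delivery activates the layer's calibrated
#' AMPA/NMDA conductances scaled by the edge weight. Output spikes are
#' upward somatic threshold crossings, refractory-deduplicated. The
#' simulation is deterministic given connectome, sources and
#' configuration.
#'
#' @param connectome a [build_connectome()] result (its `edges` may
#'   target any population; see `target`).
#' @param sources named list of [spike_raster()] objects, one per
#'   external source population appearing in `edges$pre_pop`.
#' @param layout a [build_layout()] result (sizes the target population).
#' @param config a [sim_config()].
#' @param target simulated population (default `"CA3"`); edges whose
#'   `pre_pop` equals `target` are recurrent and resolved internally.
#' @param presets preset name or list: either a single [cell_preset()]
#'   type name for all cells or an integer-indexed list (`types`,
#'   `assignment`) for mixed populations.
#' @param kinetics per-layer calibrated kinetics, see
#'   [default_kinetics()].
#' @return a [spike_raster()] for the target population; when voltages
#'   are recorded, attributes `v` (matrix) and `t_rec` are attached.
#' @export
simulate_network <- function(connectome, sources = list(), layout,
                             config = sim_config(), target = "CA3",
                             presets = "strongly_adapting",
                             kinetics = default_kinetics()) {
  pop <- layout_population(layout, target)
  n_cells <- nrow(pop)
  if (n_cells == 0) stop("no cells to simulate", call. = FALSE)
  edges <- connectome$edges
  ext_pops <- setdiff(unique(edges$pre_pop), target)
  for (p in ext_pops) {
    if (is.null(sources[[p]])) {
      stop("no source raster supplied for population ", p, call. = FALSE)
    }
  }
  if (is.character(presets)) {
    preset_list <- list(cell_preset(presets))
    assignment <- rep(0L, n_cells)
  } else {
    preset_list <- presets$types
    assignment <- as.integer(presets$assignment)
    stopifnot(length(assignment) == n_cells)
  }
  layers <- unique(edges$layer)
  missing_kin <- setdiff(layers, names(kinetics))
  if (length(missing_kin)) {
    stop("no kinetics for layer(s): ", paste(missing_kin, collapse = ", "),
         call. = FALSE)
  }
  kin_tab <- kinetics_table(kinetics)
  kin_id <- match(edges$layer, names(kin_tab)) - 1L
  comp_of <- layer_compartments()
  e_comp <- comp_of[edges$layer] - 1L
  id2idx <- function(ids, tab) match(ids, tab)  # dense ids 0..N-1
  internal <- edges$pre_pop == target
  e_pre <- integer(nrow(edges))
  e_pre[internal] <- match(edges$pre_id[internal], pop$id) - 1L
  # external deliveries (time + delay, edge), sorted by arrival time
  ext_time <- numeric(0)
  ext_edge <- integer(0)
  for (p in ext_pops) {
    sel <- which(edges$pre_pop == p)
    if (!length(sel)) next
    ras <- sources[[p]]
    tr <- ras$trains[match(edges$pre_id[sel], ras$ids)]
    nsp <- vapply(tr, length, integer(1))
    ext_time <- c(ext_time, unlist(tr, use.names = FALSE) +
                    rep.int(edges$delay_ms[sel], nsp))
    ext_edge <- c(ext_edge, rep.int(sel - 1L, nsp))
  }
  ord <- order(ext_time)
  edges_in <- list(pre_kind = as.integer(internal),
                   pre = as.integer(e_pre),
                   post = match(edges$post_id, pop$id) - 1L,
                   comp = as.integer(e_comp),
                   kin = as.integer(kin_id),
                   delay = edges$delay_ms,
                   weight = edges$weight)
  rec_idx <- match(config$record_cells, pop$id) - 1L
  res <- sim_network_cpp(preset_list, assignment, edges_in,
                         unname(kin_tab),
                         list(time = ext_time[ord],
                              edge = ext_edge[ord]),
                         list(cell = integer(0), comp = integer(0),
                              amp = numeric(0), start = numeric(0),
                              end = numeric(0)),
                         list(dt = config$dt, duration = config$duration,
                              threshold = config$threshold,
                              lockout = config$lockout,
                              rec_every = config$record_every,
                              rec_cells = as.integer(rec_idx),
                              rec_comp = preset_list[[1]]$soma))
  trains <- split(res$spike_t, factor(res$spike_id,
                                      levels = seq_len(n_cells) - 1L))
  trains <- lapply(trains, function(x) x[x < config$duration])
  out <- spike_raster(trains, duration = config$duration,
                      population = target, ids = pop$id)
  if (length(rec_idx)) {
    nr <- res$rec_rows
    attr(out, "v") <- res$v[seq_len(nr), , drop = FALSE]
    attr(out, "t_rec") <- res$t[seq_len(nr)]
  }
  out
}
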