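#' Compartment order and layer mapping of the reduced CA3 cell
#'
#' The reduced pyramidal cell is a chain of 8 compartments, one per
#' afferent layer plus the soma: distal stratum oriens, proximal oriens,
#' soma, stratum lucidum, proximal and distal radiatum, and proximal and
#' distal lacunosum-moleculare. Every pathway targets exactly one
#' compartment: lateral perforant path the distal lacunosum, medial
#' perforant path the proximal lacunosum, mossy fibers the lucidum (or
#' the proximal oriens for infrapyramidal-origin fibers within CA3c), and
#' the associational system the radiatum and oriens.
#'
#' @return named integer vector: compartment index (1-based) per layer.
#' @export
layer_compartments <- function() {
  c(oriens = 1L, oriens_proximal = 2L, soma = 3L, lucidum = 4L,
    radiatum = 5L, radiatum_distal = 6L, lacunosum_proximal = 7L,
    lacunosum_distal = 8L)
}

# Channel column order expected by the integrator.
chan_names <- c("Na", "KDR", "KA", "KM", "Ca", "KC", "KAHP", "HCN", "leak")

# Build a preset from per-compartment areas (um^2) and channel densities
# (mS/cm^2). Conductances in uS, capacitance in nF.
make_preset <- function(areas_um2, dens, cm = 1.5, rm = 10e3,
                        g_ax = NULL, e_leak = -65, v_init = -65,
                        soma = 3L, ca_beta = 0.075) {
  nc <- length(areas_um2)
  a_cm2 <- areas_um2 * 1e-8
  gbar <- matrix(0, nc, length(chan_names),
                 dimnames = list(NULL, chan_names))
  for (ch in names(dens)) {
    gbar[, ch] <- dens[[ch]] * a_cm2 * 1000  # mS/cm^2 * cm^2 -> uS
  }
  gbar[, "leak"] <- gbar[, "leak"] + a_cm2 / rm * 1e6  # Rm ohm cm^2 -> uS
  if (is.null(g_ax)) g_ax <- rep(0.1, nc - 1)
  list(C = a_cm2 * cm * 1000,            # uF/cm^2 * cm^2 -> nF
       g_ax = g_ax,
       gbar = gbar,
       ca_phi = 0.13e-3 / a_cm2,         # nA -> uA/cm^2 conversion folded in
       ca_beta = ca_beta,
       e_leak = e_leak, v_init = v_init, soma = soma - 1L,
       areas_um2 = areas_um2)
}

ca3_areas <- function() {
  # oriens_d, oriens_p, soma, lucidum, rad_p, rad_d, lm_p, lm_d
  c(4000, 2500, 1500, 1500, 3000, 3000, 2000, 2000)
}

#' Reduced-cell presets for the three CA3 firing types and granule cells
#'
#' Channel complements follow standard Hodgkin-Huxley style formalisms
#' (transient Na, delayed-rectifier K, A-type K, M-type K, high-threshold
#' Ca, fast Ca- and voltage-dependent K, slow Ca-dependent
#' afterhyperpolarization K, HCN, leak). The three pyramidal presets are
#' tuned so a standard somatic step-current protocol elicits the three
#' firing types observed in CA3: bursting (dendritic Ca/KC interplay),
#' strongly adapting (strong M-type and AHP currents) and weakly adapting.
#' The granule preset is a sparsely firing regular-spiking cell used when
#' the dentate population is simulated explicitly.
#'
#' @param type one of `"bursting"`, `"strongly_adapting"`,
#'   `"weakly_adapting"`, `"granule"`.
#' @return preset list consumed by [simulate_network()]; fields `C` (nF),
#'   `g_ax` (uS), `gbar` (uS, compartments x channels), `ca_phi`,
#'   `ca_beta`, `e_leak`, `v_init`, `soma`.
#' @export
cell_preset <- function(type = c("weakly_adapting", "strongly_adapting",
                                 "bursting", "granule")) {
  type <- match.arg(type)
  a <- ca3_areas()
  zero8 <- numeric(8)
  soma_only <- function(x) { z <- zero8; z[3] <- x; z }
  dend <- function(x, comps) { z <- zero8; z[comps] <- x; z }
  dens <- switch(type,
    weakly_adapting = list(
      Na = soma_only(30), KDR = soma_only(40),
      KM = soma_only(0.5), HCN = dend(0.05, c(1, 5, 6, 7, 8)),
      leak = zero8),
    strongly_adapting = list(
      Na = soma_only(30), KDR = soma_only(40),
      KM = soma_only(3), KAHP = dend(4, c(3, 4, 5)),
      Ca = dend(1.5, c(3, 4, 5)), HCN = dend(0.05, c(1, 5, 6, 7, 8)),
      leak = zero8),
    bursting = list(
      Na = soma_only(30), KDR = soma_only(20),
      Ca = dend(5, c(4, 5)), KC = dend(10, c(4, 5)),
      KAHP = dend(0.8, c(4, 5)), leak = zero8),
    granule = list(
      Na = soma_only(40), KDR = soma_only(30),
      KM = soma_only(1), leak = zero8)
  )
  if (type == "granule") {
    a <- c(800, 600, 600, 400, 800, 800, 600, 600)
    return(make_preset(a, dens, cm = 1, rm = 20e3,
                       g_ax = rep(0.05, 7), e_leak = -70, v_init = -70))
  }
  make_preset(a, dens)
}

#' Standard step-current protocol for firing-type classification
#'
#' Injects a somatic current step into a single isolated cell and
#' returns its spike times.
#'
#' @param preset a [cell_preset()].
#' @param amp_nA step amplitude (default 0.3 nA).
#' @param start_ms,dur_ms step onset and duration.
#' @param dt integration step, ms.
#' @return numeric spike times (ms).
#' @export
step_protocol <- function(preset, amp_nA = 0.3, start_ms = 100,
                          dur_ms = 1000, dt = 0.025) {
  res <- run_single_cell(preset, duration = start_ms + dur_ms + 100,
                         inj = list(comp = preset$soma, amp = amp_nA,
                                    start = start_ms,
                                    end = start_ms + dur_ms),
                         dt = dt)
  res$spikes
}

#' Classify the firing type of a step-current response
#'
#' A response is bursting when it opens with at least 3 spikes at
#' inter-spike intervals below 10 ms; otherwise it is classified by the
#' adaptation index \eqn{AI = (ISI_{last} - ISI_{first}) /
#' (ISI_{last} + ISI_{first})}: strongly adapting when AI > 0.3, weakly
#' adapting otherwise.
#'
#' @param spike_times spike times (ms) under the standard protocol.
#' @param burst_isi_ms onset ISI threshold for bursting (default 10).
#' @param ai_threshold adaptation-index threshold (default 0.3).
#' @return `"bursting"`, `"strongly adapting"` or `"weakly adapting"`.
#' @examples
#' classify_firing_type(c(0, 20, 40, 60))             # weakly adapting
#' classify_firing_type(cumsum(c(0, 20, 40, 80, 160)))  # strongly adapting
#' @export
classify_firing_type <- function(spike_times, burst_isi_ms = 10,
                                 ai_threshold = 0.3) {
  if (length(spike_times) < 2) {
    stop("protocol produced fewer than 2 spikes", call. = FALSE)
  }
  isi <- diff(sort(spike_times))
  if (length(isi) >= 2 && all(isi[1:2] < burst_isi_ms)) return("bursting")
  ai <- (isi[length(isi)] - isi[1]) / (isi[length(isi)] + isi[1])
  if (ai > ai_threshold) "strongly adapting" else "weakly adapting"
}

# Run one isolated cell: optional current injection and/or a single
# synaptic event; returns spikes and the somatic voltage trace.
run_single_cell <- function(preset, duration, inj = NULL, syn = NULL,
                            dt = 0.025, record_comp = NULL) {
  edges <- list(pre_kind = integer(0), pre = integer(0), post = integer(0),
                comp = integer(0), kin = integer(0), delay = numeric(0),
                weight = numeric(0))
  kin <- list()
  ext <- list(time = numeric(0), edge = integer(0))
  if (!is.null(syn)) {
    edges <- list(pre_kind = 0L, pre = 0L, post = 0L,
                  comp = as.integer(syn$comp), kin = 0L,
                  delay = 0, weight = 1)
    kin <- list(syn$kin)
    ext <- list(time = syn$time, edge = rep(0L, length(syn$time)))
  }
  inj_in <- if (is.null(inj)) {
    list(cell = integer(0), comp = integer(0), amp = numeric(0),
         start = numeric(0), end = numeric(0))
  } else {
    list(cell = 0L, comp = as.integer(inj$comp), amp = inj$amp,
         start = inj$start, end = inj$end)
  }
  if (is.null(record_comp)) record_comp <- preset$soma
  res <- sim_network_cpp(list(preset), 0L, edges, kin, ext, inj_in,
                         list(dt = dt, duration = duration,
                              threshold = -10, lockout = 2,
                              rec_every = 1L, rec_cells = 0L,
                              rec_comp = as.integer(record_comp)))
  nr <- res$rec_rows
  list(spikes = res$spike_t, t = res$t[seq_len(nr)],
       v = res$v[seq_len(nr), 1])
}
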