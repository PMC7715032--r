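#' Renewal-process parameters for surrogate spike sources
#'
#' Entorhinal input is modelled as a homogeneous Poisson process with an
#' exponentially decaying refractory period: after each spike the hazard
#' recovers as \deqn{\lambda(t) = \lambda_0 (1 - e^{-\Delta t/\tau})}
#' with recovery time constant \eqn{\tau} = 35 ms. \eqn{\lambda_0} (the
#' base rate) is calibrated so that the realized mean rate equals
#' `target_rate`. The entorhinal default realizes 5 Hz; the random
#' dentate surrogate used in the rMF configurations realizes 0.62 Hz.
#'
#' @param target_rate realized mean firing rate, Hz (>= 0).
#' @param refractory_tau refractory recovery time constant, ms (> 0).
#' @param base_rate internal dominating rate, Hz; calibrated automatically
#'   when `NULL`.
#' @return list of class `"ca3net_renewal"` with fields `target_rate`,
#'   `refractory_tau`, `base_rate`.
#' @export
renewal_params <- function(target_rate = 5, refractory_tau = 35,
                           base_rate = NULL) {
  if (target_rate < 0) stop("target_rate must be >= 0", call. = FALSE)
  if (refractory_tau <= 0) stop("refractory_tau must be > 0", call. = FALSE)
  if (is.null(base_rate)) {
    base_rate <- calibrate_base_rate(target_rate, refractory_tau)
  }
  if (base_rate < target_rate) {
    stop("base_rate must be >= target_rate", call. = FALSE)
  }
  structure(list(target_rate = target_rate,
                 refractory_tau = refractory_tau,
                 base_rate = base_rate),
            class = "ca3net_renewal")
}

#' Entorhinal and dentate-surrogate source defaults
#' @rdname renewal_params
#' @export
ec_source_params <- function() renewal_params(5, 35)

#' @rdname renewal_params
#' @export
dg_surrogate_params <- function() renewal_params(0.62, 35)

#' Calibrate the base rate of the refractory renewal process
#'
#' The realized rate of the process is the reciprocal of the mean
#' inter-spike interval, \deqn{E[ISI] = \int_0^\infty
#' \exp\{-\lambda_0 [t - \tau (1 - e^{-t/\tau})]\} dt,}
#' obtained from the hazard's survival function. The base rate
#' \eqn{\lambda_0} is found by root-finding on this semi-analytic map so
#' the realized rate matches `target_rate`.
#'
#' @param target_rate desired realized mean rate, Hz.
#' @param refractory_tau refractory time constant, ms.
#' @return base rate in Hz (0 when `target_rate` is 0). In the
#'   `refractory_tau -> 0` limit the process is plain Poisson and the base
#'   rate equals the target rate.
#' @export
calibrate_base_rate <- function(target_rate, refractory_tau = 35) {
  if (target_rate < 0) stop("target_rate must be >= 0", call. = FALSE)
  if (target_rate == 0) return(0)
  if (target_rate >= 1000) {
    stop("target_rate beyond the refractory-limited ceiling", call. = FALSE)
  }
  tau_s <- refractory_tau / 1000  # seconds
  realized <- function(lambda0) {
    isi <- stats::integrate(function(t)
      exp(-lambda0 * (t - tau_s * (1 - exp(-t / tau_s)))),
      0, Inf, rel.tol = 1e-10)$value
    1 / isi
  }
  # realized(l0) < l0 and is increasing; bracket upward from target
  lo <- target_rate
  hi <- target_rate
  repeat {
    hi <- hi * 2
    if (realized(hi) >= target_rate) break
    if (hi > 1e7) stop("calibration failed to bracket", call. = FALSE)
  }
  stats::uniroot(function(l0) realized(l0) - target_rate, c(lo, hi),
                 tol = 1e-10 * max(1, target_rate))$root
}

#' Generate one renewal-process spike train
#'
#' Exact sampling by thinning: candidate events are drawn from the
#' dominating Poisson process at the base rate and accepted with
#' probability \eqn{1 - e^{-\Delta t/\tau}}, where \eqn{\Delta t} is the
#' time since the last accepted spike. The hazard is bounded by the base
#' rate, so thinning is exact.
#'
#' @param params a [renewal_params()] object.
#' @param duration train duration, ms (> 0).
#' @param seed integer seed (per-neuron substreams are derived from it by
#'   the raster generators).
#' @return numeric vector of strictly increasing spike times in
#'   `[0, duration)` (ms); empty for `target_rate` 0.
#' @export
generate_renewal_train <- function(params, duration, seed = NULL) {
  if (duration <= 0) stop("duration must be > 0", call. = FALSE)
  if (!inherits(params, "ca3net_renewal")) {
    stop("`params` must come from renewal_params()", call. = FALSE)
  }
  if (params$target_rate == 0 || params$base_rate == 0) return(numeric(0))
  restore <- if (!is.null(seed)) local_rng(seed) else NULL
  lam0 <- params$base_rate / 1000  # events per ms
  tau <- params$refractory_tau
  out <- numeric(max(16, ceiling(params$target_rate * duration / 1000 * 2)))
  n_out <- 0L
  t <- 0
  last <- -Inf
  # draw candidates in blocks for speed
  repeat {
    n_blk <- max(16L, ceiling(lam0 * (duration - t) * 1.5))
    gaps <- stats::rexp(n_blk, lam0)
    u <- stats::runif(n_blk)
    for (k in seq_len(n_blk)) {
      t <- t + gaps[k]
      if (t >= duration) break
      if (u[k] < 1 - exp(-(t - last) / tau)) {
        n_out <- n_out + 1L
        if (n_out > length(out)) out <- c(out, numeric(length(out)))
        out[n_out] <- t
        last <- t
      }
    }
    if (t >= duration) break
  }
  if (!is.null(restore)) restore()
  out[seq_len(n_out)]
}

#' Generate a raster of independent renewal trains
#'
#' Each neuron uses an independent RNG substream derived from
#' `(seed, neuron id)` so that rasters are reproducible regardless of
#' generation order.
#'
#' @param n_neurons number of trains.
#' @param params a [renewal_params()] object.
#' @param duration duration, ms.
#' @param seed integer master seed.
#' @param population population label stored on the raster.
#' @param ids optional neuron ids (default `0:(n_neurons-1)`).
#' @return a [spike_raster()] object.
#' @export
renewal_raster <- function(n_neurons, params, duration, seed = 1L,
                           population = "EC", ids = NULL) {
  if (is.null(ids)) ids <- seq_len(n_neurons) - 1L
  trains <- lapply(seq_len(n_neurons), function(i) {
    generate_renewal_train(params, duration,
                           seed = substream_seed(seed, ids[i]))
  })
  spike_raster(trains, duration, population = population, ids = ids)
}

# Derive a 32-bit substream seed from (seed, id); stays below 2^31.
substream_seed <- function(seed, id) {
  x <- (as.double(seed) * 2654435761 + as.double(id) * 40503 + 97) %%
    2147483647
  as.integer(x)
}

#' Spike raster container
#'
#' @param trains list of numeric vectors of spike times (ms), each sorted
#'   and within `[0, duration)`.
#' @param duration raster duration, ms.
#' @param population label of the source population.
#' @param ids integer neuron ids aligned with `trains`.
#' @return object of class `"spike_raster"`.
#' @export
spike_raster <- function(trains, duration, population = "CA3", ids = NULL) {
  if (is.null(ids)) ids <- seq_along(trains) - 1L
  stopifnot(length(ids) == length(trains))
  trains <- lapply(trains, function(tt) sort(as.numeric(tt)))
  bad <- vapply(trains, function(tt)
    length(tt) && (min(tt) < 0 || max(tt) >= duration), logical(1))
  if (any(bad)) stop("spike times must lie in [0, duration)", call. = FALSE)
  structure(list(trains = trains, duration = as.numeric(duration),
                 population = population, ids = as.integer(ids)),
            class = "spike_raster")
}

#' @export
print.spike_raster <- function(x, ...) {
  ns <- vapply(x$trains, length, integer(1))
  cat("<spike_raster> ", length(x$trains), " ", x$population,
      " neurons, ", x$duration, " ms, ", sum(ns), " spikes (mean rate ",
      signif(mean(ns) / x$duration * 1000, 4), " Hz)\n", sep = "")
  invisible(x)
}

#' Realized mean firing rate of a raster
#' @param raster a [spike_raster()].
#' @return grand mean rate, Hz (total spikes / total observed time).
#' @export
mean_rate <- function(raster) {
  n <- sum(vapply(raster$trains, length, integer(1)))
  n / (length(raster$trains) * raster$duration) * 1000
}

#' Bin a spike raster into a binary matrix
#'
#' Bin `b` covers `[b*bin_ms, (b+1)*bin_ms)`. An entry is 1 if at least
#' one spike falls in the bin (binary clipping, matching the binary spike
#' trains used by the correlation statistic), so binarization is
#' idempotent and order-independent. Per-train mean and standard deviation
#' (population formula, denominator N) over all bins are attached.
#'
#' @param raster a [spike_raster()].
#' @param bin_ms bin width, ms (default 1).
#' @return list of class `"binned_spikes"`: `x` (0/1 integer matrix,
#'   neurons x bins), `bin_ms`, `n_bins`, `mu`, `sigma`, `ids`.
#' @export
bin_spikes <- function(raster, bin_ms = 1) {
  if (bin_ms <= 0) stop("bin_ms must be > 0", call. = FALSE)
  n_bins <- as.integer(ceiling(raster$duration / bin_ms))
  x <- matrix(0L, length(raster$trains), n_bins)
  for (i in seq_along(raster$trains)) {
    b <- unique(floor(raster$trains[[i]] / bin_ms)) + 1L
    x[i, b] <- 1L
  }
  mu <- rowMeans(x)
  sigma <- sqrt(rowMeans(x^2) - mu^2)
  structure(list(x = x, bin_ms = bin_ms, n_bins = n_bins,
                 mu = mu, sigma = sigma, ids = raster$ids,
                 population = raster$population),
            class = "binned_spikes")
}
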