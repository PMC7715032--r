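#' Overlap-normalized cross-correlation of two binned spike trains
#'
#' For binary trains x, y with full-train mean and population standard
#' deviation, the correlation at integer lag n is
#' \deqn{(x \star y)[n] = \frac{1}{\sigma_x \sigma_y}\,\frac{1}{L(n)}
#'   \sum_m (x[m] - \mu_x)(y[m + n] - \mu_y),}
#' the sum running over the overlap of the shifted trains, whose length is
#' \eqn{L(n) = N - |n|}. With this normalization the autocorrelation of
#' any non-constant train equals 1 at lag 0. Values are reported only
#' where the overlap holds at least 2 bins.
#'
#' @param x,y binary (0/1) vectors of equal length N.
#' @param max_lag maximum lag in bins (< N).
#' @return list of class `"ca3net_xcorr"`: `lag` (bins, -max_lag..max_lag),
#'   `value`, `overlap` (L per lag).
#' @export
normalized_xcorr <- function(x, y, max_lag) {
  N <- length(x)
  if (length(y) != N) stop("trains must have equal length", call. = FALSE)
  if (max_lag >= N) stop("max_lag must be < train length", call. = FALSE)
  mx <- mean(x); my <- mean(y)
  sx <- sqrt(mean(x^2) - mx^2); sy <- sqrt(mean(y^2) - my^2)
  if (sx == 0 || sy == 0) {
    stop("degenerate (constant) train: sigma = 0", call. = FALSE)
  }
  lags <- seq.int(-max_lag, max_lag)
  val <- numeric(length(lags))
  L <- N - abs(lags)
  for (k in seq_along(lags)) {
    n <- lags[k]
    lo <- max(0L, -n); hi <- N - 1L - max(0L, n)
    if (L[k] < 2) { val[k] <- NA_real_; next }
    m <- seq.int(lo, hi)
    val[k] <- sum((x[m + 1L] - mx) * (y[m + n + 1L] - my)) /
      (sx * sy * L[k])
  }
  structure(list(lag = lags, value = val, overlap = L),
            class = "ca3net_xcorr")
}

# Spatial bin index (0-based) for signed displacements: floor(d / h) with
# `m_neg` negative-side bins; axis covers [-m_neg*h, m_pos*h).
spatial_bin <- function(d, h, m_neg) floor(d / h) + m_neg

#' Accumulate a 3D space-time correlation map
#'
#' Computes the normalized cross-correlation of every admitted neuron
#' pair and averages pairs located at the same relative displacement:
#' the signed (post minus reference) longitudinal and transverse
#' displacements index the spatial bin (0.1 mm resolution), and the
#' pair's correlation is entered at every time lag (1 ms resolution).
#' Each unordered pair contributes both orders -- the reversed order at
#' the negated displacement with the lag axis reversed -- which enforces
#' the point symmetry map[d, t] = map[-d, -t]. Silent (sigma = 0)
#' neurons are dropped with a logged count; self-pairs are excluded.
#'
#' @param raster a [spike_raster()] of the mapped population.
#' @param layout a [build_layout()] result providing neuron positions.
#' @param admit optional logical vector over the raster's neurons: a pair
#'   is admitted when at least one member is `TRUE` (used by
#'   [local_map()]); `NULL` admits every pair.
#' @param bin_ms temporal bin width, ms (default 1).
#' @param spatial_mm spatial bin width, mm (default 0.1).
#' @param max_lag_ms maximum time lag, ms (default 500).
#' @param max_pairs optional cap on the number of unordered pairs
#'   (uniform seeded subsample); defaults to full enumeration below
#'   2,000 active neurons.
#' @param seed seed for pair subsampling.
#' @return object of class `"ca3net_corr_map"`: `value` (3D array,
#'   longitudinal lag x transverse lag x time lag; `NA` where no pair
#'   contributed), `cov` (its unnormalized-covariance twin, used by
#'   profile-width estimation), `count` (pairs per spatial bin), axis vectors
#'   `d_long`, `d_trans` (bin lower edges, mm), `lag_ms`, plus `n_bins`,
#'   `n_dropped`, `n_pairs`, `mean_pp`, `mean_inv_ss`, `scope`.
#' @export
accumulate_map <- function(raster, layout, admit = NULL, bin_ms = 1,
                           spatial_mm = 0.1, max_lag_ms = 500,
                           max_pairs = NULL, seed = 1L) {
  bs <- bin_spikes(raster, bin_ms)
  pop <- layout_population(layout, raster$population)
  pos <- pop[match(raster$ids, pop$id), , drop = FALSE]
  if (any(is.na(pos$id))) {
    stop("raster ids missing from the layout", call. = FALSE)
  }
  active <- bs$sigma > 0
  n_dropped <- sum(!active)
  idx <- which(active)
  if (length(idx) < 2) stop("fewer than 2 active neurons", call. = FALSE)
  if (!is.null(admit)) admit <- admit[idx]
  pr <- utils::combn(seq_along(idx), 2L)
  if (!is.null(admit)) {
    keep <- admit[pr[1, ]] | admit[pr[2, ]]
    pr <- pr[, keep, drop = FALSE]
  }
  if (!ncol(pr)) stop("no admissible neuron pair", call. = FALSE)
  if (is.null(max_pairs) && length(idx) > 2000) max_pairs <- 2e6
  if (!is.null(max_pairs) && ncol(pr) > max_pairs) {
    restore <- local_rng(seed)
    pr <- pr[, sample.int(ncol(pr), max_pairs), drop = FALSE]
    restore()
  }
  geom <- attr(layout, "geometry")[[raster$population]]
  m_l <- ceiling(geom[["longitudinal"]] / spatial_mm)
  m_t <- ceiling(geom[["transverse"]] / spatial_mm)
  nbl <- 2L * m_l; nbt <- 2L * m_t
  max_lag <- as.integer(round(max_lag_ms / bin_ms))

  i <- idx[pr[1, ]]; j <- idx[pr[2, ]]
  dl <- pos$longitudinal[j] - pos$longitudinal[i]
  dtr <- pos$transverse[j] - pos$transverse[i]
  bf <- spatial_bin(dl, spatial_mm, m_l) +
    nbl * spatial_bin(dtr, spatial_mm, m_t)
  br <- spatial_bin(-dl, spatial_mm, m_l) +
    nbl * spatial_bin(-dtr, spatial_mm, m_t)

  spikes <- lapply(raster$trains, function(tt)
    as.integer(unique(floor(tt / bin_ms))))
  res <- xcorr_accum_cpp(spikes[idx], bs$mu[idx], bs$sigma[idx],
                         bs$n_bins, max_lag,
                         pr[1, ] - 1L, pr[2, ] - 1L,
                         as.integer(bf), as.integer(br),
                         nbl * nbt)
  n_lag <- 2L * max_lag + 1L
  reshape3 <- function(x) aperm(array(x, dim = c(n_lag, nbl, nbt)),
                                c(2L, 3L, 1L))
  cnt <- matrix(res$count, nbl, nbt)
  denom <- ifelse(cnt > 0, cnt, NA)
  value <- sweep(reshape3(res$value), c(1, 2), denom, "/")
  covv <- sweep(reshape3(res$cov), c(1, 2), denom, "/")
  mu_i <- bs$mu[i]; mu_j <- bs$mu[j]
  structure(list(
    value = value, cov = covv, count = cnt,
    d_long = (seq_len(nbl) - 1L - m_l) * spatial_mm,
    d_trans = (seq_len(nbt) - 1L - m_t) * spatial_mm,
    lag_ms = seq.int(-max_lag, max_lag) * bin_ms,
    n_bins = bs$n_bins, bin_ms = bin_ms, spatial_mm = spatial_mm,
    n_dropped = n_dropped, n_pairs = ncol(pr),
    mean_pp = mean(mu_i * mu_j),
    mean_inv_ss = mean(1 / (bs$sigma[i] * bs$sigma[j])),
    scope = "global"), class = "ca3net_corr_map")
}

#' Local correlation map for one CA3 section
#'
#' Identical to [accumulate_map()] but admitting only pairs with at
#' least one neuron inside the given (longitudinal row, transverse
#' column) section; a pair spanning two sections contributes to both
#' sections' maps.
#'
#' @param raster,layout,... passed to [accumulate_map()].
#' @param row longitudinal window name (`"septal"`, `"middle"`,
#'   `"temporal"`).
#' @param column transverse division (`"CA3c"`, `"CA3b"`, `"CA3a"`).
#' @param grid a [section_grid()].
#' @return a `"ca3net_corr_map"` with `scope = "local(row.column)"`.
#' @export
local_map <- function(raster, layout, row, column, grid = section_grid(),
                      ...) {
  memb <- section_membership(layout, grid)
  key <- paste(row, column, sep = ".")
  if (!key %in% colnames(memb)) stop("unknown section: ", key,
                                     call. = FALSE)
  ca3 <- layout_population(layout, raster$population)
  in_sec <- memb[match(raster$ids, ca3$id), key]
  out <- accumulate_map(raster, layout, admit = in_sec, ...)
  out$scope <- paste0("local(", key, ")")
  out
}

#' Cross-sections of a correlation map
#'
#' @param map a `"ca3net_corr_map"`.
#' @param mode `"longitudinal-temporal"` (slice at a fixed transverse
#'   lag, default 0 mm) or `"longitudinal-transverse"` (slice at a fixed
#'   time lag).
#' @param at transverse lag (mm) or time lag (ms) of the slice.
#' @param threshold optional fraction of the maximum absolute value;
#'   entries with `|value| <` threshold * max are zeroed (the figures
#'   use 0.30).
#' @return matrix with axis attributes (`d_long` rows; `lag_ms` or
#'   `d_trans` columns).
#' @export
cross_section <- function(map, mode = c("longitudinal-temporal",
                                        "longitudinal-transverse"),
                          at = 0, threshold = NULL) {
  mode <- match.arg(mode)
  if (mode == "longitudinal-temporal") {
    k <- spatial_bin(at, map$spatial_mm, length(map$d_trans) / 2) + 1L
    if (k < 1 || k > length(map$d_trans)) stop("slice out of range",
                                               call. = FALSE)
    sl <- map$value[, k, ]
    dimnames(sl) <- NULL
    attr(sl, "d_long") <- map$d_long
    attr(sl, "lag_ms") <- map$lag_ms
  } else {
    k <- match(at, map$lag_ms)
    if (is.na(k)) stop("slice out of range", call. = FALSE)
    sl <- map$value[, , k]
    dimnames(sl) <- NULL
    attr(sl, "d_long") <- map$d_long
    attr(sl, "d_trans") <- map$d_trans
  }
  if (!is.null(threshold)) {
    mx <- max(abs(sl), na.rm = TRUE)
    sl[!is.na(sl) & abs(sl) < threshold * mx] <- 0
  }
  sl
}

#' Peak correlation of a map
#'
#' Maximum of the value array over all populated bins (self-pairs are
#' never part of a map). At reduced scale, bins holding very few pairs
#' are dominated by single-pair noise; `min_count` restricts the peak to
#' bins averaging at least that many pairs.
#'
#' @param map a `"ca3net_corr_map"`.
#' @param min_count minimum pairs per spatial bin (default 1, the plain
#'   maximum).
#' @return scalar peak correlation.
#' @export
peak_correlation <- function(map, min_count = 1) {
  v <- map$value
  if (min_count > 1) {
    mask <- map$count < min_count
    for (k in seq_along(map$lag_ms)) v[, , k][mask] <- NA
  }
  if (all(is.na(v))) stop("empty correlation map", call. = FALSE)
  max(v, na.rm = TRUE)
}

#' Analytic noise bound for a null (uncorrelated) map
#'
#' Under independent stationary trains the summed spike-coincidence
#' count feeding a (spatial bin, lag) cell is approximately Poisson with
#' mean `count * L(n) * mean_pp`; the cell's value is that count centered
#' and scaled by `mean_inv_ss / (count * L(n))`. The bound converts the
#' upper Poisson quantile at level `alpha`, Bonferroni-corrected over all
#' populated cells, into correlation units (one bin of slack covers the
#' near-deterministic centering terms). Map values of independent trains
#' stay below the bound with probability at least 1 - alpha.
#'
#' @param map a `"ca3net_corr_map"`.
#' @param alpha family-wise exceedance probability (default 0.01).
#' @return matrix of bounds (spatial bins x lags collapsed to the
#'   per-count bound): a list with `bound` (array like `value`) and
#'   `n_cells`.
#' @export
map_noise_bound <- function(map, alpha = 0.01) {
  L <- map$n_bins - abs(map$lag_ms / map$bin_ms)
  n_cells <- sum(map$count > 0) / 2 * length(map$lag_ms)
  dims <- dim(map$value)
  bound <- array(NA_real_, dims)
  a2 <- alpha / (2 * n_cells)
  for (k in seq_along(map$lag_ms)) {
    lam <- map$count * L[k] * map$mean_pp
    q <- stats::qpois(1 - a2, lam)
    b <- (q - lam + 1) * map$mean_inv_ss / (map$count * L[k])
    b[map$count == 0] <- NA
    bound[, , k] <- b
  }
  list(bound = bound, n_cells = n_cells)
}

#' Spatial half-width of the central correlation peak
#'
#' Extracts the longitudinal correlation profile near zero transverse
#' and time lag (averaging over a small transverse-lag band and time-lag
#' window to suppress bin noise; for separable Gaussian structure the
#' longitudinal shape is unchanged by this averaging) and fits
#' `A exp(-d^2 / (2 sigma_p^2)) + c` by least squares. The half-width at
#' half maximum is `sqrt(2 log 2) sigma_p`. For activity driven by
#' Gaussian spatial clusters of sd `s`, pair co-activation decays with
#' displacement sd `sqrt(2) s`, so the implied cluster sd is
#' `sigma_p / sqrt(2)`.
#'
#' @param map a `"ca3net_corr_map"`.
#' @param lag_band_ms half-width of the time-lag averaging window, ms.
#' @param trans_band_mm half-width of the transverse-lag averaging band,
#'   mm.
#' @param statistic `"covariance"` (default) fits the unnormalized
#'   covariance profile, whose spatial shape is free of the widening that
#'   per-train sigma normalization introduces when firing rates are
#'   spatially inhomogeneous; `"correlation"` fits the normalized map
#'   values.
#' @return list with `hwhm` (mm), `sigma_profile` (fitted profile sd,
#'   mm), `sigma_hat` (implied cluster sd, mm), `profile` (data.frame
#'   `d`, `value`).
#' @export
map_spatial_halfwidth <- function(map, lag_band_ms = 2,
                                  trans_band_mm = 0.25,
                                  statistic = c("covariance",
                                                "correlation")) {
  statistic <- match.arg(statistic)
  src <- if (statistic == "covariance") map$cov else map$value
  ctr_t <- abs(map$d_trans + map$spatial_mm / 2) <= trans_band_mm
  ctr_l <- abs(map$lag_ms) <= lag_band_ms
  sub <- src[, ctr_t, ctr_l, drop = FALSE]
  prof <- apply(sub, 1, mean, na.rm = TRUE)
  d <- map$d_long + map$spatial_mm / 2  # bin centers
  ok <- is.finite(prof)
  prof <- prof[ok]; d <- d[ok]
  if (length(prof) < 9) stop("profile too sparse", call. = FALSE)
  a0 <- max(prof) - stats::median(prof)
  obj <- function(par) {
    A <- par[1]; s <- exp(par[2]); cc <- par[3]
    sum((prof - (A * exp(-d^2 / (2 * s^2)) + cc))^2)
  }
  fit <- stats::optim(c(a0, log(0.5), stats::median(prof)), obj,
                      method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  sigma_p <- exp(fit$par[2])
  list(hwhm = sqrt(2 * log(2)) * sigma_p,
       sigma_profile = sigma_p,
       sigma_hat = sigma_p / sqrt(2),
       profile = data.frame(d = d, value = prof))
}

#' @export
print.ca3net_corr_map <- function(x, ...) {
  cat("<ca3net_corr_map> ", x$scope, ", ", x$n_pairs, " pairs, lags +/-",
      max(x$lag_ms), " ms, peak ", signif(peak_correlation(x), 4),
      "\n", sep = "")
  invisible(x)
}

#' Lag between two populations' spatio-temporal activity patterns
#'
#' Bins each population's activity into longitudinal strips by 1 ms time
#' bins, cross-correlates the strip signals of the two populations at
#' matched longitudinal positions, averages over strips, and returns the
#' time lag of the correlation peak -- the delay at which the downstream
#' pattern best matches the upstream one (positive: the second raster
#' lags the first).
#'
#' @param raster_ref,raster_post upstream and downstream
#'   [spike_raster()]s.
#' @param layout a [build_layout()] covering both populations.
#' @param strip_mm longitudinal strip width, mm.
#' @param max_lag_ms lag search range, ms.
#' @return list with `lag_ms` (peak lag), `lag` (axis), `value`
#'   (strip-averaged correlation per lag).
#' @export
population_lag <- function(raster_ref, raster_post, layout, strip_mm = 1,
                           max_lag_ms = 40) {
  pa <- layout_population(layout, raster_ref$population)
  pb <- layout_population(layout, raster_post$population)
  ba <- bin_spikes(raster_ref)
  bb <- bin_spikes(raster_post)
  sa <- floor(pa$longitudinal[match(raster_ref$ids, pa$id)] / strip_mm)
  sb <- floor(pb$longitudinal[match(raster_post$ids, pb$id)] / strip_mm)
  lags <- seq.int(-max_lag_ms, max_lag_ms)
  acc <- numeric(length(lags))
  wt <- 0
  for (st in intersect(unique(sa), unique(sb))) {
    x <- colSums(ba$x[sa == st, , drop = FALSE])
    y <- colSums(bb$x[sb == st, , drop = FALSE])
    x <- x - mean(x)
    y <- y - mean(y)
    sx <- stats::sd(x); sy <- stats::sd(y)
    if (sx == 0 || sy == 0) next
    N <- length(x)
    cc <- vapply(lags, function(n) {
      lo <- max(0L, -n); hi <- N - 1L - max(0L, n)
      m <- seq.int(lo, hi) + 1L
      sum(x[m] * y[m + n]) / ((hi - lo + 1) * sx * sy)
    }, numeric(1))
    acc <- acc + cc
    wt <- wt + 1
  }
  if (wt == 0) stop("no strip with activity in both rasters",
                    call. = FALSE)
  v <- acc / wt
  list(lag_ms = lags[which.max(v)], lag = lags, value = v)
}
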