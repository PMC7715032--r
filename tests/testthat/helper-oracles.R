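# Shared helpers: independent oracles and cached fixtures.

# Direct O(N * n_lags) evaluation of the overlap-normalized
# cross-correlation, written from the formula (independent of the
# package's sparse implementation).
brute_xcorr <- function(x, y, max_lag) {
  N <- length(x)
  mx <- mean(x); my <- mean(y)
  sx <- sqrt(mean(x^2) - mx^2)
  sy <- sqrt(mean(y^2) - my^2)
  vapply(-max_lag:max_lag, function(n) {
    s <- 0
    L <- 0
    for (m in 0:(N - 1)) {
      if (m + n >= 0 && m + n <= N - 1) {
        s <- s + (x[m + 1] - mx) * (y[m + n + 1] - my)
        L <- L + 1
      }
    }
    s / (sx * sy * L)
  }, numeric(1))
}

# Calibrated kinetics are expensive; share one calibration per session.
ref_kinetics <- local({
  kin <- NULL
  function() {
    if (is.null(kin)) kin <<- default_kinetics()
    kin
  }
})
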