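# Internal helpers shared across modules.

# Speed of light in vacuum (m/s).
.c0 <- 299792458

#' @keywords internal
stop_invalid <- function(...) stop(..., call. = FALSE)

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so simulation calls do not perturb
# unrelated randomness.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Wrap angles (rad) into [0, 2*pi).
wrap_2pi <- function(x) {
  out <- x %% (2 * pi)
  out[out < 0] <- out[out < 0] + 2 * pi
  out
}

# Signed wrap-aware angular distance a - b on the circle, result in (-pi, pi].
ang_diff <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  d[d > pi] <- d[d > pi] - 2 * pi
  d
}

# Unwrap a phase series (rad): remove jumps larger than pi between
# consecutive samples.
unwrap_phase <- function(p) {
  if (length(p) < 2) return(p)
  dp <- diff(p)
  jumps <- round(dp / (2 * pi))
  p - c(0, cumsum(jumps)) * 2 * pi
}

# FFT sample frequencies (like numpy.fft.fftfreq): length n, spacing d.
fft_freq <- function(n, d = 1) {
  k <- c(seq(0, floor((n - 1) / 2)), seq(-floor(n / 2), -1))
  k / (n * d)
}

# Parabolic interpolation of a peak at index i of y; returns fractional
# index offset in [-0.5, 0.5] (0 at edges or degenerate curvature).
parabolic_offset <- function(y, i) {
  if (i <= 1 || i >= length(y)) return(0)
  a <- y[i - 1]; b <- y[i]; cc <- y[i + 1]
  den <- a - 2 * b + cc
  if (!is.finite(den) || den == 0) return(0)
  off <- 0.5 * (a - cc) / den
  max(-0.5, min(0.5, off))
}

# Local maxima of x above `min_height`, at least `min_dist` samples apart
# (greedy, strongest first). Returns integer indices in ascending order.
find_peaks <- function(x, min_height = -Inf, min_dist = 1) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  cand <- cand[x[cand] > min_height]
  if (length(cand) <= 1 || min_dist <= 1) return(cand)
  cand <- cand[order(x[cand], decreasing = TRUE)]
  keep <- logical(0)
  kept <- integer(0)
  for (i in cand) {
    if (all(abs(i - kept) >= min_dist)) kept <- c(kept, i)
  }
  sort(kept)
}

# Linear-interpolated full width of y (on axis x) at `frac` of its maximum,
# measured around the global peak.
interp_fwhm <- function(x, y, frac = 0.5) {
  i0 <- which.max(y)
  half <- frac * y[i0]
  # walk left
  il <- i0
  while (il > 1 && y[il - 1] > half) il <- il - 1
  if (il == 1) return(NA_real_)
  xl <- x[il - 1] + (x[il] - x[il - 1]) * (half - y[il - 1]) / (y[il] - y[il - 1])
  ir <- i0
  n <- length(y)
  while (ir < n && y[ir + 1] > half) ir <- ir + 1
  if (ir == n) return(NA_real_)
  xr <- x[ir] + (x[ir + 1] - x[ir]) * (half - y[ir]) / (y[ir + 1] - y[ir])
  xr - xl
}
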