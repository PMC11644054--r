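# Processing chain: range FFT -> range gating -> slow-time phase ->
# VMD -> rate/interval estimation -> agreement statistics.

#' Range FFT of a slow-time cube
#'
#' Windowed FFT over fast time for every frame and channel. Bin spacing is
#' \eqn{c/(2B)}. The window's coherent gain is normalized out so a unit
#' target keeps unit envelope amplitude.
#'
#' @param cube a `slow_time_cube`
#' @param window `"hann"` or `"rect"`
#' @param gate range gate in metres (default 0.5-0.8 m)
#' @return a `range_profile`: complex array `bins`
#'   \[range bin, frame, channel\], `range_m` per bin, `gate`, `t`, config
#' @export
range_fft <- function(cube, window = c("hann", "rect"), gate = c(0.5, 0.8)) {
  stopifnot(inherits(cube, "slow_time_cube"))
  window <- match.arg(window)
  cfg <- cube$config
  n <- cfg$n_adc_samples
  w <- if (window == "hann")
    0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1)) else rep(1, n)
  d <- dim(cube$iq)
  bins <- array(0i, dim = d)
  for (ch in seq_len(d[3])) {
    bins[, , ch] <- stats::mvfft(cube$iq[, , ch] * w) / sum(w)
  }
  range_m <- (0:(n - 1)) * cfg$range_bin_m
  if (gate[1] >= gate[2]) stop_invalid("empty range gate")
  structure(list(bins = bins, range_m = range_m, gate = gate, t = cube$t,
                 config = cfg, truth = cube$truth),
            class = "range_profile")
}

#' Select the dominant range bin within the gate
#'
#' Bin with the maximum mean power (over frames and channels) among bins
#' whose range lies inside the gate; ties go to the lowest bin. If the
#' strongest bin of the whole profile lies outside the gate the result
#' carries a `no_target` flag (attribute) and a warning.
#'
#' @param profile a [range_fft()] result
#' @param gate optional override of the profile's gate (metres)
#' @return 0-based bin index (integer) with attributes `range_m`,
#'   `no_target`
#' @export
select_bin <- function(profile, gate = NULL) {
  stopifnot(inherits(profile, "range_profile"))
  if (is.null(gate)) gate <- profile$gate
  idx <- which(profile$range_m >= gate[1] & profile$range_m <= gate[2])
  if (length(idx) == 0)
    stop_invalid("range gate [", gate[1], ", ", gate[2],
                 "] m contains no bins of the profile")
  pow <- apply(Mod(profile$bins)^2, 1, mean)
  best_in <- idx[which.max(pow[idx])]   # which.max: first max = lowest bin
  no_target <- which.max(pow) != best_in
  if (no_target)
    warning("strongest return lies outside the range gate; gated bin may ",
            "not contain a target")
  structure(as.integer(best_in - 1L), range_m = profile$range_m[best_in],
            no_target = no_target)
}

#' Slow-time phase of a range bin
#'
#' Unwrapped phase of the selected bin over slow time; multiple RX channels
#' are unwrapped separately, their means removed, and averaged. The phase
#' maps to displacement as \eqn{R = \phi\lambda/(4\pi)}; an optional linear
#' detrend (default on) removes slow drift before decomposition.
#'
#' The measured bin phase also carries the beat-frequency leakage term of
#' the fast-time DFT, which is proportional to range: the total slope is
#' \eqn{(4\pi/\lambda)(1 + \rho)} with
#' \eqn{\rho = (N-1) B \lambda / (2 c N)} for a symmetric fast-time window
#' (about 4% at 5 GHz bandwidth and 60 GHz). The displacement estimate
#' divides this known factor out; the phase series itself is reported as
#' measured (rate estimation is scale-invariant).
#'
#' @param profile a [range_fft()] result
#' @param bin 0-based bin index (e.g. from [select_bin()])
#' @param detrend remove a linear trend from the unwrapped phase
#' @return a `phase_series`: `t`, `phase` (rad, detrended),
#'   `phase_raw` (rad), `displacement_m` (from the raw phase, mean removed),
#'   `fs`, `bin`
#' @export
extract_phase <- function(profile, bin, detrend = TRUE) {
  stopifnot(inherits(profile, "range_profile"))
  r <- bin + 1L
  if (r < 1 || r > dim(profile$bins)[1]) stop_invalid("bin out of range")
  nch <- dim(profile$bins)[3]
  ph <- sapply(seq_len(nch), function(ch) {
    p <- unwrap_phase(Arg(profile$bins[r, , ch]))
    p - mean(p)
  })
  ph <- if (is.matrix(ph)) rowMeans(ph) else ph
  cfg <- profile$config
  lam <- cfg$wavelength
  fs <- cfg$slow_rate
  rho <- (cfg$n_adc_samples - 1) * cfg$bandwidth * lam /
    (2 * .c0 * cfg$n_adc_samples)
  phase <- ph
  if (detrend) {
    tt <- profile$t
    fit <- stats::lm.fit(cbind(1, tt), ph)
    phase <- ph - fit$fitted.values
  }
  structure(list(t = profile$t, phase = phase, phase_raw = ph,
                 displacement_m = ph * lam / (4 * pi) / (1 + rho), fs = fs,
                 bin = as.integer(bin)),
            class = "phase_series")
}

#' Assign VMD modes to the respiration and heartbeat bands
#'
#' Respiration: the highest-power mode with centre frequency in
#' `resp_band` (default 0.1-0.7 Hz). Heartbeat: likewise in `heart_band`
#' (default 0.8-2.5 Hz). A band with no mode yields `NA` and a flag.
#'
#' @param result a [vmd()] result
#' @param resp_band,heart_band frequency bands in Hz
#' @return list with `resp` and `heart` mode indices (or `NA`), and logical
#'   flags `resp_missing`, `heart_missing`
#' @export
assign_modes <- function(result, resp_band = c(0.1, 0.7),
                         heart_band = c(0.8, 2.5)) {
  stopifnot(inherits(result, "vmd_result"))
  power <- colMeans(result$modes^2)
  pick <- function(band) {
    in_band <- which(result$omega_hz >= band[1] & result$omega_hz <= band[2])
    if (length(in_band) == 0) return(NA_integer_)
    in_band[which.max(power[in_band])]
  }
  resp <- pick(resp_band)
  heart <- pick(heart_band)
  list(resp = resp, heart = heart,
       resp_missing = is.na(resp), heart_missing = is.na(heart))
}

# Parabolic-interpolated frequency (Hz) of the dominant spectral peak of x.
spectral_peak <- function(x, fs) {
  n <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
  X <- Mod(stats::fft((x - mean(x)) * w))^2
  half <- floor(n / 2)
  Xh <- X[2:half]                       # skip DC
  i <- which.max(Xh) + 1L
  off <- parabolic_offset(log(X + .Machine$double.xmin), i)
  (i - 1 + off) * fs / n
}

# Peak times (s) of a quasi-periodic series sampled at fs, with
# sub-sample parabolic refinement; peaks at least 0.6/f0 apart.
mode_peak_times <- function(x, fs, f0) {
  min_dist <- max(1, floor(0.6 * fs / f0))
  idx <- find_peaks(x, min_height = 0, min_dist = min_dist)
  if (length(idx) == 0) return(numeric(0))
  (idx - 1 + vapply(idx, function(i) parabolic_offset(x, i), numeric(1))) / fs
}

#' Rate and interval estimates from assigned modes
#'
#' The rate of each vital is the parabolic-interpolated spectral peak of its
#' mode; intervals are successive peak-to-peak times of the time-domain
#' mode (inter-beat intervals in ms, breath-to-breath intervals in s).
#' Fewer than 3 detected peaks flags the interval series as short.
#'
#' @param result a [vmd()] result
#' @param assignment output of [assign_modes()] (recomputed if missing)
#' @return a `vitals_estimate`: `resp_rate_hz`, `resp_rate_bpm` (breaths per
#'   minute), `heart_rate_hz`, `heart_rate_bpm`, `ibi_ms`, `bbi_s`, flags,
#'   and the mode indices
#' @export
estimate_rates <- function(result, assignment = NULL) {
  stopifnot(inherits(result, "vmd_result"))
  if (is.null(assignment)) assignment <- assign_modes(result)
  fs <- result$fs
  est <- list(resp_mode = assignment$resp, heart_mode = assignment$heart,
              resp_missing = assignment$resp_missing,
              heart_missing = assignment$heart_missing)
  if (!is.na(assignment$resp)) {
    u <- result$modes[, assignment$resp]
    f <- spectral_peak(u, fs)
    est$resp_rate_hz <- f
    est$resp_rate_bpm <- 60 * f
    pk <- mode_peak_times(u, fs, max(f, 0.05))
    est$bbi_s <- diff(pk)
    est$bbi_short <- length(pk) < 3
  } else {
    est$resp_rate_hz <- NA_real_; est$resp_rate_bpm <- NA_real_
    est$bbi_s <- numeric(0); est$bbi_short <- TRUE
  }
  if (!is.na(assignment$heart)) {
    u <- result$modes[, assignment$heart]
    f <- spectral_peak(u, fs)
    est$heart_rate_hz <- f
    est$heart_rate_bpm <- 60 * f
    pk <- mode_peak_times(u, fs, max(f, 0.05))
    est$ibi_ms <- diff(pk) * 1000
    est$ibi_short <- length(pk) < 3
  } else {
    est$heart_rate_hz <- NA_real_; est$heart_rate_bpm <- NA_real_
    est$ibi_ms <- numeric(0); est$ibi_short <- TRUE
  }
  structure(est, class = "vitals_estimate")
}

#' @export
print.vitals_estimate <- function(x, ...) {
  cat(sprintf(
    "vitals_estimate: respiration %.3f Hz (%.1f /min), heart %.3f Hz (%.1f bpm)\n",
    x$resp_rate_hz, x$resp_rate_bpm, x$heart_rate_hz, x$heart_rate_bpm))
  cat(sprintf("  %d breath intervals, %d beat intervals\n",
              length(x$bbi_s), length(x$ibi_ms)))
  invisible(x)
}

#' Bland-Altman agreement statistics
#'
#' For paired series `a` (test) and `b` (reference): mean difference, limits
#' of agreement at \eqn{\pm 1.96} SD of the differences, coefficient of
#' variation of each series (SD/mean), and the error percentage
#' \eqn{|\bar a - \bar b|/\bar b \times 100}.
#'
#' @param a,b equal-length numeric series (>= 3 points)
#' @param labels optional label (condition name etc.) stored in the report
#' @return an `agreement_report`
#' @export
agreement <- function(a, b, labels = NULL) {
  if (length(a) != length(b)) stop_invalid("series must have equal lengths")
  if (length(a) < 3) stop_invalid("need at least 3 paired points")
  d <- a - b
  md <- mean(d)
  sdd <- stats::sd(d)
  zero_ref <- abs(mean(b)) < .Machine$double.eps
  if (zero_ref) warning("reference series has zero mean; error % undefined")
  structure(list(
    mean_difference = md,
    loa_lower = md - 1.96 * sdd, loa_upper = md + 1.96 * sdd,
    sd_difference = sdd,
    cv_a = stats::sd(a) / mean(a), cv_b = stats::sd(b) / mean(b),
    error_percent = if (zero_ref) NA_real_ else
      abs(mean(a) - mean(b)) / abs(mean(b)) * 100,
    n = length(a), labels = labels,
    means = (a + b) / 2, differences = d
  ), class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(
    "agreement_report%s: mean diff %.4g, LoA [%.4g, %.4g], error %.3g%%, n = %d\n",
    if (!is.null(x$labels)) paste0(" (", x$labels, ")") else "",
    x$mean_difference, x$loa_lower, x$loa_upper, x$error_percent, x$n))
  invisible(x)
}
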