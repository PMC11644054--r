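# Seat-occupancy detection: EWMA variance of the range-envelope amplitude
# with a cutoff-derived smoothing coefficient and threshold classification.

#' EWMA smoothing coefficient from a cutoff frequency
#'
#' For the one-pole EWMA filter \eqn{s[n] = \alpha x[n] + (1-\alpha)s[n-1]}
#' the coefficient that places the half-power (-3 dB) point at `f_c` is
#' \deqn{\alpha = \cos\Omega - 1 + \sqrt{\cos^2\Omega - 4\cos\Omega + 3},
#'   \qquad \Omega = 2\pi f_c T_s.}
#'
#' @param f_c cutoff frequency in Hz, 0 < f_c < 1/(2 T_s)
#' @param T_s sample interval in seconds
#' @return alpha in (0, 1]
#' @export
alpha_from_cutoff <- function(f_c, T_s) {
  if (f_c <= 0) stop_invalid("`f_c` must be positive")
  if (f_c >= 1 / (2 * T_s))
    stop_invalid("`f_c` must be below the Nyquist rate 1/(2*T_s) = ",
                 format(1 / (2 * T_s)), " Hz")
  om <- 2 * pi * f_c * T_s
  co <- cos(om)
  co - 1 + sqrt(co^2 - 4 * co + 3)
}

#' Occupancy detector configuration
#'
#' @param f_c EWMA cutoff frequency in Hz. The default (1.5 Hz) is sized so
#'   the variance statistic decays from a full-scale transition spike
#'   (sigma of order the envelope step over T_s) down to a calibrated
#'   threshold within the 1 s decision hold at the 13.25 Hz frame rate;
#'   lower cutoffs smooth more but respond more slowly to a vacated seat.
#' @param T_s sample interval in seconds (the radar frame time)
#' @param sigma_th detection threshold on sigma (amplitude units), or `NA`
#'   until calibrated
#' @param hold_s hysteresis hold time in seconds (state flips shorter than
#'   this are suppressed)
#' @return an `ewma_config`
#' @export
ewma_config <- function(f_c = 1.5, T_s = 75.476e-3, sigma_th = NA_real_,
                        hold_s = 1) {
  alpha <- alpha_from_cutoff(f_c, T_s)
  structure(list(f_c = f_c, T_s = T_s, alpha = alpha, sigma_th = sigma_th,
                 hold_s = hold_s),
            class = "ewma_config")
}

#' EWMA variance of an envelope series
#'
#' The recursion
#' \eqn{\sigma^2[n] = \alpha\,((y[n]-y[n-1])/T_s)^2 + (1-\alpha)\sigma^2[n-1]}
#' with \eqn{\sigma^2[1] = 0}: an exponentially weighted moving average of
#' the squared finite-difference derivative of the envelope. Depends only on
#' differences of `y`, so it is invariant to the envelope's DC level.
#'
#' @param y envelope amplitude series (length >= 2)
#' @param config an [ewma_config()] (or supply `alpha` and `T_s` directly)
#' @param alpha,T_s used when `config` is missing
#' @return sigma^2 series, same length as `y`, first element 0
#' @export
ewma_sigma <- function(y, config = NULL, alpha = NULL, T_s = NULL) {
  if (!is.null(config)) { alpha <- config$alpha; T_s <- config$T_s }
  if (is.null(alpha) || is.null(T_s))
    stop_invalid("supply `config` or both `alpha` and `T_s`")
  n <- length(y)
  if (n < 2) stop_invalid("envelope must have at least 2 samples")
  x <- alpha * (diff(y) / T_s)^2
  s <- stats::filter(x, 1 - alpha, method = "recursive", init = 0)
  c(0, as.numeric(s))
}

#' Threshold classification of an EWMA variance series
#'
#' A frame is classified `person` iff \eqn{\sqrt{\sigma^2} > \sigma_{th}}
#' (strict inequality: exactly at threshold is not-person). A hold-time
#' hysteresis (default 1 s) suppresses chatter: any run of a state shorter
#' than the hold is merged into the preceding state.
#'
#' @param sigma2 EWMA variance series
#' @param sigma_th threshold on sigma (> 0)
#' @param T_s sample interval in seconds
#' @param hold_s hysteresis hold time in seconds (0 disables)
#' @return character vector, `"person"` / `"not_person"` per frame
#' @export
classify_occupancy <- function(sigma2, sigma_th, T_s = 75.476e-3,
                               hold_s = 1) {
  if (sigma_th <= 0) stop_invalid("`sigma_th` must be positive")
  person <- sqrt(pmax(sigma2, 0)) > sigma_th
  if (hold_s > 0 && length(person) > 1) {
    hold_n <- max(1L, as.integer(round(hold_s / T_s)))
    r <- rle(person)
    if (length(r$lengths) > 1) {
      for (i in seq_along(r$lengths)[-1]) {
        if (r$lengths[i] < hold_n) r$values[i] <- r$values[i - 1]
      }
      # merge again after reassignment
      person <- inverse.rle(r)
      r2 <- rle(person)
      person <- inverse.rle(r2)
    }
  }
  ifelse(person, "person", "not_person")
}

#' Calibrate the occupancy threshold from labelled runs
#'
#' \eqn{\sigma_{th}} is the geometric mean of (i) the mean \eqn{\sigma} over
#' the person runs and (ii) the maximum \eqn{\sigma} over the empty/object
#' runs. If the classes overlap (the empty maximum reaches the person mean)
#' calibration fails with a margin report.
#'
#' @param person_runs list of sigma^2 series (or one series) recorded with a
#'   person present
#' @param empty_runs list of sigma^2 series recorded empty or with objects
#' @return `sigma_th` (amplitude units) with attribute `margin` (ratio of
#'   person mean to empty max)
#' @export
calibrate_threshold <- function(person_runs, empty_runs) {
  as_list <- function(x) if (is.list(x)) x else list(x)
  person_runs <- as_list(person_runs); empty_runs <- as_list(empty_runs)
  if (length(person_runs) < 1 || length(empty_runs) < 1)
    stop_invalid("need at least one run of each class")
  m_person <- mean(sqrt(pmax(unlist(person_runs), 0)))
  mx_empty <- max(sqrt(pmax(unlist(empty_runs), 0)))
  if (mx_empty >= m_person)
    stop_invalid(sprintf(
      "calibration failed: classes overlap (person mean sigma %.4g <= empty max sigma %.4g, margin %.3g)",
      m_person, mx_empty, m_person / mx_empty))
  structure(sqrt(m_person * mx_empty), margin = m_person / mx_empty)
}

#' Run the occupancy detector on a data cube
#'
#' Envelope y\[n\] = per-frame peak magnitude of the range profile within the
#' gate (averaged over RX channels), then [ewma_sigma()] and
#' [classify_occupancy()]. With `sigma_th = "auto"` and a ground-truth state
#' in the cube, the threshold is calibrated from the labelled segments via
#' [calibrate_threshold()].
#'
#' @param cube a `slow_time_cube` (e.g. from [occupancy_cube()])
#' @param config an [ewma_config()]
#' @param sigma_th threshold, or `"auto"`
#' @param gate range gate in metres
#' @param calib_exclude_s seconds around scripted transitions excluded from
#'   auto-calibration (the EWMA needs that long to settle after a step)
#' @return an `occupancy_trace`: `t`, `envelope`, `sigma2`, `state`,
#'   `sigma_th`, config
#' @export
detect_occupancy <- function(cube, config = ewma_config(T_s = cube$config$frame_time),
                             sigma_th = "auto", gate = c(0.5, 0.8),
                             calib_exclude_s = 2) {
  stopifnot(inherits(cube, "slow_time_cube"))
  profile <- range_fft(cube, gate = gate)
  idx <- which(profile$range_m >= gate[1] & profile$range_m <= gate[2])
  env_ch <- apply(Mod(profile$bins[idx, , , drop = FALSE]), c(2, 3), max)
  envelope <- rowMeans(env_ch)
  sigma2 <- ewma_sigma(envelope, config)
  if (identical(sigma_th, "auto")) {
    truth <- cube$truth$state
    if (is.null(truth))
      stop_invalid("`sigma_th = \"auto\"` needs ground-truth states in the cube")
    steady <- rep(TRUE, length(truth))
    trans <- which(truth[-1] != truth[-length(truth)]) + 1
    for (i in trans)
      steady <- steady & abs(cube$t - cube$t[i]) > calib_exclude_s
    sigma_th <- as.numeric(
      calibrate_threshold(sigma2[steady & truth == "person"],
                          sigma2[steady & truth != "person"]))
  }
  state <- classify_occupancy(sigma2, sigma_th, T_s = config$T_s,
                              hold_s = config$hold_s)
  structure(list(t = cube$t, envelope = envelope, sigma2 = sigma2,
                 state = state, sigma_th = sigma_th, config = config,
                 truth_state = cube$truth$state),
            class = "occupancy_trace")
}

#' @export
print.occupancy_trace <- function(x, ...) {
  tab <- table(x$state)
  cat(sprintf("occupancy_trace: %d frames, sigma_th %.4g | %s\n",
              length(x$state), x$sigma_th,
              paste(names(tab), tab, sep = ": ", collapse = ", ")))
  invisible(x)
}

#' Frame-level agreement with ground truth outside transition windows
#'
#' Fraction of frames where the detected person/not-person state matches the
#' scripted truth, excluding frames within `exclude_s` of a scripted state
#' transition (the detector's response time).
#'
#' @param trace an `occupancy_trace` with truth states
#' @param exclude_s half-width of the transition exclusion window in seconds
#' @return agreement fraction in \[0, 1\]
#' @export
occupancy_agreement <- function(trace, exclude_s = 1) {
  stopifnot(inherits(trace, "occupancy_trace"))
  truth <- trace$truth_state
  if (is.null(truth)) stop_invalid("trace has no ground-truth states")
  truth_bin <- ifelse(truth == "person", "person", "not_person")
  trans_t <- trace$t[which(truth_bin[-1] != truth_bin[-length(truth_bin)]) + 1]
  keep <- rep(TRUE, length(trace$t))
  for (tt in trans_t) keep <- keep & abs(trace$t - tt) > exclude_s
  mean(trace$state[keep] == truth_bin[keep])
}
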