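# End-to-end chain and deterministic fixture generation.

#' Run the full simulate-process-report chain
#'
#' Simulates the FMCW cube for a scenario, applies the processing chain
#' (range FFT, gating, phase extraction, VMD, mode assignment, rate and
#' interval estimation), compares intervals to the scenario's ground truth,
#' and optionally runs the occupancy detector. Deterministic for a fixed
#' scenario seed.
#'
#' Sliding-window rate estimates (default 30 s windows, 50% overlap) feed
#' the per-run rate variability (CV) statistics.
#'
#' @param scenario a [vital_scenario()]
#' @param config a [radar_config()]
#' @param K,alpha,tau VMD settings (see [vmd()])
#' @param window_s sliding window length in seconds (NULL disables windows)
#' @param sigma_th occupancy threshold (NULL skips the occupancy stage)
#' @return a list: `estimate` ([estimate_rates()] output), `agreement_hr`
#'   and `agreement_rr` (radar vs ground-truth intervals), `windows`
#'   (per-window rate data frame), `cv_hr`, `cv_resp`, `occupancy`
#'   (trace or NULL), `phase`, `vmd`, `scenario`
#' @export
run_end_to_end <- function(scenario, config = radar_config(), K = 4,
                           alpha = 2000, tau = 0, window_s = 30,
                           sigma_th = NULL) {
  stopifnot(inherits(scenario, "vital_scenario"))
  cube <- beat_signal(scenario, config)
  profile <- range_fft(cube)
  bin <- select_bin(profile)
  phase <- extract_phase(profile, bin)
  dec <- vmd(phase, K = K, alpha = alpha, tau = tau)
  est <- estimate_rates(dec)

  truth_ibi <- 1000 / scenario$heart_freq
  truth_bbi <- 1 / scenario$resp_freq
  agreement_hr <- if (length(est$ibi_ms) >= 3)
    agreement(est$ibi_ms, rep(truth_ibi, length(est$ibi_ms)),
              labels = scenario$condition)
  agreement_rr <- if (length(est$bbi_s) >= 3)
    agreement(est$bbi_s, rep(truth_bbi, length(est$bbi_s)),
              labels = scenario$condition)

  windows <- NULL; cv_hr <- NA_real_; cv_resp <- NA_real_
  if (!is.null(window_s) && window_s < scenario$duration) {
    fs <- config$slow_rate
    wlen <- floor(window_s * fs)
    step <- max(1, floor(wlen / 2))
    starts <- seq(1, length(phase$phase) - wlen + 1, by = step)
    rows <- lapply(starts, function(s0) {
      seg <- phase$phase[s0:(s0 + wlen - 1)]
      dw <- vmd(seg, fs = fs, K = K, alpha = alpha, tau = tau)
      ew <- estimate_rates(dw)
      data.frame(t_start = phase$t[s0], resp_hz = ew$resp_rate_hz,
                 heart_hz = ew$heart_rate_hz)
    })
    windows <- do.call(rbind, rows)
    hr <- windows$heart_hz[!is.na(windows$heart_hz)]
    rr <- windows$resp_hz[!is.na(windows$resp_hz)]
    if (length(hr) >= 2) cv_hr <- stats::sd(60 * hr) / mean(60 * hr)
    if (length(rr) >= 2) cv_resp <- stats::sd(60 * rr) / mean(60 * rr)
  }

  occ <- if (!is.null(sigma_th))
    detect_occupancy(cube, ewma_config(T_s = config$frame_time),
                     sigma_th = sigma_th)

  list(estimate = est, agreement_hr = agreement_hr,
       agreement_rr = agreement_rr, windows = windows, cv_hr = cv_hr,
       cv_resp = cv_resp, occupancy = occ, phase = phase, vmd = dec,
       scenario = scenario, bin = bin)
}

#' Generate deterministic test fixtures
#'
#' Small plain-text inputs for exercising the toolchain: `tones` (two-tone
#' CSV series with generating parameters in the header comment), `vitals`
#' (short standby phase-series CSV), `occupancy` (the 120 s scripted
#' timeline cube), `lens` (default 37 x 37 layout JSON+CSV, 59.2 mm side).
#'
#' @param kind one of `"tones"`, `"vitals"`, `"occupancy"`, `"lens"`
#' @param dir output directory (created if needed)
#' @param seed integer seed
#' @return character vector of files written
#' @export
make_fixtures <- function(kind = c("tones", "vitals", "occupancy", "lens"),
                          dir = ".", seed = 1L) {
  kind <- match.arg(kind)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  switch(kind,
    tones = {
      fs <- 13.25; n <- 1024
      t <- (0:(n - 1)) / fs
      f1 <- 0.3; f2 <- 1.2
      x <- cos(2 * pi * f1 * t) + 0.5 * cos(2 * pi * f2 * t)
      path <- file.path(dir, "tones.csv")
      con <- file(path, "w")
      writeLines(sprintf("# two tones: f1=%g Hz (amp 1), f2=%g Hz (amp 0.5), fs=%g Hz",
                         f1, f2, fs), con)
      utils::write.csv(data.frame(t_s = t, x = x), con, row.names = FALSE)
      close(con)
      path
    },
    vitals = {
      sc <- vital_scenario("standby", duration = 60, seed = seed)
      cube <- beat_signal(sc)
      profile <- range_fft(cube)
      series <- extract_phase(profile, select_bin(profile))
      path <- file.path(dir, "vitals_phase.csv")
      write_phase_series(series, path)
      path
    },
    occupancy = {
      cube <- occupancy_cube(seed = seed)
      write_cube(cube, file.path(dir, "occupancy_cube"))
    },
    lens = {
      layout <- aperture_layout(lookup = phase_lookup_synthetic())
      write_layout(layout, file.path(dir, "lens_layout"))
    })
}
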