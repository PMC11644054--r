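# Synthetic FMCW slow-time data generation: chest displacement model,
# beat-signal cube, scripted occupancy scenes.

#' FMCW radar configuration
#'
#' Defaults are the radar's operating parameters: 64 ADC samples per chirp,
#' 1 chirp per frame, 32 us chirp time, 1 TX / 3 RX antennas, 5 GHz sweep
#' bandwidth, 75.476 ms frame time, 70 degree azimuth field of view, 60 GHz
#' centre frequency.
#'
#' @param n_adc_samples fast-time samples per chirp
#' @param n_chirps chirps per frame
#' @param chirp_time chirp (ramp) duration in seconds
#' @param n_tx,n_rx transmit/receive antenna counts
#' @param bandwidth sweep bandwidth in Hz
#' @param frame_time frame interval in seconds (slow-time sampling period)
#' @param fov_azimuth azimuth field of view in degrees
#' @param center_frequency carrier frequency in Hz
#' @return a `radar_config` with derived fields `wavelength`, `range_bin_m`
#'   (c/2B), `fs_fast` (fast-time sample rate), `slow_rate` (1/frame_time)
#' @export
radar_config <- function(n_adc_samples = 64, n_chirps = 1, chirp_time = 32e-6,
                         n_tx = 1, n_rx = 3, bandwidth = 5e9,
                         frame_time = 75.476e-3, fov_azimuth = 70,
                         center_frequency = 60e9) {
  if (bandwidth <= 0) stop_invalid("`bandwidth` must be positive")
  if (frame_time <= chirp_time)
    stop_invalid("`frame_time` must exceed `chirp_time`")
  if (n_adc_samples < 2) stop_invalid("need at least 2 ADC samples")
  structure(list(
    n_adc_samples = as.integer(n_adc_samples), n_chirps = as.integer(n_chirps),
    chirp_time = chirp_time, n_tx = as.integer(n_tx), n_rx = as.integer(n_rx),
    bandwidth = bandwidth, frame_time = frame_time, fov_azimuth = fov_azimuth,
    center_frequency = center_frequency,
    wavelength = .c0 / center_frequency,
    range_bin_m = .c0 / (2 * bandwidth),
    fs_fast = n_adc_samples / chirp_time,
    slow_rate = 1 / frame_time
  ), class = "radar_config")
}

#' @export
print.radar_config <- function(x, ...) {
  cat(sprintf(
    "radar_config: %g GHz, B = %g GHz, %d samples/%g us chirp, frame %g ms (slow rate %.2f Hz), %dTX/%dRX\n",
    x$center_frequency / 1e9, x$bandwidth / 1e9, x$n_adc_samples,
    x$chirp_time * 1e6, x$frame_time * 1e3, x$slow_rate, x$n_tx, x$n_rx))
  invisible(x)
}

# Table-2 RMS accelerations (m/s^2) and default vital rates (Hz) per
# condition, with and without the lens.
.scenario_defaults <- list(
  with_lens = list(
    standby = list(rms = 0.030, fr = 0.45, fh = 1.12),
    driving = list(rms = 0.200, fr = 0.53, fh = 1.20),
    bumpy   = list(rms = 0.310, fr = 0.52, fh = 1.18)
  ),
  without_lens = list(
    standby = list(rms = 0.037, fr = 0.41, fh = 1.11),
    driving = list(rms = 0.325, fr = 0.51, fh = 1.17),
    bumpy   = list(rms = 0.470, fr = 0.57, fh = 1.18)
  )
)

#' Vital-sign measurement scenario
#'
#' Chest displacement model: \eqn{R(\tau) = d_0 + A\sin(2\pi f_r\tau) +
#' B_h\sin(2\pi f_h\tau)} plus a seeded band-limited vibration term scaled to
#' the condition's RMS acceleration (standby / driving / bumpy). The lens is
#' modelled as an SNR offset (default +10 dB) and the lower vibration levels
#' measured with it.
#'
#' Defaults per condition (rates from the with/without-lens spectra; RMS
#' accelerations as tabulated): standby 0.45/1.12 Hz at 0.030 m/s^2, driving
#' 0.53/1.20 Hz at 0.200 m/s^2, bumpy 0.52/1.18 Hz at 0.310 m/s^2 with the
#' lens; 0.037/0.325/0.470 m/s^2 without.
#'
#' @param condition `"standby"`, `"driving"` or `"bumpy"`
#' @param with_lens logical; selects vibration level and SNR
#' @param d0 nominal chest distance in metres (within the 0.5-0.8 m gate)
#' @param resp_amplitude A, respiration displacement amplitude in metres
#' @param heart_amplitude B_h, heartbeat displacement amplitude in metres
#'   (must satisfy A > B_h > 0)
#' @param resp_freq f_r in Hz (0.1-0.7); default per condition
#' @param heart_freq f_h in Hz (0.7-2.5); default per condition
#' @param duration seconds of data
#' @param motion_rms_acc RMS acceleration of the vibration term in m/s^2;
#'   default per condition/lens
#' @param snr_db per-sample complex-baseband SNR in dB; default 20 with the
#'   lens, 10 without (`lens_gain_db` apart)
#' @param lens_gain_db SNR benefit attributed to the lens
#' @param motion_band Hz band of the vibration acceleration (default
#'   8-20 Hz, the road/drivetrain band; it may exceed the slow-time Nyquist
#'   rate — the displacement is generated on an oversampled grid and
#'   aliases into the frame samples exactly as at the radar)
#' @param seed integer seed driving all randomness of this scenario
#' @return a `vital_scenario` object
#' @export
vital_scenario <- function(condition = c("standby", "driving", "bumpy"),
                           with_lens = TRUE, d0 = 0.6,
                           resp_amplitude = 4e-3, heart_amplitude = 0.3e-3,
                           resp_freq = NULL, heart_freq = NULL,
                           duration = 300, motion_rms_acc = NULL,
                           snr_db = NULL, lens_gain_db = 10,
                           motion_band = c(8, 20), seed = 1L) {
  condition <- match.arg(condition)
  def <- .scenario_defaults[[if (with_lens) "with_lens" else "without_lens"]][[condition]]
  if (is.null(resp_freq)) resp_freq <- def$fr
  if (is.null(heart_freq)) heart_freq <- def$fh
  if (is.null(motion_rms_acc)) motion_rms_acc <- def$rms
  if (is.null(snr_db)) snr_db <- if (with_lens) 20 else 20 - lens_gain_db
  if (!(resp_amplitude > heart_amplitude && heart_amplitude > 0))
    stop_invalid("require A > B_h > 0")
  if (resp_freq < 0.1 || resp_freq > 0.7)
    stop_invalid("`resp_freq` must lie in [0.1, 0.7] Hz")
  if (heart_freq < 0.7 || heart_freq > 2.5)
    stop_invalid("`heart_freq` must lie in [0.7, 2.5] Hz")
  if (d0 < 0.5 || d0 > 0.8)
    stop_invalid("`d0` must lie within the 0.5-0.8 m gate")
  structure(list(
    condition = condition, with_lens = with_lens, d0 = d0,
    resp_amplitude = resp_amplitude, heart_amplitude = heart_amplitude,
    resp_freq = resp_freq, heart_freq = heart_freq, duration = duration,
    motion_rms_acc = motion_rms_acc, snr_db = snr_db,
    motion_band = motion_band, seed = as.integer(seed)
  ), class = "vital_scenario")
}

#' @export
print.vital_scenario <- function(x, ...) {
  cat(sprintf(
    "vital_scenario: %s %s lens | f_r %.2f Hz, f_h %.2f Hz, A %.1f mm, B_h %.2f mm\n",
    x$condition, if (x$with_lens) "with" else "without",
    x$resp_freq, x$heart_freq, x$resp_amplitude * 1e3,
    x$heart_amplitude * 1e3))
  cat(sprintf("  d0 %.2f m, %g s, RMS acc %.3f m/s^2, SNR %.0f dB, seed %d\n",
              x$d0, x$duration, x$motion_rms_acc, x$snr_db, x$seed))
  invisible(x)
}

# Band-limited vibration displacement sampled on a uniform time grid:
# white acceleration restricted to `band` (Hz), integrated twice
# spectrally, with the acceleration RMS scaled to `rms_acc` exactly. The
# vibration band may lie above the sampling Nyquist rate (road vibration
# vs the radar frame rate): the series is generated on an oversampled grid
# and decimated, so out-of-band vibration aliases into the samples exactly
# as it would at the radar.
motion_displacement <- function(n, dt, rms_acc, band = c(8, 20),
                                seed = NULL) {
  if (rms_acc <= 0 || n < 4) return(numeric(n))
  q <- max(1L, ceiling(2.5 * band[2] * dt))
  n_os <- n * q
  dt_os <- dt / q
  f <- fft_freq(n_os, dt_os)
  in_band <- abs(f) >= band[1] & abs(f) <= band[2]
  if (!any(in_band)) return(numeric(n))
  spec <- with_seed(seed, {
    s <- complex(real = stats::rnorm(n_os), imaginary = stats::rnorm(n_os))
    s[!in_band] <- 0
    s
  })
  # hermitian symmetrization for a real series
  spec <- (spec + Conj(spec[c(1, n_os:2)])) / 2
  a <- Re(stats::fft(spec, inverse = TRUE)) / n_os
  rms <- sqrt(mean(a^2))
  if (rms == 0) return(numeric(n))
  a <- a * rms_acc / rms
  ahat <- stats::fft(a)
  w2 <- (2 * pi * f)^2
  dhat <- ifelse(w2 > 0, -ahat / w2, 0)
  d <- Re(stats::fft(dhat, inverse = TRUE)) / n_os
  d[seq(1, by = q, length.out = n)]
}

#' Chest displacement series of a scenario
#'
#' \eqn{R(\tau) = d_0 + A\sin(2\pi f_r\tau) + B_h\sin(2\pi f_h\tau)} plus the
#' seeded band-limited vibration displacement whose acceleration RMS equals
#' `motion_rms_acc`. Timestamps must be sorted and (for a nonzero motion
#' term) uniformly spaced.
#'
#' @param scenario a [vital_scenario()]
#' @param timestamps sorted times in seconds
#' @return displacement in metres, one value per timestamp
#' @export
displacement_series <- function(scenario, timestamps) {
  stopifnot(inherits(scenario, "vital_scenario"))
  if (is.unsorted(timestamps)) stop_invalid("timestamps must be sorted")
  r <- scenario$d0 +
    scenario$resp_amplitude * sin(2 * pi * scenario$resp_freq * timestamps) +
    scenario$heart_amplitude * sin(2 * pi * scenario$heart_freq * timestamps)
  if (scenario$motion_rms_acc > 0 && length(timestamps) >= 4) {
    dt <- diff(timestamps)
    if (max(abs(dt - dt[1])) > 1e-9 * dt[1])
      stop_invalid("motion term requires uniformly spaced timestamps")
    r <- r + motion_displacement(length(timestamps), dt[1],
                                 scenario$motion_rms_acc,
                                 scenario$motion_band, scenario$seed)
  }
  r
}

# Complex baseband frames for a point target with per-frame range R (m) and
# per-frame amplitude. Returns n_adc x n_frames matrix (no noise).
.target_frames <- function(R, amplitude, config) {
  fb <- 2 * config$bandwidth * R / (.c0 * config$chirp_time)
  if (any(fb >= config$fs_fast / 2))
    stop_invalid("target range ", format(max(R)),
                 " m exceeds the unambiguous range of the configuration")
  phb <- 4 * pi * R / config$wavelength
  n <- 0:(config$n_adc_samples - 1)
  # outer: rows fast time, cols frames
  ph <- outer(n / config$fs_fast, 2 * pi * fb) +
    matrix(phb, config$n_adc_samples, length(R), byrow = TRUE)
  matrix(amplitude, config$n_adc_samples, length(R), byrow = TRUE) *
    exp(1i * ph)
}

# Wrap iq array + metadata as a slow_time_cube.
new_cube <- function(iq, t, config, truth) {
  structure(list(iq = iq, t = t, config = config, truth = truth),
            class = "slow_time_cube")
}

#' @export
print.slow_time_cube <- function(x, ...) {
  d <- dim(x$iq)
  cat(sprintf(
    "slow_time_cube: %d fast-time x %d frames x %d channel(s), %.1f s @ %.2f Hz slow rate\n",
    d[1], d[2], d[3], utils::tail(x$t, 1), x$config$slow_rate))
  invisible(x)
}

#' Simulate the FMCW beat-signal cube of a vital scenario
#'
#' For each frame m the fast-time samples carry the beat frequency
#' \eqn{f_b = 2 B R(\tau_m)/(c T_c)} and the slow-time phase
#' \eqn{\phi_b = 4\pi R(\tau_m)/\lambda}; complex white noise is added to
#' meet the scenario SNR, independently per RX channel (residual chirp phase
#' noise is neglected).
#'
#' @param scenario a [vital_scenario()]
#' @param config a [radar_config()]
#' @return a `slow_time_cube`: complex array `iq`
#'   \[fast time, slow time, channel\], slow-time stamps `t`, the config, and
#'   ground truth (displacement series and generating rates)
#' @export
beat_signal <- function(scenario, config = radar_config()) {
  stopifnot(inherits(scenario, "vital_scenario"),
            inherits(config, "radar_config"))
  if (config$slow_rate / 2 <= scenario$heart_freq)
    stop_invalid("slow-time Nyquist ", format(config$slow_rate / 2),
                 " Hz does not exceed the heart frequency")
  m <- floor(scenario$duration / config$frame_time)
  t <- (0:(m - 1)) * config$frame_time
  R <- displacement_series(scenario, t)
  clean <- .target_frames(R, 1, config)
  sigma <- sqrt(10^(-scenario$snr_db / 10) / 2)
  iq <- with_seed(scenario$seed + 1L, {
    arr <- array(0i, dim = c(config$n_adc_samples, m, config$n_rx))
    for (ch in seq_len(config$n_rx)) {
      noise <- matrix(complex(real = stats::rnorm(length(clean), sd = sigma),
                              imaginary = stats::rnorm(length(clean), sd = sigma)),
                      nrow = nrow(clean))
      arr[, , ch] <- clean + noise
    }
    arr
  })
  new_cube(iq, t, config,
           truth = list(displacement_m = R, resp_freq = scenario$resp_freq,
                        heart_freq = scenario$heart_freq,
                        scenario = scenario))
}

#' Scripted occupancy timeline
#'
#' Contiguous, non-overlapping segments of seat state. The default is the
#' 120 s demonstration timeline: empty 0-20 s, bag 20-40 s, person 40-80 s,
#' empty 80-120 s.
#'
#' @param segments data frame with columns `state` (one of `"empty"`,
#'   `"object"`, `"person"`), `start`, `end` (seconds)
#' @return an `occupancy_script`
#' @export
occupancy_script <- function(segments = data.frame(
  state = c("empty", "object", "person", "empty"),
  start = c(0, 20, 40, 80),
  end = c(20, 40, 80, 120))) {
  need <- c("state", "start", "end")
  if (!all(need %in% names(segments)))
    stop_invalid("segments need columns ", paste(need, collapse = ", "))
  if (!all(segments$state %in% c("empty", "object", "person")))
    stop_invalid("states must be empty/object/person")
  o <- order(segments$start)
  segments <- segments[o, ]
  if (any(segments$end <= segments$start))
    stop_invalid("segments must have end > start")
  if (nrow(segments) > 1 &&
      any(abs(segments$start[-1] - segments$end[-nrow(segments)]) > 1e-9))
    stop_invalid("segments must be contiguous and non-overlapping")
  structure(list(segments = segments), class = "occupancy_script")
}

#' Simulate a scripted occupancy data cube
#'
#' Empty seat: a static reflector at the seat surface (plus noise). Object:
#' a stronger static reflector, no micro-motion. Person: the full
#' vital-sign beat signal with breathing-modulated reflection amplitude.
#' State amplitudes follow the demonstration timeline levels (empty about
#' 0.2, bag below 0.5, person about 0.5 envelope units).
#'
#' @param script an [occupancy_script()]
#' @param config a [radar_config()]
#' @param seed integer seed
#' @param amplitudes named vector of envelope amplitudes per state
#' @param ranges_m named vector of reflector ranges per state (m)
#' @param person_scenario [vital_scenario()] for person segments (its `d0`
#'   overrides `ranges_m["person"]`)
#' @param breath_mod fractional amplitude modulation of the person's
#'   reflection at the respiration rate
#' @param noise_sigma complex noise standard deviation per fast-time sample
#' @return a `slow_time_cube` whose truth carries the per-frame state label
#'   and displacement
#' @export
occupancy_cube <- function(script = occupancy_script(),
                           config = radar_config(), seed = 1L,
                           amplitudes = c(empty = 0.2, object = 0.35,
                                          person = 0.5),
                           ranges_m = c(empty = 0.70, object = 0.65,
                                        person = 0.60),
                           person_scenario = vital_scenario("standby",
                                                            duration = 1,
                                                            seed = seed),
                           breath_mod = 0.15, noise_sigma = 0.004) {
  stopifnot(inherits(script, "occupancy_script"),
            inherits(config, "radar_config"))
  total <- max(script$segments$end)
  m <- floor(total / config$frame_time)
  t <- (0:(m - 1)) * config$frame_time
  state <- character(m)
  R <- numeric(m)
  amp <- numeric(m)
  for (s in seq_len(nrow(script$segments))) {
    seg <- script$segments[s, ]
    sel <- t >= seg$start & t < seg$end
    state[sel] <- seg$state
    if (seg$state == "person") {
      sc <- person_scenario
      sc$duration <- seg$end - seg$start
      tau <- t[sel] - seg$start
      R[sel] <- displacement_series(sc, tau)
      amp[sel] <- amplitudes["person"] *
        (1 + breath_mod * sin(2 * pi * sc$resp_freq * tau))
    } else {
      R[sel] <- ranges_m[seg$state]
      amp[sel] <- amplitudes[seg$state]
    }
  }
  clean <- .target_frames(R, amp, config)
  iq <- with_seed(seed + 2L, {
    arr <- array(0i, dim = c(config$n_adc_samples, m, config$n_rx))
    for (ch in seq_len(config$n_rx)) {
      noise <- matrix(
        complex(real = stats::rnorm(length(clean), sd = noise_sigma / sqrt(2)),
                imaginary = stats::rnorm(length(clean),
                                         sd = noise_sigma / sqrt(2))),
        nrow = nrow(clean))
      arr[, , ch] <- clean + noise
    }
    arr
  })
  new_cube(iq, t, config,
           truth = list(state = state, displacement_m = R, amplitude = amp,
                        script = script))
}
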