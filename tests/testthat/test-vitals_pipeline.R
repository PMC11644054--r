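make_cube <- function(d0 = 0.6, duration = 10, snr_db = 60, seed = 3,
                      motion = 0, ...) {
  sc <- vital_scenario("standby", d0 = d0, duration = duration,
                       snr_db = snr_db, motion_rms_acc = motion,
                       seed = seed, ...)
  beat_signal(sc, radar_config())
}

test_that("range FFT puts a 0.6 m target in bin 20 at 0.03 m spacing", {
  cube <- make_cube()
  pr <- range_fft(cube)
  expect_equal(pr$range_m[2] - pr$range_m[1], C0 / (2 * 5e9))
  pow <- apply(Mod(pr$bins)^2, 1, mean)
  expect_equal(which.max(pow) - 1L, 20L)
  # zero input -> all-zero profile
  z <- cube; z$iq[] <- 0
  expect_true(all(Mod(range_fft(z)$bins) == 0))
})

test_that("two targets at least two bins apart resolve into two peaks", {
  cfg <- radar_config()
  m <- 16
  R <- rep(0.60, m)
  c1 <- mmvital:::.target_frames(R, 1, cfg)
  c2 <- mmvital:::.target_frames(rep(0.69, m), 0.8, cfg)  # 3 bins away
  cube <- mmvital:::new_cube(array(c1 + c2, dim = c(cfg$n_adc_samples, m, 1)),
                             (0:(m - 1)) * cfg$frame_time, cfg, list())
  pow <- apply(Mod(range_fft(cube)$bins)^2, 1, mean)
  pk <- mmvital:::find_peaks(pow, min_dist = 2)
  expect_true(all(c(21L, 24L) %in% pk))  # 1-based indices of bins 20 and 23
})

test_that("bin selection respects the gate, flags out-of-gate targets", {
  cube <- make_cube()
  pr <- range_fft(cube)
  b <- select_bin(pr)
  expect_equal(as.integer(b), 20L)
  expect_equal(attr(b, "range_m"), 20 * C0 / 1e10, tolerance = 1e-6)
  expect_false(attr(b, "no_target"))
  # gate containing no bins errors
  expect_error(select_bin(pr, gate = c(0.601, 0.605)), "no bins")
  # target outside the gate: flagged
  cube2 <- make_cube(d0 = 0.6)
  pr2 <- range_fft(cube2)
  expect_warning(b2 <- select_bin(pr2, gate = c(0.75, 0.8)), "outside")
  expect_true(attr(b2, "no_target"))
  # deterministic tie-break: equal powers pick the lowest bin
  prt <- pr
  prt$bins[] <- 0
  prt$bins[19, , ] <- 1; prt$bins[23, , ] <- 1
  expect_equal(as.integer(select_bin(prt)), 18L)
})

test_that("extracted phase inverts to the true displacement", {
  # noise-free 1 mm sinusoid at lambda = 5 mm: phase amplitude 2.513 rad
  cube <- make_cube(duration = 30, snr_db = 300, resp_amplitude = 1e-3,
                    heart_amplitude = 1e-9, resp_freq = 0.25)
  pr <- range_fft(cube)
  ph <- extract_phase(pr, select_bin(pr), detrend = FALSE)
  # measured slope = (4 pi / lambda) (1 + rho): displacement term plus the
  # range-proportional beat-leakage phase of the fast-time DFT
  cfg <- cube$config
  rho <- (cfg$n_adc_samples - 1) * cfg$bandwidth * cfg$wavelength /
    (2 * C0 * cfg$n_adc_samples)
  expect_equal(diff(range(ph$phase_raw)) / 2,
               4 * pi * 1e-3 / cfg$wavelength * (1 + rho),
               tolerance = 1e-3)
  truth <- cube$truth$displacement_m - mean(cube$truth$displacement_m)
  err <- ph$displacement_m - truth
  expect_lt(sqrt(mean((err - mean(err))^2)), 1e-6)  # < 1 um RMS
  # constant range: constant phase
  cubec <- make_cube(duration = 2, snr_db = 300, resp_amplitude = 1e-12,
                     heart_amplitude = 1e-13)
  prc <- range_fft(cubec)
  phc <- extract_phase(prc, select_bin(prc), detrend = FALSE)
  expect_lt(diff(range(phc$phase_raw)), 1e-6)
})

test_that("unwrapping keeps continuity when displacement crosses lambda/4", {
  cube <- make_cube(duration = 30, snr_db = 300, resp_amplitude = 4e-3,
                    heart_amplitude = 1e-9, resp_freq = 0.2)
  pr <- range_fft(cube)
  ph <- extract_phase(pr, select_bin(pr), detrend = FALSE)
  # 4 mm exceeds lambda/4 = 1.25 mm; no 2 pi jumps after unwrap
  expect_lt(max(abs(diff(ph$phase_raw))), pi)
  expect_gt(diff(range(ph$phase_raw)), 2 * pi)  # really did wrap
})

test_that("mode assignment picks in-band highest-power modes and flags", {
  fake <- function(omega, power) {
    n <- 256
    modes <- sapply(seq_along(omega), function(k)
      sqrt(power[k]) * cos(2 * pi * omega[k] * (0:(n - 1)) / 13.25))
    structure(list(modes = modes, omega_hz = omega, fs = 13.25,
                   residual = 0, converged = TRUE, n_iter = 1,
                   K = length(omega), alpha = 2000, tau = 0),
              class = "vmd_result")
  }
  a <- assign_modes(fake(c(0.3, 1.2), c(1, 1)))
  expect_equal(a$resp, 1L)
  expect_equal(a$heart, 2L)
  # out-of-band on both sides: both flags raised
  b <- assign_modes(fake(c(0.05, 3.4), c(1, 1)))
  expect_true(b$resp_missing && b$heart_missing)
  # two candidates in the heart band: the higher-power one wins
  cc <- assign_modes(fake(c(0.3, 0.9, 1.8), c(1, 0.2, 0.8)))
  expect_equal(cc$heart, 3L)
})

test_that("rates: pure tone at 1 Hz reads 60 bpm; flags on degenerate input", {
  fs <- 13.25
  t <- (0:2047) / fs
  v <- vmd(cos(2 * pi * 1.0 * t), fs = fs, K = 1, alpha = 500)
  a <- list(resp = NA_integer_, heart = 1L, resp_missing = TRUE,
            heart_missing = FALSE)
  est <- estimate_rates(v, a)
  expect_equal(est$heart_rate_bpm, 60.0, tolerance = 0.05)
  expect_equal(mean(est$ibi_ms), 1000, tolerance = 1)
  # constant mode: no peaks, interval series flagged short
  vc <- v
  vc$modes[, 1] <- 1
  estc <- estimate_rates(vc, a)
  expect_true(estc$ibi_short)
  expect_length(estc$ibi_ms, 0)
})

test_that("seeded standby scenario recovers its generating rates", {
  sc <- vital_scenario("standby", resp_freq = 0.25, heart_freq = 1.1,
                       duration = 120, seed = 5)
  res <- suppressWarnings(run_end_to_end(sc, window_s = NULL))
  expect_equal(res$estimate$resp_rate_hz, 0.25, tolerance = 0.02 / 0.25)
  expect_equal(res$estimate$heart_rate_hz, 1.1, tolerance = 0.02 / 1.1)
})

test_that("agreement statistics match the direct formulas", {
  # differences {1, -1, 0}: mean 0, sample SD 1, limits +/- 1.96
  # (zero-mean reference deliberately triggers the error-percent warning)
  r <- suppressWarnings(agreement(c(1, -1, 0), c(0, 0, 0)))
  expect_equal(r$mean_difference, 0)
  expect_equal(r$loa_lower, -1.96)
  expect_equal(r$loa_upper, 1.96)
  # identical series: zero everywhere
  r2 <- agreement(c(5, 6, 7), c(5, 6, 7))
  expect_equal(r2$mean_difference, 0)
  expect_equal(r2$loa_upper, 0)
  expect_equal(r2$error_percent, 0)
  # printed heart-rate pair: 72.0661 vs 72.6271 bpm -> 0.772% error
  r3 <- agreement(rep(72.0661, 3), rep(72.6271, 3))
  expect_equal(round(r3$error_percent, 3), 0.772)
  expect_error(agreement(1:2, 1:3), "equal lengths")
  expect_warning(agreement(c(1, -1, 0), c(1, -1, 0)), "zero mean")
})
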