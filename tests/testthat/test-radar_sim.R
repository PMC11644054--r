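test_that("displacement series follows the two-sinusoid chest model", {
  sc <- vital_scenario("standby", resp_amplitude = 4e-3,
                       heart_amplitude = 1e-9, resp_freq = 0.25,
                       motion_rms_acc = 0, seed = 1)
  # A = 4 mm, f_r = 0.25 Hz at tau = 1 s: d0 + 4 mm (heartbeat negligible)
  expect_equal(displacement_series(sc, 1), 0.6 + 4e-3, tolerance = 1e-8)
  # no amplitudes, no motion: constant d0
  sc0 <- vital_scenario("standby", resp_amplitude = 1e-12,
                        heart_amplitude = 1e-13, motion_rms_acc = 0)
  expect_equal(displacement_series(sc0, seq(0, 10, 0.1)),
               rep(0.6, 101), tolerance = 1e-9)
})

test_that("motion term's acceleration matches the scenario RMS level", {
  n <- 10000; dt <- 0.01
  d <- mmvital:::motion_displacement(n, dt, rms_acc = 0.31, band = c(2, 4),
                                     seed = 11)
  # finite-difference second derivative (band well below Nyquist here)
  acc <- diff(d, differences = 2) / dt^2
  expect_equal(sqrt(mean(acc^2)), 0.31, tolerance = 0.1)
  # displacement is band-limited: nothing below the band edge
  X <- Mod(stats::fft(d))^2
  f <- (0:(n - 1)) / (n * dt)
  expect_lt(sum(X[f > 0.05 & f < 1.5]) / sum(X[f > 0]), 1e-12)
  expect_identical(mmvital:::motion_displacement(100, dt, 0, seed = 1),
                   numeric(100))
})

test_that("scenario validation enforces the physiological gates", {
  expect_error(vital_scenario("standby", resp_amplitude = 1e-4,
                              heart_amplitude = 3e-4), "A > B_h")
  expect_error(vital_scenario("standby", resp_freq = 0.05), "0.1")
  expect_error(vital_scenario("standby", heart_freq = 3.1), "2.5")
  expect_error(vital_scenario("standby", d0 = 0.4), "gate")
  # Table-2 vibration levels are wired to the condition/lens combination
  expect_equal(vital_scenario("bumpy")$motion_rms_acc, 0.310)
  expect_equal(vital_scenario("driving", with_lens = FALSE)$motion_rms_acc,
               0.325)
})

test_that("beat signal puts the target in the expected range bin", {
  cfg <- radar_config()
  # R = 0.6 m, B = 5 GHz, Tc = 32 us -> f_b = 625 kHz -> bin 20
  fb <- 2 * cfg$bandwidth * 0.6 / (C0 * cfg$chirp_time)
  expect_equal(fb, 625e3, tolerance = 1e-3)
  expect_equal(fb / (cfg$fs_fast / cfg$n_adc_samples), 20, tolerance = 1e-3)
  sc <- vital_scenario("standby", duration = 5, motion_rms_acc = 0,
                       snr_db = 60, seed = 2)
  cube <- beat_signal(sc, cfg)
  spec <- Mod(stats::fft(cube$iq[, 1, 1]))
  expect_equal(which.max(spec) - 1L, 20L)
})

test_that("slow-time phase steps follow 4 pi dR / lambda", {
  cfg <- radar_config()
  sc <- vital_scenario("standby", resp_amplitude = 1e-3,
                       heart_amplitude = 1e-9, resp_freq = 0.25,
                       motion_rms_acc = 0, snr_db = 200, seed = 1)
  cube <- beat_signal(sc, cfg)
  # displacement step of 1 mm at lambda = 5 mm -> phase step 2.513 rad
  lam <- cfg$wavelength
  dR <- diff(cube$truth$displacement_m)
  ph <- mmvital:::unwrap_phase(Arg(cube$iq[1, , 1]))
  expect_equal(diff(ph), 4 * pi * dR / lam, tolerance = 1e-6)
  expect_equal(4 * pi * 0.001 / 0.005, 2.513, tolerance = 1e-3)
})

test_that("zero-noise constant-range frames are identical; seeds reproduce", {
  cfg <- radar_config()
  sc <- vital_scenario("standby", resp_amplitude = 1e-12,
                       heart_amplitude = 1e-13, motion_rms_acc = 0,
                       snr_db = 400, duration = 2, seed = 9)
  cube <- beat_signal(sc, cfg)
  expect_true(all(abs(cube$iq[, , 1] - cube$iq[, 1, 1]) < 1e-6))
  sc2 <- vital_scenario("driving", duration = 3, seed = 21)
  expect_identical(beat_signal(sc2, cfg)$iq, beat_signal(sc2, cfg)$iq)
})

test_that("scenarios keep the heart rate under the slow-time Nyquist", {
  cfg <- radar_config()
  expect_gt(cfg$slow_rate / 2, 2.5)  # upper heart band edge
  slow_cfg <- radar_config(frame_time = 0.9)
  sc <- vital_scenario("standby", duration = 2)
  expect_error(beat_signal(sc, slow_cfg), "Nyquist")
})

test_that("occupancy cube follows the scripted timeline", {
  script <- occupancy_script()
  cube <- occupancy_cube(script, seed = 4)
  # 120 s / 75.476 ms frames
  expect_equal(dim(cube$iq)[2], floor(120 / 0.075476))
  expect_equal(dim(cube$iq)[2], 1589L)
  tr <- cube$truth
  expect_equal(unique(tr$state[cube$t < 20]), "empty")
  expect_equal(unique(tr$state[cube$t >= 20 & cube$t < 40]), "object")
  # object segment has zero ground-truth displacement variance
  expect_equal(stats::var(tr$displacement_m[tr$state == "object"]), 0)
  # all-empty script
  all_empty <- occupancy_script(data.frame(state = "empty", start = 0,
                                           end = 10))
  expect_true(all(occupancy_cube(all_empty, seed = 1)$truth$state == "empty"))
  expect_error(occupancy_script(data.frame(
    state = c("empty", "person"), start = c(0, 5), end = c(10, 15))),
    "contiguous")
})
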