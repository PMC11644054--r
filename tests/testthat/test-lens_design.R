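test_that("guided wavelength follows c/(f sqrt(eps)) and rejects bad input", {
  # vacuum case: plain free-space wavelength
  expect_equal(guided_wavelength(60e9, 1.0), C0 / 60e9)
  # polyimide cell at 60 GHz: 2.67 mm as printed for the design
  expect_equal(round(guided_wavelength(60e9, 3.5) * 1e3, 2), 2.67)
  # direct-evaluation oracle at another point
  expect_equal(guided_wavelength(30e9, 4.0), C0 / 30e9 / 2)
  expect_error(guided_wavelength(-1, 3.5), "positive")
  expect_error(guided_wavelength(60e9, 0.5), ">= 1")
})

test_that("hyperbolic phase is the equal-path profile: zero on axis, even", {
  expect_equal(hyperbolic_phase(0, 0.150, 0.005), 0)
  x <- 0.0296
  oracle <- (2 * pi / 0.005) * (sqrt(x^2 + 0.150^2) - 0.150)
  expect_equal(hyperbolic_phase(x, 0.150, 0.005), oracle)
  expect_equal(hyperbolic_phase(-x, 0.150, 0.005),
               hyperbolic_phase(x, 0.150, 0.005))
  expect_true(all(hyperbolic_phase(seq(-0.05, 0.05, 0.001), 0.1, 0.005) >= 0))
  expect_error(hyperbolic_phase(0, -1, 0.005), "positive")
})

test_that("element phase map: centre zero, radial symmetry, corner oracle", {
  lay <- aperture_layout()
  el <- lay$elements
  expect_equal(lay$side_m, 37 * 1.6e-3)
  centre <- el$phase_rad[el$x_m == 0 & el$y_m == 0]
  expect_equal(centre, 0)
  # corner element: R = 18 * 1.6mm * sqrt(2); direct evaluation of the
  # focusing-phase formula, reduced mod 2pi
  k <- 2 * pi * 60e9 / C0
  R <- 18 * 1.6e-3 * sqrt(2)
  oracle <- (k * (sqrt(R^2 + 0.15^2) - 0.15)) %% (2 * pi)
  corner <- el$phase_rad[el$i == 0 & el$j == 0]
  expect_equal(corner, oracle, tolerance = 1e-12)
  # all elements equidistant from the centre share one phase
  r <- round(sqrt(el$x_m^2 + el$y_m^2), 12)
  ph_by_r <- tapply(el$phase_rad, r, function(p) diff(range(p)))
  expect_true(all(ph_by_r < 1e-9))
  # invariant under 90 degree rotation of the grid (x,y) -> (-y,x)
  key1 <- paste(round(el$x_m, 9), round(el$y_m, 9))
  key2 <- paste(round(-el$y_m, 9), round(el$x_m, 9))
  expect_equal(el$phase_rad[match(key2, key1)], el$phase_rad)
})

test_that("two-way profile doubles the one-way phase before wrapping", {
  lay1 <- aperture_layout(n_side = 5)
  lay2 <- aperture_layout(n_side = 5, two_way = TRUE)
  expect_equal(lay2$elements$phase_rad,
               (2 * lay1$elements$phase_rad) %% (2 * pi))
})

test_that("quantization picks wrap-aware nearest entries, ties to smaller L", {
  lk <- phase_lookup(data.frame(L_mm = c(0.2, 0.5, 0.8, 1.1),
                                mag_dB = rep(0, 4),
                                phase_deg = c(0, 90, 180, 270)))
  q <- quantize_phases(c(100, 350, 45) * pi / 180, lk)
  expect_equal(q$L_mm[1], 0.5)   # 100 deg -> 90 deg entry
  expect_equal(q$L_mm[2], 0.2)   # 350 deg wraps to the 0 deg entry
  expect_equal(q$L_mm[3], 0.2)   # tie 0 vs 90: smaller L wins
  expect_error(quantize_phases(1, phase_lookup(data.frame(
    L_mm = numeric(0), mag_dB = numeric(0), phase_deg = numeric(0)))),
    "empty")
})

test_that("dense lookup keeps residuals below half the adjacent phase gap", {
  lk <- phase_lookup_synthetic(n = 64)
  targets <- seq(0, 2 * pi, length.out = 201)
  q <- quantize_phases(targets, lk)
  ph <- sort(lk$phase_deg * pi / 180)
  gaps <- diff(c(ph, ph[1] + 2 * pi))
  expect_true(all(abs(q$residual_rad) <= max(gaps) / 2 + 1e-12))
  # exhaustive-search oracle agrees with the vectorized assignment
  for (t in targets[seq(1, 201, by = 20)]) {
    d <- abs(atan2(sin(t - lk$phase_deg * pi / 180),
                   cos(t - lk$phase_deg * pi / 180)))
    expect_equal(q$L_mm[which(targets == t)], lk$L_mm[which.min(d)])
  }
})

test_that("ideal continuous lookup reproduces target phases exactly", {
  lay <- aperture_layout(n_side = 9)
  # lookup whose entries are exactly the wanted phases
  ph <- sort(unique(round(lay$elements$phase_rad, 10)))
  lk <- phase_lookup(data.frame(L_mm = seq_along(ph),
                                mag_dB = rep(0, length(ph)),
                                phase_deg = ph * 180 / pi))
  q <- quantize_phases(lay, lk)
  expect_true(all(abs(q$elements$residual_rad) < 1e-8))
})

test_that("beam angles follow the gradient vector sum, evanescent errors", {
  k0 <- 2 * pi * 60e9 / C0
  # single gradient: theta = asin(p1/k0), phi = alpha1
  tc <- tilt_config(p1 = 0.3 * k0, p2 = 0, alpha1 = 0.7, k0 = k0)
  a <- beam_angles(tc)
  expect_equal(a$theta, asin(0.3))
  expect_equal(a$phi, 0.7)
  # opposed equal gradients cancel: broadside
  tc0 <- tilt_config(p1 = 123, p2 = 123, alpha1 = 0, alpha2 = pi, k0 = k0)
  expect_equal(beam_angles(tc0)$theta, 0, tolerance = 1e-12)
  expect_equal(zero_tilt_residual(tc0), 0, tolerance = 1e-6)
  # grazing case: p1 = p2 = k0/2 aligned gives theta = pi/2
  tg <- tilt_config(p1 = k0 / 2, p2 = k0 / 2, alpha1 = 0, alpha2 = 0, k0 = k0)
  expect_equal(beam_angles(tg)$theta, pi / 2)
  expect_equal(beam_angles(tg)$phi, 0)
  # evanescent combination is a domain error
  te <- tilt_config(p1 = k0, p2 = k0, alpha1 = 0, alpha2 = 0, k0 = k0)
  expect_error(beam_angles(te), "evanescent")
})

test_that("zero-tilt residual evaluates p1^2 + p2^2 + 2 p1 p2 cos(da)", {
  expect_equal(zero_tilt_residual(tilt_config(1, 0, 0, 2)), 1)
  expect_equal(zero_tilt_residual(tilt_config(2, 1, pi / 2, 0)), 5)
  expect_equal(zero_tilt_residual(tilt_config(3, 3, 0, pi)), 0)
})

test_that("lookup validation enforces ordering, magnitude and span report", {
  expect_error(phase_lookup(data.frame(L_mm = c(2, 1), mag_dB = 0,
                                       phase_deg = c(0, 90))), "increasing")
  expect_error(phase_lookup(data.frame(L_mm = 1, mag_dB = 3,
                                       phase_deg = 0)), "0 dB")
  lk <- phase_lookup_synthetic()
  expect_gte(attr(lk, "phase_span_deg"), 340)
})
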