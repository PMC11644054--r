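Ts <- 75.476e-3

test_that("alpha follows the EWMA half-power identity", {
  # direct evaluation of the identity at the frame rate
  expect_equal(alpha_from_cutoff(0.5, Ts), 0.2102, tolerance = 1e-3)
  # f_c -> 0 drives alpha -> 0
  expect_lt(alpha_from_cutoff(1e-4, Ts), 1e-3)
  expect_error(alpha_from_cutoff(0, Ts), "positive")
  expect_error(alpha_from_cutoff(7, Ts), "Nyquist")
})

test_that("one-pole EWMA at the computed alpha is -3 dB at f_c", {
  for (fc in c(0.5, 1.5, 3)) {
    a <- alpha_from_cutoff(fc, Ts)
    # filter a long sinusoid at f_c through s[n] = a x[n] + (1-a) s[n-1]
    t <- (0:19999) * Ts
    x <- sin(2 * pi * fc * t)
    s <- stats::filter(a * x, 1 - a, method = "recursive")
    gain2 <- mean(s[2000:20000]^2) / mean(x[2000:20000]^2)
    expect_equal(gain2, 0.5, tolerance = 0.01)
  }
})

test_that("EWMA variance recursion matches hand computation", {
  # y = {0, 1}, Ts = 1, alpha = 0.5: sigma2[2] = 0.5 * 1 + 0.5 * 0
  expect_equal(ewma_sigma(c(0, 1), alpha = 0.5, T_s = 1), c(0, 0.5))
  # full recursion against an explicit loop
  set.seed(7)
  y <- rnorm(100)
  a <- 0.3
  ref <- numeric(100)
  for (n in 2:100) ref[n] <- a * ((y[n] - y[n - 1]) / Ts)^2 +
    (1 - a) * ref[n - 1]
  expect_equal(ewma_sigma(y, alpha = a, T_s = Ts), ref)
  # constant envelope: identically zero
  expect_true(all(ewma_sigma(rep(3, 50), alpha = 0.4, T_s = Ts) == 0))
})

test_that("sigma2 is DC-invariant and quadratic in scale", {
  set.seed(8)
  y <- rnorm(200)
  s <- ewma_sigma(y, alpha = 0.37, T_s = Ts)
  expect_equal(ewma_sigma(y + 17, alpha = 0.37, T_s = Ts), s)
  expect_equal(ewma_sigma(3 * y, alpha = 0.37, T_s = Ts), 9 * s)
})

test_that("white-noise steady state approaches 2 v / Ts^2 for any alpha", {
  set.seed(9)
  v <- 0.25
  y <- rnorm(200000, sd = sqrt(v))
  for (a in c(0.1, 0.5, 0.9)) {
    s <- ewma_sigma(y, alpha = a, T_s = Ts)
    expect_equal(mean(s[1000:length(s)]), 2 * v / Ts^2, tolerance = 0.02)
  }
})

test_that("classification is strict at the threshold with chatter hold", {
  # sigma exactly at threshold counts as not-person
  s2 <- c(0, 1, 1, 1)  # sigma = 1
  expect_true(all(classify_occupancy(s2, sigma_th = 1,
                                     hold_s = 0) == "not_person"))
  expect_equal(classify_occupancy(c(0, 4, 4, 4), sigma_th = 1, hold_s = 0),
               c("not_person", rep("person", 3)))
  # an isolated one-frame blip is absorbed by the 1 s hold
  s <- rep(0.1, 60); s[30] <- 100
  out <- classify_occupancy(s, sigma_th = 1, T_s = Ts, hold_s = 1)
  expect_true(all(out == "not_person"))
  expect_true(all(classify_occupancy(rep(0, 20), 0.5) == "not_person"))
  expect_error(classify_occupancy(s2, sigma_th = 0), "positive")
})

test_that("threshold calibration is the geometric mean and detects overlap", {
  # person sigma ~ 1, empty sigma ~ 0.01 -> threshold 0.1
  th <- calibrate_threshold(list(rep(1, 10)), list(rep(1e-4, 10)))
  expect_equal(as.numeric(th), 0.1)
  expect_equal(attr(th, "margin"), 100)
  expect_error(calibrate_threshold(list(rep(1, 5)), list(rep(1, 5))),
               "overlap")
  # single runs: deterministic
  expect_equal(as.numeric(calibrate_threshold(4, 1e-4)), sqrt(2 * 0.01))
})

test_that("scripted timeline is classified correctly outside transitions", {
  cube <- occupancy_cube(seed = 2)
  tr <- detect_occupancy(cube)
  expect_gte(occupancy_agreement(tr, exclude_s = 1), 0.99)
  # person detected within the person window, not during the bag
  in_person <- tr$t > 45 & tr$t < 75
  in_bag <- tr$t > 22 & tr$t < 38
  expect_true(all(tr$state[in_person] == "person"))
  expect_true(all(tr$state[in_bag] == "not_person"))
})
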