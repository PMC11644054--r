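# Shared helpers for the mmvital test suite.

C0 <- 299792458

# Two-tone test series used by several VMD tests.
two_tone <- function(f1 = 0.3, f2 = 1.2, a1 = 1, a2 = 0.5, fs = 13.25,
                     n = 2048) {
  t <- (0:(n - 1)) / fs
  list(t = t, fs = fs, f1 = f1, f2 = f2,
       x = a1 * cos(2 * pi * f1 * t) + a2 * cos(2 * pi * f2 * t))
}

# FFT-peak oracle: frequency (Hz) of the strongest spectral component.
fft_peak_oracle <- function(x, fs) {
  n <- length(x)
  X <- Mod(stats::fft(x - mean(x)))^2
  half <- floor(n / 2)
  f <- (0:(n - 1)) * fs / n
  f[2:half][which.max(X[2:half])]
}

# Uniform square aperture field of m samples on an n x n grid.
square_aperture <- function(m, n, dx, wavelength) {
  c0 <- floor(n / 2) + 1
  idx <- (c0 - m / 2):(c0 + m / 2 - 1)
  u <- matrix(0 + 0i, n, n)
  u[idx, idx] <- 1
  aperture_field(u, dx, wavelength)
}
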