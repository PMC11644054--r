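#' Guided wavelength in a dielectric substrate
#'
#' Wavelength of a wave at `frequency` inside a medium of relative
#' permittivity `permittivity`: \eqn{\lambda_g = (c/f)/\sqrt{\epsilon_r}}.
#' For the 1.6 mm polyimide unit cell (\eqn{\epsilon_r = 3.5}) at 60 GHz this
#' gives 2.67 mm, i.e. the cell pitch is roughly \eqn{0.6\lambda_g} —
#' subwavelength, which suppresses grating lobes.
#'
#' @param frequency operating frequency in Hz (> 0)
#' @param permittivity relative permittivity (>= 1), dimensionless
#' @return wavelength in metres
#' @examples
#' guided_wavelength(60e9, 3.5)  # ~2.67e-3 m
#' @export
guided_wavelength <- function(frequency, permittivity = 3.5) {
  if (any(frequency <= 0)) stop_invalid("`frequency` must be positive")
  if (any(permittivity < 1)) stop_invalid("`permittivity` must be >= 1")
  (.c0 / frequency) / sqrt(permittivity)
}

#' Hyperbolic focusing phase profile
#'
#' Phase a focusing surface must impose at transverse position `x` so that
#' all paths to the focal point at distance `focal_length` are equal:
#' \eqn{\phi(x) = (2\pi/\lambda)(\sqrt{x^2 + F^2} - F)}. Non-negative and
#' even in `x`.
#'
#' @param x transverse coordinate(s) in metres
#' @param focal_length design focal distance F in metres (> 0)
#' @param wavelength working wavelength in metres (> 0)
#' @return phase in radians (same length as `x`)
#' @export
hyperbolic_phase <- function(x, focal_length, wavelength) {
  if (focal_length <= 0) stop_invalid("`focal_length` must be positive")
  if (wavelength <= 0) stop_invalid("`wavelength` must be positive")
  (2 * pi / wavelength) * (sqrt(x^2 + focal_length^2) - focal_length)
}

#' Unit-cell geometry of the transmitarray
#'
#' Records the square patch side `L`, the cell pitch `W` (1.6 mm), the hole
#' radius `R` and the substrate permittivity that together set the cell's
#' transmission phase.
#'
#' @param L patch side length in mm (0 < L < W)
#' @param W cell pitch in mm
#' @param R hole radius in mm (R < W/2)
#' @param substrate_permittivity relative permittivity (>= 1)
#' @param frequency design frequency in Hz
#' @return an object of class `unit_cell_spec`
#' @export
unit_cell_spec <- function(L, W = 1.6, R = 0.6, substrate_permittivity = 3.5,
                           frequency = 60e9) {
  if (L <= 0 || L >= W) stop_invalid("require 0 < L < W")
  if (R >= W / 2) stop_invalid("require R < W/2")
  if (substrate_permittivity < 1) stop_invalid("permittivity must be >= 1")
  if (frequency <= 0) stop_invalid("`frequency` must be positive")
  structure(list(L = L, W = W, R = R,
                 substrate_permittivity = substrate_permittivity,
                 frequency = frequency),
            class = "unit_cell_spec")
}

#' Synthetic unit-cell phase lookup table
#'
#' Monotone stand-in for a full-wave characterization of the unit cell:
#' transmission phase spanning `phase_span_deg` (default 350 degrees, the
#' achievable span of the 1.6 mm cell) linearly over patch sides
#' `L` in \[0.2, 1.2\] mm, with transmission magnitude no worse than -3 dB
#' (best at mid-range L). Replace with [read_phase_lookup()] when measured
#' or simulated cell data are available.
#'
#' @param n number of entries
#' @param L_range range of patch side lengths in mm
#' @param phase_span_deg total phase span in degrees
#' @param frequency frequency the table applies at, Hz
#' @return a `phase_lookup` object (data frame with columns `L_mm`, `mag_dB`,
#'   `phase_deg`)
#' @export
phase_lookup_synthetic <- function(n = 128, L_range = c(0.2, 1.2),
                                   phase_span_deg = 350, frequency = 60e9) {
  L <- seq(L_range[1], L_range[2], length.out = n)
  u <- (L - mean(L_range)) / (diff(L_range) / 2)  # -1..1
  phase_lookup(data.frame(
    L_mm = L,
    mag_dB = -0.5 - 2.5 * u^2,
    phase_deg = seq(0, phase_span_deg, length.out = n) %% 360
  ), frequency = frequency)
}

#' Construct/validate a unit-cell phase lookup
#'
#' @param entries data frame with columns `L_mm` (strictly increasing),
#'   `mag_dB` (<= 0) and `phase_deg` (reduced to \[0, 360))
#' @param frequency frequency the table applies at, Hz
#' @return a `phase_lookup` object; its `phase_span_deg` attribute reports
#'   the covered span on the circle
#' @export
phase_lookup <- function(entries, frequency = 60e9) {
  need <- c("L_mm", "mag_dB", "phase_deg")
  if (!all(need %in% names(entries)))
    stop_invalid("lookup needs columns ", paste(need, collapse = ", "))
  if (nrow(entries) == 0) stop_invalid("lookup is empty")
  if (any(diff(entries$L_mm) <= 0))
    stop_invalid("L_mm values must be strictly increasing")
  if (any(entries$mag_dB > 1e-9))
    stop_invalid("transmission magnitude must be <= 0 dB")
  entries$phase_deg <- entries$phase_deg %% 360
  ph <- sort(entries$phase_deg)
  gaps <- diff(c(ph, ph[1] + 360))
  span <- 360 - max(gaps)
  structure(entries, class = c("phase_lookup", "data.frame"),
            frequency = frequency, phase_span_deg = span)
}

#' Square transmitarray aperture layout
#'
#' Builds the element grid of an `n_side` x `n_side` transmitarray (default
#' 37 x 37 at 1.6 mm pitch, a 59.2 mm square), computes each element's target
#' focusing phase, and optionally quantizes it to realizable unit cells via a
#' phase lookup.
#'
#' The target phase of element i is
#' \eqn{\Delta\phi_i = g \, k (\sqrt{R_i^2 + F_t^2} - F_t) \bmod 2\pi}
#' with \eqn{R_i} the element's distance from the aperture centre and
#' \eqn{g = 1} for the standard one-way profile (`two_way = FALSE`) or
#' \eqn{g = 2} for the two-way variant.
#'
#' @param n_side elements per side (odd recommended so an element sits at the
#'   centre)
#' @param pitch element pitch in metres
#' @param focal_length design focal length in metres
#' @param frequency design frequency in Hz
#' @param lookup optional [phase_lookup()]; when supplied the layout is
#'   quantized on construction
#' @param two_way logical; use the factor-2 (round-trip) phase profile
#' @return an `aperture_layout` with per-element data frame `elements`
#'   (columns `i`, `j` 0-based, `x_m`, `y_m`, `phase_rad`, and after
#'   quantization `L_mm`, `residual_rad`)
#' @export
aperture_layout <- function(n_side = 37, pitch = 1.6e-3, focal_length = 0.150,
                            frequency = 60e9, lookup = NULL, two_way = FALSE) {
  if (n_side < 1) stop_invalid("`n_side` must be >= 1")
  if (pitch <= 0) stop_invalid("`pitch` must be positive")
  if (focal_length <= 0) stop_invalid("`focal_length` must be positive")
  if (frequency <= 0) stop_invalid("`frequency` must be positive")
  idx <- expand.grid(i = 0:(n_side - 1), j = 0:(n_side - 1))
  half <- (n_side - 1) / 2
  elements <- data.frame(
    i = idx$i, j = idx$j,
    x_m = (idx$i - half) * pitch,
    y_m = (idx$j - half) * pitch
  )
  layout <- structure(list(
    n_side = n_side, pitch = pitch, focal_length = focal_length,
    frequency = frequency, wavelength = .c0 / frequency,
    side_m = n_side * pitch, two_way = two_way,
    elements = elements
  ), class = "aperture_layout")
  layout$elements$phase_rad <- element_phase_map(layout)
  if (!is.null(lookup)) layout <- quantize_phases(layout, lookup)
  layout
}

#' @export
print.aperture_layout <- function(x, ...) {
  cat(sprintf("aperture_layout: %d x %d elements, pitch %.3g mm, side %.4g mm\n",
              x$n_side, x$n_side, x$pitch * 1e3, x$side_m * 1e3))
  cat(sprintf("  F = %.4g mm, f = %.4g GHz%s%s\n",
              x$focal_length * 1e3, x$frequency / 1e9,
              if (x$two_way) ", two-way phase" else "",
              if (!is.null(x$elements$L_mm)) ", quantized" else ""))
  invisible(x)
}

#' Per-element focusing phase of an aperture layout
#'
#' \eqn{R_i = \sqrt{x_{ij}^2 + y_{ij}^2}},
#' \eqn{\Delta\phi_i = g\,k(\sqrt{R_i^2 + F_t^2} - F_t)} reduced modulo
#' \eqn{2\pi} (g = 1, or 2 when the layout was built with `two_way = TRUE`).
#' The centre element's phase is 0 and equidistant elements share one phase.
#'
#' @param layout an [aperture_layout()]
#' @return numeric vector of phases in radians in \[0, 2pi), one per element
#' @export
element_phase_map <- function(layout) {
  stopifnot(inherits(layout, "aperture_layout"))
  k <- 2 * pi / layout$wavelength
  g <- if (isTRUE(layout$two_way)) 2 else 1
  r <- sqrt(layout$elements$x_m^2 + layout$elements$y_m^2)
  wrap_2pi(g * k * (sqrt(r^2 + layout$focal_length^2) - layout$focal_length))
}

#' Quantize target phases to realizable unit cells
#'
#' Assigns to each element the lookup entry whose transmission phase is
#' closest to the target on the circle (wrap-aware distance); ties are broken
#' toward the smaller patch side L. The signed residual (target - chosen) is
#' reported per element.
#'
#' @param layout an [aperture_layout()] (or a numeric vector of target phases
#'   in radians)
#' @param lookup a [phase_lookup()]
#' @return the layout with `L_mm`, `quantized_phase_rad`, `residual_rad`
#'   columns added (or, for a numeric input, a data frame of the same)
#' @export
quantize_phases <- function(layout, lookup) {
  if (!inherits(lookup, "phase_lookup")) lookup <- phase_lookup(lookup)
  targets <- if (inherits(layout, "aperture_layout"))
    layout$elements$phase_rad else as.numeric(layout)
  entry_phase <- lookup$phase_deg * pi / 180
  # distance matrix entries x targets; ties -> smaller L (lower row index
  # wins in which.min because lookup rows are ordered by increasing L)
  pick <- vapply(targets, function(t) {
    d <- abs(ang_diff(t, entry_phase))
    which.min(round(d, 12))
  }, integer(1))
  res <- data.frame(
    L_mm = lookup$L_mm[pick],
    quantized_phase_rad = entry_phase[pick],
    residual_rad = ang_diff(targets, entry_phase[pick])
  )
  if (inherits(layout, "aperture_layout")) {
    layout$elements$L_mm <- res$L_mm
    layout$elements$quantized_phase_rad <- res$quantized_phase_rad
    layout$elements$residual_rad <- res$residual_rad
    layout$lookup <- lookup
    layout
  } else res
}

#' Tilt configuration of the phase-gradient surface pair
#'
#' Two phase-delay gradients `p1`, `p2` (rad/m) at in-plane rotation angles
#' `alpha1`, `alpha2` (rad) add vectorially to steer the transmitted beam.
#'
#' @param p1,p2 phase-delay gradient magnitudes in rad/m
#' @param alpha1,alpha2 rotation angles in rad
#' @param k0 free-space wavenumber in rad/m (> 0); default from `frequency`
#' @param frequency frequency in Hz used when `k0` is missing
#' @return a `tilt_config` object
#' @export
tilt_config <- function(p1, p2, alpha1 = 0, alpha2 = 0, k0 = NULL,
                        frequency = 60e9) {
  if (is.null(k0)) k0 <- 2 * pi * frequency / .c0
  if (k0 <= 0) stop_invalid("`k0` must be positive")
  structure(list(p1 = p1, p2 = p2, alpha1 = alpha1, alpha2 = alpha2, k0 = k0),
            class = "tilt_config")
}

#' Beam angles from phase-delay gradients
#'
#' The transverse wavenumbers are
#' \eqn{k_x = p_1\cos\alpha_1 + p_2\cos\alpha_2},
#' \eqn{k_y = p_1\sin\alpha_1 + p_2\sin\alpha_2}; the elevation is
#' \eqn{\theta = \arcsin(\sqrt{k_x^2+k_y^2}/k_0)} and the azimuth
#' \eqn{\phi = \mathrm{atan2}(k_y, k_x)}. An evanescent combination
#' (\eqn{\sqrt{k_x^2+k_y^2} > k_0}) is a domain error.
#'
#' @param tilt a [tilt_config()]
#' @return list with `theta` and `phi` in radians
#' @export
beam_angles <- function(tilt) {
  stopifnot(inherits(tilt, "tilt_config"))
  kx <- tilt$p1 * cos(tilt$alpha1) + tilt$p2 * cos(tilt$alpha2)
  ky <- tilt$p1 * sin(tilt$alpha1) + tilt$p2 * sin(tilt$alpha2)
  kt <- sqrt(kx^2 + ky^2)
  if (kt > tilt$k0 * (1 + 1e-12))
    stop_invalid("evanescent configuration: sqrt(kx^2 + ky^2) = ",
                 format(kt), " exceeds k0 = ", format(tilt$k0),
                 "; no propagating beam exists")
  list(theta = asin(min(kt / tilt$k0, 1)), phi = atan2(ky, kx))
}

#' Broadside-condition residual of a gradient pair
#'
#' Returns \eqn{p_1^2 + p_2^2 + 2 p_1 p_2 \cos(\alpha_1 - \alpha_2)}, which
#' is zero exactly when the two phase-delay gradients cancel and the beam
#' leaves at broadside (theta = 0).
#'
#' @param tilt a [tilt_config()]
#' @return residual in (rad/m)^2
#' @export
zero_tilt_residual <- function(tilt) {
  stopifnot(inherits(tilt, "tilt_config"))
  tilt$p1^2 + tilt$p2^2 + 2 * tilt$p1 * tilt$p2 * cos(tilt$alpha1 - tilt$alpha2)
}
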