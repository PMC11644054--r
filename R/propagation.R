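# Scalar-diffraction evaluation of the designed aperture: angular-spectrum
# propagation, focal metrics, bend-degradation study.

#' Sampled complex aperture field
#'
#' @param u complex matrix (x along rows, y along columns), the field in the
#'   aperture plane
#' @param dx grid spacing in metres (must satisfy dx <= lambda/2 so the
#'   angular spectrum is alias-free)
#' @param wavelength wavelength in metres (in the propagation medium)
#' @return an `aperture_field` object
#' @export
aperture_field <- function(u, dx, wavelength) {
  if (!is.matrix(u)) stop_invalid("`u` must be a matrix")
  if (dx <= 0 || wavelength <= 0) stop_invalid("dx and wavelength must be > 0")
  if (dx > wavelength / 2)
    stop_invalid("grid too coarse: dx = ", format(dx), " exceeds lambda/2 = ",
                 format(wavelength / 2), " (aliasing)")
  structure(list(u = u, dx = dx, wavelength = wavelength),
            class = "aperture_field")
}

# x (and y) coordinates of the field grid, centred so that index
# floor(n/2)+1 is x = 0 (matches the layout rasterizer below).
field_axis <- function(field) {
  n <- nrow(field$u)
  (seq_len(n) - (floor(n / 2) + 1)) * field$dx
}

# kz grid (rad/m) for the angular spectrum; complex for evanescent waves.
.kz_grid <- function(n, dx, wavelength) {
  k <- 2 * pi / wavelength
  kx <- 2 * pi * fft_freq(n, dx)
  kx2 <- outer(kx^2, kx^2, "+")
  arg <- k^2 - kx2
  kz <- sqrt(as.complex(arg))   # principal branch: imaginary for evanescent
  list(kz = kz, propagating = arg >= 0)
}

# Band limit of the sampled propagator (Matsushima & Shimobaba): plane
# waves steeper than atan(L/2z) exit the computation box before z and, with
# a periodic FFT box, would wrap around instead; their propagator phase is
# also under-sampled. Returns the per-axis |k_x| limit in rad/m.
.asm_band_limit <- function(n, dx, z) {
  if (z <= 0) return(1)
  L_half <- n * dx / 2
  # kx_max / k = sin(atan(L/2z)) = (L/2) / sqrt(z^2 + (L/2)^2)
  L_half / sqrt(z^2 + L_half^2)
}

#' Angular-spectrum propagation of a sampled field
#'
#' Exact scalar free-space propagation: the field is decomposed into plane
#' waves by 2-D FFT, each advanced by \eqn{\exp(i k_z z)} with
#' \eqn{k_z = \sqrt{k^2 - k_x^2 - k_y^2}}, and recomposed. Evanescent
#' components decay as \eqn{\exp(-|k_z| z)}. Power carried by propagating
#' components is conserved.
#'
#' With `band_limit = TRUE` (default) the propagator is band-limited per
#' axis to plane waves whose transverse ray stays inside the computation box
#' over the distance `z` (the band-limited angular spectrum method); this
#' suppresses the periodic wrap-around artefacts of the FFT box at long
#' propagation distances without affecting components that remain inside.
#'
#' @param field an [aperture_field()]
#' @param z propagation distance in metres (>= 0)
#' @param band_limit apply the anti-wrap propagator band limit
#' @return the propagated [aperture_field()] at distance `z`
#' @export
propagate_angular_spectrum <- function(field, z, band_limit = TRUE) {
  stopifnot(inherits(field, "aperture_field"))
  if (z < 0) stop_invalid("`z` must be >= 0")
  if (z == 0) return(field)
  n <- nrow(field$u)
  g <- .kz_grid(n, field$dx, field$wavelength)
  A <- stats::fft(field$u)
  Az <- A * exp(1i * g$kz * z)
  if (band_limit) {
    k <- 2 * pi / field$wavelength
    kmax <- k * .asm_band_limit(n, field$dx, z)
    kx <- 2 * pi * fft_freq(n, field$dx)
    keep <- abs(kx) <= kmax
    Az[!keep, ] <- 0
    Az[, !keep] <- 0
  }
  uz <- stats::fft(Az, inverse = TRUE) / length(Az)
  aperture_field(uz, field$dx, field$wavelength)
}

# On-axis complex field at distances zs (vector), evaluated directly from
# the propagating part of the angular spectrum (no per-z inverse FFT),
# with the same per-z anti-wrap band limit as the full propagator.
on_axis_field <- function(field, zs, band_limit = TRUE) {
  n <- nrow(field$u)
  g <- .kz_grid(n, field$dx, field$wavelength)
  A <- stats::fft(field$u)
  # spatial phase factor putting the evaluation point at the grid centre
  c0 <- floor(n / 2)  # 0-based index of x = 0
  ex <- exp(2i * pi * (0:(n - 1)) * c0 / n)
  B <- A * outer(ex, ex)
  keep <- which(g$propagating)
  Bv <- B[keep] / n^2
  kzv <- Re(g$kz[keep])
  k <- 2 * pi / field$wavelength
  kx <- 2 * pi * fft_freq(n, field$dx)
  kmax_ax <- pmax(abs(kx[(keep - 1) %% n + 1]),
                  abs(kx[(keep - 1) %/% n + 1]))
  vapply(zs, function(z) {
    sel <- if (band_limit) kmax_ax <= k * .asm_band_limit(n, field$dx, z)
           else TRUE
    sum(Bv[sel] * exp(1i * kzv[sel] * z))
  }, complex(1))
}

#' Cylindrical bending of the element sheet
#'
#' Wraps the aperture isometrically (arc length preserved) around a cylinder
#' whose subtended angle across the sheet is `angle_deg`, about `axis`. Each
#' element keeps its arc coordinate; its chord (projected) position and
#' out-of-plane sag are returned, together with the extra transmission phase
#' `k0 * sag` the sag imposes on a normally incident wave.
#'
#' @param layout an [aperture_layout()]
#' @param angle_deg subtended bend angle in degrees (0 to 40 studied)
#' @param axis bend axis, `"y"` (sheet curves along x, default) or `"x"`
#' @return data frame per element: `x_m`, `y_m` (projected positions),
#'   `sag_m`, `extra_phase_rad`
#' @export
bend_aperture <- function(layout, angle_deg, axis = c("y", "x")) {
  stopifnot(inherits(layout, "aperture_layout"))
  axis <- match.arg(axis)
  if (angle_deg < 0 || angle_deg > 40)
    stop_invalid("bend angle must be within [0, 40] degrees")
  el <- layout$elements
  s <- if (axis == "y") el$x_m else el$y_m  # arc coordinate
  if (angle_deg == 0) {
    sag <- rep(0, nrow(el))
    xp <- el$x_m; yp <- el$y_m
  } else {
    theta <- angle_deg * pi / 180
    R <- layout$side_m / theta           # radius of curvature, arc = side
    chord <- R * sin(s / R)
    sag <- R * (1 - cos(s / R))
    if (axis == "y") { xp <- chord; yp <- el$y_m }
    else             { xp <- el$x_m; yp <- chord }
  }
  k0 <- 2 * pi / layout$wavelength
  data.frame(x_m = xp, y_m = yp, sag_m = sag, extra_phase_rad = k0 * sag)
}

# Rasterize the (possibly bent) layout onto a regular grid. With
# phase_model "element" each grid point inside the projected aperture takes
# the phase of its nearest element (piecewise-constant, like the physical
# cell array); "quantized" additionally uses the lookup-quantized phases and
# cell transmission magnitudes; "continuous" evaluates the hyperbolic
# profile at the grid points themselves (idealized smooth lens).
layout_field <- function(layout, bend_angle_deg = 0, bend_axis = "y",
                         dx = 0.25e-3, grid_n = NULL,
                         phase_model = c("auto", "quantized", "element",
                                         "continuous")) {
  stopifnot(inherits(layout, "aperture_layout"))
  phase_model <- match.arg(phase_model)
  if (phase_model == "auto")
    phase_model <- if (!is.null(layout$elements$quantized_phase_rad))
      "quantized" else "element"
  if (phase_model == "quantized" &&
      is.null(layout$elements$quantized_phase_rad))
    stop_invalid("layout is not quantized; supply a lookup first")
  lam <- layout$wavelength
  geom <- bend_aperture(layout, bend_angle_deg, bend_axis)
  el <- layout$elements
  use_quantized <- phase_model == "quantized"
  ph <- if (use_quantized) el$quantized_phase_rad else el$phase_rad
  ph <- ph - geom$extra_phase_rad   # lens phase minus bend-induced error
  amp <- if (use_quantized && !is.null(el$L_mm) && !is.null(layout$lookup)) {
    10^(layout$lookup$mag_dB[match(el$L_mm, layout$lookup$L_mm)] / 20)
  } else rep(1, nrow(el))
  if (is.null(grid_n)) {
    grid_n <- 2^ceiling(log2(2 * layout$side_m / dx))
    grid_n <- max(grid_n, 64)
  }
  x <- (seq_len(grid_n) - (floor(grid_n / 2) + 1)) * dx
  half <- layout$pitch * layout$n_side / 2
  theta <- bend_angle_deg * pi / 180
  Rc <- if (theta > 0) layout$side_m / theta else Inf
  half_proj <- if (theta > 0) Rc * sin(half / Rc) else half
  u <- matrix(0 + 0i, grid_n, grid_n)
  if (phase_model == "continuous") {
    # smooth hyperbolic profile evaluated at grid points; the bent axis's
    # grid (chord) coordinate maps back to arc length for phase and sag
    inside_b <- abs(x) <= half_proj + 1e-12    # bent axis
    inside_f <- abs(x) <= half + 1e-12         # flat axis
    xb <- x
    sag <- numeric(grid_n)
    if (theta > 0) {
      s_arc <- ifelse(abs(x) <= Rc, Rc * asin(pmax(-1, pmin(1, x / Rc))), x)
      sag <- Rc * (1 - cos(s_arc / Rc))
      xb <- s_arc                              # phase designed on the arc
    }
    g <- if (isTRUE(layout$two_way)) 2 else 1
    k <- 2 * pi / lam
    bend_corr <- (2 * pi / lam) * sag
    if (bend_axis == "y") {
      xr <- xb; xc <- x; mr <- inside_b; mc <- inside_f
      corr <- matrix(bend_corr, grid_n, grid_n)
    } else {
      xr <- x; xc <- xb; mr <- inside_f; mc <- inside_b
      corr <- matrix(bend_corr, grid_n, grid_n, byrow = TRUE)
    }
    r2 <- outer(xr^2, xc^2, "+")
    phi <- g * k * (sqrt(r2 + layout$focal_length^2) - layout$focal_length)
    u <- exp(-1i * (phi - corr))
    u[!mr, ] <- 0; u[, !mc] <- 0
    return(aperture_field(u, dx, lam))
  }
  # per-element complex transmission on the n x n index grid ([i+1, j+1];
  # expand.grid order in aperture_layout makes the natural fill correct)
  tmat <- matrix(complex(modulus = amp, argument = -ph),
                 layout$n_side, layout$n_side)
  nearest_idx <- function(q, centers) {
    i <- findInterval(q, c(-Inf, centers[-1] - diff(centers) / 2, Inf))
    pmin(pmax(i, 1L), length(centers))
  }
  # element centre coordinates in projected space; bending only rescales
  # one axis, monotonically, so sorting preserves the element order
  exc <- sort(unique(el$x_m)); eyc <- sort(unique(el$y_m))
  pxc <- if (bend_axis == "y") sort(unique(geom$x_m)) else exc
  pyc <- if (bend_axis == "x") sort(unique(geom$y_m)) else eyc
  ix <- nearest_idx(x, pxc); iy <- nearest_idx(x, pyc)
  inside_x <- abs(x) <= half + 1e-12
  if (bend_axis == "y") {
    inside_xb <- abs(x) <= half_proj + 1e-12; inside_yb <- inside_x
  } else {
    inside_xb <- inside_x; inside_yb <- abs(x) <= half_proj + 1e-12
  }
  cols <- which(inside_yb)
  rows <- which(inside_xb)
  u[rows, cols] <- tmat[cbind(rep(ix[rows], length(cols)),
                              rep(iy[cols], each = length(rows)))]
  aperture_field(u, dx, lam)
}

#' Focal metrics of a (possibly bent) transmitarray
#'
#' Builds the aperture field from the element phases (a bent sheet
#' contributes per-element path-length phase errors and projected element
#' positions), scans the on-axis power over `zs`, and measures the focal
#' spot in the peak plane.
#'
#' `snr_db` is the peak power in the evaluation plane over the mean power
#' outside the exclusion radius, in dB. By default the evaluation plane is
#' the configuration's own peak plane and the exclusion radius twice its
#' own FWHM; for cross-configuration comparisons (the bend study) fix both
#' via `snr_z` and `snr_mask_radius` so the statistic is measured in the
#' plane the radar targets, with a common mask.
#'
#' @param layout an [aperture_layout()]
#' @param bend_angle_deg bend angle in degrees (0 = flat)
#' @param bend_axis `"y"` or `"x"`
#' @param zs z-scan distances in metres (default 10-300 mm in 1 mm steps)
#' @param dx grid sampling in metres
#' @param phase_model `"auto"` (quantized if available, else element-wise
#'   target phases), `"quantized"`, `"element"`, or `"continuous"` (smooth
#'   hyperbolic profile, the idealized lens)
#' @param snr_z evaluation plane for the SNR (m); default the peak plane
#' @param snr_mask_radius exclusion radius for the SNR mask (m); default
#'   twice the measured FWHM
#' @return a `focus_metrics` list: `zs`, `on_axis_power` (normalized),
#'   `peak_z`, `focal_shift`, `fwhm_x`, `snr_db`, `boundary_peak` flag,
#'   `focal_profile`
#' @export
focus_metrics <- function(layout, bend_angle_deg = 0, bend_axis = "y",
                          zs = seq(0.010, 0.300, by = 0.001), dx = 0.25e-3,
                          phase_model = "auto", snr_z = NULL,
                          snr_mask_radius = NULL) {
  field <- layout_field(layout, bend_angle_deg, bend_axis, dx = dx,
                        phase_model = phase_model)
  p <- Mod(on_axis_field(field, zs))^2
  ipk <- which.max(p)
  boundary <- ipk %in% c(1L, length(zs))
  if (boundary)
    warning("on-axis peak lies on the scan boundary; extend the z range")
  off <- parabolic_offset(p, ipk)
  dz <- if (length(zs) > 1) zs[2] - zs[1] else 0
  peak_z <- zs[ipk] + off * dz
  focal <- propagate_angular_spectrum(field, peak_z)
  x <- field_axis(focal)
  c0 <- floor(nrow(focal$u) / 2) + 1L
  pw <- Mod(focal$u)^2
  prof <- pw[, c0]
  fwhm <- interp_fwhm(x, prof)
  eval_pw <- if (is.null(snr_z) || abs(snr_z - peak_z) < 1e-12) pw else
    Mod(propagate_angular_spectrum(field, snr_z)$u)^2
  mask_r <- if (is.null(snr_mask_radius)) 2 * fwhm else snr_mask_radius
  rr <- sqrt(outer(x^2, x^2, "+"))
  outside <- rr > mask_r
  snr_db <- 10 * log10(max(eval_pw) / mean(eval_pw[outside]))
  structure(list(
    zs = zs, on_axis_power = p / max(p), peak_z = peak_z,
    focal_shift = peak_z - layout$focal_length,
    fwhm_x = fwhm, snr_db = snr_db,
    bend_angle_deg = bend_angle_deg, boundary_peak = boundary,
    focal_profile = data.frame(x_m = x, power = prof / max(prof))
  ), class = "focus_metrics")
}

#' @export
print.focus_metrics <- function(x, ...) {
  cat(sprintf(
    "focus_metrics (bend %g deg): peak_z %.1f mm, shift %+.1f mm, FWHM %.1f mm, SNR %.1f dB\n",
    x$bend_angle_deg, x$peak_z * 1e3, x$focal_shift * 1e3, x$fwhm_x * 1e3,
    x$snr_db))
  invisible(x)
}

#' Bend-degradation study
#'
#' Runs [focus_metrics()] at each bend angle. Focal position and width are
#' each configuration's own; the SNR is measured for every angle in the
#' unbent design's focal plane (the plane the radar targets on the chest)
#' with a common exclusion mask of twice the unbent FWHM, so values are
#' comparable across angles — increasing bend degrades it.
#'
#' @param layout an [aperture_layout()]
#' @param angles_deg bend angles in degrees
#' @param ... passed to [focus_metrics()]
#' @return data frame with one row per angle: `angle_deg`, `peak_z_m`,
#'   `focal_shift_m`, `fwhm_x_m`, `snr_db`
#' @export
bend_study <- function(layout, angles_deg = c(0, 10, 20, 30, 40), ...) {
  flat <- focus_metrics(layout, bend_angle_deg = 0, ...)
  rows <- lapply(angles_deg, function(a) {
    m <- if (a == 0) flat else
      focus_metrics(layout, bend_angle_deg = a, snr_z = flat$peak_z,
                    snr_mask_radius = 2 * flat$fwhm_x, ...)
    data.frame(angle_deg = a, peak_z_m = m$peak_z,
               focal_shift_m = m$focal_shift, fwhm_x_m = m$fwhm_x,
               snr_db = m$snr_db)
  })
  do.call(rbind, rows)
}
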