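# Transfer-matrix reflection/transmission of layered dielectric stacks
# (seatbelt fabric / matching layer / tissue studies).

#' Layered dielectric stack
#'
#' Ordered finite layers between two semi-infinite media. Losses enter via
#' the loss tangent: \eqn{\epsilon = \epsilon_r (1 - i\tan\delta)}.
#'
#' @param layers data frame with columns `name`, `thickness_m` (> 0),
#'   `eps_r` (>= 1) and optionally `tan_delta` (default 0); may have zero
#'   rows for a bare interface
#' @param eps_in,eps_out relative permittivities of the semi-infinite
#'   incidence and exit media
#' @return a `layer_stack` object
#' @export
layer_stack <- function(layers = data.frame(), eps_in = 1, eps_out = 1) {
  if (nrow(layers) > 0) {
    need <- c("name", "thickness_m", "eps_r")
    if (!all(need %in% names(layers)))
      stop_invalid("layers need columns ", paste(need, collapse = ", "))
    if (any(layers$thickness_m <= 0))
      stop_invalid("layer thicknesses must be positive")
    if (is.null(layers$tan_delta)) layers$tan_delta <- 0
  }
  structure(list(layers = layers, eps_in = eps_in, eps_out = eps_out),
            class = "layer_stack")
}

#' The four-layer human tissue model
#'
#' 10 mm skin (eps 35), 20 mm fat (eps 9), 20 mm muscle (eps 52) and 15 mm
#' bone (eps 14), between air and an air half-space by default.
#'
#' @param eps_in,eps_out bounding media permittivities
#' @return a [layer_stack()]
#' @export
tissue_stack <- function(eps_in = 1, eps_out = 1) {
  layer_stack(data.frame(
    name = c("skin", "fat", "muscle", "bone"),
    thickness_m = c(10e-3, 20e-3, 20e-3, 15e-3),
    eps_r = c(35, 9, 52, 14)
  ), eps_in = eps_in, eps_out = eps_out)
}

#' Transfer-matrix reflection and transmission of a layer stack
#'
#' Characteristic-matrix solution for a plane wave hitting the stack at
#' `incidence` (radians from normal, default normal incidence), TE or TM
#' polarization. For lossless stacks \eqn{|r|^2 + T_{power} = 1}.
#'
#' @param stack a [layer_stack()]
#' @param frequency frequency in Hz (> 0)
#' @param incidence angle of incidence in radians
#' @param polarization `"TE"` or `"TM"` (identical at normal incidence)
#' @return list with complex `r`, `t`, and power quantities `R` (=|r|^2) and
#'   `T` (transmitted power fraction)
#' @export
tmm_reflection <- function(stack, frequency, incidence = 0,
                           polarization = c("TE", "TM")) {
  stopifnot(inherits(stack, "layer_stack"))
  polarization <- match.arg(polarization)
  if (frequency <= 0) stop_invalid("`frequency` must be positive")
  k0 <- 2 * pi * frequency / .c0
  n_in <- sqrt(as.complex(stack$eps_in))
  n_out <- sqrt(as.complex(stack$eps_out))
  sin_i <- sin(incidence)
  cos_of <- function(n) sqrt(1 - (n_in * sin_i / n)^2)
  eta <- function(n, cth) if (polarization == "TE") n * cth else n / cth
  M <- matrix(c(1 + 0i, 0i, 0i, 1 + 0i), 2, 2)
  if (nrow(stack$layers) > 0) {
    for (l in seq_len(nrow(stack$layers))) {
      eps <- stack$layers$eps_r[l] *
        complex(real = 1, imaginary = -stack$layers$tan_delta[l])
      n <- sqrt(eps)
      cth <- cos_of(n)
      delta <- k0 * n * cth * stack$layers$thickness_m[l]
      et <- eta(n, cth)
      Ml <- matrix(c(cos(delta), 1i * et * sin(delta),
                     1i * sin(delta) / et, cos(delta)), 2, 2)
      M <- M %*% Ml
    }
  }
  eta_in <- eta(n_in, cos_of(n_in))
  eta_out <- eta(n_out, cos_of(n_out))
  denom <- M[1, 1] * eta_in + M[1, 2] * eta_in * eta_out + M[2, 1] +
    M[2, 2] * eta_out
  r <- (M[1, 1] * eta_in + M[1, 2] * eta_in * eta_out - M[2, 1] -
          M[2, 2] * eta_out) / denom
  t <- 2 * eta_in / denom
  Tp <- Re(eta_out) / Re(eta_in) * Mod(t)^2
  list(r = r, t = t, R = Mod(r)^2, T = Tp)
}

#' Matching-layer sweep of reflection magnitude
#'
#' Evaluates |r| of the stack over a grid of (permittivity, thickness) values
#' for one layer (default the first — the matching layer) and reports the
#' minimizing combination. Reproduces the style of matching-layer maps used
#' to pick a seatbelt matching layer.
#'
#' @param stack_template a [layer_stack()] whose swept layer is replaced
#' @param eps_range numeric vector of permittivities to try
#' @param thickness_range numeric vector of thicknesses (m) to try
#' @param frequency frequency in Hz
#' @param layer_index index of the swept layer
#' @param incidence incidence angle in radians
#' @return list with matrix `R_mag` (rows = eps, cols = thickness), the axes,
#'   and `optimum` (eps, thickness, |r|)
#' @export
matching_sweep <- function(stack_template, eps_range, thickness_range,
                           frequency = 60e9, layer_index = 1, incidence = 0) {
  stopifnot(inherits(stack_template, "layer_stack"))
  if (length(eps_range) == 0 || length(thickness_range) == 0)
    stop_invalid("sweep ranges must be non-empty")
  if (nrow(stack_template$layers) < layer_index)
    stop_invalid("stack has no layer ", layer_index)
  R_mag <- matrix(NA_real_, length(eps_range), length(thickness_range),
                  dimnames = list(NULL, NULL))
  for (a in seq_along(eps_range)) {
    for (b in seq_along(thickness_range)) {
      st <- stack_template
      st$layers$eps_r[layer_index] <- eps_range[a]
      st$layers$thickness_m[layer_index] <- thickness_range[b]
      R_mag[a, b] <- Mod(tmm_reflection(st, frequency, incidence)$r)
    }
  }
  imin <- arrayInd(which.min(R_mag), dim(R_mag))
  list(R_mag = R_mag, eps = eps_range, thickness_m = thickness_range,
       optimum = list(eps = eps_range[imin[1]],
                      thickness_m = thickness_range[imin[2]],
                      r_mag = R_mag[imin[1], imin[2]]))
}
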