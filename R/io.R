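# File interchange: lookup CSV, layout JSON+CSV, layer-stack YAML,
# cube CSV+JSON sidecar, run manifests.

#' Read a unit-cell phase lookup from CSV
#'
#' Expected header: `L_mm, mag_dB, phase_deg`.
#'
#' @param path CSV file path
#' @param frequency frequency the table applies at, Hz
#' @return a [phase_lookup()]
#' @export
read_phase_lookup <- function(path, frequency = 60e9) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  phase_lookup(df, frequency = frequency)
}

#' Write a phase lookup to CSV
#' @param lookup a [phase_lookup()]
#' @param path destination CSV path
#' @return `path`, invisibly
#' @export
write_phase_lookup <- function(lookup, path) {
  utils::write.csv(as.data.frame(lookup)[c("L_mm", "mag_dB", "phase_deg")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Export an aperture layout
#'
#' Writes `<stem>.json` (grid metadata) and `<stem>_elements.csv`
#' (per-element `i, j, x_m, y_m, phase_rad` and, if quantized, `L_mm`,
#' `residual_rad`).
#'
#' @param layout an [aperture_layout()]
#' @param stem output path stem (no extension)
#' @return the two paths, invisibly
#' @export
write_layout <- function(layout, stem) {
  stopifnot(inherits(layout, "aperture_layout"))
  meta <- layout[c("n_side", "pitch", "focal_length", "frequency",
                   "wavelength", "side_m", "two_way")]
  json_path <- paste0(stem, ".json")
  csv_path <- paste0(stem, "_elements.csv")
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA)
  utils::write.csv(layout$elements, csv_path, row.names = FALSE)
  invisible(c(json_path, csv_path))
}

#' Read an aperture layout written by [write_layout()]
#' @param stem path stem used when writing
#' @return an [aperture_layout()] (element table restored verbatim)
#' @export
read_layout <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  el <- utils::read.csv(paste0(stem, "_elements.csv"))
  layout <- aperture_layout(n_side = meta$n_side, pitch = meta$pitch,
                            focal_length = meta$focal_length,
                            frequency = meta$frequency,
                            two_way = isTRUE(meta$two_way))
  for (col in setdiff(names(el), names(layout$elements)))
    layout$elements[[col]] <- el[[col]]
  layout
}

#' Read a layer stack from YAML
#'
#' Format: `layers: [{name, thickness_m, eps_r, tan_delta}]` plus optional
#' top-level `eps_in` / `eps_out`.
#'
#' @param path YAML file path
#' @return a [layer_stack()]
#' @export
read_layer_stack <- function(path) {
  y <- yaml::read_yaml(path)
  layers <- if (length(y$layers))
    do.call(rbind, lapply(y$layers, function(l)
      data.frame(name = l$name, thickness_m = l$thickness_m, eps_r = l$eps_r,
                 tan_delta = if (is.null(l$tan_delta)) 0 else l$tan_delta)))
  else data.frame()
  layer_stack(layers,
              eps_in = if (is.null(y$eps_in)) 1 else y$eps_in,
              eps_out = if (is.null(y$eps_out)) 1 else y$eps_out)
}

#' Write a layer stack to YAML
#' @param stack a [layer_stack()]
#' @param path destination path
#' @return `path`, invisibly
#' @export
write_layer_stack <- function(stack, path) {
  stopifnot(inherits(stack, "layer_stack"))
  y <- list(eps_in = stack$eps_in, eps_out = stack$eps_out,
            layers = lapply(seq_len(nrow(stack$layers)), function(i)
              as.list(stack$layers[i, ])))
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Write a slow-time cube to CSV + JSON sidecar
#'
#' `<stem>.csv` holds the long-format IQ samples (`frame`, `sample`,
#' `channel`, `re`, `im`); `<stem>.json` holds the radar config and ground
#' truth.
#'
#' @param cube a `slow_time_cube`
#' @param stem output path stem
#' @return the two paths, invisibly
#' @export
write_cube <- function(cube, stem) {
  stopifnot(inherits(cube, "slow_time_cube"))
  d <- dim(cube$iq)
  df <- data.frame(
    frame = rep(seq_len(d[2]) - 1L, each = d[1], times = d[3]),
    sample = rep(seq_len(d[1]) - 1L, times = d[2] * d[3]),
    channel = rep(seq_len(d[3]) - 1L, each = d[1] * d[2]),
    re = as.vector(Re(cube$iq)), im = as.vector(Im(cube$iq)))
  csv_path <- paste0(stem, ".csv")
  json_path <- paste0(stem, ".json")
  utils::write.csv(df, csv_path, row.names = FALSE)
  cfg <- unclass(cube$config)
  truth <- cube$truth
  truth$scenario <- if (!is.null(truth$scenario)) unclass(truth$scenario)
  truth$script <- if (!is.null(truth$script)) truth$script$segments
  jsonlite::write_json(list(config = cfg, t = cube$t, truth = truth),
                       json_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(csv_path, json_path))
}

#' Read a slow-time cube written by [write_cube()]
#' @param stem path stem used when writing
#' @return a `slow_time_cube`
#' @export
read_cube <- function(stem) {
  df <- utils::read.csv(paste0(stem, ".csv"))
  side <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  n <- max(df$sample) + 1L
  m <- max(df$frame) + 1L
  nch <- max(df$channel) + 1L
  iq <- array(complex(real = df$re, imaginary = df$im), dim = c(n, m, nch))
  cfg <- do.call(radar_config,
                 side$config[c("n_adc_samples", "n_chirps", "chirp_time",
                               "n_tx", "n_rx", "bandwidth", "frame_time",
                               "fov_azimuth", "center_frequency")])
  new_cube(iq, side$t, cfg, truth = side$truth)
}

#' Write a slow-time phase series to CSV (`t_s, phase_rad`)
#' @param series a `phase_series`
#' @param path destination path
#' @return `path`, invisibly
#' @export
write_phase_series <- function(series, path) {
  stopifnot(inherits(series, "phase_series"))
  utils::write.csv(data.frame(t_s = series$t, phase_rad = series$phase),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a slow-time phase series from CSV (`t_s, phase_rad`)
#' @param path CSV path
#' @return a `phase_series` (fs inferred from the timestamps)
#' @export
read_phase_series <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("t_s", "phase_rad") %in% names(df)))
    stop_invalid("expected columns t_s, phase_rad")
  fs <- 1 / stats::median(diff(df$t_s))
  structure(list(t = df$t_s, phase = df$phase_rad, phase_raw = df$phase_rad,
                 displacement_m = NULL, fs = fs, bin = NA_integer_),
            class = "phase_series")
}

#' Write a run manifest
#'
#' One JSON record per pipeline run: seed, package version, effective
#' configuration, input/output paths and timing.
#'
#' @param path destination JSON path
#' @param seed integer seed of the run
#' @param config named list describing the effective configuration
#' @param inputs,outputs character vectors of paths
#' @param timing named numeric vector of stage timings in seconds
#' @return `path`, invisibly
#' @export
write_manifest <- function(path, seed, config = list(), inputs = character(),
                           outputs = character(), timing = numeric()) {
  jsonlite::write_json(list(
    package = "mmvital",
    version = as.character(utils::packageVersion("mmvital")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed, config = config, inputs = inputs, outputs = outputs,
    timing_s = as.list(timing)
  ), path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
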