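#' Write a recording to disk
#'
#' Signals are stored as a single-column CSV of full-precision voltages with
#' a JSON metadata sidecar (`<path>.json`) carrying the sampling rate,
#' channel role, depth, and site id.
#'
#' @param rec An `mer_recording`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_signal <- function(rec, path) {
  stopifnot(inherits(rec, "mer_recording"))
  utils::write.csv(
    data.frame(voltage = format(rec$samples, digits = 17, trim = TRUE, scientific = TRUE)),
    path, row.names = FALSE, quote = FALSE
  )
  meta <- list(rate = rec$rate, channel_role = rec$channel_role,
               site_id = rec$site_id)
  if (length(rec$depth_mm) == 1 && !is.na(rec$depth_mm)) meta$depth_mm <- rec$depth_mm
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a recording from disk
#'
#' Reads a CSV written by [write_signal()]. A missing metadata sidecar is
#' tolerated (with a warning) if `rate` is given; depth is then unknown.
#'
#' @param path CSV path.
#' @param rate Fallback sampling rate when the sidecar is missing.
#' @return An `mer_recording`.
#' @export
read_signal <- function(path, rate = NULL) {
  samples <- utils::read.csv(path)$voltage
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    recording(samples, rate = meta$rate,
              channel_role = meta$channel_role %||% "MER",
              depth_mm = meta$depth_mm %||% NA_real_,
              site_id = meta$site_id %||% basename(path))
  } else {
    if (is.null(rate)) abort("no metadata sidecar found and no `rate` given.")
    warn("metadata sidecar missing: depth and site id unknown.")
    recording(samples, rate = rate)
  }
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return For `read_run_config`, a named list merged over the defaults of
#'   [run_config()].
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' @rdname read_run_config
#' @param config A [run_config()] list.
#' @export
write_run_config <- function(config, path) {
  cfg <- config
  cfg$templates <- NULL  # templates are regenerated from the seed
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Default pipeline configuration
#'
#' All defaults follow standard microelectrode practice: 300 Hz - 9 kHz
#' spike band, -4 robust-SD detection threshold, 2 ms extraction window
#' split 0.5/1.5 ms around the alignment extremum, 2 ms refractory ISI
#' threshold with a 2% QC limit, a \[-0.1, 0.9\] s cardiac window, and a
#' 200-300 Hz LFP comparison band.
#'
#' @param ... Overrides for any default field.
#' @return A named list of pipeline parameters.
#' @export
run_config <- function(...) {
  defaults <- list(
    input = NULL,            # signal CSV path; NULL = simulate
    ekg_input = NULL,
    output_dir = "crpspike-out",
    filter_low = 300, filter_high = 9000,
    threshold_multiplier = -4,
    n_units = 2,
    fit_tolerance = 0.02,
    isi_threshold = 0.002,
    refractory_qc_pct = 2,
    serial = TRUE,
    cardiac = FALSE,
    cardiac_window = c(-0.1, 0.9),
    cardiac_bins = 50,
    band = c(200, 300),
    k_override = NULL,
    sim = list(duration = 10, n_shapes = 2, firing_rate = c(20, 12),
               snr = 10),
    seed = 1
  )
  utils::modifyList(defaults, list(...))
}
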