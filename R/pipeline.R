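#' Run the full parameterization pipeline on one recording
#'
#' Orchestrates the stages end to end: ingest (or simulate) a recording,
#' band-pass filter, detect and align waveforms, seed templates from
#' principal components, template-match sort, CRP-parameterize each unit,
#' optionally resolve overlaps by serial subtraction/re-sorting, isolate the
#' residual LFP, and compare raw vs spike-removed band power. All artifacts
#' are written as CSV/JSON into `config$output_dir`, together with a run
#' manifest recording every parameter and seed, so any output can be
#' regenerated from the manifest alone.
#'
#' A requested cardiac stage with no EKG channel is skipped with a warning
#' (never an error). Any stage failure is recorded in the manifest as
#' partial completion.
#'
#' @param config A [run_config()].
#'
#' @return Invisibly, a list with the main in-memory results (`rec`,
#'   `filtered`, `sort`, `fit`, `lfp`, `band_test`, `cardiac`,
#'   `manifest_path`).
#' @export
run_pipeline <- function(config = run_config()) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("crpspike")),
                   parameters = config[setdiff(names(config), "templates")],
                   stages = list(), completed = FALSE)
  out <- list()
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null", force = TRUE)
  }
  on.exit(write_manifest())

  # --- ingest or simulate ---------------------------------------------------
  ekg <- NULL
  truth <- NULL
  if (is.null(config$input)) {
    sim <- config$sim
    templates <- make_templates(sim$n_shapes, seed = config$seed)
    cc <- if (isTRUE(config$cardiac)) list(A = 50 * sim$snr, n = 2, m = 10) else NULL
    scfg <- sim_config(duration = sim$duration,
                       templates = templates,
                       firing_rate = sim$firing_rate,
                       amp_mean = sim$snr,
                       cardiac = cc,
                       seed = config$seed)
    if (isTRUE(config$cardiac)) {
      ses <- simulate_cardiac_session(scfg)
      rec <- ses$mer
      ekg <- ses$ekg
      truth <- ses$truth
    } else {
      simr <- simulate_recording(scfg)
      rec <- simr$rec
      truth <- simr$truth
    }
    utils::write.csv(truth, file.path(config$output_dir, "ground_truth.csv"),
                     row.names = FALSE)
    manifest$stages$ingest <- "simulated"
  } else {
    rec <- read_signal(config$input)
    if (!is.null(config$ekg_input)) ekg <- read_signal(config$ekg_input)
    manifest$stages$ingest <- config$input
  }

  # --- filter / detect / sort ----------------------------------------------
  filtered <- bandpass_filter(rec, config$filter_low, config$filter_high)
  threshold <- estimate_threshold(filtered, config$threshold_multiplier)
  det <- detect_waveforms(filtered, threshold)
  manifest$stages$detect <- list(threshold = threshold, n_events = nrow(det$events))
  if (nrow(det$events) < config$n_units) {
    warn("too few detected events to sort; stopping after detection.")
    manifest$stages$sort <- "skipped"
    out <- list(rec = rec, filtered = filtered, detected = det)
    return(invisible(out))
  }
  tpl <- pca_template_selection(det$waveforms, config$n_units, seed = config$seed)
  srt <- template_match_sort(det, tpl$templates, fit_tolerance = config$fit_tolerance,
                             refine = 1, rate = rec$rate,
                             isi_threshold = config$isi_threshold)
  manifest$stages$sort <- list(n_assigned = sum(!is.na(srt$events$unit_id)),
                               qc_flags = srt$qc_flags)

  # --- serial overlap resolution -------------------------------------------
  n_units_found <- length(unique(stats::na.omit(srt$events$unit_id)))
  if (isTRUE(config$serial) && n_units_found >= 2) {
    srt <- serial_sort(filtered, srt, threshold)
    manifest$stages$serial <- list(n_recovered = srt$n_recovered,
                                   unresolved_overlap_estimate = srt$unresolved_overlap_estimate)
  } else {
    manifest$stages$serial <- "skipped"
  }

  # --- CRP parameterization -------------------------------------------------
  fit <- crp_parameterize(srt)
  events_out <- dplyr::mutate(fit$events, site_id = rec$site_id, .before = 1)
  utils::write.csv(events_out, file.path(config$output_dir, "events.csv"),
                   row.names = FALSE)
  unit_summary <- glance.crp_fit(fit, duration_s = rec_duration(rec))
  jsonlite::write_json(unit_summary, file.path(config$output_dir, "units.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  manifest$stages$parameterize <- list(n_units = length(fit$units))

  # --- residual LFP + spectra ----------------------------------------------
  lfp <- residual_lfp(rec, fit)
  write_signal(lfp, file.path(config$output_dir, "lfp.csv"))
  band_test <- NULL
  if (rec_duration(rec) >= 2) {
    p_raw <- psd(rec)
    p_res <- psd(lfp)
    utils::write.csv(
      data.frame(freq_hz = p_raw$freq_hz, power_raw = p_raw$power,
                 power_residual = p_res$power),
      file.path(config$output_dir, "psd.csv"), row.names = FALSE
    )
    manifest$stages$spectral <- list(
      raw_band_power = band_power(p_raw, config$band[1], config$band[2]),
      residual_band_power = band_power(p_res, config$band[1], config$band[2])
    )
  }

  # --- similarity / clustering (within-site units) --------------------------
  clusters <- NULL
  if (length(fit$units) >= 2) {
    clusters <- cluster_shapes(unname(fit$units), k = config$k_override)
    utils::write.csv(as.data.frame(clusters$similarity),
                     file.path(config$output_dir, "similarity.csv"))
    utils::write.csv(clusters$labels, file.path(config$output_dir, "cluster_labels.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(merge = unclass(clusters$tree$merge), height = clusters$tree$height, k = clusters$k),
      file.path(config$output_dir, "dendrogram.json"), digits = NA
    )
    manifest$stages$cluster <- list(k = clusters$k, sizes = clusters$sizes)
  } else {
    manifest$stages$cluster <- "skipped"
  }

  # --- cardiac modulation ---------------------------------------------------
  cardiac <- NULL
  if (isTRUE(config$cardiac)) {
    if (is.null(ekg)) {
      warn("cardiac stage requested but no EKG channel present; skipping.")
      manifest$stages$cardiac <- "skipped (no EKG)"
    } else {
      r_times <- detect_r_waves(ekg)
      cardiac <- purrr::map(fit$units, function(un) {
        sel <- fit$events$unit_id == un$unit_id & !is.na(fit$events$unit_id)
        prof <- cardiac_profile(fit$events$time_s[sel], fit$events$alpha_scaled[sel],
                                r_times, window = config$cardiac_window,
                                n_bins = config$cardiac_bins)
        fit_impulse_response(prof)
      })
      cj <- purrr::imap(cardiac, function(cf, id) {
        list(unit_id = id, A = cf$A, n = cf$n, m = cf$m, r_squared = cf$r_squared,
             converged = cf$converged)
      })
      jsonlite::write_json(unname(cj), file.path(config$output_dir, "cardiac.json"),
                           auto_unbox = TRUE, digits = NA)
      manifest$stages$cardiac <- list(n_r_waves = length(r_times))
    }
  }

  manifest$completed <- TRUE
  out <- list(rec = rec, filtered = filtered, sort = srt, fit = fit, lfp = lfp,
              clusters = clusters, cardiac = cardiac, truth = truth,
              manifest_path = file.path(config$output_dir, "manifest.json"))
  invisible(out)
}
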