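#' Band-pass filter a recording for spike analysis
#'
#' Zero-phase (forward-backward) 4th-order Butterworth band-pass, 300 Hz to
#' 9 kHz by default — the standard spike band for microelectrode recordings.
#' Zero-phase filtering preserves waveform shape, which matters for all
#' downstream shape analysis.
#'
#' @param rec An [recording()].
#' @param low,high Band edges in Hz. Must satisfy `0 < low < high < rate/2`.
#' @param order Butterworth order (applied twice by `filtfilt`).
#'
#' @return A filtered `mer_recording` of the same length.
#' @export
bandpass_filter <- function(rec, low = 300, high = 9000, order = 4) {
  stopifnot(inherits(rec, "mer_recording"))
  nyq <- rec$rate / 2
  if (!(low > 0 && low < high && high < nyq)) {
    abort("band edges must satisfy 0 < low < high < rate/2.")
  }
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  out <- rec
  out$samples <- as.numeric(signal::filtfilt(bf, rec$samples))
  out
}

#' Robust spike-detection threshold
#'
#' Threshold = `multiplier` times a robust noise scale, the median absolute
#' value divided by 0.6745 (the MAD-type estimate of the noise SD, insensitive
#' to the spikes themselves). The default multiplier of -4 detects
#' negative-going spikes four noise SDs below zero.
#'
#' @param filtered A band-passed `mer_recording`.
#' @param multiplier Threshold in units of the robust noise SD (default -4).
#'
#' @return A single voltage threshold (negative for the default multiplier).
#' @export
estimate_threshold <- function(filtered, multiplier = -4.0) {
  stopifnot(inherits(filtered, "mer_recording"))
  scale <- stats::median(abs(filtered$samples)) / 0.6745
  if (scale == 0) abort("trace has zero robust scale (all-zero input?).")
  multiplier * scale
}

#' Detect and align spike waveforms by threshold crossing
#'
#' Scans the filtered trace for downward crossings of a (negative) threshold.
#' Each crossing is aligned to the largest-magnitude sample within 0.6 ms
#' after the crossing, and a 2 ms waveform (0.5 ms before to 1.5 ms after
#' the alignment extremum) is extracted. Crossings closer than 0.5 ms are
#' collapsed to the one with the larger extremum (one spike, one event), and
#' events whose extraction frame would leave the trace are discarded.
#'
#' For positive-going detection pass a positive threshold; the trace is
#' sign-flipped internally.
#'
#' @param filtered A band-passed `mer_recording`.
#' @param threshold Voltage threshold (negative for downward detection).
#'
#' @return A list with `events`, a tibble (`event_id`, `time` alignment
#'   sample index, `time_s`), and `waveforms`, a matrix with one 2 ms
#'   waveform per row (alignment extremum at column `frame_geometry(rate)$i0`).
#' @export
detect_waveforms <- function(filtered, threshold) {
  stopifnot(inherits(filtered, "mer_recording"))
  x <- filtered$samples
  flip <- threshold > 0
  if (flip) {
    x <- -x
    threshold <- -threshold
  }
  rate <- filtered$rate
  geom <- frame_geometry(rate)
  n <- length(x)

  below <- x < threshold
  crossings <- which(!below[-n] & below[-1]) + 1L
  search <- round(0.0006 * rate)
  min_sep <- round(0.0005 * rate)

  if (length(crossings) == 0) {
    return(list(events = tibble::tibble(event_id = integer(), time = integer(),
                                        time_s = numeric()),
                waveforms = matrix(numeric(0), 0, geom$len)))
  }

  # align each crossing to the largest-magnitude sample within 0.6 ms
  align <- integer(length(crossings))
  peak <- numeric(length(crossings))
  for (j in seq_along(crossings)) {
    idx <- crossings[j]:min(n, crossings[j] + search)
    k <- idx[which.max(abs(x[idx]))]
    align[j] <- k
    peak[j] <- abs(x[k])
  }

  # collapse crossings closer than 0.5 ms, keeping the larger extremum
  keep <- rep(TRUE, length(crossings))
  j <- 1L
  while (j < length(crossings)) {
    nxt <- j + 1L
    while (nxt <= length(crossings) && crossings[nxt] - crossings[j] < min_sep) {
      if (peak[nxt] > peak[j]) keep[j] <- FALSE else keep[nxt] <- FALSE
      if (peak[nxt] > peak[j]) j <- nxt
      nxt <- nxt + 1L
    }
    j <- nxt
  }
  align <- align[keep]
  peak <- peak[keep]
  # duplicate alignment points (distinct crossings, same extremum) collapse too
  dup <- !duplicated(align)
  align <- align[dup]

  # drop events whose 2 ms frame leaves the trace
  ok <- (align - (geom$i0 - 1L) >= 1L) & (align + (geom$len - geom$i0) <= n)
  align <- align[ok]

  wf <- matrix(0, length(align), geom$len)
  sig <- if (flip) -filtered$samples else filtered$samples
  for (j in seq_along(align)) {
    wf[j, ] <- sig[(align[j] - geom$i0 + 1L):(align[j] + geom$len - geom$i0)]
  }

  list(
    events = tibble::tibble(event_id = seq_along(align), time = align,
                            time_s = (align - 1L) / rate),
    waveforms = wf
  )
}

#' Seed sorting templates from principal components
#'
#' Projects detected waveforms onto their first two principal components and
#' partitions the 2-D score cloud with k-means; the per-group mean waveforms
#' become the initial sorting templates.
#'
#' @param waveforms Matrix of extracted waveforms (one per row).
#' @param n_units Number of units/templates to seed.
#' @param seed Integer seed for the k-means restarts.
#'
#' @return A list with `templates` (matrix, one per row), `labels`
#'   (initial k-means labels), and `degenerate` (TRUE when the score cloud
#'   carries no variance, e.g. identical duplicated waveforms).
#' @export
pca_template_selection <- function(waveforms, n_units, seed = 1) {
  if (!is.matrix(waveforms)) waveforms <- matrix(waveforms, nrow = 1)
  if (n_units > nrow(waveforms)) abort("`n_units` exceeds the number of waveforms.")
  if (n_units < 1) abort("`n_units` must be >= 1.")
  if (n_units == 1) {
    return(list(templates = matrix(colMeans(waveforms), 1),
                labels = rep(1L, nrow(waveforms)), degenerate = FALSE))
  }
  pc <- prcomp(waveforms, center = TRUE, rank. = 2)
  scores <- pc$x
  if (ncol(scores) < 2) scores <- cbind(scores, 0)
  degenerate <- all(abs(scores) < 1e-12) || nrow(unique(round(scores, 10))) < n_units
  if (degenerate) {
    warn("degenerate waveform cloud: fewer distinct score points than units.")
    labels <- rep(1L, nrow(waveforms))
    templates <- matrix(colMeans(waveforms), 1)[rep(1, n_units), , drop = FALSE]
    return(list(templates = templates, labels = labels, degenerate = TRUE))
  }
  km <- with_seed(seed, kmeans(scores, centers = n_units, nstart = 10))
  templates <- matrix(0, n_units, ncol(waveforms))
  for (g in seq_len(n_units)) {
    templates[g, ] <- colMeans(waveforms[km$cluster == g, , drop = FALSE])
  }
  list(templates = templates, labels = km$cluster, degenerate = FALSE)
}

#' Convert a Plexon-style fit tolerance to the normalized scale
#'
#' The vendor convention expresses the tolerance in units of 0.01% of the
#' maximum A/D value; this helper maps it to the package's normalized scale
#' (per-sample RMS deviation as a fraction of full scale, squared).
#'
#' @param tol Vendor tolerance value.
#' @param bits A/D resolution in bits.
#' @return Normalized mean-squared-error tolerance.
#' @export
plexon_fit_tolerance <- function(tol, bits = 16) {
  (tol * 1e-4)^2
}

#' Sort detected events by template matching
#'
#' For each waveform: (1) compute the sum-of-squares difference to every
#' template, (2) find the minimum, (3) assign the event to that template's
#' unit iff the minimum (normalized) difference is at or below the fit
#' tolerance, else leave it unassigned. Ties in the minimum go to the
#' lower-indexed template and are logged. Templates can optionally be
#' re-estimated from the assignments (refinement passes).
#'
#' The fit tolerance is expressed as mean per-sample squared error divided by
#' the squared full-scale range of the trace (its maximum absolute voltage),
#' making it independent of amplifier units; see [plexon_fit_tolerance()] for
#' the vendor-unit conversion.
#'
#' @param detected Output of [detect_waveforms()] (events + waveforms).
#' @param templates Template matrix, one per row.
#' @param fit_tolerance Normalized tolerance (default 0.02).
#' @param full_scale Full-scale voltage for normalization; defaults to the
#'   largest absolute waveform sample.
#' @param refine Number of template re-estimation passes (default 1).
#' @param rate Sampling rate in Hz (carried into the result for time-based
#'   summaries).
#' @param isi_threshold Refractory ISI threshold in seconds for the QC table.
#'
#' @return A `sort_result` list: `events` tibble (`event_id`, `time`,
#'   `time_s`, `unit_id` with `NA` = unassigned, `ss` the normalized
#'   minimum sum-of-squares), `waveforms`, `templates` (possibly refined),
#'   `fit_tolerance`, `full_scale`, `refractory` tibble per unit, `qc_flags`,
#'   `ties` count, and `rate`.
#' @export
template_match_sort <- function(detected, templates, fit_tolerance = 0.02,
                                full_scale = NULL, refine = 1, rate = NULL,
                                isi_threshold = 0.002) {
  wf <- detected$waveforms
  events <- detected$events
  if (!is.matrix(templates)) templates <- matrix(templates, nrow = 1)
  if (nrow(templates) < 1) abort("at least one template required.")
  if (fit_tolerance <= 0) abort("`fit_tolerance` must be positive.")
  if (nrow(events) == 0) {
    return(new_sort_result(events = dplyr::mutate(events, unit_id = integer(), ss = numeric()),
                           waveforms = wf, templates = templates,
                           fit_tolerance = fit_tolerance, full_scale = full_scale %||% 1,
                           ties = 0L, rate = rate, isi_threshold = isi_threshold))
  }
  if (is.null(full_scale)) full_scale <- max(abs(wf))
  L <- ncol(wf)

  assign_pass <- function(templates) {
    # normalized mean squared error of each waveform to each template
    ss <- matrix(0, nrow(wf), nrow(templates))
    for (g in seq_len(nrow(templates))) {
      d <- sweep(wf, 2, templates[g, ])
      ss[, g] <- rowMeans(d^2) / full_scale^2
    }
    min_ss <- apply(ss, 1, min)
    best <- apply(ss, 1, which.min)   # ties -> lowest index
    n_tie <- sum(apply(ss, 1, function(r) sum(r == min(r)) > 1))
    unit <- ifelse(min_ss <= fit_tolerance, best, NA_integer_)
    list(unit = as.integer(unit), ss = min_ss, ties = n_tie)
  }

  res <- assign_pass(templates)
  pass <- 0
  while (pass < refine) {
    for (g in seq_len(nrow(templates))) {
      sel <- which(res$unit == g)
      if (length(sel) > 0) templates[g, ] <- colMeans(wf[sel, , drop = FALSE])
    }
    res <- assign_pass(templates)
    pass <- pass + 1
  }
  if (res$ties > 0) inform(sprintf("%d tie(s) in template matching assigned to the lower-indexed template.", res$ties))

  events$unit_id <- res$unit
  events$ss <- res$ss
  new_sort_result(events = events, waveforms = wf, templates = templates,
                  fit_tolerance = fit_tolerance, full_scale = full_scale,
                  ties = res$ties, rate = rate, isi_threshold = isi_threshold)
}

new_sort_result <- function(events, waveforms, templates, fit_tolerance,
                            full_scale, ties, rate, isi_threshold = 0.002) {
  refr <- refractory_table(events, rate, isi_threshold)
  structure(
    list(events = events, waveforms = waveforms, templates = templates,
         fit_tolerance = fit_tolerance, full_scale = full_scale,
         refractory = refr, ties = ties, rate = rate,
         qc_flags = refr$unit_id[refr$violation_pct > 2]),
    class = "sort_result"
  )
}

refractory_table <- function(events, rate, isi_threshold = 0.002) {
  assigned <- dplyr::filter(events, !is.na(.data$unit_id))
  if (nrow(assigned) == 0 || is.null(rate)) {
    return(tibble::tibble(unit_id = integer(), n_spikes = integer(),
                          violation_pct = numeric(), qc_fail = logical()))
  }
  assigned |>
    dplyr::group_by(.data$unit_id) |>
    dplyr::summarise(
      n_spikes = dplyr::n(),
      violation_pct = refractory_violation_rate(sort(.data$time_s), isi_threshold),
      .groups = "drop"
    ) |>
    dplyr::mutate(qc_fail = .data$violation_pct > 2)
}

#' Refractory-period violation rate
#'
#' Percentage of spikes in a unit whose inter-spike interval to the previous
#' spike is below the physiological minimum (2 ms default). Units with fewer
#' than 2 spikes return 0. Rates above 2% flag the unit for re-sorting.
#'
#' @param spike_times Sorted ascending spike times in seconds.
#' @param isi_threshold Minimum physiological ISI in seconds.
#'
#' @return Violation rate in percent (0-100).
#' @export
refractory_violation_rate <- function(spike_times, isi_threshold = 0.002) {
  if (is.unsorted(spike_times)) abort("`spike_times` must be sorted ascending.")
  n <- length(spike_times)
  if (n < 2) return(0)
  100 * sum(diff(spike_times) < isi_threshold) / n
}

#' @export
print.sort_result <- function(x, ...) {
  n_assigned <- sum(!is.na(x$events$unit_id))
  cat(sprintf("<sort_result> %d events (%d assigned) across %d template(s)\n",
              nrow(x$events), n_assigned, nrow(x$templates)))
  if (nrow(x$refractory) > 0) print(x$refractory)
  invisible(x)
}

#' @method tidy sort_result
#' @export
tidy.sort_result <- function(x, ...) x$events

#' @method glance sort_result
#' @export
glance.sort_result <- function(x, ...) {
  tibble::tibble(
    n_events = nrow(x$events),
    n_assigned = sum(!is.na(x$events$unit_id)),
    n_units = nrow(x$templates),
    fit_tolerance = x$fit_tolerance,
    max_refractory_pct = if (nrow(x$refractory)) max(x$refractory$violation_pct) else NA_real_,
    n_qc_flagged = length(x$qc_flags)
  )
}

#' Plot sorted unit templates and example waveforms
#'
#' @param object A `sort_result`.
#' @param max_waveforms Waveforms drawn per unit (thin grey lines).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sort_result
#' @export
autoplot.sort_result <- function(object, max_waveforms = 50, ...) {
  rate <- object$rate %||% 44000
  geom <- frame_geometry(rate)
  tms <- (seq_len(geom$len) - geom$i0) / rate * 1000
  tpl <- purrr::map_dfr(seq_len(nrow(object$templates)), function(g) {
    tibble::tibble(unit_id = g, t_ms = tms, voltage = object$templates[g, ])
  })
  wfs <- object$events |>
    dplyr::filter(!is.na(.data$unit_id)) |>
    dplyr::group_by(.data$unit_id) |>
    dplyr::slice_head(n = max_waveforms) |>
    dplyr::ungroup()
  wf_df <- purrr::map_dfr(seq_len(nrow(wfs)), function(j) {
    tibble::tibble(unit_id = wfs$unit_id[j], event_id = wfs$event_id[j],
                   t_ms = tms, voltage = object$waveforms[wfs$event_id[j], ])
  })
  p <- ggplot2::ggplot(tpl, ggplot2::aes(.data$t_ms, .data$voltage))
  if (nrow(wf_df) > 0) {
    p <- p + ggplot2::geom_line(
      data = wf_df, ggplot2::aes(group = .data$event_id),
      colour = "grey70", linewidth = 0.2, alpha = 0.5)
  }
  p +
    ggplot2::geom_line(colour = "firebrick", linewidth = 0.8) +
    ggplot2::facet_wrap(~unit_id, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Time from alignment extremum (ms)", y = "Voltage") +
    ggplot2::theme_minimal()
}
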