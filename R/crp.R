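#' Projection profile of a unit's waveforms over candidate spike windows
#'
#' The significant spike window of a sorted unit is discovered empirically by
#' projecting each spike onto the unit's mean waveform with a semi-normalized
#' dot product, while sweeping the window length. Forward profiles anchor at
#' the alignment extremum (time 0) and grow toward the end of the 2 ms frame;
#' reverse profiles anchor at a fixed end sample and grow backward toward the
#' start of the frame.
#'
#' For window `w`, spike `k` contributes
#' `p_k(w) = <v_k[w], m_(-k)[w]> / ||v_k[w]||`, where `m_(-k)` is the
#' leave-one-out mean waveform; the profile is the mean of `p_k` over spikes.
#' Normalizing by the projecting spike's own window norm makes the profile
#' peak at the true support edge: beyond it the numerator stops growing while
#' noise keeps inflating the denominator. Alternative targets (`"mean"`:
#' plain mean waveform; `"tstat"`: mean/SE of the per-spike projections) are
#' available as a robustness check.
#'
#' @param waveforms Matrix of one unit's extracted waveforms (one per row,
#'   2 ms frame).
#' @param rate Sampling rate in Hz.
#' @param direction `"forward"` or `"reverse"`.
#' @param anchor For `"reverse"`, the end column index of the window
#'   (typically the discovered spike end); ignored for `"forward"`.
#' @param target Profile estimator (see Details).
#' @param min_duration Minimum window length in samples.
#'
#' @return A tibble with one row per candidate window: `direction`,
#'   `start_idx`, `end_idx`, `duration` (samples), `edge_t_s` (the moving
#'   window edge in seconds relative to the extremum), `magnitude`.
#' @export
projection_profile <- function(waveforms, rate, direction = c("forward", "reverse"),
                               anchor = NULL, target = c("loo", "mean", "tstat"),
                               min_duration = 3) {
  direction <- match.arg(direction)
  target <- match.arg(target)
  if (!is.matrix(waveforms) || nrow(waveforms) < 5) {
    abort("at least 5 waveforms are required to profile a unit.", class = "crpspike_insufficient_data")
  }
  geom <- frame_geometry(rate)
  K <- nrow(waveforms)
  L <- ncol(waveforms)
  i0 <- geom$i0
  M <- colMeans(waveforms)

  if (direction == "forward") {
    cols <- i0:L
  } else {
    if (is.null(anchor)) anchor <- L
    # start samples strictly before the extremum so the window contains it
    cols <- rev(seq_len(i0 - 1L))
    end_idx <- anchor
  }

  # cumulative cross- and self-products along the sweep direction
  if (direction == "forward") {
    P <- sweep(waveforms[, cols, drop = FALSE], 2, M[cols], `*`)
    Q <- waveforms[, cols, drop = FALSE]^2
    cp <- t(apply(P, 1, cumsum))
    cq <- t(apply(Q, 1, cumsum))
    start_idx <- rep(i0, length(cols))
    end_idx_v <- cols
  } else {
    # fixed tail [s, anchor]; accumulate from anchor backwards
    span <- seq_len(end_idx)
    P <- sweep(waveforms[, span, drop = FALSE], 2, M[span], `*`)
    Q <- waveforms[, span, drop = FALSE]^2
    cp_full <- t(apply(P[, rev(span), drop = FALSE], 1, cumsum))
    cq_full <- t(apply(Q[, rev(span), drop = FALSE], 1, cumsum))
    # window [s, anchor] corresponds to the (anchor - s + 1)-th cumulant
    pos <- end_idx - cols + 1L
    cp <- cp_full[, pos, drop = FALSE]
    cq <- cq_full[, pos, drop = FALSE]
    start_idx <- cols
    end_idx_v <- rep(end_idx, length(cols))
  }

  num <- switch(target,
    loo = (K * cp - cq) / (K - 1),
    mean = cp,
    tstat = cp
  )
  den <- sqrt(pmax(cq, 0))
  p <- ifelse(den > 0, num / den, 0)
  mag <- colMeans(p)
  if (target == "tstat") {
    se <- apply(p, 2, sd) / sqrt(K)
    mag <- ifelse(se > 0, mag / se, 0)
  }

  edge <- if (direction == "forward") (end_idx_v - i0) / rate else (start_idx - i0) / rate
  out <- tibble::tibble(
    direction = direction,
    start_idx = as.integer(start_idx),
    end_idx = as.integer(end_idx_v),
    duration = as.integer(end_idx_v - start_idx + 1L),
    edge_t_s = edge,
    magnitude = as.numeric(mag)
  )
  dplyr::filter(out, .data$duration >= min_duration)
}

# earliest duration whose magnitude is within rel tol of the max (plateau tie-break)
profile_argmax <- function(profile, tol = 1e-9) {
  if (!all(is.finite(profile$magnitude))) {
    abort("non-finite projection profile.", class = "crpspike_numerical_failure")
  }
  m <- max(profile$magnitude)
  thr <- m - abs(m) * tol
  cand <- profile[profile$magnitude >= thr, ]
  cand[which.min(cand$duration), ]
}

#' Discover the significant spike window of a unit
#'
#' Two-pass window discovery: the forward projection profile (anchored at the
#' alignment extremum, time 0) peaks at the spike end time `tau_R`; a reverse
#' profile anchored at `tau_R` then peaks at the spike start time `tau_i`.
#' Outside `[tau_i, tau_R]` the waveform is statistically unreliable and is
#' excluded from the canonical shape.
#'
#' With fewer than `min_spikes` waveforms the window falls back to the full
#' 2 ms extraction frame and is flagged.
#'
#' @param waveforms Matrix of one unit's waveforms (one per row).
#' @param rate Sampling rate in Hz.
#' @param target Profile estimator passed to [projection_profile()].
#' @param min_spikes Minimum spikes for discovery (default 5).
#'
#' @return A list: `tau_i`, `tau_R` (seconds relative to the extremum,
#'   `tau_i < 0 <= tau_R`), `idx_start`, `idx_end` (frame column indices),
#'   `flagged` (fallback used), and the two profiles.
#' @export
discover_spike_window <- function(waveforms, rate, target = "loo", min_spikes = 5) {
  geom <- frame_geometry(rate)
  if (!is.matrix(waveforms) || nrow(waveforms) < min_spikes) {
    warn("fewer than `min_spikes` waveforms: spike window falls back to the full extraction frame.")
    return(list(tau_i = -(geom$i0 - 1) / rate, tau_R = (geom$len - geom$i0) / rate,
                idx_start = 1L, idx_end = geom$len, flagged = TRUE,
                forward = NULL, reverse = NULL))
  }
  fwd <- projection_profile(waveforms, rate, "forward", target = target)
  pk_f <- profile_argmax(fwd)
  idx_end <- pk_f$end_idx
  rev_p <- projection_profile(waveforms, rate, "reverse", anchor = idx_end,
                              target = target, min_duration = 1)
  pk_r <- profile_argmax(rev_p)
  idx_start <- pk_r$start_idx
  # enforce a minimally informative window (>= 4 samples)
  if (idx_end - idx_start + 1L < 4L) idx_end <- min(geom$len, idx_start + 3L)
  list(
    tau_i = (idx_start - geom$i0) / rate,
    tau_R = (idx_end - geom$i0) / rate,
    idx_start = as.integer(idx_start), idx_end = as.integer(idx_end),
    flagged = FALSE, forward = fwd, reverse = rev_p
  )
}

#' Construct a parameterized spike unit
#'
#' Bundles a sorted unit's mean waveform, its empirically discovered spike
#' window `[tau_i, tau_R]`, and the canonical shape `C(t)` — the mean
#' waveform over the window scaled to unit L2 norm, so that per-spike
#' projections onto `C` are plain inner products on the voltage scale.
#'
#' @param unit_id Unit identifier.
#' @param waveforms Matrix of the unit's waveforms (one per row, 2 ms frame).
#' @param spike_times Spike times in seconds (alignment extrema).
#' @param rate Sampling rate in Hz.
#' @param window Optional precomputed window (output of
#'   [discover_spike_window()]); discovered from the waveforms when `NULL`.
#'
#' @return A `spike_unit` object: `unit_id`, `mean_waveform` (full frame),
#'   `canonical_shape` (unit-norm, length `n_window`), `tau_i`, `tau_R`,
#'   `idx_start`, `idx_end`, `n_window`, `spike_times`, `rate`, `flagged`.
#' @export
spike_unit <- function(unit_id, waveforms, spike_times = numeric(0), rate = 44000,
                       window = NULL) {
  if (!is.matrix(waveforms)) waveforms <- matrix(waveforms, nrow = 1)
  if (is.null(window)) window <- discover_spike_window(waveforms, rate)
  mw <- colMeans(waveforms)
  seg <- mw[window$idx_start:window$idx_end]
  nrm <- sqrt(sum(seg^2))
  if (nrm == 0) abort("unit mean waveform is zero over the spike window.")
  structure(
    list(unit_id = unit_id, mean_waveform = mw, canonical_shape = seg / nrm,
         tau_i = window$tau_i, tau_R = window$tau_R,
         idx_start = window$idx_start, idx_end = window$idx_end,
         n_window = window$idx_end - window$idx_start + 1L,
         spike_times = spike_times, rate = rate,
         flagged = isTRUE(window$flagged)),
    class = "spike_unit"
  )
}

#' @export
print.spike_unit <- function(x, ...) {
  cat(sprintf("<spike_unit %s> window [%.3f, %.3f] ms (%d samples), %d spikes\n",
              x$unit_id, x$tau_i * 1000, x$tau_R * 1000, x$n_window,
              length(x$spike_times)))
  invisible(x)
}

#' Per-spike projection weights and quality metrics
#'
#' Each spike `v_k` of a unit is represented as `alpha_k * C(t)` over the
#' unit's spike window: `alpha_k = <v_k[window], C>` (a voltage-scale weight,
#' since `||C|| = 1`) and `alpha'_k = alpha_k / sqrt(T)` with `T` the number
#' of window samples — for a spike exactly proportional to `C`, `alpha'`
#' equals the spike's RMS voltage deflection. Residual-based quality metrics
#' follow from `Vo = v_k[window] - alpha_k * C`:
#' LFP energy `Vo'Vo`; signal-to-noise `alpha_k / (Vo'Vo)` as conventionally
#' printed (a scale-consistent variant `alpha'_k / rms(Vo)` is also
#' reported); explained variance `1 - Vo'Vo / v'v`.
#'
#' @param waveforms Matrix of the unit's waveforms (one per row).
#' @param unit A [spike_unit()].
#'
#' @return A tibble with one row per spike: `alpha`, `alpha_scaled`,
#'   `lfp_energy`, `snr`, `snr_rms`, `explained_variance`. A perfect fit
#'   (`Vo = 0`) reports `snr` capped at `1e12`.
#' @export
parameterize_spikes <- function(waveforms, unit) {
  stopifnot(inherits(unit, "spike_unit"))
  if (!is.matrix(waveforms)) waveforms <- matrix(waveforms, nrow = 1)
  V <- waveforms[, unit$idx_start:unit$idx_end, drop = FALSE]
  C <- unit$canonical_shape
  alpha <- as.numeric(V %*% C)
  resid <- V - tcrossprod(alpha, C)
  vo_energy <- rowSums(resid^2)
  v_energy <- rowSums(V^2)
  if (any(v_energy == 0)) abort("zero-energy spike window (degenerate input).")
  tibble::tibble(
    alpha = alpha,
    alpha_scaled = alpha / sqrt(unit$n_window),
    lfp_energy = vo_energy,
    snr = ifelse(vo_energy > 0, pmin(alpha / vo_energy, 1e12), 1e12),
    snr_rms = ifelse(vo_energy > 0,
                     (alpha / sqrt(unit$n_window)) / sqrt(vo_energy / unit$n_window),
                     1e12),
    explained_variance = 1 - vo_energy / v_energy
  )
}

#' Quality metrics for a single spike
#'
#' Scalar version of the metrics in [parameterize_spikes()] for one spike
#' window `v` given its projection weight `alpha` on the canonical shape.
#'
#' @param v Spike samples over the unit's window.
#' @param alpha Projection weight `<v, C>`.
#' @param unit A [spike_unit()].
#' @return A one-row tibble (`lfp_energy`, `snr`, `snr_rms`,
#'   `explained_variance`).
#' @export
spike_metrics <- function(v, alpha, unit) {
  out <- parameterize_spikes(matrix(v, nrow = 1), unit)
  out[, c("lfp_energy", "snr", "snr_rms", "explained_variance")]
}

#' Subtract a unit's parameterized spikes from a trace
#'
#' Removes `alpha_k * C(t - tau_k)` for every spike of the unit; samples
#' outside all spike windows are untouched. Spikes whose window extends past
#' a trace edge are subtracted over the overlapping part only, with a
#' warning.
#'
#' @param rec The voltage trace to subtract from.
#' @param unit A [spike_unit()].
#' @param events Tibble with one row per spike: `time` (alignment sample
#'   index into `rec`) and `alpha`.
#'
#' @return The trace with the unit's spikes removed.
#' @export
subtract_unit <- function(rec, unit, events) {
  stopifnot(inherits(rec, "mer_recording"), inherits(unit, "spike_unit"))
  x <- rec$samples
  n <- length(x)
  geom <- frame_geometry(rec$rate)
  off <- (unit$idx_start:unit$idx_end) - geom$i0
  n_partial <- 0L
  for (j in seq_len(nrow(events))) {
    idx <- events$time[j] + off
    inside <- idx >= 1L & idx <= n
    if (!all(inside)) n_partial <- n_partial + 1L
    x[idx[inside]] <- x[idx[inside]] - events$alpha[j] * unit$canonical_shape[inside]
  }
  if (n_partial > 0) warn(sprintf("%d spike window(s) extended past the trace edge; partial subtraction applied.", n_partial))
  out <- rec
  out$samples <- x
  out
}

#' Parameterize every sorted unit of a sort result
#'
#' For each assigned unit: discovers the spike window, builds the canonical
#' shape, and computes per-spike `alpha`, `alpha'`, and quality metrics.
#'
#' @param sort A `sort_result` from [template_match_sort()].
#' @param rate Sampling rate in Hz (taken from the sort result if present).
#' @param target Profile estimator for window discovery.
#'
#' @return A `crp_fit` object: `events` (the sort's event tibble augmented
#'   with `alpha`, `alpha_scaled`, `lfp_energy`, `snr`, `snr_rms`,
#'   `explained_variance`), `units` (named list of [spike_unit()]), and the
#'   originating `sort`.
#' @export
crp_parameterize <- function(sort, rate = NULL, target = "loo") {
  stopifnot(inherits(sort, "sort_result"))
  rate <- rate %||% sort$rate
  if (is.null(rate)) abort("sampling rate unknown; pass `rate`.")
  ev <- sort$events
  ev$alpha <- NA_real_
  ev$alpha_scaled <- NA_real_
  ev$lfp_energy <- NA_real_
  ev$snr <- NA_real_
  ev$snr_rms <- NA_real_
  ev$explained_variance <- NA_real_
  unit_ids <- sort(unique(ev$unit_id[!is.na(ev$unit_id)]))
  units <- list()
  for (u in unit_ids) {
    sel <- which(ev$unit_id == u)
    wf <- sort$waveforms[sel, , drop = FALSE]
    un <- spike_unit(u, wf, spike_times = ev$time_s[sel], rate = rate)
    pars <- parameterize_spikes(wf, un)
    ev$alpha[sel] <- pars$alpha
    ev$alpha_scaled[sel] <- pars$alpha_scaled
    ev$lfp_energy[sel] <- pars$lfp_energy
    ev$snr[sel] <- pars$snr
    ev$snr_rms[sel] <- pars$snr_rms
    ev$explained_variance[sel] <- pars$explained_variance
    units[[as.character(u)]] <- un
  }
  structure(list(events = ev, units = units, sort = sort, rate = rate),
            class = "crp_fit")
}

#' @export
print.crp_fit <- function(x, ...) {
  cat(sprintf("<crp_fit> %d parameterized unit(s), %d spikes\n",
              length(x$units), sum(!is.na(x$events$unit_id))))
  print(glance.crp_fit(x))
  invisible(x)
}

#' @method tidy crp_fit
#' @export
tidy.crp_fit <- function(x, ...) x$events

#' Per-unit summary metrics of a CRP fit
#'
#' One row per unit: spike count, firing rate, window duration, and means of
#' the per-spike metrics — the standard summary table for a parameterized
#' recording site.
#'
#' @param x A `crp_fit`.
#' @param duration_s Recording duration in seconds used for firing rates;
#'   inferred from the span of spike times when `NULL`.
#' @param ... Unused.
#' @return A tibble with one row per unit.
#' @method glance crp_fit
#' @export
glance.crp_fit <- function(x, duration_s = NULL, ...) {
  purrr::map_dfr(x$units, function(un) {
    sel <- x$events$unit_id == un$unit_id & !is.na(x$events$unit_id)
    ev <- x$events[sel, ]
    dur <- duration_s %||% max(ev$time_s)
    isis <- diff(sort(ev$time_s))
    tibble::tibble(
      unit_id = un$unit_id,
      n_spikes = nrow(ev),
      firing_rate_hz = nrow(ev) / dur,
      window_ms = (un$tau_R - un$tau_i) * 1000,
      mean_alpha = mean(ev$alpha),
      mean_alpha_scaled = mean(ev$alpha_scaled),
      mean_lfp_energy = mean(ev$lfp_energy),
      mean_snr = mean(ev$snr),
      mean_explained_variance = mean(ev$explained_variance),
      mean_isi_s = if (length(isis)) mean(isis) else NA_real_
    )
  })
}

#' Plot projection profiles of a unit's window discovery
#'
#' @param object A `spike_unit` built with discovery, or the output of
#'   [discover_spike_window()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot crp_fit
#' @export
autoplot.crp_fit <- function(object, ...) {
  rate <- object$rate
  geom <- frame_geometry(rate)
  tms <- (seq_len(geom$len) - geom$i0) / rate * 1000
  df <- purrr::map_dfr(object$units, function(un) {
    tibble::tibble(unit_id = un$unit_id, t_ms = tms, voltage = un$mean_waveform,
                   tau_i = un$tau_i * 1000, tau_R = un$tau_R * 1000)
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$t_ms, .data$voltage)) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$tau_i, xmax = .data$tau_R,
                                    ymin = -Inf, ymax = Inf),
                       fill = "steelblue", alpha = 0.08) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~unit_id, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Time from alignment extremum (ms)", y = "Voltage",
                  title = "Mean waveforms with discovered spike windows") +
    ggplot2::theme_minimal()
}

#' Serial parameterization and re-sorting to resolve overlapping spikes
#'
#' Overlapping action potentials hide smaller spikes inside larger ones.
#' Because each spike is parameterized as `alpha * C(t)`, a unit can be
#' subtracted from the filtered trace and the residual re-sorted with the
#' *same* voltage threshold, exposing spikes the first pass missed. Units are
#' processed in descending order of template amplitude; after each
#' subtraction, newly detected events are template-matched against the
#' remaining units' templates and merged. Refractory-violation rates are
#' recomputed after every pass, since recovered spikes may belong to another
#' unit. Spikes exactly coincident at the alignment extremum cannot be
#' resolved; an expected count of such chance coincidences is reported.
#'
#' @param filtered The band-passed `mer_recording` that was sorted.
#' @param sort A `sort_result` with at least two assigned units.
#' @param threshold The detection threshold used for the original sort.
#' @param dedup_s New detections within this window of any existing event are
#'   considered re-detections and ignored (default 0.5 ms).
#'
#' @return An augmented `sort_result`: `events` gains a `recovered` flag,
#'   recovered waveforms are appended, `n_recovered` and
#'   `unresolved_overlap_estimate` are set, and `residual` holds the trace
#'   after all subtractions.
#' @export
serial_sort <- function(filtered, sort, threshold, dedup_s = 0.0005) {
  stopifnot(inherits(filtered, "mer_recording"), inherits(sort, "sort_result"))
  rate <- filtered$rate
  ev <- sort$events
  ev$recovered <- FALSE
  unit_ids <- sort(unique(ev$unit_id[!is.na(ev$unit_id)]))
  if (length(unit_ids) < 2) {
    inform("serial re-sorting requires at least two sorted units; returning input unchanged.")
    out <- sort
    out$events <- ev
    out$n_recovered <- 0L
    return(out)
  }
  # largest template first
  amp <- vapply(unit_ids, function(u) max(abs(sort$templates[u, ])), numeric(1))
  order_units <- unit_ids[order(amp, decreasing = TRUE)]

  wf_all <- sort$waveforms
  residual <- filtered
  remaining <- order_units
  n_rec <- 0L
  for (u in order_units) {
    remaining <- setdiff(remaining, u)
    sel <- which(ev$unit_id == u)
    if (length(sel) < 2) next
    un <- spike_unit(u, wf_all[sel, , drop = FALSE],
                     spike_times = ev$time_s[sel], rate = rate)
    # re-match unassigned events over the unit's spike window only: a trailing
    # overlapping spike sits outside the window and must not veto assignment
    unass <- which(is.na(ev$unit_id))
    if (length(unass) > 0) {
      win <- un$idx_start:un$idx_end
      d <- sweep(wf_all[unass, win, drop = FALSE], 2, sort$templates[u, win])
      ss_win <- rowMeans(d^2) / sort$full_scale^2
      hits <- unass[ss_win <= sort$fit_tolerance]
      if (length(hits) > 0) {
        ev$unit_id[hits] <- u
        ev$recovered[hits] <- TRUE
        n_rec <- n_rec + length(hits)
        sel <- sort.int(c(sel, hits))
        un <- spike_unit(u, wf_all[sel, , drop = FALSE],
                         spike_times = ev$time_s[sel], rate = rate)
      }
    }
    pars <- parameterize_spikes(wf_all[sel, , drop = FALSE], un)
    residual <- subtract_unit(residual, un,
                              tibble::tibble(time = ev$time[sel], alpha = pars$alpha))
    if (length(remaining) == 0) break
    redet <- detect_waveforms(residual, threshold)
    if (nrow(redet$events) == 0) next
    # a detection is only a re-detection if it re-finds a spike still present
    # in the residual, i.e. an event assigned to a remaining unit; detections
    # at subtracted spikes' times or at formerly unassigned events are
    # candidates, their residual waveforms now being free of unit u
    assigned_there <- ev$time_s[!is.na(ev$unit_id) & ev$unit_id %in% remaining]
    is_cand <- vapply(redet$events$time_s, function(t) {
      length(assigned_there) == 0 || all(abs(t - assigned_there) >= dedup_s)
    }, logical(1))
    if (!any(is_cand)) next
    new_wf <- redet$waveforms[is_cand, , drop = FALSE]
    new_ev <- redet$events[is_cand, ]
    m <- template_match_sort(list(events = new_ev, waveforms = new_wf),
                             sort$templates[remaining, , drop = FALSE],
                             fit_tolerance = sort$fit_tolerance,
                             full_scale = sort$full_scale, refine = 0,
                             rate = rate)
    keep <- which(!is.na(m$events$unit_id))
    if (length(keep) == 0) next
    add <- m$events[keep, ]
    add$unit_id <- remaining[add$unit_id]
    add$recovered <- TRUE
    # candidates coinciding with a formerly unassigned event replace it
    unass <- which(is.na(ev$unit_id))
    drop_rows <- integer(0)
    for (r in seq_len(nrow(add))) {
      if (length(unass)) {
        d <- abs(add$time_s[r] - ev$time_s[unass])
        hit <- which(d < dedup_s)
        if (length(hit)) drop_rows <- c(drop_rows, unass[hit])
      }
    }
    if (length(drop_rows)) {
      drop_rows <- unique(drop_rows)
      keep_rows <- setdiff(seq_len(nrow(ev)), drop_rows)
      wf_all <- wf_all[keep_rows, , drop = FALSE]
      ev <- ev[keep_rows, ]
    }
    add$event_id <- max(ev$event_id) + seq_len(nrow(add))
    ev <- dplyr::bind_rows(ev, add)
    wf_all <- rbind(wf_all, new_wf[keep, , drop = FALSE])
    n_rec <- n_rec + nrow(add)
  }
  # wf_all rows are in the order events were accumulated; re-align to time order
  wf_order_ids <- ev$event_id
  ev <- dplyr::arrange(ev, .data$time)
  wf_all <- wf_all[match(ev$event_id, wf_order_ids), , drop = FALSE]
  ev$event_id <- seq_len(nrow(ev))

  out <- new_sort_result(events = ev, waveforms = wf_all, templates = sort$templates,
                         fit_tolerance = sort$fit_tolerance, full_scale = sort$full_scale,
                         ties = sort$ties, rate = rate)
  out$n_recovered <- n_rec
  out$residual <- residual
  # expected chance coincidences at the alignment sample (unresolvable)
  dur <- rec_duration(filtered)
  counts <- table(factor(ev$unit_id, levels = unit_ids))
  est <- 0
  if (length(unit_ids) >= 2) {
    for (i in seq_along(unit_ids)[-length(unit_ids)]) {
      for (j in (i + 1):length(unit_ids)) {
        est <- est + as.numeric(counts[i]) * as.numeric(counts[j]) * (2 * dedup_s) / dur
      }
    }
  }
  out$unresolved_overlap_estimate <- est
  out
}

#' Residual local field potential after spike removal
#'
#' Subtracts every unit's parameterized spikes (`alpha_k * C`) from the
#' *unfiltered* raw trace — the projection weights having been estimated on
#' the band-passed trace — leaving the residual LFP `Vo(t)`, a proxy for the
#' non-spiking population signal (narrow-band oscillations plus 1/f
#' broadband).
#'
#' @param raw The unfiltered `mer_recording` (same length as the filtered
#'   trace the fit came from).
#' @param fit A `crp_fit` from [crp_parameterize()].
#'
#' @return The raw recording with all parameterized spikes removed.
#' @export
residual_lfp <- function(raw, fit) {
  stopifnot(inherits(raw, "mer_recording"), inherits(fit, "crp_fit"))
  if (any(fit$events$time > length(raw$samples), na.rm = TRUE)) {
    abort("event times exceed the raw trace length (mismatched traces?).")
  }
  out <- raw
  for (un in fit$units) {
    sel <- which(fit$events$unit_id == un$unit_id & !is.na(fit$events$alpha))
    if (length(sel) == 0) next
    out <- subtract_unit(out, un, tibble::tibble(time = fit$events$time[sel],
                                                 alpha = fit$events$alpha[sel]))
  }
  out
}
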