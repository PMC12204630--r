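# Shared fixture builders. Everything is generated in code at test time;
# results are cached per session so several test files can reuse one
# simulated recording.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# full detection + sorting + parameterization on a simulated recording
sort_pipeline <- function(sim, n_units, seed = 1) {
  filt <- bandpass_filter(sim$rec)
  thr <- estimate_threshold(filt)
  det <- detect_waveforms(filt, thr)
  tpl <- pca_template_selection(det$waveforms, n_units, seed = seed)
  srt <- template_match_sort(det, tpl$templates, rate = sim$rec$rate)
  list(filtered = filt, threshold = thr, detected = det, sort = srt)
}

# match each true spike to the nearest event within tol; NA if none
match_events <- function(true_times, event_times, tol = 2e-4) {
  vapply(true_times, function(t) {
    if (length(event_times) == 0) return(NA_integer_)
    d <- abs(event_times - t)
    j <- which.min(d)
    if (d[j] < tol) j else NA_integer_
  }, integer(1))
}

# unit-assignment accuracy under the best label permutation
best_map_accuracy <- function(true_units, assigned_units) {
  tab <- table(true_units, assigned_units)
  sum(apply(tab, 1, max)) / sum(tab)
}

# spike_unit built directly from a template's known support (bypasses
# window discovery; used where the discovery step is not under test)
unit_from_template <- function(id, waveform, template, rate = 44000,
                               spike_times = numeric(0)) {
  geom <- crpspike:::frame_geometry(rate)
  win <- list(
    idx_start = max(1L, geom$i0 + as.integer(round(template$support_start * rate))),
    idx_end = min(geom$len, geom$i0 + as.integer(round(template$support_end * rate))),
    flagged = FALSE
  )
  win$tau_i <- (win$idx_start - geom$i0) / rate
  win$tau_R <- (win$idx_end - geom$i0) / rate
  spike_unit(id, matrix(waveform, nrow = 1), spike_times = spike_times,
             rate = rate, window = win)
}

# exhaustive minimum-cost assignment (independent oracle for the Munkres
# implementation)
brute_force_assign <- function(cost) {
  k <- nrow(cost)
  best <- Inf
  best_p <- NULL
  rec <- function(remaining, acc) {
    if (!length(remaining)) {
      s <- sum(cost[cbind(seq_len(k), acc)])
      if (s < best) {
        best <<- s
        best_p <<- acc
      }
      return(invisible())
    }
    for (x in remaining) rec(setdiff(remaining, x), c(acc, x))
  }
  rec(seq_len(k), integer(0))
  list(perm = best_p, cost = best)
}

# brute-force average-linkage agglomeration (independent oracle for hclust)
brute_force_average_linkage <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  repeat {
    m <- length(clusters)
    if (m == 1) break
    best <- c(Inf, NA, NA)
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        dd <- mean(d[clusters[[i]], clusters[[j]]])
        if (dd < best[1]) best <- c(dd, i, j)
      }
    }
    heights <- c(heights, best[1])
    merged <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters <- c(clusters[-c(best[2], best[3])], list(merged))
  }
  heights
}
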