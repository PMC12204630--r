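test_that("band-pass filter rejects DC, passes 1 kHz, attenuates 50 Hz", {
  rate <- 44000
  n <- rate  # 1 s
  tt <- (0:(n - 1)) / rate
  dc <- bandpass_filter(recording(rep(5, n), rate))
  mid <- 2000:(n - 2000)  # away from filtfilt edge transients
  expect_lt(max(abs(dc$samples[mid])), 5e-6 * 5)

  s1k <- bandpass_filter(recording(sin(2 * pi * 1000 * tt), rate))
  amp1k <- max(abs(s1k$samples[mid]))
  expect_lt(abs(amp1k - 1), 0.05)

  s50 <- bandpass_filter(recording(sin(2 * pi * 50 * tt), rate))
  amp50 <- max(abs(s50$samples[mid]))
  expect_lt(20 * log10(amp50), -20)

  expect_equal(length(s1k$samples), n)
  expect_error(bandpass_filter(recording(rnorm(100), rate = 10000), high = 9000),
               "rate/2")
})

test_that("threshold is -4 robust noise SD and scales homogeneously", {
  set.seed(42)
  x <- recording(rnorm(441000), 44100)
  thr <- estimate_threshold(x)
  expect_lt(abs(thr - (-4)) / 4, 0.02)
  x10 <- x
  x10$samples <- x$samples * 10
  expect_equal(estimate_threshold(x10), 10 * thr)
  expect_equal(eval(formals(estimate_threshold)$multiplier), -4.0)
  expect_error(estimate_threshold(recording(rep(0, 100))), "robust scale")
})

test_that("detection count matches a brute-force crossing scan on noise", {
  rate <- 44000
  for (s in 1:3) {
    set.seed(s)
    x <- rnorm(rate)  # 1 s of noise
    thr <- -4 * stats::median(abs(x)) / 0.6745
    rec <- recording(x, rate)
    det <- detect_waveforms(rec, thr)
    # independent naive scan with the same stated rules
    geom <- crpspike:::frame_geometry(rate)
    cross <- which(x[-1] < thr & x[-length(x)] >= thr) + 1L
    search <- round(0.0006 * rate)
    aligns <- integer(0)
    peaks <- numeric(0)
    for (cidx in cross) {
      idx <- cidx:min(length(x), cidx + search)
      k <- idx[which.max(abs(x[idx]))]
      aligns <- c(aligns, k)
      peaks <- c(peaks, abs(x[k]))
    }
    keep <- rep(TRUE, length(cross))
    j <- 1L
    while (j < length(cross)) {
      nxt <- j + 1L
      while (nxt <= length(cross) && cross[nxt] - cross[j] < round(0.0005 * rate)) {
        if (peaks[nxt] > peaks[j]) {
          keep[j] <- FALSE
          j <- nxt
        } else {
          keep[nxt] <- FALSE
        }
        nxt <- nxt + 1L
      }
      j <- nxt
    }
    aligns <- unique(aligns[keep])
    aligns <- aligns[aligns - geom$i0 + 1L >= 1 & aligns + geom$len - geom$i0 <= length(x)]
    expect_equal(nrow(det$events), length(aligns))
  }
})

test_that("a single clean template yields one correctly aligned event", {
  rate <- 44000
  tpl <- make_templates(1, seed = 1)[[1]]
  geom <- crpspike:::frame_geometry(rate)
  x <- numeric(rate)
  a <- 20000L
  x[(a - geom$i0 + 1L):(a + geom$len - geom$i0)] <- 5 * tpl$samples
  det <- detect_waveforms(recording(x, rate), -1)
  expect_equal(nrow(det$events), 1)
  expect_equal(det$events$time, a)
  expect_equal(which.max(abs(det$waveforms[1, ])), geom$i0)
})

test_that("two crossings 0.3 ms apart collapse to one event", {
  rate <- 44000
  tpl <- make_templates(1, seed = 1)[[1]]
  geom <- crpspike:::frame_geometry(rate)
  x <- numeric(rate)
  a <- 20000L
  b <- a + round(0.0003 * rate)
  span <- function(p) (p - geom$i0 + 1L):(p + geom$len - geom$i0)
  x[span(a)] <- x[span(a)] + 6 * tpl$samples
  x[span(b)] <- x[span(b)] + 4 * tpl$samples
  det <- detect_waveforms(recording(x, rate), -1)
  expect_equal(nrow(det$events), 1)
  expect_equal(det$events$time, a)  # larger extremum wins
})

test_that("detection and sorting are equivariant under trace scaling", {
  sim <- cached("sim_2unit_5s", simulate_recording(
    sim_config(duration = 5, templates = make_templates(2, seed = 7),
               firing_rate = c(20, 12), amp_mean = 10, seed = 3)))
  filt <- bandpass_filter(sim$rec)
  thr <- estimate_threshold(filt)
  d1 <- detect_waveforms(filt, thr)
  f2 <- filt
  f2$samples <- filt$samples * 7.5
  d2 <- detect_waveforms(f2, thr * 7.5)
  expect_equal(d1$events$time, d2$events$time)
  expect_equal(d2$waveforms, d1$waveforms * 7.5)
})

test_that("PCA template seeding separates two well-isolated units", {
  sim <- cached("sim_2unit_5s", simulate_recording(
    sim_config(duration = 5, templates = make_templates(2, seed = 7),
               firing_rate = c(20, 12), amp_mean = 10, seed = 3)))
  filt <- bandpass_filter(sim$rec)
  det <- detect_waveforms(filt, estimate_threshold(filt))
  sel <- pca_template_selection(det$waveforms, 2, seed = 1)
  tpl_true <- make_templates(2, seed = 7)
  # each seeded template must resemble one distinct ground-truth template
  simil <- matrix(0, 2, 2)
  for (i in 1:2) {
    for (j in 1:2) {
      a <- normalize_shape(sel$templates[i, ])
      b <- normalize_shape(tpl_true[[j]]$samples)
      simil[i, j] <- sum(a * b)
    }
  }
  expect_true(all(apply(simil, 1, max) > 0.95))
  expect_equal(which.max(simil[1, ]) != which.max(simil[2, ]), TRUE)

  # single group: grand mean
  one <- pca_template_selection(det$waveforms, 1)
  expect_equal(one$templates[1, ], colMeans(det$waveforms))

  # duplicated identical waveforms: degenerate, flagged
  dup <- det$waveforms[rep(1, 10), ]
  expect_warning(res <- pca_template_selection(dup, 2, seed = 1), "degenerate")
  expect_true(res$degenerate)

  expect_error(pca_template_selection(det$waveforms[1:3, ], 5), "exceeds")
})

test_that("template matching assigns by minimum sum-of-squares with tolerance", {
  rate <- 44000
  tplA <- make_templates(2, seed = 7)[[1]]$samples * 8
  tplB <- make_templates(2, seed = 7)[[2]]$samples * 8
  wf <- rbind(tplA, tplB * 0.97)
  det <- list(events = tibble::tibble(event_id = 1:2, time = c(1000L, 2000L),
                                      time_s = c(1000, 2000) / rate),
              waveforms = wf)
  srt <- template_match_sort(det, rbind(tplA, tplB), fit_tolerance = 0.01,
                             refine = 0, rate = rate)
  expect_equal(srt$events$unit_id, c(1L, 2L))
  expect_equal(srt$events$ss[1], 0)

  # exact tie between two identical templates goes to the lower index
  expect_message(
    tie <- template_match_sort(det, rbind(tplA, tplA), fit_tolerance = 0.01,
                               refine = 0, rate = rate),
    "tie"
  )
  expect_equal(tie$events$unit_id[1], 1L)

  # out-of-tolerance waveform stays unassigned
  far <- template_match_sort(list(events = det$events[1, ],
                                  waveforms = matrix(tplA * 3, 1)),
                             rbind(tplA, tplB), fit_tolerance = 1e-6,
                             refine = 0, rate = rate)
  expect_true(is.na(far$events$unit_id[1]))
})

test_that("sorting accuracy exceeds 95% on a clean two-unit recording", {
  sim <- cached("sim_2unit_10s", simulate_recording(
    sim_config(duration = 10, templates = make_templates(2, seed = 7),
               firing_rate = c(20, 12), amp_mean = 10, seed = 21)))
  pipe <- sort_pipeline(sim, n_units = 2)
  ev <- pipe$sort$events
  m <- match_events(sim$truth$time_s, ev$time_s)
  ok <- !is.na(m) & !is.na(ev$unit_id[m])
  expect_gt(mean(!is.na(m)), 0.95)
  expect_gt(best_map_accuracy(sim$truth$unit_id[ok], ev$unit_id[m[ok]]), 0.95)
  # refractory QC: no more violations than the generator's own rate + 1 point
  refr <- pipe$sort$refractory
  truth_rate <- vapply(split(sim$truth$time_s, sim$truth$unit_id), function(t) {
    refractory_violation_rate(sort(t))
  }, numeric(1))
  expect_true(all(refr$violation_pct <= max(truth_rate) + 1))
})

test_that("refractory violation rate follows its definition", {
  expect_equal(refractory_violation_rate(c(0, 0.001, 0.010, 0.020)), 25)
  expect_equal(refractory_violation_rate(c(0, 0.002, 0.004)), 0)
  expect_equal(refractory_violation_rate(0.5), 0)
  expect_equal(refractory_violation_rate(numeric(0)), 0)
  expect_error(refractory_violation_rate(c(0.3, 0.1)), "sorted")
})
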