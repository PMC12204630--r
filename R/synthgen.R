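#' Generate a family of synthetic spike templates
#'
#' Builds `n_shapes` biphasic/triphasic extracellular action-potential
#' templates on the standard 2 ms extraction frame (0.5 ms before to 1.5 ms
#' after the alignment extremum). Shapes are difference-of-Gaussian waveforms
#' with total widths spread over 0.3-1.2 ms, alternating biphasic/triphasic
#' morphology, and occasional positive-leading polarity, emulating the
#' variety of unit shapes seen along a pallidal microelectrode track.
#'
#' Each template is peak-normalized (alignment extremum magnitude 1) with the
#' extremum exactly at the frame's time-zero index; samples outside the
#' template's support are exactly zero.
#'
#' @param n_shapes Number of templates (>= 1).
#' @param rate Sampling rate in Hz.
#' @param seed Integer seed; the same seed reproduces the same templates.
#'
#' @return A list of `spike_template` objects with fields `shape_id`,
#'   `samples` (length `round(0.002*rate)`), `t0_index`, `support_start`,
#'   `support_end` (seconds relative to the extremum), and `polarity`.
#' @export
make_templates <- function(n_shapes, rate = 44000, seed = 1) {
  if (!is.numeric(n_shapes) || n_shapes < 1) abort("`n_shapes` must be >= 1.")
  n_shapes <- as.integer(n_shapes)
  geom <- frame_geometry(rate)
  t <- (seq_len(geom$len) - geom$i0) / rate   # seconds relative to extremum

  with_seed(seed, {
    widths <- seq(0.3e-3, 1.2e-3, length.out = max(n_shapes, 2))[seq_len(n_shapes)]
    widths <- widths * runif(n_shapes, 0.95, 1.05)
    templates <- vector("list", n_shapes)
    for (i in seq_len(n_shapes)) {
      w <- widths[i]
      triphasic <- (i %% 2L == 0L)
      positive <- (i %% 4L == 0L)
      rebound <- runif(1, 0.35, 0.55)
      sigma_main <- w / 7
      delta <- 0.45 * w
      sigma_reb <- w / 4
      shape <- -exp(-t^2 / (2 * sigma_main^2)) +
        rebound * exp(-(t - delta)^2 / (2 * sigma_reb^2))
      if (triphasic) {
        shape <- shape + 0.25 * exp(-(t + 0.2 * w)^2 / (2 * (w / 9)^2))
      }
      sup_lo <- max(-0.45e-3, -0.45 * w)
      sup_hi <- min(1.45e-3, 1.35 * w)
      shape <- shape * support_taper(t, sup_lo, sup_hi)
      shape[t < sup_lo | t > sup_hi] <- 0
      # peak-normalize; the main trough/peak must stay the global extremum
      shape <- shape / abs(shape[geom$i0])
      if (which.max(abs(shape)) != geom$i0) {
        shape <- shape / max(abs(shape)) * 0.99
        shape[geom$i0] <- sign(shape[geom$i0]) * 1
      }
      if (positive) shape <- -shape
      templates[[i]] <- structure(
        list(shape_id = i, samples = shape, t0_index = geom$i0,
             support_start = sup_lo, support_end = sup_hi,
             polarity = if (positive) "positive-leading" else "negative-leading",
             rate = rate),
        class = "spike_template"
      )
    }
    templates
  })
}

# Raised-cosine taper to zero at the support edges (outer 25% each side),
# so hard-zeroing outside the support introduces no discontinuity.
support_taper <- function(t, lo, hi) {
  tap <- rep(1, length(t))
  span <- hi - lo
  edge <- 0.25 * span
  left <- t >= lo & t < lo + edge
  right <- t > hi - edge & t <= hi
  tap[left] <- 0.5 * (1 - cos(pi * (t[left] - lo) / edge))
  tap[right] <- 0.5 * (1 - cos(pi * (hi - t[right]) / edge))
  tap[t < lo | t > hi] <- 0
  tap
}

#' Simulation configuration for synthetic recordings
#'
#' Bundles everything the generator needs: templates, per-unit firing
#' statistics, amplitude model, noise model, optional overlap injection and
#' cardiac modulation. With a fixed seed the generated recording and ground
#' truth are fully reproducible.
#'
#' @param duration Trace duration in seconds.
#' @param rate Sampling rate in Hz; must exceed twice the spike-band upper
#'   edge (9 kHz).
#' @param templates List of `spike_template` (see [make_templates()]).
#' @param firing_rate Per-unit mean firing rate(s) in Hz (recycled).
#' @param amp_mean Per-unit mean spike peak amplitude(s), in the same
#'   (arbitrary) voltage units as the noise SD (recycled).
#' @param amp_jitter Lognormal amplitude jitter `sdlog` (0.1 default;
#'   multiplicative, mean-one).
#' @param refractory Per-unit absolute refractory dead time in seconds.
#' @param noise List: `sd` total noise SD, `beta` 1/f exponent, `white_frac`
#'   fraction of noise variance that is white, `line_hz`/`line_amp` optional
#'   mains sinusoid, `osc_hz`/`osc_amp` optional narrow-band oscillation.
#' @param overlap Optional list to inject overlapping spike pairs:
#'   `frac` fraction of leader spikes that get a trailing follower spike,
#'   `offset` two-element range of lags in seconds, `leader`/`follower`
#'   unit indices.
#' @param cardiac Optional list enabling cardiac amplitude modulation:
#'   `A`, `n`, `m` impulse-response parameters (amplitude follows
#'   `baseline + A * t^n * exp(-m t)` with `t` the time since the last
#'   R-wave), `heart_rate` beats/min, `hrv_cv` coefficient of variation of
#'   the beat interval, `unit` index of the modulated unit.
#' @param seed Integer seed.
#'
#' @return A `sim_config` list.
#' @export
sim_config <- function(duration = 30, rate = 44000,
                       templates = make_templates(2, rate = rate, seed = seed),
                       firing_rate = 20, amp_mean = 10, amp_jitter = 0.1,
                       refractory = 0.002,
                       noise = list(), overlap = NULL, cardiac = NULL,
                       seed = 1) {
  if (duration <= 0) abort("`duration` must be positive.")
  if (rate <= 2 * 9000) abort("`rate` must exceed twice the 9 kHz spike-band edge.")
  noise_def <- list(sd = 1, beta = 1, white_frac = 0.2,
                    line_hz = NULL, line_amp = 0, osc_hz = NULL, osc_amp = 0)
  noise <- utils::modifyList(noise_def, noise)
  n_units <- length(templates)
  cfg <- list(
    duration = duration, rate = rate, templates = templates,
    firing_rate = rep_len(firing_rate, n_units),
    amp_mean = rep_len(amp_mean, n_units),
    amp_jitter = amp_jitter, refractory = refractory,
    noise = noise, overlap = overlap, cardiac = cardiac, seed = seed
  )
  if (!is.null(cardiac)) {
    # with n = 2, m = 10 the impulse response peaks at t = n/m = 0.2 s with
    # value A (n/m)^n e^-n ~= 0.0054 A; A = 500 puts the peak near 27% of the
    # default unit amplitude
    card_def <- list(A = 500, n = 2, m = 10, heart_rate = 60, hrv_cv = 0.03, unit = 1L)
    cfg$cardiac <- utils::modifyList(card_def, cardiac)
    if (cfg$cardiac$heart_rate <= 0) abort("`heart_rate` must be positive.")
  }
  if (!is.null(overlap)) {
    ov_def <- list(frac = 0.1, offset = c(3e-4, 1e-3), leader = 1L, follower = 2L)
    cfg$overlap <- utils::modifyList(ov_def, overlap)
    if (n_units < max(cfg$overlap$leader, cfg$overlap$follower)) {
      abort("overlap leader/follower exceed the number of units.")
    }
  }
  structure(cfg, class = "sim_config")
}

# Stationary renewal train: dead time + exponential gap, thinned so the
# overall mean rate equals `rate_hz`. Requires rate_hz * refractory < 1.
sim_spike_train <- function(duration, rate_hz, refractory) {
  if (rate_hz <= 0) return(numeric(0))
  if (rate_hz * refractory >= 1) abort("firing rate incompatible with refractory dead time.")
  lambda <- rate_hz / (1 - rate_hz * refractory)
  times <- numeric(0)
  t <- rexp(1, lambda)
  while (t < duration) {
    times <- c(times, t)
    t <- t + refractory + rexp(1, lambda)
  }
  times
}

# 1/f^beta + white noise, frequency-domain synthesis.
sim_noise <- function(n, rate, noise) {
  out <- numeric(n)
  if (noise$sd > 0) {
    col_sd <- noise$sd * sqrt(1 - noise$white_frac)
    white_sd <- noise$sd * sqrt(noise$white_frac)
    if (col_sd > 0) {
      nf <- floor(n / 2)
      freqs <- seq_len(nf) * rate / n
      mag <- freqs^(-noise$beta / 2)
      z <- complex(real = rnorm(nf), imaginary = rnorm(nf)) * mag
      spec <- complex(real = numeric(n))
      spec[2:(nf + 1)] <- z
      spec[n:(n - nf + 1)] <- Conj(z)
      x <- Re(fft(spec, inverse = TRUE)) / n
      x <- x / sd(x) * col_sd
      out <- out + x
    }
    if (white_sd > 0) out <- out + rnorm(n, sd = white_sd)
  }
  tt <- (seq_len(n) - 1) / rate
  if (!is.null(noise$line_hz) && noise$line_amp > 0) {
    out <- out + noise$line_amp * sin(2 * pi * noise$line_hz * tt + runif(1, 0, 2 * pi))
  }
  if (!is.null(noise$osc_hz) && noise$osc_amp > 0) {
    out <- out + noise$osc_amp * sin(2 * pi * noise$osc_hz * tt + runif(1, 0, 2 * pi))
  }
  out
}

sim_r_times <- function(duration, heart_rate, hrv_cv) {
  mean_rr <- 60 / heart_rate
  times <- numeric(0)
  t <- runif(1, 0, mean_rr)
  while (t < duration) {
    times <- c(times, t)
    rr <- mean_rr * max(0.5, 1 + rnorm(1, sd = hrv_cv))
    t <- t + rr
  }
  times
}

#' Simulate a microelectrode recording with known ground truth
#'
#' Superimposes template spikes (Poisson firing with refractory dead time,
#' lognormal amplitude jitter, optional cardiac amplitude modulation and
#' injected overlapping pairs) on 1/f-plus-white background noise.
#'
#' Spikes whose template support would extend past either end of the trace
#' are dropped (never truncated) and reported in the `dropped` attribute of
#' the ground truth.
#'
#' @param config A [sim_config()].
#'
#' @return A list with elements `rec` (an [recording()]) and `truth`, a
#'   tibble with one row per inserted spike: `unit_id`, `time` (alignment
#'   sample index), `time_s`, `amplitude` (true peak-scaled amplitude), and
#'   `injected_overlap`. Attributes: `r_times` (cardiac R-wave times, if
#'   modulation was enabled), `dropped` (spikes lost at the trace edges),
#'   `noise_only` (the pure noise component of the trace).
#' @export
simulate_recording <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, sim_recording_impl(config))
}

sim_recording_impl <- function(config, r_times = NULL) {
  rate <- config$rate
  n <- round(config$duration * rate)
  geom <- frame_geometry(rate)
  n_units <- length(config$templates)

  if (!is.null(config$cardiac) && is.null(r_times)) {
    r_times <- sim_r_times(config$duration, config$cardiac$heart_rate, config$cardiac$hrv_cv)
  }

  spikes <- vector("list", n_units)
  for (u in seq_len(n_units)) {
    st <- sim_spike_train(config$duration, config$firing_rate[u], config$refractory)
    spikes[[u]] <- tibble::tibble(unit_id = u, time_s = st, injected_overlap = FALSE)
  }

  if (!is.null(config$overlap) && nrow(spikes[[config$overlap$leader]]) > 0) {
    ov <- config$overlap
    leader <- spikes[[ov$leader]]$time_s
    sel <- which(runif(length(leader)) < ov$frac)
    if (length(sel) > 0) {
      lag <- runif(length(sel), ov$offset[1], ov$offset[2])
      new_t <- leader[sel] + lag
      # respect the follower unit's refractory period
      keep <- vapply(new_t, function(x) {
        all(abs(x - spikes[[ov$follower]]$time_s) >= config$refractory)
      }, logical(1))
      new_t <- new_t[keep]
      spikes[[ov$follower]] <- dplyr::bind_rows(
        spikes[[ov$follower]],
        tibble::tibble(unit_id = ov$follower, time_s = new_t, injected_overlap = TRUE)
      ) |> dplyr::arrange(.data$time_s)
    }
  }

  truth <- dplyr::bind_rows(spikes)
  truth$time <- round(truth$time_s * rate) + 1L
  truth$time_s <- (truth$time - 1L) / rate

  # per-spike amplitudes
  amp <- config$amp_mean[truth$unit_id]
  if (!is.null(config$cardiac)) {
    cc <- config$cardiac
    mod <- truth$unit_id == cc$unit
    t_rel <- t_since_r(truth$time_s[mod], r_times)
    mod_amp <- config$amp_mean[cc$unit] + cc$A * ifelse(
      is.na(t_rel) | t_rel <= 0, 0, t_rel^cc$n * exp(-cc$m * t_rel))
    if (any(mod_amp <= 0)) abort("cardiac modulation yields non-positive amplitudes.")
    amp[mod] <- mod_amp
  }
  if (config$amp_jitter > 0) {
    amp <- amp * rlnorm(nrow(truth),
                        meanlog = -config$amp_jitter^2 / 2, sdlog = config$amp_jitter)
  }
  truth$amplitude <- amp

  # drop spikes whose frame leaves the trace
  lo <- truth$time - (geom$i0 - 1L)
  hi <- truth$time + (geom$len - geom$i0)
  ok <- lo >= 1L & hi <= n
  dropped <- truth[!ok, ]
  truth <- truth[ok, ]
  lo <- lo[ok]

  trace <- sim_noise(n, rate, config$noise)
  noise_only <- trace
  for (j in seq_len(nrow(truth))) {
    tpl <- config$templates[[truth$unit_id[j]]]$samples
    idx <- lo[j]:(lo[j] + geom$len - 1L)
    trace[idx] <- trace[idx] + truth$amplitude[j] * tpl
  }

  truth <- dplyr::arrange(truth[, c("unit_id", "time", "time_s", "amplitude", "injected_overlap")],
                          .data$unit_id, .data$time)
  attr(truth, "dropped") <- dropped
  attr(truth, "r_times") <- r_times
  attr(truth, "noise_only") <- noise_only
  list(rec = recording(trace, rate = rate), truth = truth)
}

# Time since the most recent R-wave; NA before the first R-wave.
t_since_r <- function(times, r_times) {
  if (is.null(r_times) || length(r_times) == 0) return(rep(NA_real_, length(times)))
  idx <- findInterval(times, r_times)
  out <- rep(NA_real_, length(times))
  has <- idx >= 1
  out[has] <- times[has] - r_times[idx[has]]
  out
}

#' Simulate a paired MER + EKG session with cardiac amplitude modulation
#'
#' Generates an R-wave train at the configured heart rate, modulates the
#' designated unit's spike amplitudes as `baseline + A * t^n * exp(-m t)`
#' (t = time since the last R-wave), and synthesizes an EKG channel with
#' QRS-like deflections at the R-wave times.
#'
#' @param config A [sim_config()] with `cardiac` enabled.
#'
#' @return A list with `mer` (recording), `ekg` (recording), and `truth`
#'   (ground-truth tibble; R-wave times in `attr(truth, "r_times")`).
#' @export
simulate_cardiac_session <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(config$cardiac)) abort("`config$cardiac` must be set.")
  with_seed(config$seed, {
    r_times <- sim_r_times(config$duration, config$cardiac$heart_rate, config$cardiac$hrv_cv)
    out <- sim_recording_impl(config, r_times = r_times)
    n <- length(out$rec$samples)
    tt <- (seq_len(n) - 1) / config$rate
    ekg <- rnorm(n, sd = 0.02)
    # QRS-like biphasic wavelet (derivative of Gaussian, ~25 ms wide)
    for (r in r_times) {
      idx <- which(abs(tt - r) < 0.03)
      u <- (tt[idx] - r) / 0.008
      ekg[idx] <- ekg[idx] + exp(-u^2 / 2) * (1 - u^2) # mexican hat, peak at R
    }
    list(mer = out$rec,
         ekg = recording(ekg, rate = config$rate, channel_role = "EKG"),
         truth = out$truth)
  })
}

#' Simulate a population of sorted units along a depth track
#'
#' Draws `n_units` unit mean waveforms from a small set of base templates
#' (with per-unit amplitude variation and waveform noise), assigns each unit
#' a depth so that shape groups are segregated along the track, and returns
#' everything the shape-clustering stage consumes, together with the
#' ground-truth group labels.
#'
#' @param templates List of base `spike_template`s (one per shape group).
#' @param n_units Number of units to draw.
#' @param amp_range Range of per-unit peak amplitudes (uniform).
#' @param shape_noise SD of white waveform noise added to each unit's mean
#'   waveform, relative to its peak amplitude.
#' @param depth_range Two-element depth range in mm (top to bottom of track).
#' @param n_spikes_range Range of per-unit spike counts (for firing stats).
#' @param duration Nominal recording duration per site in seconds.
#' @param seed Integer seed.
#'
#' @return A tibble with one row per unit: `unit_id`, `true_shape`,
#'   `depth_mm`, `amplitude`, `waveform` (list-column, 2 ms frame),
#'   `spike_times` (list-column), `duration_s`.
#' @export
simulate_unit_track <- function(templates, n_units = 50, amp_range = c(5, 40),
                                shape_noise = 0.02, depth_range = c(10, -2),
                                n_spikes_range = c(100, 600), duration = 30,
                                seed = 1) {
  k <- length(templates)
  rate <- templates[[1]]$rate
  with_seed(seed, {
    labels <- sort(rep_len(seq_len(k), n_units))
    # contiguous depth bands per shape group, emulating anatomical segregation
    edges <- seq(depth_range[1], depth_range[2], length.out = k + 1)
    depth <- numeric(n_units)
    for (g in seq_len(k)) {
      sel <- which(labels == g)
      depth[sel] <- sort(runif(length(sel), min(edges[g], edges[g + 1]),
                               max(edges[g], edges[g + 1])),
                         decreasing = (depth_range[1] > depth_range[2]))
    }
    amp <- runif(n_units, amp_range[1], amp_range[2])
    wf <- vector("list", n_units)
    st <- vector("list", n_units)
    for (i in seq_len(n_units)) {
      base <- templates[[labels[i]]]$samples
      wf[[i]] <- amp[i] * (base + rnorm(length(base), sd = shape_noise))
      n_sp <- round(runif(1, n_spikes_range[1], n_spikes_range[2]))
      st[[i]] <- sort(runif(n_sp, 0, duration))
    }
    tibble::tibble(
      unit_id = seq_len(n_units), true_shape = labels, depth_mm = depth,
      amplitude = amp, waveform = wf, spike_times = st, duration_s = duration
    )
  })
}

#' Simulate a cardiac-modulated per-spike amplitude series
#'
#' Lightweight generator for validating the cardiac-modulation stage without
#' synthesizing a full voltage trace: spike times follow the
#' refractory-renewal process, R-waves the configured heart rate, and each
#' spike's scaled weight is `baseline + A * t^n * exp(-m t)` (t = time since
#' the last R-wave; baseline alone before the first R-wave) with
#' multiplicative lognormal noise.
#'
#' @param duration Duration in seconds.
#' @param firing_rate Mean firing rate in Hz.
#' @param baseline Baseline amplitude.
#' @param A,n,m Impulse-response parameters (`A = 0` disables modulation).
#' @param heart_rate Beats per minute.
#' @param hrv_cv Coefficient of variation of the beat interval.
#' @param noise_cv Multiplicative amplitude noise (lognormal sdlog).
#' @param refractory Dead time in seconds.
#' @param seed Integer seed.
#'
#' @return A tibble (`time_s`, `alpha_scaled`) with R-wave times in
#'   `attr(, "r_times")`.
#' @export
simulate_alpha_series <- function(duration = 60, firing_rate = 20, baseline = 10,
                                  A = 500, n = 2, m = 10, heart_rate = 60,
                                  hrv_cv = 0.03, noise_cv = 0.1,
                                  refractory = 0.002, seed = 1) {
  with_seed(seed, {
    st <- sim_spike_train(duration, firing_rate, refractory)
    r_times <- sim_r_times(duration, heart_rate, hrv_cv)
    t_rel <- t_since_r(st, r_times)
    amp <- baseline + A * ifelse(is.na(t_rel) | t_rel <= 0, 0,
                                 t_rel^n * exp(-m * t_rel))
    if (any(amp <= 0)) abort("modulation parameters yield non-positive amplitudes.")
    if (noise_cv > 0) {
      amp <- amp * rlnorm(length(amp), meanlog = -noise_cv^2 / 2, sdlog = noise_cv)
    }
    out <- tibble::tibble(time_s = st, alpha_scaled = amp)
    attr(out, "r_times") <- r_times
    out
  })
}
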