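#' Detect R-wave times on an EKG channel
#'
#' Simple adaptive-threshold peak picking: local maxima exceeding 0.6 times
#' a rolling maximum of the rectified trace, with a 300 ms minimum
#' separation (no physiological heart beats faster). The threshold adapts to
#' the signal scale, so amplifier gain does not matter.
#'
#' @param ekg An `mer_recording` with `channel_role = "EKG"`.
#' @param frac Threshold as a fraction of the rolling maximum (default 0.6).
#' @param min_separation_s Minimum beat separation in seconds.
#' @param window_s Rolling-maximum window in seconds.
#'
#' @return Numeric vector of R-wave times in seconds (possibly empty, with a
#'   warning for a flat trace).
#' @export
detect_r_waves <- function(ekg, frac = 0.6, min_separation_s = 0.3, window_s = 2) {
  stopifnot(inherits(ekg, "mer_recording"))
  x <- ekg$samples
  rate <- ekg$rate
  n <- length(x)
  if (max(abs(x)) == 0) {
    warn("flat EKG trace: no R-waves detected.")
    return(numeric(0))
  }
  # rolling max of |x| over coarse blocks (interpolated), robust and O(n)
  block <- max(1L, round(window_s * rate / 8))
  nb <- ceiling(n / block)
  bmax <- vapply(seq_len(nb), function(b) {
    max(abs(x[((b - 1) * block + 1):min(n, b * block)]))
  }, numeric(1))
  # each block's threshold uses the max over its neighborhood (+-4 blocks)
  roll <- vapply(seq_len(nb), function(b) {
    max(bmax[max(1, b - 4):min(nb, b + 4)])
  }, numeric(1))
  thr <- frac * roll[pmin(nb, (seq_len(n) - 1L) %/% block + 1L)]

  above <- abs(x) > thr
  # local maxima of |x| among supra-threshold samples
  cand <- which(above)
  if (length(cand) == 0) return(numeric(0))
  # group contiguous runs, take the largest |x| in each
  breaks <- c(0, which(diff(cand) > 1), length(cand))
  peaks <- integer(length(breaks) - 1)
  for (g in seq_len(length(breaks) - 1)) {
    run <- cand[(breaks[g] + 1):breaks[g + 1]]
    peaks[g] <- run[which.max(abs(x[run]))]
  }
  # enforce minimum separation, keeping the larger peak
  min_sep <- round(min_separation_s * rate)
  keep <- rep(TRUE, length(peaks))
  last <- 1
  for (j in seq_along(peaks)[-1]) {
    if (peaks[j] - peaks[last] < min_sep) {
      if (abs(x[peaks[j]]) > abs(x[peaks[last]])) {
        keep[last] <- FALSE
        last <- j
      } else {
        keep[j] <- FALSE
      }
    } else {
      last <- j
    }
  }
  (peaks[keep] - 1) / rate
}

#' Cardiac-phase profile of per-spike amplitudes
#'
#' Each parameterized spike is referenced to its enclosing cardiac cycle:
#' the window from 0.1 s before to 0.9 s after the nearest preceding R-wave.
#' The scaled projection weights `alpha'` are binned by time relative to the
#' R-wave and averaged across all cycles; the pre-R baseline (mean `alpha'`
#' in \[-0.1, 0) s) is subtracted. Spikes falling in no cycle window (e.g.
#' before the first R-wave) are dropped and tallied.
#'
#' @param spike_times Spike times in seconds.
#' @param alpha_scaled Per-spike `alpha'` values (same length).
#' @param r_times R-wave times in seconds (>= 1).
#' @param window Two-element window around each R-wave in seconds.
#' @param n_bins Number of profile bins (default 50).
#'
#' @return A `cardiac_profile` list: `profile` tibble (`t_s` bin centers,
#'   `alpha_scaled` baselined bin means, `n` spikes per bin), `baseline`,
#'   `n_assigned`, `n_dropped`, `n_cycles`.
#' @export
cardiac_profile <- function(spike_times, alpha_scaled, r_times,
                            window = c(-0.1, 0.9), n_bins = 50) {
  if (length(r_times) < 1) abort("at least one R-wave time is required.")
  stopifnot(length(spike_times) == length(alpha_scaled))
  # relative time to the latest R-wave whose window contains the spike
  idx <- findInterval(spike_times - window[1], r_times)
  rel <- rep(NA_real_, length(spike_times))
  has <- idx >= 1
  rel[has] <- spike_times[has] - r_times[idx[has]]
  ok <- !is.na(rel) & rel >= window[1] & rel < window[2]
  n_dropped <- sum(!ok)
  if (!any(ok)) abort("no spikes fall inside any cardiac window.", class = "crpspike_empty_profile")
  rel <- rel[ok]
  a <- alpha_scaled[ok]
  edges <- seq(window[1], window[2], length.out = n_bins + 1)
  bin <- cut(rel, edges, include.lowest = TRUE, labels = FALSE)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  prof <- tibble::tibble(bin = bin, alpha = a) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(alpha_scaled = mean(.data$alpha), n = dplyr::n(), .groups = "drop")
  full <- tibble::tibble(bin = seq_len(n_bins), t_s = centers) |>
    dplyr::left_join(prof, by = "bin") |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
  baseline <- mean(a[rel < 0])
  if (is.nan(baseline)) baseline <- 0
  full$alpha_scaled <- full$alpha_scaled - baseline
  structure(
    list(profile = full[, c("t_s", "alpha_scaled", "n")], baseline = baseline,
         n_assigned = sum(ok), n_dropped = n_dropped,
         n_cycles = length(r_times), window = window),
    class = "cardiac_profile"
  )
}

#' Fit an impulse-response model to a cardiac profile
#'
#' Fits `A * t^n * exp(-m t)` to the baselined `alpha'` profile on the
#' post-R bins (`t > 0`) by nonlinear least squares, with a multi-start grid
#' over initial `(n, m)` to avoid local minima. Parameters are unbounded
#' (an unmodulated unit can fit with negative `m` and near-zero `R^2`).
#' A fit failing to converge from every start returns a failure result with
#' diagnostics rather than raising.
#'
#' @param profile A `cardiac_profile` (or a tibble with `t_s` and
#'   `alpha_scaled`).
#' @param n_starts_n,n_starts_m Initial-value grids for `n` and `m`.
#'
#' @return A `cardiac_fit` list: `A`, `n`, `m`, `r_squared`, `converged`,
#'   `profile`, `fitted`, `baseline`, `diagnostics`.
#' @export
fit_impulse_response <- function(profile,
                                 n_starts_n = c(0.5, 1, 2, 4),
                                 n_starts_m = c(1, 5, 10, 20)) {
  prof <- if (inherits(profile, "cardiac_profile")) profile$profile else profile
  baseline <- if (inherits(profile, "cardiac_profile")) profile$baseline else NA_real_
  df <- dplyr::filter(prof, .data$t_s > 0, !is.na(.data$alpha_scaled))
  if (nrow(df) < 5) abort("need at least 5 post-R bins with data to fit.")
  y <- df$alpha_scaled
  t <- df$t_s
  ss_tot <- sum((y - mean(y))^2)

  best <- NULL
  diags <- character(0)
  for (n0 in n_starts_n) {
    for (m0 in n_starts_m) {
      a0 <- max(abs(y)) / max(t^n0 * exp(-m0 * t))
      fit <- tryCatch(
        minpack.lm::nlsLM(
          y ~ A * t^n * exp(-m * t),
          start = list(A = a0, n = n0, m = m0),
          control = minpack.lm::nls.lm.control(maxiter = 200)
        ),
        error = function(e) e, warning = function(w) w
      )
      if (inherits(fit, "nls")) {
        rss <- sum(stats::resid(fit)^2)
        if (is.null(best) || rss < best$rss) {
          best <- list(fit = fit, rss = rss)
        }
      } else {
        diags <- c(diags, conditionMessage(fit))
      }
    }
  }
  if (is.null(best)) {
    return(structure(
      list(A = NA_real_, n = NA_real_, m = NA_real_, r_squared = NA_real_,
           converged = FALSE, profile = prof, fitted = NULL,
           baseline = baseline, diagnostics = unique(diags)),
      class = "cardiac_fit"
    ))
  }
  cf <- stats::coef(best$fit)
  r2 <- if (ss_tot > 0) 1 - best$rss / ss_tot else NA_real_
  structure(
    list(A = unname(cf["A"]), n = unname(cf["n"]), m = unname(cf["m"]),
         r_squared = r2, converged = TRUE, profile = prof,
         fitted = tibble::tibble(t_s = t, fitted = stats::fitted(best$fit)),
         baseline = baseline, diagnostics = character(0)),
    class = "cardiac_fit"
  )
}

#' @export
print.cardiac_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<cardiac_fit> did not converge\n")
    return(invisible(x))
  }
  cat(sprintf("<cardiac_fit> A = %.4g, n = %.3g, m = %.3g, R^2 = %.3f\n",
              x$A, x$n, x$m, x$r_squared))
  invisible(x)
}

#' @method tidy cardiac_fit
#' @export
tidy.cardiac_fit <- function(x, ...) {
  tibble::tibble(term = c("A", "n", "m"), estimate = c(x$A, x$n, x$m))
}

#' @method glance cardiac_fit
#' @export
glance.cardiac_fit <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, converged = x$converged,
                 baseline = x$baseline)
}

#' Plot a cardiac profile with its impulse-response fit
#'
#' @param object A `cardiac_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cardiac_fit
#' @export
autoplot.cardiac_fit <- function(object, ...) {
  p <- ggplot2::ggplot(object$profile, ggplot2::aes(.data$t_s, .data$alpha_scaled)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "Time from R-wave (s)",
                  y = expression(paste("Baselined ", alpha, "'")),
                  title = if (object$converged) {
                    sprintf("Impulse-response fit: R² = %.2f", object$r_squared)
                  } else "Impulse-response fit (not converged)") +
    ggplot2::theme_minimal()
  if (!is.null(object$fitted)) {
    p <- p + ggplot2::geom_line(data = object$fitted,
                                ggplot2::aes(.data$t_s, .data$fitted),
                                colour = "firebrick")
  }
  p
}
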