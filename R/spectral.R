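#' Welch power spectral density
#'
#' Averaged periodogram over Hann-windowed, 50%-overlapping segments
#' (1 s default). One-sided density normalization: the integral of the
#' density over frequency approximates the signal variance.
#'
#' @param rec An `mer_recording`.
#' @param segment_s Segment length in seconds.
#' @param overlap Fractional segment overlap in \[0, 1).
#'
#' @return A tibble with columns `freq_hz` and `power` (density, V^2/Hz).
#' @export
psd <- function(rec, segment_s = 1.0, overlap = 0.5) {
  stopifnot(inherits(rec, "mer_recording"))
  x <- rec$samples
  rate <- rec$rate
  nseg <- round(segment_s * rate)
  if (length(x) < nseg) abort("trace shorter than one PSD segment.")
  step <- max(1L, round(nseg * (1 - overlap)))
  starts <- seq(1L, length(x) - nseg + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq(0, nseg - 1) / (nseg - 1)))  # Hann
  u <- sum(w^2)
  nf <- floor(nseg / 2) + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)] * w
    sp <- abs(fft(seg)[seq_len(nf)])^2
    acc <- acc + sp
  }
  p <- acc / (length(starts) * u * rate)
  # one-sided: double everything except DC (and Nyquist when nseg even)
  dbl <- rep(2, nf)
  dbl[1] <- 1
  if (nseg %% 2 == 0) dbl[nf] <- 1
  tibble::tibble(freq_hz = (seq_len(nf) - 1) * rate / nseg, power = p * dbl)
}

#' Mean band power from a PSD
#'
#' Mean power density over the PSD bins inside `[lo, hi]` Hz. Mean (not
#' integrated) density keeps values comparable across bands of different
#' width.
#'
#' @param spectrum Tibble from [psd()].
#' @param lo,hi Band edges in Hz (default 200-300 Hz, the band where spike
#'   shape energy contaminates the LFP).
#'
#' @return Scalar mean density.
#' @export
band_power <- function(spectrum, lo = 200, hi = 300) {
  sel <- spectrum$freq_hz >= lo & spectrum$freq_hz <= hi
  if (!any(sel)) abort("no PSD bins inside the requested band.")
  mean(spectrum$power[sel])
}

#' Paired band-power comparison across recording sites
#'
#' Tests whether spike removal reduces band power across sites: a paired
#' t-test on per-site (raw, spike-removed) band-power pairs, with the
#' percent reduction `100 * mean(raw - residual) / mean(raw)`. Zero-variance
#' differences (e.g. residual identical to raw) flag the result as
#' degenerate and skip the test.
#'
#' @param raw_powers Per-site band power of the raw traces.
#' @param residual_powers Per-site band power of the spike-removed traces
#'   (same length >= 2).
#' @param band Band edges in Hz (metadata only).
#'
#' @return A `band_power_result` list: `sites` tibble, `band`, `t`, `df`,
#'   `p_value`, `percent_reduction`, `degenerate`.
#' @export
paired_band_power_test <- function(raw_powers, residual_powers, band = c(200, 300)) {
  n <- length(raw_powers)
  if (n < 2 || length(residual_powers) != n) {
    abort("need >= 2 sites with equal-length raw/residual power vectors.")
  }
  diffs <- raw_powers - residual_powers
  degenerate <- sd(diffs) == 0
  reduction <- 100 * mean(diffs) / mean(raw_powers)
  if (degenerate) {
    warn("zero-variance differences: paired t-test skipped.")
    tt <- list(statistic = NA_real_, parameter = n - 1, p.value = NA_real_)
  } else {
    tt <- t.test(raw_powers, residual_powers, paired = TRUE)
  }
  structure(
    list(
      sites = tibble::tibble(site = seq_len(n), raw = raw_powers,
                             residual = residual_powers, difference = diffs),
      band = band,
      t = unname(tt$statistic), df = unname(tt$parameter),
      p_value = tt$p.value, percent_reduction = reduction,
      degenerate = degenerate
    ),
    class = "band_power_result"
  )
}

#' @export
print.band_power_result <- function(x, ...) {
  cat(sprintf("<band_power_result> %g-%g Hz, %d sites: %.1f%% reduction",
              x$band[1], x$band[2], nrow(x$sites), x$percent_reduction))
  if (x$degenerate) {
    cat(" (degenerate: zero-variance differences)\n")
  } else {
    cat(sprintf(", t(%d) = %.2f, p = %.4g\n", x$df, x$t, x$p_value))
  }
  invisible(x)
}

#' @method tidy band_power_result
#' @export
tidy.band_power_result <- function(x, ...) x$sites

#' @method glance band_power_result
#' @export
glance.band_power_result <- function(x, ...) {
  tibble::tibble(statistic = x$t, df = x$df, p_value = x$p_value,
                 percent_reduction = x$percent_reduction,
                 degenerate = x$degenerate)
}

#' Plot per-site band power before and after spike removal
#'
#' @param object A `band_power_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot band_power_result
#' @export
autoplot.band_power_result <- function(object, ...) {
  df <- tidyr::pivot_longer(object$sites, c("raw", "residual"),
                            names_to = "signal", values_to = "power")
  ggplot2::ggplot(df, ggplot2::aes(.data$signal, .data$power, group = .data$site)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$signal), size = 2) +
    ggplot2::scale_colour_manual(values = c(raw = "black", residual = "forestgreen"),
                                 guide = "none") +
    ggplot2::labs(x = NULL, y = sprintf("%g-%g Hz band power", object$band[1], object$band[2]),
                  title = sprintf("Spike removal: %.1f%% band-power reduction",
                                  object$percent_reduction)) +
    ggplot2::theme_minimal()
}
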