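#' Create a single-channel recording object
#'
#' Container for one voltage trace: the sampled signal, its rate, the channel
#' role (microelectrode or EKG), and optional site metadata (depth along the
#' surgical trajectory, site identifier).
#'
#' @param samples Numeric vector of voltages. Must be finite.
#' @param rate Sampling rate in Hz (default 44000, the clinical MER rate).
#' @param channel_role `"MER"` (microelectrode) or `"EKG"`.
#' @param depth_mm Electrode depth in millimetres relative to the surgical
#'   target (negative = below target), or `NA` if unknown.
#' @param site_id Character label for the recording site.
#'
#' @return An object of class `mer_recording`.
#' @export
recording <- function(samples, rate = 44000, channel_role = c("MER", "EKG"),
                      depth_mm = NA_real_, site_id = "site1") {
  channel_role <- match.arg(channel_role)
  samples <- as.numeric(samples)
  if (length(samples) == 0L) abort("`samples` must be non-empty.")
  if (!all(is.finite(samples))) abort("`samples` must be finite.")
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    abort("`rate` must be a single positive number.")
  }
  depth_mm <- if (length(depth_mm) != 1) NA_real_ else as.numeric(depth_mm)
  structure(
    list(samples = samples, rate = rate, channel_role = channel_role,
         depth_mm = depth_mm, site_id = site_id),
    class = "mer_recording"
  )
}

#' @export
print.mer_recording <- function(x, ...) {
  dur <- length(x$samples) / x$rate
  cat(sprintf("<mer_recording> %s channel, %.3f s at %g Hz (%d samples)\n",
              x$channel_role, dur, x$rate, length(x$samples)))
  if (!is.na(x$depth_mm)) cat(sprintf("  site %s at %.2f mm from target\n", x$site_id, x$depth_mm))
  invisible(x)
}

#' @export
length.mer_recording <- function(x) length(x$samples)

#' Duration of a recording in seconds
#' @param rec An `mer_recording`.
#' @return Duration in seconds.
#' @export
rec_duration <- function(rec) length(rec$samples) / rec$rate

#' Convert a recording to a tibble
#'
#' @param x An `mer_recording`.
#' @param ... Unused.
#' @return A tibble with columns `time_s` and `voltage`.
#' @method as_tibble mer_recording
#' @export
as_tibble.mer_recording <- function(x, ...) {
  tibble::tibble(time_s = (seq_along(x$samples) - 1) / x$rate, voltage = x$samples)
}

#' Plot a recording trace
#'
#' @param object An `mer_recording`.
#' @param t_lim Optional two-element time window (seconds) to restrict the plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mer_recording
#' @export
autoplot.mer_recording <- function(object, t_lim = NULL, ...) {
  df <- as_tibble.mer_recording(object)
  if (!is.null(t_lim)) df <- dplyr::filter(df, .data$time_s >= t_lim[1], .data$time_s <= t_lim[2])
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$voltage)) +
    ggplot2::geom_line(linewidth = 0.25) +
    ggplot2::labs(x = "Time (s)", y = "Voltage",
                  title = sprintf("%s trace (%s)", object$channel_role, object$site_id)) +
    ggplot2::theme_minimal()
}
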