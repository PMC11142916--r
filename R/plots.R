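# ggplot2 visualisations of traces, segmentations and fits.

#' @export
autoplot.angular_trace <- function(object, max_points = 2e5, ...) {
  d <- object
  if (nrow(d) > max_points) {
    d <- d[seq(1L, nrow(d), length.out = max_points), ]
  }
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$time_s)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$angle_rad), colour = "grey70",
                       linewidth = 0.2) +
    ggplot2::labs(x = "time (s)", y = "rotor angle (rad)")
  if (!is.null(d$angle_filt_rad)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$angle_filt_rad),
                                colour = "firebrick", linewidth = 0.4)
  }
  p
}

#' @export
autoplot.state_segmentation <- function(object, ...) {
  d <- tibble(time_s = object$time_bin_s, angle_rad = object$y_bin,
              state = object$labels_bin)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_s, y = .data$angle_rad,
                                  colour = .data$state)) +
    ggplot2::geom_point(size = 0.3) +
    ggplot2::geom_hline(yintercept = object$levels, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::scale_colour_manual(
      values = c(free = "grey55", bound = "firebrick",
                 translocating = "steelblue"),
      drop = FALSE) +
    ggplot2::labs(x = "time (s)", y = "filtered angle (rad)", colour = NULL)
}

#' @export
autoplot.gauss_mix_fit <- function(object, data = NULL, ...) {
  xs <- if (!is.null(data)) range(data) else
    range(object$means + 3 * c(-1, 1) * max(object$sds))
  grid <- seq(xs[1L], xs[2L], length.out = 400)
  dens <- rowSums(vapply(seq_len(object$K), function(k) {
    object$weights[k] * dnorm(grid, object$means[k], object$sds[k])
  }, numeric(length(grid))))
  p <- ggplot2::ggplot()
  if (!is.null(data)) {
    p <- p + ggplot2::geom_histogram(
      data = tibble(x = data),
      ggplot2::aes(x = .data$x, y = ggplot2::after_stat(density)),
      bins = 30, fill = "grey80", colour = "grey50")
  }
  p + ggplot2::geom_line(data = tibble(x = grid, d = dens),
                         ggplot2::aes(x = .data$x, y = .data$d),
                         colour = "firebrick") +
    ggplot2::labs(x = "value", y = "density")
}

#' @export
autoplot.exp_mix_fit <- function(object, data = NULL, ...) {
  tmax <- max(object$lifetimes) * 4
  grid <- seq(0, tmax, length.out = 400)
  surv <- rowSums(vapply(seq_len(object$K), function(k) {
    object$weights[k] * exp(-grid / object$lifetimes[k])
  }, numeric(length(grid))))
  p <- ggplot2::ggplot()
  if (!is.null(data)) {
    d <- sort(data)
    emp <- tibble(t = d, s = 1 - (seq_along(d) - 0.5) / length(d))
    p <- p + ggplot2::geom_step(data = emp,
                                ggplot2::aes(x = .data$t, y = .data$s),
                                colour = "grey50")
  }
  p + ggplot2::geom_line(data = tibble(t = grid, s = surv),
                         ggplot2::aes(x = .data$t, y = .data$s),
                         colour = "firebrick") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "dwell time (s)", y = "survival probability")
}

#' @export
autoplot.exp_phase_fit <- function(object, ...) {
  if (is.null(object$data)) abort("fit carries no data to plot.")
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$time_s)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$signal), size = 0.3,
                        colour = "grey60") +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "firebrick") +
    ggplot2::labs(x = "time (s)", y = "signal")
}

#' Plot event-size and rate histograms
#'
#' @param events A classified event table.
#' @return A patchwork-free two-panel ggplot (faceted).
#' @export
plot_event_distributions <- function(events) {
  d <- tidyr::pivot_longer(
    events[, c("max_loop_size_bp", "rate_bp_s")],
    cols = dplyr::everything(),
    names_to = "quantity", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 25, fill = "steelblue", colour = "grey30") +
    ggplot2::facet_wrap(~.data$quantity, scales = "free") +
    ggplot2::labs(x = NULL, y = "events")
}

#' Plot a kymograph with an optional track overlay
#'
#' @param kymo Intensity matrix (one scan line per row).
#' @param track Optional [build_track()] tibble.
#' @param line_time,pixel_size Axis scaling.
#' @return A ggplot.
#' @export
plot_kymograph <- function(kymo, track = NULL, line_time = 0.028,
                           pixel_size = 100) {
  d <- expand.grid(line = seq_len(nrow(kymo)), px = seq_len(ncol(kymo)))
  d$intensity <- as.vector(kymo)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = (.data$px - 1) * pixel_size / 1000,
                                       y = (.data$line - 1) * line_time)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "position (um)", y = "time (s)", fill = "counts")
  if (!is.null(track)) {
    p <- p + ggplot2::geom_path(
      data = track,
      ggplot2::aes(x = .data$position_px * pixel_size / 1000,
                   y = .data$time_s),
      colour = "white", linewidth = 0.3, na.rm = TRUE)
  }
  p
}
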