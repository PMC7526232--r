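#' Plot ROC operating points
#'
#' Draws `(1 - NPA, PPA)` for each operating point, in increasing cutoff
#' order, faceted by device and sound type for evaluation objects.
#'
#' @param object An `auscultr_roc` tibble from [roc()] or an `auscultr_eval`
#'   from [evaluate_scores()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.auscultr_roc <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = 1 - .data$npa, y = .data$ppa)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey60") +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "1 - NPA", y = "PPA") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.auscultr_roc
#' @exportS3Method ggplot2::autoplot
autoplot.auscultr_eval <- function(object, ...) {
  pts <- tidy(object)
  ggplot2::ggplot(pts, ggplot2::aes(x = 1 - .data$npa, y = .data$ppa)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey60") +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::facet_grid(ggplot2::vars(.data$sound),
                        ggplot2::vars(.data$device)) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "1 - NPA", y = "PPA") +
    ggplot2::theme_minimal()
}

#' Plot a waveform
#'
#' Quick amplitude-versus-time line plot, with optional ground-truth event
#' overlays.
#'
#' @param w A [waveform()].
#' @param events Optional list of [acoustic_event()] objects to shade.
#' @return A ggplot object.
#' @export
plot_waveform <- function(w, events = NULL) {
  stopifnot(is_waveform(w))
  d <- tibble::tibble(time_s = wave_times(w), amplitude = w$samples)
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$time_s, .data$amplitude)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::labs(x = "time (s)", y = "amplitude") +
    ggplot2::theme_minimal()
  if (!is.null(events) && length(events)) {
    ev <- tibble::tibble(
      xmin = vapply(events, `[[`, numeric(1), "onset_s"),
      xmax = vapply(events, function(e) e$onset_s + e$duration_s, numeric(1)),
      kind = vapply(events, `[[`, character(1), "kind")
    )
    p <- p + ggplot2::geom_rect(
      data = ev,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax, ymin = -Inf,
                   ymax = Inf, fill = .data$kind),
      alpha = 0.2, inherit.aes = FALSE
    )
  }
  p
}
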