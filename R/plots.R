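#' Plot group-average BOLD time courses
#'
#' Overlays group/condition mean responses per region with a ribbon of
#' plus/minus one standard error, shading the inform-cue and stimulation
#' periods of the paradigm.
#'
#' @param avg Output of [average_runs()].
#' @param paradigm A `bold_paradigm` (for TR and event timing).
#' @param colour Column mapped to colour (default `"group"` when present).
#' @return A ggplot object.
#' @export
plot_timecourses <- function(avg, paradigm, colour = NULL) {
  if (is.null(colour)) {
    colour <- intersect(c("group", "condition"), names(avg))[1]
  }
  d <- dplyr::mutate(avg, time = .data$t * paradigm$TR)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$mean))
  p <- p + ggplot2::annotate(
    "rect", xmin = paradigm$inform_time, xmax = paradigm$inform_time + 10,
    ymin = -Inf, ymax = Inf, fill = "gold", alpha = 0.3)
  if (paradigm$stim_duration > 0) {
    p <- p + ggplot2::annotate(
      "rect", xmin = paradigm$stimulus_onset,
      xmax = paradigm$stimulus_onset + paradigm$stim_duration,
      ymin = -Inf, ymax = Inf, fill = "darkgreen", alpha = 0.2)
  }
  if (!is.na(colour)) {
    p <- p +
      ggplot2::geom_ribbon(
        ggplot2::aes(ymin = .data$mean - .data$sem,
                     ymax = .data$mean + .data$sem,
                     group = .data[[colour]]), alpha = 0.2) +
      ggplot2::geom_line(ggplot2::aes(colour = .data[[colour]]))
  } else {
    p <- p +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                        ymax = .data$mean + .data$sem),
                           alpha = 0.2) +
      ggplot2::geom_line()
  }
  p + ggplot2::facet_wrap(~region, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "BOLD (% signal change)")
}

#' Plot a fitted signaling model
#'
#' Bar chart of the fitted DB value per connection (positive = excitatory
#' input, negative = inhibitory), with latent-input edges marked.
#'
#' @param object An `sapm_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sapm_fit
#' @export
autoplot.sapm_fit <- function(object, ...) {
  d <- tidy(object)
  d$connection <- factor(d$connection, levels = rev(d$connection))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$DB, y = .data$connection,
                                  fill = .data$type)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "DB (connectivity weighting)", y = NULL,
                  title = sprintf("%s network fit (mean R2 = %.2f)",
                                  object$network$name,
                                  mean(object$R2$R2, na.rm = TRUE)))
}

#' Plot group-average pupil traces
#'
#' @param avg Output of [average_trace()].
#' @return A ggplot object.
#' @export
plot_pupil <- function(avg) {
  ggplot2::ggplot(avg, ggplot2::aes(x = .data$time, y = .data$mean,
                                    colour = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem,
                                      fill = .data$group),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "pupil area (pixel units)")
}
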