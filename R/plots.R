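#' Plot methods for result objects
#'
#' `autoplot()` methods give each result type a standard ggplot2 display:
#' the shift-sweep accuracy curve, the distribution of cross-validated
#' prediction accuracies, the explained-variance scree of the semantic
#' components, and the layer-wise representational-similarity curve with its
#' bootstrap band. `plot_activation()` draws a cluster activation time course
#' with its permutation-null thresholds and the selected peak/dip frames.
#'
#' @param object the result object.
#' @param ... unused.
#' @return a ggplot object.
#' @name semenc-plots
NULL

#' @rdname semenc-plots
#' @export
autoplot.shift_sweep <- function(object, ...) {
  df <- object$curve
  ggplot2::ggplot(df, ggplot2::aes(x = .data$shift)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$n_significant / max(1, max(.data$n_significant)) *
                                     max(.data$mean_r_all, na.rm = TRUE)),
                      fill = "grey80", width = 0.8 / object$frame_rate) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean_r_significant), colour = "firebrick") +
    ggplot2::geom_vline(xintercept = object$best_shift, linetype = 2) +
    ggplot2::labs(x = "stimulus-response shift (s)",
                  y = "mean r over significant electrodes",
                  title = sprintf("Best shift: %g s", object$best_shift)) +
    ggplot2::theme_minimal()
}

#' @rdname semenc-plots
#' @export
autoplot.encoding_fit <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r_cv, fill = .data$significant)) +
    ggplot2::geom_histogram(bins = 30, colour = "white") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "cross-validated r", y = "electrodes",
                  title = sprintf("Encoding accuracy at %g s shift", object$time_shift)) +
    ggplot2::theme_minimal()
}

#' @rdname semenc-plots
#' @export
autoplot.semantic_components <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component,
                                   y = 100 * .data$explained_variance_ratio)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "semantic component", y = "% variance explained") +
    ggplot2::theme_minimal()
}

#' @rdname semenc-plots
#' @export
autoplot.rsa_result <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$idx <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$idx, y = .data$similarity)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lower, ymax = .data$ci_upper),
                         fill = "grey80") +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = df$idx, labels = df$layer) +
    ggplot2::labs(x = NULL, y = "similarity with semantic components") +
    ggplot2::theme_minimal()
}

#' @rdname semenc-plots
#' @param selection a `peak_dip_selection`.
#' @param frame_rate frames per second for the time axis (default 25).
#' @export
plot_activation <- function(selection, frame_rate = 25) {
  df <- tibble::tibble(time = seq_along(selection$activation) / frame_rate,
                       activation = selection$activation,
                       sem = selection$sem_band)
  marks <- tibble::tibble(
    time = c(selection$peak_frames, selection$dip_frames) / frame_rate,
    activation = selection$activation[c(selection$peak_frames, selection$dip_frames)],
    kind = rep(c("peak", "dip"),
               c(length(selection$peak_frames), length(selection$dip_frames))))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$activation)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$activation - .data$sem,
                                      ymax = .data$activation + .data$sem),
                         fill = "grey85") +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = c(selection$lower_threshold,
                                       selection$upper_threshold),
                        linetype = 3) +
    ggplot2::geom_point(data = marks, ggplot2::aes(colour = .data$kind), size = 1) +
    ggplot2::scale_colour_manual(values = c(peak = "firebrick", dip = "navy")) +
    ggplot2::labs(x = "time (s)", y = "exemplar activation") +
    ggplot2::theme_minimal()
}
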