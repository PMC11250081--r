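# ggplot2 views of the main result types.

#' Plot a trial tensor as channel traces
#'
#' One line per landmark, faceted by coordinate, over the 128
#' normalized time samples.
#'
#' @param object a `trial_tensor`.
#' @param coords coordinates to show (default all three).
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.trial_tensor <- function(object, coords = c("x", "y", "z"), ...) {
  df <- tidy.trial_tensor(object)
  df <- df[df$coord %in% coords, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample, y = .data$value,
                                   group = .data$landmark_id,
                                   colour = factor(.data$landmark_id))) +
    ggplot2::geom_line(linewidth = 0.3, show.legend = FALSE) +
    ggplot2::facet_wrap(~coord, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "normalized time sample", y = "normalized coordinate") +
    ggplot2::theme_minimal()
}

#' Plot a detector's error distributions against its threshold
#'
#' @param object a `dystonia_detector`.
#' @param new_scores optional tibble from [predict.dystonia_detector()]
#'   to overlay (e.g. patient trials).
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.dystonia_detector <- function(object, new_scores = NULL, ...) {
  df <- tibble::tibble(error = object$validation_errors,
                       set = "healthy validation")
  if (!is.null(new_scores)) {
    df <- dplyr::bind_rows(df, tibble::tibble(
      error = new_scores$error,
      set = ifelse(is.na(new_scores$group), "new", new_scores$group)))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$error, fill = .data$set)) +
    ggplot2::geom_histogram(bins = 30, alpha = 0.7, position = "identity") +
    ggplot2::geom_vline(xintercept = object$calibration$threshold,
                        linetype = "dashed") +
    ggplot2::labs(x = "reconstruction error (MSE)", y = "trials",
                  fill = NULL,
                  subtitle = "dashed line: mean + 2 SD threshold") +
    ggplot2::theme_minimal()
}

#' Plot a ZEST staircase
#'
#' SOA placement per trial, marked by response correctness, with the
#' final threshold estimate.
#'
#' @param object a `toj_result`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.toj_result <- function(object, ...) {
  df <- object$state$trials
  ggplot2::ggplot(df, ggplot2::aes(x = .data$trial, y = .data$soa_ms)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$correct)) +
    ggplot2::geom_hline(yintercept = object$threshold_ms, linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "trial", y = "SOA (ms)", colour = "correct",
                  subtitle = sprintf("TOJ threshold %.1f ms",
                                     object$threshold_ms)) +
    ggplot2::theme_minimal()
}

#' Plot group asymmetry comparisons
#'
#' Per-subject left-right asymmetry norms by function and group, with
#' BH-adjusted p-values in the facet strips.
#'
#' @param object an `asymmetry_comparison`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.asymmetry_comparison <- function(object, ...) {
  asym <- attr(object, "asymmetries")
  lab <- stats::setNames(
    sprintf("%s\nadj. p = %.3f", object$fn, object$p_adj), object$fn)
  ggplot2::ggplot(asym, ggplot2::aes(x = .data$group, y = .data$assym,
                                     colour = .data$group)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, show.legend = FALSE) +
    ggplot2::stat_summary(fun = stats::median, geom = "crossbar",
                          width = 0.4, show.legend = FALSE) +
    ggplot2::facet_wrap(~fn, scales = "free_y",
                        labeller = ggplot2::labeller(fn = lab)) +
    ggplot2::labs(x = NULL, y = "left-right asymmetry (z-profile norm)") +
    ggplot2::theme_minimal()
}
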