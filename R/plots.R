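# ggplot2 displays for validation results.

#' Box plot of candidate-minus-reference differences per joint
#'
#' Whiskers end at the most extreme points within 1.5 IQR of the quartiles;
#' outliers beyond the whiskers are drawn only when `show_outliers = TRUE`.
#'
#' @param result A `pose_validation` object.
#' @param show_outliers Draw points beyond the whiskers?
#' @return A ggplot object.
#' @export
plot_difference_boxes <- function(result, show_outliers = FALSE) {
  box <- result$boxplot
  p <- ggplot2::ggplot(box, ggplot2::aes(x = .data$joint)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$whisker_low, ymax = .data$whisker_high),
      width = 0.3
    ) +
    ggplot2::geom_boxplot(
      ggplot2::aes(ymin = .data$whisker_low, lower = .data$q1,
                   middle = .data$median, upper = .data$q3,
                   ymax = .data$whisker_high),
      stat = "identity", width = 0.6
    ) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "candidate - reference (degrees)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if (show_outliers) {
    pts <- box |>
      dplyr::select("joint", "outliers") |>
      tidyr::unnest("outliers")
    if (nrow(pts) > 0) {
      p <- p + ggplot2::geom_point(
        data = pts, ggplot2::aes(y = .data$outliers),
        shape = 1, alpha = 0.4
      )
    }
  }
  p
}

#' Dot plot of per-video ICC values per joint
#'
#' Dashed line at 0.75, the lower edge of the "excellent" Fleiss band.
#'
#' @param result A `pose_validation` object run with `per_video = TRUE`.
#' @return A ggplot object.
#' @export
plot_per_video_icc <- function(result) {
  stopifnot(!is.null(result$per_video_icc))
  ggplot2::ggplot(
    result$per_video_icc,
    ggplot2::aes(x = .data$joint, y = .data$icc)
  ) +
    ggplot2::geom_point(position = ggplot2::position_jitter(width = 0.12,
                                                            height = 0),
                        alpha = 0.7) +
    ggplot2::geom_hline(yintercept = 0.75, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "ICC(A,2) per video") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Cross-correlation functions per joint
#'
#' One panel per joint; dotted lines mark the `+/- 1.96 / sqrt(n)`
#' significance band.
#'
#' @param result A `pose_validation` object.
#' @return A ggplot object.
#' @export
plot_ccf <- function(result) {
  ggplot2::ggplot(result$ccf, ggplot2::aes(x = .data$lag, y = .data$ccf)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$lag, yend = 0)) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$conf_bound),
                        linetype = "dotted", color = "blue") +
    ggplot2::geom_hline(ggplot2::aes(yintercept = -.data$conf_bound),
                        linetype = "dotted", color = "blue") +
    ggplot2::facet_wrap(~joint) +
    ggplot2::labs(x = "lag (frames)", y = "cross-correlation") +
    ggplot2::theme_minimal()
}

#' Autoplot method for pose_validation objects
#'
#' @param object A `pose_validation` object.
#' @param type `"differences"` (box plot), `"icc"` (per-video dot plot), or
#'   `"ccf"`.
#' @param ... Passed to the underlying `plot_*` function.
#' @return A ggplot object.
#' @method autoplot pose_validation
#' @export
autoplot.pose_validation <- function(object,
                                     type = c("differences", "icc", "ccf"),
                                     ...) {
  type <- match.arg(type)
  switch(type,
    differences = plot_difference_boxes(object, ...),
    icc = plot_per_video_icc(object),
    ccf = plot_ccf(object)
  )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
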