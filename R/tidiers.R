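# broom-style accessors for pose_validation objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a pose_validation object
#'
#' @param x A `pose_validation` object from [run_validation()].
#' @param ... Unused.
#' @return The per-joint agreement panel as a tibble (one row per joint).
#' @method tidy pose_validation
#' @export
tidy.pose_validation <- function(x, ...) {
  x$agreement
}

#' One-row summary of a pose_validation object
#'
#' @param x A `pose_validation` object.
#' @param ... Unused.
#' @return A one-row tibble: joint and pair counts, bias extremes, ICC
#'   range, worst per-video ICC, and whether every joint peaked at lag 0.
#' @method glance pose_validation
#' @export
glance.pose_validation <- function(x, ...) {
  ok <- x$agreement[is.na(x$agreement$error), ]
  tibble::tibble(
    n_joints = nrow(x$agreement),
    n_pairs = x$paired_n,
    max_abs_bias = max(abs(ok$bias)),
    icc_min = min(ok$icc),
    icc_max = max(ok$icc),
    per_video_icc_min = if (!is.null(x$per_video_icc)) {
      min(x$per_video_icc$icc, na.rm = TRUE)
    } else NA_real_,
    all_lag_zero = all(x$ccf_best$best_lag == 0)
  )
}
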