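# Intraclass correlation ICC(A,k): two-way model, absolute agreement,
# average of k = 2 measurements (McGraw & Wong nomenclature), with the
# F-based confidence interval.

#' Intraclass correlation ICC(A,2) with confidence interval
#'
#' Two-way ANOVA decomposition of the n-by-2 matrix of paired measurements
#' (subjects = paired frames, raters = candidate and reference):
#' \deqn{ICC(A,k) = \frac{MS_R - MS_E}{MS_R + (MS_C - MS_E)/n}}
#' with k = 2, where \eqn{MS_R}, \eqn{MS_C}, \eqn{MS_E} are the row
#' (subject), column (rater), and residual mean squares. This is the
#' absolute-agreement, average-measures form: a constant offset between the
#' two raters strictly lowers it. The confidence interval is the McGraw &
#' Wong F-based interval for single measures transformed to average measures
#' by the Spearman-Brown relation.
#'
#' @param candidate,reference Equal-length numeric vectors (n >= 3 pairs).
#' @param conf_level Confidence level of the interval (default 0.95).
#' @return A one-row tibble: `icc`, `icc_ci_low`, `icc_ci_high`.
#' @references McGraw, K.O. & Wong, S.P. (1996). Forming inferences about
#'   some intraclass correlation coefficients. Psychological Methods, 1(1).
#' @examples
#' set.seed(1)
#' r <- rnorm(50, 90, 10)
#' icc_a2(r + rnorm(50, 0, 2), r)
#' @export
icc_a2 <- function(candidate, reference, conf_level = 0.95) {
  stopifnot(length(candidate) == length(reference),
            is.numeric(candidate), is.numeric(reference),
            conf_level > 0, conf_level < 1)
  if (anyNA(candidate) || anyNA(reference)) {
    stop_poseagree("ICC input contains missing values",
                   "poseagree_insufficient_data_error")
  }
  n <- length(candidate)
  if (n < 3L) {
    stop_poseagree("ICC requires at least 3 paired observations",
                   "poseagree_insufficient_data_error")
  }
  k <- 2
  x <- cbind(candidate, reference)
  grand <- mean(x)
  rowm <- (candidate + reference) / 2
  colm <- colMeans(x)
  ssr <- k * sum((rowm - grand)^2)
  ssc <- n * sum((colm - grand)^2)
  sst <- sum((x - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (msr <= 0) {
    stop_poseagree(
      "zero between-subject variance: ICC undefined (all paired frames equal)",
      "poseagree_degenerate_error"
    )
  }
  icc <- (msr - mse) / (msr + (msc - mse) / n)
  if (mse <= 0 && msc <= 0) {
    # perfect agreement: interval degenerates at 1
    return(tibble::tibble(icc = icc, icc_ci_low = icc, icc_ci_high = icc))
  }
  # single-measures estimate and its F-based interval (McGraw & Wong), then
  # Spearman-Brown step up to average measures
  r1 <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  a <- k * r1 / (n * (1 - r1))
  b <- 1 + k * r1 * (n - 1) / (n * (1 - r1))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  alpha <- 1 - conf_level
  f_l <- qf(1 - alpha / 2, n - 1, v)
  f_u <- qf(1 - alpha / 2, v, n - 1)
  l1 <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  u1 <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  step_up <- function(r) r * k / (1 + (k - 1) * r)
  tibble::tibble(
    icc = icc,
    icc_ci_low = step_up(l1),
    icc_ci_high = step_up(u1)
  )
}

#' Classify an ICC value on the Fleiss scale
#'
#' Bands: below 0.40 poor; 0.40 up to (but excluding) 0.75 fair to good;
#' 0.75 and above excellent.
#'
#' @param icc Numeric ICC value(s) in `[-1, 1]`.
#' @return Character vector: `"poor"`, `"fair-to-good"`, or `"excellent"`.
#' @examples
#' classify_icc(c(0.39, 0.5, 0.951))
#' @export
classify_icc <- function(icc) {
  stopifnot(is.numeric(icc), all(is.na(icc) | (icc >= -1 & icc <= 1)))
  dplyr::case_when(
    is.na(icc) ~ NA_character_,
    icc < 0.40 ~ "poor",
    icc < 0.75 ~ "fair-to-good",
    TRUE ~ "excellent"
  )
}

#' Per-video ICC(A,2) table
#'
#' Applies [icc_a2()] within each (video, joint) group of a paired tibble.
#' Groups whose ICC falls below 0.75 (less than excellent on the Fleiss
#' scale) are flagged. A group whose ICC is undefined is reported with an
#' `error` message and does not abort the other groups.
#'
#' @param paired A paired tibble from [pair_angles()].
#' @param conf_level Confidence level for per-group intervals.
#' @return A tibble with one row per (video, joint): `n`, `icc`,
#'   `icc_ci_low`, `icc_ci_high`, `icc_class`, `flag_low`, `error`.
#' @export
per_video_icc <- function(paired, conf_level = 0.95) {
  check_columns(paired, c("video_id", "joint", "candidate", "reference"),
                "paired tibble")
  paired |>
    dplyr::group_by(.data$video_id, .data$joint) |>
    dplyr::group_modify(function(g, key) {
      res <- tryCatch(
        icc_a2(g$candidate, g$reference, conf_level),
        poseagree_error = function(e) {
          tibble::tibble(icc = NA_real_, icc_ci_low = NA_real_,
                         icc_ci_high = NA_real_) |>
            dplyr::mutate(error = conditionMessage(e))
        }
      )
      if (!"error" %in% names(res)) res$error <- NA_character_
      dplyr::mutate(res, n = nrow(g), .before = 1)
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      icc_class = classify_icc(.data$icc),
      flag_low = !is.na(.data$icc) & .data$icc < 0.75
    )
}
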