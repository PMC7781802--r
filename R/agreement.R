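# The agreement panel: bias, error metrics, ICC, box-plot statistics.

#' Bias (mean difference) statistics
#'
#' For differences `d = candidate - reference`: the mean (bias), the sample
#' standard deviation (n - 1 denominator), the standard error of the mean,
#' and the normal-approximation 95% interval `bias +/- 1.96 se`. The normal
#' multiplier (not Student-t) is used; at the pair counts this panel is
#' designed for the two coincide to well below the reported precision.
#'
#' @param d Numeric vector of paired differences, length >= 2.
#' @return A one-row tibble: `n`, `bias`, `sd`, `se`, `ci_low`, `ci_high`.
#' @examples
#' bias_stats(c(1.2, -0.3, 0.8, 0.1))
#' @export
bias_stats <- function(d) {
  stopifnot(is.numeric(d))
  if (anyNA(d) || length(d) < 2L) {
    stop_poseagree("bias_stats needs >= 2 complete differences",
                   "poseagree_insufficient_data_error")
  }
  n <- length(d)
  bias <- mean(d)
  s <- sd(d)
  se <- s / sqrt(n)
  tibble::tibble(
    n = n, bias = bias, sd = s, se = se,
    ci_low = bias - 1.96 * se, ci_high = bias + 1.96 * se
  )
}

#' Error metrics for paired angle series
#'
#' * `mae` — mean absolute difference.
#' * `mad` — by default the median absolute deviation of the differences
#'   about their median (robust scale, no consistency constant);
#'   `mad_type = "mean"` gives the mean absolute deviation about the mean.
#' * `rmse` — root mean squared difference.
#' * `smape` — symmetric mean absolute percentage error in percent, with the
#'   half-sum denominator `(|c| + |r|)/2`, bounded in `[0, 200]`; a summand
#'   with `c = r = 0` is defined as 0.
#'
#' @param candidate,reference Equal-length numeric vectors.
#' @param mad_type `"median"` (default) or `"mean"`, see above.
#' @return A one-row tibble: `mae`, `mad`, `rmse`, `smape`.
#' @examples
#' error_metrics(c(10, 20, 30), c(12, 19, 33))
#' @export
error_metrics <- function(candidate, reference, mad_type = c("median", "mean")) {
  mad_type <- match.arg(mad_type)
  stopifnot(is.numeric(candidate), is.numeric(reference),
            length(candidate) == length(reference), length(candidate) >= 1L,
            !anyNA(candidate), !anyNA(reference))
  d <- candidate - reference
  denom <- (abs(candidate) + abs(reference)) / 2
  sm <- abs(d) / denom
  sm[denom == 0] <- 0
  tibble::tibble(
    mae = mean(abs(d)),
    mad = if (mad_type == "median") median(abs(d - median(d)))
          else mean(abs(d - mean(d))),
    rmse = sqrt(mean(d^2)),
    smape = 100 * mean(sm)
  )
}

#' RMSE from bias, SD, and pair count
#'
#' Internal-consistency identity linking the panel columns: with bias
#' \eqn{\bar d}, sample SD \eqn{s} (n - 1 denominator), and n pairs,
#' \deqn{RMSE = \sqrt{\bar d^2 + s^2 (n-1)/n}.}
#' Equals the RMSE of the underlying differences exactly.
#'
#' @param bias Mean difference in degrees.
#' @param sd Sample standard deviation of the differences.
#' @param n Number of pairs (>= 2).
#' @return RMSE in degrees.
#' @examples
#' rmse_from_moments(0.15, 2.03, 30000)
#' @export
rmse_from_moments <- function(bias, sd, n) {
  stopifnot(is.numeric(bias), is.numeric(sd), all(sd >= 0), all(n >= 2))
  sqrt(bias^2 + sd^2 * (n - 1) / n)
}

#' Box-plot statistics with 1.5 IQR whiskers
#'
#' Median and quartiles by the linear-interpolation quantile rule (R type 7);
#' whiskers at the most extreme data points within
#' `[q1 - 1.5 IQR, q3 + 1.5 IQR]`; outliers are the points beyond the
#' whiskers.
#'
#' @param x Non-empty numeric vector (typically paired differences).
#' @return A one-row tibble: `n`, `median`, `q1`, `q3`, `iqr`,
#'   `whisker_low`, `whisker_high`, and a list column `outliers`.
#' @examples
#' boxplot_stats(c(1:100, 1000))
#' @export
boxplot_stats <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 1L, !anyNA(x))
  q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[3] + 1.5 * iqr
  inside <- x[x >= lo & x <= hi]
  tibble::tibble(
    n = length(x),
    median = q[2], q1 = q[1], q3 = q[3], iqr = iqr,
    whisker_low = min(inside), whisker_high = max(inside),
    outliers = list(sort(x[x < lo | x > hi]))
  )
}

#' Per-joint box-plot summary of candidate-minus-reference differences
#'
#' @param paired A paired tibble from [pair_angles()].
#' @return A tibble with one [boxplot_stats()] row per joint, plus an
#'   `n_outliers` count.
#' @export
boxplot_summary <- function(paired) {
  check_columns(paired, c("joint", "candidate", "reference"), "paired tibble")
  paired |>
    dplyr::group_by(.data$joint) |>
    dplyr::group_modify(~ boxplot_stats(.x$candidate - .x$reference)) |>
    dplyr::ungroup() |>
    dplyr::mutate(n_outliers = lengths(.data$outliers))
}

#' Full per-joint agreement panel
#'
#' Pools the paired frames of all videos per joint and computes the complete
#' method-comparison panel: bias with SD, SE and 95% CI, MAE, MAD, RMSE,
#' sMAPE, and ICC(A,2) with its 95% CI and Fleiss classification. A joint
#' whose panel cannot be computed is reported with an `error` message
#' without aborting the other joints.
#'
#' @param paired A paired tibble from [pair_angles()].
#' @param mad_type Passed to [error_metrics()].
#' @param conf_level Confidence level for the ICC interval.
#' @return A tibble with one row per joint carrying the panel columns.
#' @export
agreement_stats <- function(paired, mad_type = c("median", "mean"),
                            conf_level = 0.95) {
  check_columns(paired, c("video_id", "joint", "candidate", "reference"),
                "paired tibble")
  mad_type <- match.arg(mad_type)
  paired |>
    dplyr::group_by(.data$joint) |>
    dplyr::group_modify(function(g, key) {
      tryCatch({
        d <- g$candidate - g$reference
        dplyr::bind_cols(
          bias_stats(d),
          error_metrics(g$candidate, g$reference, mad_type),
          icc_a2(g$candidate, g$reference, conf_level)
        ) |>
          dplyr::mutate(
            icc_class = classify_icc(.data$icc),
            error = NA_character_
          )
      }, poseagree_error = function(e) {
        tibble::tibble(n = nrow(g), error = conditionMessage(e))
      })
    }) |>
    dplyr::ungroup()
}
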