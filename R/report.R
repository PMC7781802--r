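# Rendering and writing of report tables.

joint_display <- function(joint) {
  pretty <- gsub("_", " ", joint)
  paste0(toupper(substring(pretty, 1, 1)), substring(pretty, 2))
}

keypoints_display <- function(triplets) {
  tibble::tibble(
    joint = triplets$joint,
    key_points_used = paste(gsub("_", " ", triplets$a),
                            gsub("_", " ", triplets$b),
                            gsub("_", " ", triplets$c), sep = ", ")
  )
}

#' Render the per-joint agreement panel as a formatted table
#'
#' One row per joint with the columns of a standard method-comparison
#' report: the key points used, `mean difference (SD); CI`, MAE, MAD, RMSE,
#' sMAPE, `ICC (CI)`, and the SE of the mean difference. Numbers are
#' rendered once from the unrounded panel values, rounded half away from
#' zero at 2 decimals (3 for the ICC).
#'
#' @param agreement Agreement tibble from [agreement_stats()].
#' @param triplets Registry used, for the key-points column.
#' @return A tibble of formatted strings.
#' @export
render_table1 <- function(agreement, triplets = joint_triplets()) {
  stopifnot(nrow(agreement) >= 1)
  ok <- agreement[is.na(agreement$error), ]
  ok |>
    dplyr::left_join(keypoints_display(triplets), by = "joint") |>
    dplyr::transmute(
      joint = joint_display(.data$joint),
      key_points_used = .data$key_points_used,
      mean_difference = sprintf("%s (%s); %s to %s", fmt_num(.data$bias),
                                fmt_num(.data$sd), fmt_num(.data$ci_low),
                                fmt_num(.data$ci_high)),
      mae = fmt_num(.data$mae),
      mad = fmt_num(.data$mad),
      rmse = fmt_num(.data$rmse),
      smape = fmt_num(.data$smape),
      icc = sprintf("%s (%s to %s)", fmt_num(.data$icc, 3),
                    fmt_num(.data$icc_ci_low, 3),
                    fmt_num(.data$icc_ci_high, 3)),
      se = fmt_num(.data$se)
    )
}

#' Render the per-joint maximum cross-correlation table
#'
#' @param ccf_best Output of [best_lag()].
#' @return A tibble: joint, lag with maximum correlation, maximum
#'   correlation coefficient (2 decimals).
#' @export
render_table2 <- function(ccf_best) {
  ccf_best |>
    dplyr::transmute(
      joint = joint_display(.data$joint),
      lag_max_correlation = .data$best_lag,
      max_correlation = fmt_num(.data$best_corr)
    )
}

#' Write all validation reports to a directory
#'
#' Writes `agreement.csv` / `agreement.json` (the unrounded panel),
#' `table1.csv` / `table2.csv` (the formatted tables), `per_video_icc.csv`,
#' `boxplot.csv` (outlier lists collapsed to `;`-separated strings),
#' `adf.csv`, `ccf.csv`, and `run_log.json` (config echo, stage log, and
#' package version). Re-running on the same result is byte-identical.
#'
#' @param result A `pose_validation` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_validation_reports <- function(result, dir) {
  stopifnot(inherits(result, "pose_validation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    readr::write_csv(df, file.path(dir, name), progress = FALSE, na = "")
  }
  w(result$agreement, "agreement.csv")
  jsonlite::write_json(result$agreement, file.path(dir, "agreement.json"),
                       digits = NA, na = "null")
  w(render_table1(result$agreement), "table1.csv")
  w(render_table2(result$ccf_best), "table2.csv")
  if (!is.null(result$per_video_icc)) w(result$per_video_icc, "per_video_icc.csv")
  box <- result$boxplot
  box$outliers <- vapply(box$outliers, function(o) {
    paste(format(o, digits = 10, trim = TRUE), collapse = ";")
  }, character(1))
  w(box, "boxplot.csv")
  if (!is.null(result$adf)) w(result$adf, "adf.csv")
  w(result$ccf, "ccf.csv")
  jsonlite::write_json(
    list(config = result$config, log = result$log,
         paired_n = result$paired_n),
    file.path(dir, "run_log.json"), digits = NA, auto_unbox = TRUE
  )
  invisible(dir)
}
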