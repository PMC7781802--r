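# End-to-end validation pipeline:
# read -> angles -> smooth -> impute -> pair -> agreement (+ per-video ICC,
# box plots) -> stationarity -> cross-correlation.

read_stream_input <- function(input, format = NULL, fps = 30, layout = NULL) {
  if (is.data.frame(input)) return(input)
  stopifnot(is.character(input), length(input) == 1L)
  format <- match.arg(format, c("body25", "panoptic", "csv"))
  switch(format,
    body25 = read_body25_json(input, fps = fps),
    panoptic = read_panoptic_pose(input, fps = fps),
    csv = read_keypoints_csv(input, layout = layout %||% "body25", fps = fps)
  )
}

#' Run the full candidate-vs-reference validation pipeline
#'
#' Executes, in order: angle extraction from both keypoint streams
#' ([extract_angles()]), Bartlett smoothing ([bartlett_smooth()]),
#' moving-average imputation ([impute_moving_average()]), frame alignment
#' ([pair_angles()]), the per-joint agreement panel ([agreement_stats()]),
#' per-video ICC ([per_video_icc()]), box-plot summaries
#' ([boxplot_summary()]), stationarity tests ([stationarity_tests()]), and
#' cross-correlation lag analysis ([cross_correlation()], [best_lag()]).
#'
#' Inputs may be keypoint-stream tibbles, file paths (with
#' `candidate_format` / `reference_format`), or pre-extracted angle tibbles
#' (detected by the presence of an `angle` column), in which case extraction
#' is skipped for that input.
#'
#' @param candidate,reference Keypoint-stream tibbles, angle tibbles, or
#'   file paths.
#' @param candidate_format,reference_format `"body25"`, `"panoptic"`, or
#'   `"csv"` when the corresponding input is a path.
#' @param fps Frame rate assumed when reading from a path.
#' @param layout Layout for `"csv"` path inputs.
#' @param triplets Joint-angle registry, default [joint_triplets()].
#' @param smooth_window Bartlett window length (odd, default 11).
#' @param impute_window Imputation window length (odd, default 5).
#' @param max_lag Maximum cross-correlation lag (frames); `NULL` = automatic.
#' @param mad_type MAD definition, see [error_metrics()].
#' @param per_video Compute the per-video ICC table?
#' @param adf_series Series passed to [stationarity_tests()]; `NULL` skips
#'   stationarity testing.
#' @return An object of class `pose_validation`: a list with elements
#'   `agreement`, `per_video_icc`, `boxplot`, `adf`, `ccf`, `ccf_best`,
#'   `paired_n`, `log`, and `config`.
#' @examples
#' \donttest{
#' ds <- generate_paired_dataset(motion_spec(n_videos = 2, duration_s = 20))
#' fit <- run_validation(ds$candidate, ds$reference)
#' tidy(fit)
#' }
#' @export
run_validation <- function(candidate, reference,
                           candidate_format = NULL, reference_format = NULL,
                           fps = 30, layout = NULL,
                           triplets = joint_triplets(),
                           smooth_window = 11, impute_window = 5,
                           max_lag = NULL,
                           mad_type = c("median", "mean"),
                           per_video = TRUE,
                           adf_series = c("candidate", "reference",
                                          "difference")) {
  mad_type <- match.arg(mad_type)
  log_rows <- list()
  note <- function(stage, message) {
    log_rows[[length(log_rows) + 1L]] <<-
      tibble::tibble(stage = stage, message = message)
  }

  as_angles <- function(input, format, role) {
    if (is.data.frame(input) && "angle" %in% names(input)) {
      note("extract", sprintf("%s: pre-extracted angles (%d rows)",
                              role, nrow(input)))
      return(input)
    }
    stream <- read_stream_input(input, format, fps, layout)
    note("read", sprintf("%s: %d landmark-frames, %d video(s)", role,
                         nrow(stream), dplyr::n_distinct(stream$video_id)))
    a <- extract_angles(stream, triplets)
    note("extract", sprintf("%s: %d angle values, %d missing", role,
                            nrow(a), sum(a$missing)))
    a
  }
  ang_c <- as_angles(candidate, candidate_format, "candidate")
  ang_r <- as_angles(reference, reference_format, "reference")

  ang_c <- bartlett_smooth(ang_c, smooth_window)
  ang_r <- bartlett_smooth(ang_r, smooth_window)
  note("smooth", sprintf("Bartlett window %d applied to both streams",
                         smooth_window))
  ang_c <- impute_moving_average(ang_c, impute_window)
  ang_r <- impute_moving_average(ang_r, impute_window)
  note("impute", sprintf("imputed %d candidate and %d reference values",
                         sum(ang_c$imputed), sum(ang_r$imputed)))

  paired <- pair_angles(ang_c, ang_r)
  note("pair", sprintf("%d pairs across %d joints, %d video(s)", nrow(paired),
                       dplyr::n_distinct(paired$joint),
                       dplyr::n_distinct(paired$video_id)))

  agreement <- agreement_stats(paired, mad_type = mad_type)
  pv <- if (per_video) per_video_icc(paired) else NULL
  box <- boxplot_summary(paired)
  adf <- if (!is.null(adf_series)) {
    stationarity_tests(paired, series = adf_series)
  }
  ccf_tbl <- cross_correlation(paired, max_lag = max_lag)
  ccf_best <- best_lag(ccf_tbl)
  note("analyze", sprintf("agreement panel for %d joints; max ccf lag window %d",
                          nrow(agreement), max(abs(ccf_tbl$lag))))

  failed <- agreement$joint[!is.na(agreement$error)]
  if (length(failed) > 0) {
    warning("agreement panel failed for joint(s): ",
            paste(failed, collapse = ", "))
  }
  structure(
    list(
      agreement = agreement,
      per_video_icc = pv,
      boxplot = box,
      adf = adf,
      ccf = ccf_tbl,
      ccf_best = ccf_best,
      paired_n = nrow(paired),
      log = dplyr::bind_rows(log_rows),
      config = list(
        smooth_window = smooth_window, impute_window = impute_window,
        max_lag = max_lag, mad_type = mad_type, per_video = per_video,
        adf_series = adf_series, fps = fps,
        poseagree_version = as.character(utils::packageVersion("poseagree"))
      )
    ),
    class = "pose_validation"
  )
}

#' @export
print.pose_validation <- function(x, ...) {
  ok <- x$agreement[is.na(x$agreement$error), ]
  cat("<pose_validation> ", nrow(x$agreement), " joints, ",
      x$paired_n, " pairs\n", sep = "")
  if (nrow(ok) > 0) {
    cat(sprintf("  bias range: %.2f to %.2f deg; ICC range: %.3f to %.3f\n",
                min(ok$bias), max(ok$bias), min(ok$icc), max(ok$icc)))
    cat(sprintf("  joints at cross-correlation lag 0: %d of %d\n",
                sum(x$ccf_best$best_lag == 0), nrow(x$ccf_best)))
  }
  if (any(!is.na(x$agreement$error))) {
    cat("  failed joints:",
        paste(x$agreement$joint[!is.na(x$agreement$error)], collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Run the synthetic study end to end
#'
#' Generates a paired synthetic data set ([generate_paired_dataset()]),
#' extracts candidate angles, applies the spec's `injected_bias` (if any) to
#' the candidate angle series, and runs [run_validation()]. The returned
#' object additionally carries the generation manifest, so recovery checks
#' can compare estimates against the injected ground truth.
#'
#' @param motion A [motion_spec()].
#' @param noise A [noise_spec()].
#' @param seed Seed for the degradation draws; defaults to `motion$seed`.
#' @param ... Passed on to [run_validation()].
#' @return A `pose_validation` object with an extra `manifest` element.
#' @export
run_synthetic_study <- function(motion = motion_spec(), noise = noise_spec(),
                                seed = motion$seed, ...) {
  ds <- generate_paired_dataset(motion, noise, seed)
  ang_c <- extract_angles(ds$candidate)
  if (noise$injected_bias != 0) {
    ang_c <- inject_angle_bias(ang_c, noise$injected_bias, noise$bias_joint)
  }
  res <- run_validation(ang_c, ds$reference, ...)
  res$manifest <- ds$manifest
  res
}
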