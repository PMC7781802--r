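# Smoothing, imputation, and frame alignment of angle series.

bartlett_weights <- function(window) {
  if (!is_odd_window(window)) {
    stop_poseagree("window must be an odd integer >= 3",
                   "poseagree_parameter_error")
  }
  h <- (window - 1) / 2
  w <- 1 - abs(seq(0, window - 1) - h) / h  # triangular, zero endpoints
  w / sum(w)
}

# centered weighted moving average with reflect padding (edge sample not
# duplicated); NA values excluded and weights renormalized over the
# available neighbours; NA positions preserved
smooth_vec <- function(v, w) {
  n <- length(v)
  window <- length(w)
  if (window > n) {
    stop_poseagree("window larger than series length",
                   "poseagree_parameter_error")
  }
  h <- (window - 1) / 2
  pad <- function(z) c(z[(h + 1):2], z, z[(n - 1):(n - h)])
  miss <- is.na(v)
  vv <- ifelse(miss, 0, v)
  ind <- as.numeric(!miss)
  num <- stats::filter(pad(vv), w, sides = 2)
  den <- stats::filter(pad(ind), w, sides = 2)
  out <- (num / den)[(h + 1):(h + n)]
  out[den[(h + 1):(h + n)] == 0] <- NA_real_
  out[miss] <- NA_real_
  as.numeric(out)
}

#' Bartlett-window smoothing of angle series
#'
#' Convolves each per-(video, joint) angle series with a normalized
#' triangular (Bartlett) weight vector of odd length `window` (default 11).
#' The weights sum to 1, so constant series pass through unchanged and
#' linear trends are preserved away from the edges. Edges are handled by
#' reflect padding (mirror about the boundary sample, edge value not
#' duplicated) so the output length equals the input length. Missing values
#' are excluded from each window (weights renormalized over the available
#' neighbours) and the missing mask is preserved.
#'
#' @param angles An angle tibble from [extract_angles()].
#' @param window Odd integer window length, `>= 3` and at most the shortest
#'   series length.
#' @return An angle tibble of identical shape with smoothed `angle` values.
#' @export
bartlett_smooth <- function(angles, window = 11) {
  check_columns(angles, c("video_id", "joint", "frame", "angle", "missing"),
                "angle tibble")
  w <- bartlett_weights(window)
  angles |>
    dplyr::group_by(.data$video_id, .data$joint) |>
    dplyr::arrange(.data$frame, .by_group = TRUE) |>
    dplyr::mutate(angle = smooth_vec(.data$angle, w)) |>
    dplyr::ungroup()
}

impute_vec <- function(v, window) {
  n <- length(v)
  miss <- is.na(v)
  if (all(miss)) {
    stop_poseagree("series is entirely missing; cannot impute",
                   "poseagree_imputation_error")
  }
  if (!any(miss)) return(v)
  h <- (window - 1) / 2
  vv <- c(rep(0, h), ifelse(miss, 0, v), rep(0, h))
  ind <- c(rep(0, h), as.numeric(!miss), rep(0, h))
  num <- stats::filter(vv, rep(1, window), sides = 2)[(h + 1):(h + n)]
  den <- stats::filter(ind, rep(1, window), sides = 2)[(h + 1):(h + n)]
  fill <- ifelse(den > 0, num / den, NA_real_)
  out <- v
  out[miss] <- fill[miss]
  if (anyNA(out)) {
    # gaps longer than the window: linear interpolation between the nearest
    # valid neighbours; leading/trailing gaps take the nearest valid value
    valid <- which(!miss)
    nas <- which(is.na(out))
    if (length(valid) == 1L) {
      out[nas] <- v[valid]
    } else {
      out[nas] <- approx(valid, v[valid], xout = nas, rule = 2)$y
    }
  }
  out
}

#' Moving-average imputation of missing angle values
#'
#' Replaces each missing value with the mean of the non-missing original
#' values inside a centered window of odd length `window` (default 5). Runs
#' of missing values longer than the window are filled by linear
#' interpolation between the nearest valid neighbours; leading/trailing gaps
#' take the nearest valid value. Non-missing values are never altered. The
#' returned tibble has an empty missing mask.
#'
#' @param angles An angle tibble from [extract_angles()].
#' @param window Odd integer window length, `>= 3`.
#' @return An angle tibble with no missing values; a logical column
#'   `imputed` marks the filled positions.
#' @export
impute_moving_average <- function(angles, window = 5) {
  check_columns(angles, c("video_id", "joint", "frame", "angle", "missing"),
                "angle tibble")
  if (!is_odd_window(window)) {
    stop_poseagree("window must be an odd integer >= 3",
                   "poseagree_parameter_error")
  }
  angles |>
    dplyr::group_by(.data$video_id, .data$joint) |>
    dplyr::arrange(.data$frame, .by_group = TRUE) |>
    dplyr::mutate(
      imputed = is.na(.data$angle),
      angle = impute_vec(.data$angle, window),
      missing = FALSE
    ) |>
    dplyr::ungroup()
}

pair_one <- function(cand, ref) {
  fps_c <- cand$fps[1]
  fps_r <- ref$fps[1]
  if (isTRUE(all.equal(fps_c, fps_r))) {
    common <- intersect(cand$frame, ref$frame)
    if (length(common) < 2L) {
      stop_poseagree("candidate and reference share fewer than 2 frames",
                     "poseagree_pairing_error")
    }
    common <- sort(common)
    tibble::tibble(
      time = common / fps_r,
      candidate = cand$angle[match(common, cand$frame)],
      reference = ref$angle[match(common, ref$frame)]
    )
  } else {
    # resample the higher-rate series onto the lower-rate series' timestamps
    if (fps_c > fps_r) { fast <- cand; slow <- ref; cand_fast <- TRUE }
    else { fast <- ref; slow <- cand; cand_fast <- FALSE }
    tf <- fast$frame / fast$fps[1]
    ts <- slow$frame / slow$fps[1]
    keep <- ts >= min(tf) & ts <= max(tf)
    if (sum(keep) < 2L) {
      stop_poseagree("candidate and reference time ranges do not overlap",
                     "poseagree_pairing_error")
    }
    ts <- ts[keep]
    fast_resampled <- approx(tf, fast$angle, xout = ts)$y
    slow_vals <- slow$angle[keep]
    tibble::tibble(
      time = ts,
      candidate = if (cand_fast) fast_resampled else slow_vals,
      reference = if (cand_fast) slow_vals else fast_resampled
    )
  }
}

#' Pair candidate and reference angle series frame by frame
#'
#' Joins imputed candidate and reference angle tibbles per (video, joint)
#' into frame-aligned pairs. Equal-rate series are matched on frame index;
#' when the rates differ, the higher-rate series is linearly resampled in
#' time onto the lower-rate series' frame times, restricted to the
#' overlapping time range. The per-pair difference
#' `candidate - reference` is the unit of all downstream agreement analysis.
#'
#' @param candidate,reference Angle tibbles with no missing values (run
#'   [impute_moving_average()] first).
#' @return A paired tibble with columns `video_id`, `joint`, `time`,
#'   `candidate`, `reference`.
#' @export
pair_angles <- function(candidate, reference) {
  for (nm in c("candidate", "reference")) {
    a <- get(nm)
    check_columns(a, c("video_id", "joint", "frame", "fps", "angle"),
                  paste(nm, "angles"))
    if (anyNA(a$angle)) {
      stop_poseagree(
        sprintf("%s series contain missing values; impute before pairing", nm),
        "poseagree_pairing_error"
      )
    }
  }
  keys <- dplyr::inner_join(
    dplyr::distinct(candidate, .data$video_id, .data$joint),
    dplyr::distinct(reference, .data$video_id, .data$joint),
    by = c("video_id", "joint")
  )
  if (nrow(keys) == 0L) {
    stop_poseagree("no (video, joint) groups in common",
                   "poseagree_pairing_error")
  }
  cand_g <- candidate |>
    dplyr::arrange(.data$frame) |>
    dplyr::group_by(.data$video_id, .data$joint)
  ref_g <- reference |>
    dplyr::arrange(.data$frame) |>
    dplyr::group_by(.data$video_id, .data$joint)
  cand_s <- setNames(
    dplyr::group_split(cand_g),
    apply(dplyr::group_keys(cand_g), 1, paste, collapse = "\r")
  )
  ref_s <- setNames(
    dplyr::group_split(ref_g),
    apply(dplyr::group_keys(ref_g), 1, paste, collapse = "\r")
  )
  purrr::pmap_dfr(keys, function(video_id, joint) {
    key <- paste(video_id, joint, sep = "\r")
    pair_one(cand_s[[key]], ref_s[[key]]) |>
      dplyr::mutate(video_id = video_id, joint = joint, .before = 1)
  })
}
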