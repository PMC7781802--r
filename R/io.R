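# Readers and writers for keypoint streams.
#
# Internal representation: one long tibble per data set with columns
# video_id, frame, joint, x, y, confidence, missing, fps, layout. A landmark
# is flagged missing on read when its confidence is 0 or its coordinates are
# exactly (0, 0) (the OpenPose sentinel convention); coordinates of missing
# landmarks are carried as stored but ignored downstream.

new_keypoint_stream <- function(df) {
  df <- tibble::as_tibble(df)
  class(df) <- c("keypoint_stream", class(df))
  df
}

stream_tibble <- function(video_id, frame, layout, x, y, confidence, missing,
                          fps) {
  nj <- length(layout$joint_names)
  nf <- length(frame)
  new_keypoint_stream(tibble::tibble(
    video_id = as.character(video_id),
    frame = rep(as.integer(frame), each = nj),
    joint = rep(layout$joint_names, times = nf),
    x = as.double(x),
    y = as.double(y),
    confidence = as.double(confidence),
    missing = as.logical(missing),
    fps = as.double(fps),
    layout = layout$name
  ))
}

check_frames_increasing <- function(frame, video_id) {
  if (is.unsorted(frame, strictly = TRUE)) {
    stop_poseagree(
      sprintf("frame indices for video '%s' are not strictly increasing",
              video_id),
      "poseagree_parse_error"
    )
  }
}

#' Read an OpenPose Body25-style keypoint stream from JSON
#'
#' The expected dialect is a JSON array of frames where each frame is either
#' a flat array of 75 numbers `(x1, y1, c1, ..., x25, y25, c25)` or an object
#' `{"frame": <index>, "keypoints": [<75 numbers>]}`. A landmark is flagged
#' missing when its confidence is 0 or its coordinates are exactly (0, 0).
#'
#' @param path Path to the JSON file.
#' @param video_id Video identifier; defaults to the file name without
#'   extension.
#' @param fps Frames per second of the stream (positive).
#' @return A keypoint-stream tibble with columns `video_id`, `frame`,
#'   `joint`, `x`, `y`, `confidence`, `missing`, `fps`, `layout`.
#' @seealso [write_body25_json()], [read_panoptic_pose()],
#'   [read_keypoints_csv()]
#' @export
read_body25_json <- function(path,
                             video_id = tools::file_path_sans_ext(basename(path)),
                             fps = 30) {
  stopifnot(file.exists(path), is.numeric(fps), fps > 0)
  js <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.list(js)) {
    stop_poseagree("Body25 JSON must be an array of frames",
                   "poseagree_parse_error")
  }
  layout <- skeleton_layout("body25")
  n <- length(js)
  frame_idx <- integer(n)
  kp <- vector("list", n)
  for (i in seq_len(n)) {
    rec <- js[[i]]
    if (is.list(rec) && !is.null(rec$keypoints)) {
      frame_idx[i] <- if (!is.null(rec$frame)) as.integer(rec$frame) else i - 1L
      vals <- unlist(rec$keypoints, use.names = FALSE)
    } else {
      frame_idx[i] <- i - 1L
      vals <- unlist(rec, use.names = FALSE)
    }
    if (!is.numeric(vals)) {
      stop_poseagree(sprintf("malformed Body25 record at frame %d", i - 1L),
                     "poseagree_parse_error")
    }
    if (length(vals) != 75L) {
      stop_poseagree(
        sprintf("frame %d has %d values; expected 75 (25 landmarks x 3)",
                i - 1L, length(vals)),
        "poseagree_layout_error"
      )
    }
    kp[[i]] <- vals
  }
  check_frames_increasing(frame_idx, video_id)
  m <- matrix(unlist(kp, use.names = FALSE), ncol = 3L, byrow = TRUE)
  x <- m[, 1]; y <- m[, 2]; conf <- m[, 3]
  missing <- (conf == 0) | (x == 0 & y == 0)
  stream_tibble(video_id, frame_idx, layout, x, y, conf, missing, fps)
}

#' Write a keypoint stream as Body25-style JSON
#'
#' Inverse of [read_body25_json()]: one object per frame with a flat
#' 75-number keypoint list. Missing landmarks are encoded with the OpenPose
#' sentinel `(0, 0, 0)`.
#'
#' @param stream A single-video keypoint-stream tibble in the `body25`
#'   layout.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_body25_json <- function(stream, path) {
  check_columns(stream, c("video_id", "frame", "joint", "x", "y",
                          "confidence", "missing"), "stream")
  stopifnot(length(unique(stream$video_id)) == 1L,
            unique(stream$layout) == "body25")
  layout <- skeleton_layout("body25")
  frames <- sort(unique(stream$frame))
  ord <- order(stream$frame, match(stream$joint, layout$joint_names))
  s <- stream[ord, ]
  x <- ifelse(s$missing, 0, s$x)
  y <- ifelse(s$missing, 0, s$y)
  conf <- ifelse(s$missing, 0, ifelse(is.na(s$confidence), 1, s$confidence))
  flat <- as.vector(rbind(x, y, conf))
  per_frame <- split(flat, rep(seq_along(frames), each = 75L))
  out <- purrr::map2(frames, per_frame, function(f, v) {
    list(frame = f, keypoints = as.numeric(v))
  })
  jsonlite::write_json(out, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' Read a Panoptic-style 15-landmark pose stream from JSON
#'
#' The expected dialect is a JSON array of frames, each an array of 15
#' landmark entries `[x, y]` or `[x, y, confidence]`. A `null` entry marks
#' the landmark missing at that frame; a landmark that is `null` in every
#' frame is reported as absent (message) but is not an error.
#'
#' @inheritParams read_body25_json
#' @return A keypoint-stream tibble in the `panoptic15` layout.
#' @export
read_panoptic_pose <- function(path,
                               video_id = tools::file_path_sans_ext(basename(path)),
                               fps = 30) {
  stopifnot(file.exists(path), is.numeric(fps), fps > 0)
  js <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.list(js)) {
    stop_poseagree("Panoptic pose JSON must be an array of frames",
                   "poseagree_parse_error")
  }
  layout <- skeleton_layout("panoptic15")
  n <- length(js)
  x <- y <- conf <- matrix(NA_real_, nrow = n, ncol = 15L)
  miss <- matrix(TRUE, nrow = n, ncol = 15L)
  for (i in seq_len(n)) {
    rec <- js[[i]]
    if (!is.list(rec) || length(rec) != 15L) {
      stop_poseagree(
        sprintf("frame %d has %d landmark entries; expected 15",
                i - 1L, length(rec)),
        "poseagree_layout_error"
      )
    }
    for (j in seq_len(15L)) {
      e <- rec[[j]]
      if (is.null(e)) next
      v <- unlist(e, use.names = FALSE)
      if (!is.numeric(v) || length(v) < 2L) {
        stop_poseagree(
          sprintf("malformed landmark %d at frame %d", j - 1L, i - 1L),
          "poseagree_parse_error"
        )
      }
      x[i, j] <- v[1]; y[i, j] <- v[2]
      conf[i, j] <- if (length(v) >= 3L) v[3] else 1
      miss[i, j] <- (length(v) >= 3L && v[3] == 0) || (v[1] == 0 && v[2] == 0)
    }
  }
  absent <- layout$joint_names[colSums(!miss) == 0L]
  if (length(absent) > 0) {
    message("landmark(s) absent from all frames: ",
            paste(absent, collapse = ", "))
  }
  stream_tibble(video_id, seq_len(n) - 1L, layout,
                as.vector(t(x)), as.vector(t(y)), as.vector(t(conf)),
                as.vector(t(miss)), fps)
}

#' Write a keypoint stream as Panoptic-style pose JSON
#'
#' Inverse of [read_panoptic_pose()]: an array of frames, each an array of
#' 15 `[x, y, confidence]` entries; missing landmarks are written as `null`.
#'
#' @param stream A single-video keypoint-stream tibble in the `panoptic15`
#'   layout.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panoptic_pose <- function(stream, path) {
  check_columns(stream, c("video_id", "frame", "joint", "x", "y",
                          "confidence", "missing"), "stream")
  stopifnot(length(unique(stream$video_id)) == 1L,
            unique(stream$layout) == "panoptic15")
  layout <- skeleton_layout("panoptic15")
  frames <- sort(unique(stream$frame))
  ord <- order(stream$frame, match(stream$joint, layout$joint_names))
  s <- stream[ord, ]
  out <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    rows <- ((i - 1L) * 15L + 1L):(i * 15L)
    out[[i]] <- purrr::map(rows, function(r) {
      if (s$missing[r]) NULL
      else c(s$x[r], s$y[r], if (is.na(s$confidence[r])) 1 else s$confidence[r])
    })
  }
  jsonlite::write_json(out, path, digits = I(17), null = "null")
  invisible(path)
}

#' Read keypoint streams from a generic long-format CSV
#'
#' Columns: `video_id, frame, joint_id, x, y[, confidence]`. `joint_id` may
#' be a layout joint name or a 0-based integer index into the layout's joint
#' order. A `(video, frame, joint)` combination with no row is flagged
#' missing; duplicated combinations are an error. All videos are returned in
#' one long tibble keyed by `video_id`.
#'
#' @param path Path to the CSV file.
#' @param layout A [skeleton_layout()] (or built-in layout name) describing
#'   the joint convention of the file.
#' @param fps Frames per second of the streams (positive).
#' @return A keypoint-stream tibble covering all videos in the file.
#' @export
read_keypoints_csv <- function(path, layout, fps = 30) {
  stopifnot(file.exists(path), is.numeric(fps), fps > 0)
  lay <- skeleton_layout(layout)
  # base read.csv: its strtod double parser is correctly rounded, so
  # write_csv (shortest round-trip representation) -> read is exact
  df <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  check_columns(df, c("video_id", "frame", "joint_id", "x", "y"), "keypoint CSV")
  if (!"confidence" %in% names(df)) df$confidence <- 1
  joint <- df$joint_id
  if (is.numeric(joint)) {
    # 0-based indices, matching the pose-estimation ecosystem convention
    joint <- lay$joint_names[as.integer(joint) + 1L]
  } else {
    joint <- as.character(joint)
  }
  bad <- unique(df$joint_id[is.na(joint) | !(joint %in% lay$joint_names)])
  if (length(bad) > 0) {
    stop_poseagree(
      sprintf("joint_id value(s) not in layout '%s': %s", lay$name,
              paste(head(bad, 5), collapse = ", ")),
      "poseagree_layout_error"
    )
  }
  df$joint <- joint
  if (anyDuplicated(df[c("video_id", "frame", "joint")])) {
    stop_poseagree("duplicate (video_id, frame, joint_id) rows",
                   "poseagree_parse_error")
  }
  grid <- df |>
    dplyr::distinct(.data$video_id, .data$frame) |>
    tidyr::crossing(joint = lay$joint_names)
  out <- grid |>
    dplyr::left_join(
      dplyr::select(df, "video_id", "frame", "joint", "x", "y", "confidence"),
      by = c("video_id", "frame", "joint")
    ) |>
    dplyr::mutate(
      missing = is.na(.data$x) | is.na(.data$y) |
        (!is.na(.data$confidence) & .data$confidence == 0) |
        (!is.na(.data$x) & !is.na(.data$y) & .data$x == 0 & .data$y == 0),
      fps = as.double(fps),
      layout = lay$name,
      video_id = as.character(.data$video_id),
      frame = as.integer(.data$frame)
    ) |>
    dplyr::arrange(.data$video_id, .data$frame,
                   match(.data$joint, lay$joint_names))
  new_keypoint_stream(out)
}

#' Write a keypoint stream as generic long-format CSV
#'
#' Inverse of [read_keypoints_csv()]. Only non-missing landmark rows are
#' written; absence of a row encodes missingness. `joint_id` is written as
#' the layout joint name.
#'
#' @param stream A keypoint-stream tibble (any number of videos).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_keypoints_csv <- function(stream, path) {
  check_columns(stream, c("video_id", "frame", "joint", "x", "y",
                          "confidence", "missing"), "stream")
  stream |>
    dplyr::filter(!.data$missing) |>
    dplyr::transmute(
      video_id = .data$video_id, frame = .data$frame,
      joint_id = .data$joint, x = .data$x, y = .data$y,
      confidence = .data$confidence
    ) |>
    readr::write_csv(path, progress = FALSE)
  invisible(path)
}
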