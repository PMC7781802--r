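# Joint-angle extraction: unsigned interior angles at keypoint triplets.

#' Default joint-angle triplet registry
#'
#' Ten joint angles, each defined by an ordered landmark triplet (a, b, c)
#' with b the vertex: right/left shoulder (hip, shoulder, elbow), right/left
#' elbow (shoulder, elbow, wrist), right/left hip (shoulder, hip, knee),
#' right/left knee (hip, knee, ankle), neck (pelvis, neck, head), and pelvis
#' (left knee, pelvis, right knee). Landmark names are canonical (see
#' [skeleton_layout()]), so the same registry applies to any layout.
#'
#' @return A tibble with columns `joint`, `a`, `b`, `c`.
#' @examples
#' joint_triplets()
#' @export
joint_triplets <- function() {
  tibble::tribble(
    ~joint,            ~a,               ~b,               ~c,
    "right_shoulder",  "right_hip",      "right_shoulder", "right_elbow",
    "left_shoulder",   "left_hip",       "left_shoulder",  "left_elbow",
    "right_elbow",     "right_shoulder", "right_elbow",    "right_wrist",
    "left_elbow",      "left_shoulder",  "left_elbow",     "left_wrist",
    "right_hip",       "right_shoulder", "right_hip",      "right_knee",
    "left_hip",        "left_shoulder",  "left_hip",       "left_knee",
    "right_knee",      "right_hip",      "right_knee",     "right_ankle",
    "left_knee",       "left_hip",       "left_knee",      "left_ankle",
    "neck",            "pelvis",         "neck",           "head",
    "pelvis",          "left_knee",      "pelvis",         "right_knee"
  )
}

validate_triplets <- function(triplets) {
  check_columns(triplets, c("joint", "a", "b", "c"), "triplet registry")
  lm <- unique(c(triplets$a, triplets$b, triplets$c))
  bad <- setdiff(lm, .canonical_landmarks)
  if (length(bad) > 0) {
    stop_poseagree(
      sprintf("triplet registry uses non-canonical landmark(s): %s",
              paste(bad, collapse = ", ")),
      "poseagree_config_error"
    )
  }
  if (anyDuplicated(triplets$joint)) {
    stop_poseagree("duplicate joint names in triplet registry",
                   "poseagree_config_error")
  }
  triplets
}

# vectorized unsigned interior angle at vertex (bx, by); NA for degenerate rays
interior_angle_xy <- function(ax, ay, bx, by, cx, cy) {
  ux <- ax - bx; uy <- ay - by
  vx <- cx - bx; vy <- cy - by
  cross <- ux * vy - uy * vx
  dot <- ux * vx + uy * vy
  ang <- atan2(abs(cross), dot) * 180 / pi
  ang[(ux == 0 & uy == 0) | (vx == 0 & vy == 0)] <- NA_real_
  ang
}

#' Unsigned interior angle at a vertex
#'
#' The angle at vertex `b` between rays `b -> a` and `b -> c`, in degrees,
#' in `[0, 180]`. Computed with `atan2(|cross|, dot)`, which is
#' numerically stable for near-collinear rays.
#'
#' @param a,b,c Numeric length-2 vectors `(x, y)`, or n-by-2 matrices for
#'   vectorized evaluation.
#' @return Angle(s) in degrees in `[0, 180]`.
#' @examples
#' interior_angle(c(0, 1), c(0, 0), c(1, 0)) # 90
#' interior_angle(c(-1, 0), c(0, 0), c(2, 0)) # 180
#' @export
interior_angle <- function(a, b, c) {
  as_m <- function(p) if (is.matrix(p)) p else matrix(p, ncol = 2)
  a <- as_m(a); b <- as_m(b); c <- as_m(c)
  stopifnot(ncol(a) == 2, ncol(b) == 2, ncol(c) == 2,
            all(is.finite(a)), all(is.finite(b)), all(is.finite(c)))
  ang <- interior_angle_xy(a[, 1], a[, 2], b[, 1], b[, 2], c[, 1], c[, 2])
  if (anyNA(ang)) {
    stop_poseagree("degenerate geometry: a ray of the triplet has zero length",
                   "poseagree_geometry_error")
  }
  ang
}

#' Extract per-frame joint-angle series from a keypoint stream
#'
#' Computes, for every triplet in the registry, the unsigned interior angle
#' at the vertex landmark for every frame of every video in the stream. A
#' frame's angle is missing iff any of the triplet's three landmarks is
#' missing at that frame or the geometry is degenerate (zero-length ray).
#'
#' Canonical-landmark resolution is total for the built-in layouts: in
#' `body25` the head is the nose keypoint and the pelvis is MidHip; in a
#' layout without a pelvis index the pelvis is the midpoint of the two hips.
#' A triplet landmark that cannot be resolved raises a configuration error
#' naming the joint and the landmark.
#'
#' @param stream A keypoint-stream tibble (see [read_body25_json()]).
#' @param triplets Triplet registry, default [joint_triplets()].
#' @param layout Optional [skeleton_layout()] overriding the stream's
#'   `layout` column (needed only for custom layouts).
#' @return An angle tibble with columns `video_id`, `joint`, `frame`, `fps`,
#'   `angle` (degrees, `NA` where missing), `missing`.
#' @export
extract_angles <- function(stream, triplets = joint_triplets(), layout = NULL) {
  check_columns(stream, c("video_id", "frame", "joint", "x", "y", "missing",
                          "fps", "layout"), "stream")
  triplets <- validate_triplets(triplets)
  if (is.null(layout)) {
    lname <- unique(stream$layout)
    if (length(lname) != 1L) {
      stop_poseagree("stream mixes layouts; extract per layout",
                     "poseagree_config_error")
    }
    layout <- skeleton_layout(lname)
  } else {
    layout <- skeleton_layout(layout)
  }
  needed <- unique(c(triplets$a, triplets$b, triplets$c))
  per_video <- function(sv) {
    frames <- sort(unique(sv$frame))
    nf <- length(frames)
    nj <- length(layout$joint_names)
    ri <- match(sv$frame, frames)
    ci <- match(sv$joint, layout$joint_names)
    xm <- ym <- matrix(NA_real_, nf, nj)
    missm <- matrix(TRUE, nf, nj)
    idx <- cbind(ri, ci)
    xm[idx] <- sv$x; ym[idx] <- sv$y; missm[idx] <- sv$missing
    land <- lapply(setNames(needed, needed), function(lm) {
      tryCatch(resolve_landmark(lm, layout, xm, ym, missm),
        poseagree_config_error = function(e) e)
    })
    fps <- sv$fps[1]
    purrr::pmap_dfr(triplets, function(joint, a, b, c) {
      for (lm in c(a, b, c)) {
        if (inherits(land[[lm]], "error")) {
          stop_poseagree(
            sprintf("joint '%s': %s", joint, conditionMessage(land[[lm]])),
            "poseagree_config_error"
          )
        }
      }
      A <- land[[a]]; B <- land[[b]]; C <- land[[c]]
      ang <- interior_angle_xy(A$x, A$y, B$x, B$y, C$x, C$y)
      miss <- A$missing | B$missing | C$missing | is.na(ang)
      ang[miss] <- NA_real_
      tibble::tibble(
        video_id = sv$video_id[1], joint = joint, frame = frames,
        fps = fps, angle = ang, missing = miss
      )
    })
  }
  stream |>
    dplyr::group_by(.data$video_id) |>
    dplyr::group_split() |>
    purrr::map_dfr(per_video)
}
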