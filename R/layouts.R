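# Skeleton layouts and canonical landmark resolution.
#
# A layout names the landmarks of a skeleton convention in order and maps the
# 15 canonical anatomical landmarks used by the joint-angle registry to
# indices in that order. Built-in layouts: "body25" (the OpenPose 25-landmark
# convention) and "panoptic15" (the 15-anatomical-landmark convention of
# multiview reference skeletons).

.canonical_landmarks <- c(
  "head", "neck", "pelvis",
  "right_shoulder", "right_elbow", "right_wrist",
  "right_hip", "right_knee", "right_ankle",
  "left_shoulder", "left_elbow", "left_wrist",
  "left_hip", "left_knee", "left_ankle"
)

.body25_joints <- c(
  "Nose", "Neck", "RShoulder", "RElbow", "RWrist", "LShoulder", "LElbow",
  "LWrist", "MidHip", "RHip", "RKnee", "RAnkle", "LHip", "LKnee", "LAnkle",
  "REye", "LEye", "REar", "LEar", "LBigToe", "LSmallToe", "LHeel", "RBigToe",
  "RSmallToe", "RHeel"
)

# the Body25 skeleton has no dedicated head landmark; the nose keypoint
# stands in for the head (see extract_angles() docs)
.body25_canonical <- c(
  head = 1L, neck = 2L, pelvis = 9L,
  right_shoulder = 3L, right_elbow = 4L, right_wrist = 5L,
  right_hip = 10L, right_knee = 11L, right_ankle = 12L,
  left_shoulder = 6L, left_elbow = 7L, left_wrist = 8L,
  left_hip = 13L, left_knee = 14L, left_ankle = 15L
)

.panoptic15_joints <- c(
  "Neck", "Head", "BodyCenter", "LShoulder", "LElbow", "LWrist", "LHip",
  "LKnee", "LAnkle", "RShoulder", "RElbow", "RWrist", "RHip", "RKnee",
  "RAnkle"
)

.panoptic15_canonical <- c(
  head = 2L, neck = 1L, pelvis = 3L,
  right_shoulder = 10L, right_elbow = 11L, right_wrist = 12L,
  right_hip = 13L, right_knee = 14L, right_ankle = 15L,
  left_shoulder = 4L, left_elbow = 5L, left_wrist = 6L,
  left_hip = 7L, left_knee = 8L, left_ankle = 9L
)

#' Skeleton layout definitions
#'
#' A skeleton layout names the landmarks of a keypoint convention in order
#' and maps the 15 canonical anatomical landmark names (head, neck, pelvis,
#' and left/right shoulder, elbow, wrist, hip, knee, ankle) to indices in
#' that order. The canonical names are what the joint-angle triplet registry
#' ([joint_triplets()]) refers to, so any layout with a complete canonical
#' map can feed angle extraction.
#'
#' Built-in layouts:
#' * `"body25"` — the OpenPose Body25 convention (25 landmarks). It has no
#'   dedicated head landmark; the nose keypoint is used as the head, and the
#'   MidHip keypoint as the pelvis.
#' * `"panoptic15"` — a 15-anatomical-landmark convention as used by
#'   multiview reference skeletons (neck, head, body center/pelvis, and the
#'   left/right limb landmarks).
#'
#' A canonical landmark may be declared absent (index `NA`). A layout with
#' no pelvis index but with both hip indices is still usable: the pelvis is
#' resolved as the midpoint of the two hips at extraction time.
#'
#' @param name Layout name. `"body25"` or `"panoptic15"` return the built-in
#'   definitions; any other name requires `joint_names` and `canonical`.
#' @param joint_names Character vector of landmark names, in storage order.
#' @param canonical Named integer vector mapping canonical landmark names to
#'   indices into `joint_names` (`NA` = declared absent).
#' @return An object of class `skeleton_layout`: a list with elements
#'   `name`, `joint_names`, and `canonical`.
#' @examples
#' skeleton_layout("body25")
#' skeleton_layout("panoptic15")$canonical[["pelvis"]]
#' @export
skeleton_layout <- function(name, joint_names = NULL, canonical = NULL) {
  if (inherits(name, "skeleton_layout")) {
    return(name)
  }
  if (is.null(joint_names)) {
    built_in <- switch(name,
      body25 = list(joint_names = .body25_joints, canonical = .body25_canonical),
      panoptic15 = list(joint_names = .panoptic15_joints,
                        canonical = .panoptic15_canonical),
      stop_poseagree(
        sprintf("unknown layout '%s'; supply joint_names and canonical", name),
        "poseagree_layout_error"
      )
    )
    joint_names <- built_in$joint_names
    canonical <- built_in$canonical
  }
  if (anyDuplicated(joint_names)) {
    stop_poseagree("layout joint names must be unique", "poseagree_layout_error")
  }
  unknown <- setdiff(names(canonical), .canonical_landmarks)
  if (length(unknown) > 0) {
    stop_poseagree(
      sprintf("unknown canonical landmark name(s): %s",
              paste(unknown, collapse = ", ")),
      "poseagree_layout_error"
    )
  }
  canonical <- canonical[.canonical_landmarks[.canonical_landmarks %in% names(canonical)]]
  idx <- canonical[!is.na(canonical)]
  if (length(idx) > 0 &&
      (any(idx < 1 | idx > length(joint_names)) || anyDuplicated(idx))) {
    stop_poseagree(
      "canonical indices must be unique and within the joint count",
      "poseagree_layout_error"
    )
  }
  full <- setNames(rep(NA_integer_, length(.canonical_landmarks)),
                   .canonical_landmarks)
  full[names(canonical)] <- as.integer(canonical)
  structure(
    list(name = name, joint_names = joint_names, canonical = full),
    class = "skeleton_layout"
  )
}

#' @export
print.skeleton_layout <- function(x, ...) {
  cat("<skeleton_layout> ", x$name, ": ", length(x$joint_names),
      " landmarks\n", sep = "")
  absent <- names(x$canonical)[is.na(x$canonical)]
  if (length(absent) > 0) {
    cat("  absent canonical landmarks:", paste(absent, collapse = ", "), "\n")
  }
  invisible(x)
}

# resolve the (x, y, missing) columns of one canonical landmark from wide
# per-video matrices; pelvis falls back to the hip midpoint when unmapped
resolve_landmark <- function(landmark, layout, xm, ym, missm) {
  idx <- layout$canonical[[landmark]]
  if (!is.na(idx)) {
    return(list(x = xm[, idx], y = ym[, idx], missing = missm[, idx]))
  }
  if (landmark == "pelvis") {
    ih <- layout$canonical[["left_hip"]]
    jh <- layout$canonical[["right_hip"]]
    if (!is.na(ih) && !is.na(jh)) {
      return(list(
        x = (xm[, ih] + xm[, jh]) / 2,
        y = (ym[, ih] + ym[, jh]) / 2,
        missing = missm[, ih] | missm[, jh]
      ))
    }
  }
  stop_poseagree(
    sprintf("landmark '%s' is declared absent in layout '%s'",
            landmark, layout$name),
    "poseagree_config_error"
  )
}
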