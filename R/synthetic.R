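# Synthetic paired-skeleton generator.
#
# Emulates the structure of a markerless-capture validation study: ~10
# videos of a few minutes at 25-30 fps, a subject exercising joints through
# their range of motion, a clean reference stream and a degraded candidate
# stream. Nine of the ten registry angles (both shoulders, elbows, hips,
# knees, and the neck) are driven directly by sum-of-two-sinusoid
# trajectories and realized exactly by a pelvis-rooted kinematic chain; the
# pelvis angle (left knee, pelvis, right knee) is geometrically determined
# by the two legs and its ground truth is computed from the noise-free
# chain.

.driven_joints <- c("right_shoulder", "left_shoulder", "right_elbow",
                    "left_elbow", "right_hip", "left_hip", "right_knee",
                    "left_knee", "neck")

default_movement <- function() {
  tibble::tribble(
    ~joint,           ~baseline, ~amp1, ~amp2,
    "right_shoulder", 60,        15,    6,
    "left_shoulder",  60,        15,    6,
    "right_elbow",    110,       23,    9,
    "left_elbow",     110,       23,    9,
    "right_hip",      145,       13,    5,
    "left_hip",       145,       13,    5,
    "right_knee",     140,       20,    8,
    "left_knee",      140,       20,    8,
    "neck",           148,       21,    8
  ) |>
    dplyr::mutate(freq1 = NA_real_, phase1 = NA_real_,
                  freq2 = NA_real_, phase2 = NA_real_)
}

default_limb_lengths <- function() {
  # pixels, roughly a standing adult filmed at HD resolution
  list(trunk = 120, head = 50, shoulder_width = 40, hip_width = 25,
       upper_arm = 55, forearm = 50, thigh = 80, shank = 75)
}

#' Motion specification for the synthetic study
#'
#' Defines the study conditions the generator emulates: the number of
#' videos, their duration, the frame rates of the reference and candidate
#' streams, the per-joint angular trajectories, and the skeleton's segment
#' lengths. Each of the nine driven joint angles follows
#' `baseline + amp1 sin(2 pi freq1 t + phase1) + amp2 sin(2 pi freq2 t + phase2)`
#' (degrees); frequencies and phases left `NA` in `movement` are drawn per
#' video (frequencies in 0.10-0.35 Hz and 0.45-0.90 Hz, phases uniform),
#' deterministically from `seed`.
#'
#' Defaults mirror a range-of-motion validation recording: 10 videos of
#' 145 s at 30 fps for both streams.
#'
#' @param n_videos Number of videos.
#' @param duration_s Duration of each video in seconds.
#' @param fps_reference,fps_candidate Frame rates (Hz) of the two streams.
#' @param movement Tibble with columns `joint`, `baseline`, `amp1`, `amp2`,
#'   `freq1`, `phase1`, `freq2`, `phase2` for the nine driven joints; see
#'   `default_movement()` via `motion_spec()$movement`.
#' @param limb_lengths Named list of segment lengths in pixels.
#' @param sway_deg Amplitude of the slow trunk sway (degrees).
#' @param seed Integer seed; all generation is deterministic given it.
#' @return An object of class `motion_spec`.
#' @export
motion_spec <- function(n_videos = 10, duration_s = 145,
                        fps_reference = 30, fps_candidate = 30,
                        movement = default_movement(),
                        limb_lengths = default_limb_lengths(),
                        sway_deg = 4, seed = 20201221) {
  stopifnot(n_videos >= 1, duration_s > 0, fps_reference > 0,
            fps_candidate > 0, sway_deg >= 0)
  check_columns(movement, c("joint", "baseline", "amp1", "amp2",
                            "freq1", "phase1", "freq2", "phase2"),
                "movement table")
  if (!setequal(movement$joint, .driven_joints)) {
    stop_poseagree(
      paste("movement table must define exactly the driven joints:",
            paste(.driven_joints, collapse = ", ")),
      "poseagree_spec_error"
    )
  }
  amp_tot <- abs(movement$amp1) + abs(movement$amp2)
  if (any(movement$baseline - amp_tot <= 0) ||
      any(movement$baseline + amp_tot >= 180)) {
    stop_poseagree("movement amplitudes must keep all angles inside (0, 180)",
                   "poseagree_spec_error")
  }
  nyq <- min(fps_reference, fps_candidate) / 2
  if (any(stats::na.omit(c(movement$freq1, movement$freq2)) >= nyq)) {
    stop_poseagree("movement frequencies must be below fps/2",
                   "poseagree_spec_error")
  }
  structure(
    list(n_videos = as.integer(n_videos), duration_s = duration_s,
         fps_reference = fps_reference, fps_candidate = fps_candidate,
         movement = movement, limb_lengths = limb_lengths,
         sway_deg = sway_deg, seed = as.integer(seed)),
    class = "motion_spec"
  )
}

#' Degradation specification for the synthetic candidate stream
#'
#' A simple degradation model standing in for pose-estimator error:
#' i.i.d. Gaussian pixel noise on every landmark, random landmark dropout
#' (flagged missing), sparse large-displacement outliers, an optional
#' integer temporal lag of the whole candidate stream, and an optional
#' constant bias added to candidate joint angles after extraction.
#'
#' The defaults are calibrated so that the default [motion_spec()] study
#' lands in the 0.95-0.99 ICC range typical of a well-performing 2D pose
#' estimator, with occasional heavy-tailed difference outliers.
#'
#' @param keypoint_noise_sd SD of the Gaussian pixel noise per coordinate.
#' @param dropout_prob Per landmark-frame probability of dropout.
#' @param outlier_prob Per landmark-frame probability of a large
#'   displacement.
#' @param outlier_shift Magnitude of the outlier displacement in pixels.
#' @param injected_lag Integer frame lag applied to the candidate stream
#'   (positive = candidate trails the reference).
#' @param injected_bias Constant bias in degrees added to candidate angle
#'   series by [run_synthetic_study()].
#' @param bias_joint Joint name(s) receiving `injected_bias`; `NULL` = all.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(keypoint_noise_sd = 7, dropout_prob = 0.01,
                       outlier_prob = 0.002, outlier_shift = 80,
                       injected_lag = 0L, injected_bias = 0,
                       bias_joint = NULL) {
  stopifnot(keypoint_noise_sd >= 0, dropout_prob >= 0, dropout_prob <= 1,
            outlier_prob >= 0, outlier_prob <= 1, outlier_shift >= 0,
            injected_lag == floor(injected_lag))
  structure(
    list(keypoint_noise_sd = keypoint_noise_sd, dropout_prob = dropout_prob,
         outlier_prob = outlier_prob, outlier_shift = outlier_shift,
         injected_lag = as.integer(injected_lag),
         injected_bias = injected_bias, bias_joint = bias_joint),
    class = "noise_spec"
  )
}

rot_dir <- function(dx, dy, theta_rad) {
  # rotate unit direction (dx, dy) by theta
  list(x = dx * cos(theta_rad) - dy * sin(theta_rad),
       y = dx * sin(theta_rad) + dy * cos(theta_rad))
}

unit_dir <- function(fx, fy, tx, ty) {
  dx <- tx - fx; dy <- ty - fy
  len <- sqrt(dx^2 + dy^2)
  list(x = dx / len, y = dy / len)
}

draw_video_params <- function(spec, video_index) {
  mv <- spec$movement
  withr::with_seed(derive_seed(spec$seed, video_index), {
    mv$freq1 <- ifelse(is.na(mv$freq1), runif(nrow(mv), 0.10, 0.35), mv$freq1)
    mv$freq2 <- ifelse(is.na(mv$freq2), runif(nrow(mv), 0.45, 0.90), mv$freq2)
    mv$phase1 <- ifelse(is.na(mv$phase1), runif(nrow(mv), 0, 2 * pi), mv$phase1)
    mv$phase2 <- ifelse(is.na(mv$phase2), runif(nrow(mv), 0, 2 * pi), mv$phase2)
    sway_phase <- runif(1, 0, 2 * pi)
  })
  list(movement = mv, sway_freq = 0.05, sway_phase = sway_phase)
}

#' Generate one noise-free truth stream with known joint angles
#'
#' Builds a pelvis-rooted kinematic chain whose nine driven interior angles
#' follow the trajectories in the [motion_spec()] exactly; the pelvis angle
#' is geometrically determined and its ground truth is computed from the
#' chain. Deterministic given `spec$seed` and `video_index`, for any `fps`
#' and layout (the trajectory parameters are drawn before any sampling).
#'
#' @param spec A [motion_spec()].
#' @param video_index 1-based video number (controls the per-video
#'   trajectory draw and the video id `"video_<index>"`).
#' @param fps Sampling rate; defaults to the reference rate.
#' @param layout `"panoptic15"` or `"body25"` output convention.
#' @return A list with `stream` (keypoint-stream tibble), `truth` (angle
#'   tibble for the 10 registry joints), and `params` (realized per-video
#'   trajectory parameters).
#' @export
generate_truth_stream <- function(spec, video_index,
                                  fps = spec$fps_reference,
                                  layout = c("panoptic15", "body25")) {
  stopifnot(inherits(spec, "motion_spec"), video_index >= 1)
  layout <- match.arg(layout)
  pars <- draw_video_params(spec, video_index)
  mv <- pars$movement
  nf <- round(spec$duration_s * fps)
  t <- (seq_len(nf) - 1L) / fps
  theta <- sapply(.driven_joints, function(j) {
    r <- mv[mv$joint == j, ]
    (r$baseline +
       r$amp1 * sin(2 * pi * r$freq1 * t + r$phase1) +
       r$amp2 * sin(2 * pi * r$freq2 * t + r$phase2)) * pi / 180
  })
  sway <- (spec$sway_deg * pi / 180) *
    sin(2 * pi * pars$sway_freq * t + pars$sway_phase)
  L <- spec$limb_lengths
  ux <- sin(sway); uy <- -cos(sway)        # trunk "up" (pixel y points down)
  rx <- -uy; ry <- ux                      # lateral direction
  px <- rep(960, nf); py <- rep(540, nf)   # pelvis root, fixed
  nx <- px + L$trunk * ux; ny <- py + L$trunk * uy
  side <- function(sgn, th_sh, th_el, th_hip, th_knee) {
    hx <- px + sgn * L$hip_width * rx; hy <- py + sgn * L$hip_width * ry
    sx <- nx + sgn * L$shoulder_width * rx; sy <- ny + sgn * L$shoulder_width * ry
    rot_sign <- -sgn  # arms/legs open outward from the trunk
    d <- unit_dir(sx, sy, hx, hy)
    e <- rot_dir(d$x, d$y, rot_sign * th_sh)
    ex <- sx + L$upper_arm * e$x; ey <- sy + L$upper_arm * e$y
    d <- unit_dir(ex, ey, sx, sy)
    w <- rot_dir(d$x, d$y, rot_sign * th_el)
    wx <- ex + L$forearm * w$x; wy <- ey + L$forearm * w$y
    d <- unit_dir(hx, hy, sx, sy)
    k <- rot_dir(d$x, d$y, rot_sign * th_hip)
    kx <- hx + L$thigh * k$x; ky <- hy + L$thigh * k$y
    d <- unit_dir(kx, ky, hx, hy)
    a <- rot_dir(d$x, d$y, rot_sign * th_knee)
    ax <- kx + L$shank * a$x; ay <- ky + L$shank * a$y
    list(hip = cbind(hx, hy), shoulder = cbind(sx, sy),
         elbow = cbind(ex, ey), wrist = cbind(wx, wy),
         knee = cbind(kx, ky), ankle = cbind(ax, ay))
  }
  rgt <- side(+1, theta[, "right_shoulder"], theta[, "right_elbow"],
              theta[, "right_hip"], theta[, "right_knee"])
  lft <- side(-1, theta[, "left_shoulder"], theta[, "left_elbow"],
              theta[, "left_hip"], theta[, "left_knee"])
  d <- unit_dir(nx, ny, px, py)            # neck -> pelvis ray
  h <- rot_dir(d$x, d$y, theta[, "neck"])
  hx <- nx + L$head * h$x; hy <- ny + L$head * h$y
  pelvis_angle <- interior_angle_xy(lft$knee[, 1], lft$knee[, 2], px, py,
                                    rgt$knee[, 1], rgt$knee[, 2])
  pts <- list(
    head = cbind(hx, hy), neck = cbind(nx, ny), pelvis = cbind(px, py),
    right_shoulder = rgt$shoulder, right_elbow = rgt$elbow,
    right_wrist = rgt$wrist, right_hip = rgt$hip, right_knee = rgt$knee,
    right_ankle = rgt$ankle,
    left_shoulder = lft$shoulder, left_elbow = lft$elbow,
    left_wrist = lft$wrist, left_hip = lft$hip, left_knee = lft$knee,
    left_ankle = lft$ankle
  )
  lay <- skeleton_layout(layout)
  nj <- length(lay$joint_names)
  xm <- ym <- matrix(NA_real_, nf, nj)
  for (cn in .canonical_landmarks) {
    idx <- lay$canonical[[cn]]
    xm[, idx] <- pts[[cn]][, 1]
    ym[, idx] <- pts[[cn]][, 2]
  }
  if (layout == "body25") {
    # cosmetic landmarks not used by any registry angle
    off <- list(REye = c(-6, -6), LEye = c(6, -6), REar = c(-12, 0),
                LEar = c(12, 0))
    for (nm in names(off)) {
      j <- match(nm, lay$joint_names)
      xm[, j] <- hx + off[[nm]][1]; ym[, j] <- hy + off[[nm]][2]
    }
    feet <- list(RBigToe = c("right_ankle", 10, 8),
                 RSmallToe = c("right_ankle", 16, 8),
                 RHeel = c("right_ankle", -6, 4),
                 LBigToe = c("left_ankle", -10, 8),
                 LSmallToe = c("left_ankle", -16, 8),
                 LHeel = c("left_ankle", 6, 4))
    for (nm in names(feet)) {
      j <- match(nm, lay$joint_names)
      src <- pts[[feet[[nm]][1]]]
      xm[, j] <- src[, 1] + as.numeric(feet[[nm]][2])
      ym[, j] <- src[, 2] + as.numeric(feet[[nm]][3])
    }
  }
  video_id <- paste0("video_", video_index)
  stream <- stream_tibble(video_id, seq_len(nf) - 1L, lay,
                          as.vector(t(xm)), as.vector(t(ym)),
                          1, FALSE, fps)
  truth <- tibble::tibble(
    video_id = video_id,
    joint = rep(c(.driven_joints, "pelvis"), each = nf),
    frame = rep(seq_len(nf) - 1L, times = 10),
    fps = fps,
    angle = c(as.vector(theta) * 180 / pi, pelvis_angle),
    missing = FALSE
  )
  list(stream = stream, truth = truth, params = pars)
}

#' Degrade a keypoint stream according to a noise specification
#'
#' Applies, in order: the integer temporal lag (frame `f` takes the
#' coordinates of frame `f - lag`, clamped at the stream ends), i.i.d.
#' Gaussian pixel noise on every landmark coordinate, sparse
#' large-displacement outliers (a shift of `outlier_shift` pixels in a
#' uniform random direction), and landmark dropout (flagged missing,
#' confidence set to 0). Deterministic given `seed`. `injected_bias` is not
#' applied here — it acts on angle series, see [run_synthetic_study()].
#'
#' @param stream A keypoint-stream tibble.
#' @param noise A [noise_spec()].
#' @param seed Integer seed for the degradation draws.
#' @return A keypoint-stream tibble of identical shape.
#' @export
corrupt_stream <- function(stream, noise, seed = 1L) {
  stopifnot(inherits(noise, "noise_spec"))
  check_columns(stream, c("video_id", "frame", "joint", "x", "y",
                          "confidence", "missing"), "stream")
  out <- stream
  if (noise$injected_lag != 0L) {
    lag <- noise$injected_lag
    out <- out |>
      dplyr::group_by(.data$video_id, .data$joint) |>
      dplyr::arrange(.data$frame, .by_group = TRUE) |>
      dplyr::mutate(
        x = .data$x[pmin(pmax(dplyr::row_number() - lag, 1L), dplyr::n())],
        y = .data$y[pmin(pmax(dplyr::row_number() - lag, 1L), dplyr::n())]
      ) |>
      dplyr::ungroup()
  }
  n <- nrow(out)
  withr::with_seed(as.integer(seed), {
    if (noise$keypoint_noise_sd > 0) {
      out$x <- out$x + rnorm(n, 0, noise$keypoint_noise_sd)
      out$y <- out$y + rnorm(n, 0, noise$keypoint_noise_sd)
    }
    if (noise$outlier_prob > 0) {
      hit <- runif(n) < noise$outlier_prob
      ang <- runif(n, 0, 2 * pi)
      out$x <- out$x + ifelse(hit, noise$outlier_shift * cos(ang), 0)
      out$y <- out$y + ifelse(hit, noise$outlier_shift * sin(ang), 0)
    }
    if (noise$dropout_prob > 0) {
      drop <- runif(n) < noise$dropout_prob
      out$missing <- out$missing | drop
      out$confidence[drop] <- 0
    }
  })
  out
}

#' Generate a full paired synthetic data set
#'
#' For each video: the reference stream is the noise-free truth sampled at
#' `fps_reference` in the `panoptic15` layout; the candidate stream is the
#' same truth sampled at `fps_candidate` in the `body25` layout and degraded
#' per the [noise_spec()]. The manifest records every ground-truth parameter
#' so recovery tests can check the pipeline against what was injected.
#'
#' @param motion A [motion_spec()].
#' @param noise A [noise_spec()].
#' @param seed Seed for the degradation draws; defaults to `motion$seed`.
#' @return An object of class `paired_pose_dataset`: a list with
#'   `candidate`, `reference` (keypoint-stream tibbles), `truth` (angle
#'   tibble at the reference rate), and `manifest`.
#' @export
generate_paired_dataset <- function(motion, noise = noise_spec(),
                                    seed = motion$seed) {
  stopifnot(inherits(motion, "motion_spec"), inherits(noise, "noise_spec"))
  refs <- cands <- truths <- vector("list", motion$n_videos)
  params <- vector("list", motion$n_videos)
  for (i in seq_len(motion$n_videos)) {
    ref <- generate_truth_stream(motion, i, motion$fps_reference, "panoptic15")
    cand_truth <- generate_truth_stream(motion, i, motion$fps_candidate,
                                        "body25")
    refs[[i]] <- ref$stream
    truths[[i]] <- ref$truth
    cands[[i]] <- corrupt_stream(cand_truth$stream, noise,
                                 derive_seed(seed, 1000L + i))
    params[[i]] <- ref$params
  }
  structure(
    list(
      candidate = new_keypoint_stream(dplyr::bind_rows(cands)),
      reference = new_keypoint_stream(dplyr::bind_rows(refs)),
      truth = dplyr::bind_rows(truths),
      manifest = list(motion = motion, noise = noise, seed = seed,
                      video_params = params)
    ),
    class = "paired_pose_dataset"
  )
}

#' Add a constant bias to candidate angle series
#'
#' Used by recovery experiments: adds `bias` degrees to the `angle` column,
#' for the named joint(s) or for all joints.
#'
#' @param angles An angle tibble.
#' @param bias Bias in degrees.
#' @param joint Joint name(s) to bias; `NULL` = all.
#' @return The angle tibble with biased values.
#' @export
inject_angle_bias <- function(angles, bias, joint = NULL) {
  check_columns(angles, c("joint", "angle"), "angle tibble")
  sel <- if (is.null(joint)) rep(TRUE, nrow(angles)) else angles$joint %in% joint
  angles$angle[sel] <- angles$angle[sel] + bias
  angles
}
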