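# Independent oracles, coded separately from the package implementations.

# ICC(A,k) by a two-way ANOVA fitted with stats::aov on long-format data
icc_oracle_aov <- function(x, y) {
  n <- length(x)
  long <- data.frame(
    score = c(x, y),
    subject = factor(rep(seq_len(n), 2)),
    rater = factor(rep(c("a", "b"), each = n))
  )
  tab <- anova(stats::aov(score ~ subject + rater, data = long))
  msr <- tab["subject", "Mean Sq"]
  msc <- tab["rater", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  (msr - mse) / (msr + (msc - mse) / n)
}

# type-7 quantile by the textbook order-statistic interpolation formula
quantile_oracle <- function(x, p) {
  s <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# normalized triangular weights written out longhand
bartlett_weights_oracle <- function(m) {
  h <- (m - 1) / 2
  w <- c(0:h, (h - 1):0)
  w / sum(w)
}

# arccos of the normalized dot product (vs the package's atan2 route)
angle_acos_oracle <- function(a, b, c) {
  u <- a - b
  v <- c - b
  cc <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(pmax(cc, -1), 1)) * 180 / pi
}

# movement table with guaranteed high-frequency content, used by the lag
# experiments where a flat narrowband ccf peak would make exact argmax
# recovery ill-posed
broadband_movement <- function() {
  mv <- motion_spec()$movement
  mv$freq2 <- 0.8
  mv
}

# a complete angle tibble from a plain numeric vector
angles_from_values <- function(values, joint = "right_knee",
                               video_id = "v1", fps = 30) {
  tibble::tibble(
    video_id = video_id, joint = joint,
    frame = seq_along(values) - 1L, fps = fps,
    angle = values, missing = is.na(values)
  )
}

# a minimal single-video panoptic15 stream from per-landmark coordinate
# matrices (named list of n x 2 matrices)
stream_from_points <- function(pts, fps = 30) {
  lay <- skeleton_layout("panoptic15")
  nf <- nrow(pts[[1]])
  rows <- lapply(lay$joint_names, function(jn) jn)
  canon_of <- setNames(names(lay$canonical), lay$canonical)
  tb <- tidyr::crossing(frame = 0:(nf - 1), joint = lay$joint_names) |>
    dplyr::mutate(video_id = "v1", .before = 1)
  idx <- match(tb$joint, lay$joint_names)
  cn <- canon_of[as.character(idx)]
  tb$x <- mapply(function(c1, f) pts[[c1]][f + 1, 1], cn, tb$frame)
  tb$y <- mapply(function(c1, f) pts[[c1]][f + 1, 2], cn, tb$frame)
  tb$confidence <- 1
  tb$missing <- FALSE
  tb$fps <- fps
  tb$layout <- "panoptic15"
  tb
}
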