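# Readers/writers and the missingness conventions.

body25_frame <- function(coords25) {
  # coords25: 25 x 3 matrix -> flat 75-number list
  as.numeric(t(coords25))
}

test_that("body25 reader parses frames and applies the (0,0)/zero-confidence sentinel", {
  set.seed(11)
  good <- cbind(matrix(runif(50, 1, 500), 25, 2), runif(25, 0.5, 1))
  bad <- good
  bad[5, ] <- c(0, 0, 0) # landmark 4 in 0-based numbering
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(body25_frame(good), body25_frame(bad)), path,
                       digits = NA)
  s <- read_body25_json(path, video_id = "v", fps = 30)
  expect_equal(nrow(s), 50)
  expect_equal(unique(s$layout), "body25")
  f0 <- s[s$frame == 0, ]
  expect_false(any(f0$missing))
  f1 <- s[s$frame == 1, ]
  expect_identical(f1$joint[f1$missing], "RWrist") # index 4, 0-based
})

test_that("body25 reader rejects malformed records and wrong landmark counts", {
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(as.list(rep(1, 60))), path)
  expect_error(read_body25_json(path), class = "poseagree_layout_error")
  writeLines('[["a", "b"]]', path)
  expect_error(read_body25_json(path), class = "poseagree_parse_error")
})

test_that("each writer/reader pair round-trips synthetic streams exactly", {
  m <- motion_spec(n_videos = 3, duration_s = 100 / 30, seed = 5)
  b25 <- generate_truth_stream(m, 1, layout = "body25")$stream
  p15 <- generate_truth_stream(m, 1, layout = "panoptic15")$stream

  jb <- withr::local_tempfile(fileext = ".json")
  write_body25_json(b25, jb)
  back <- read_body25_json(jb, video_id = "video_1", fps = 30)
  expect_equal(nrow(back), nrow(b25))
  expect_identical(back$x, b25$x)
  expect_identical(back$y, b25$y)
  expect_identical(back$missing, b25$missing)

  jp <- withr::local_tempfile(fileext = ".json")
  write_panoptic_pose(p15, jp)
  back <- read_panoptic_pose(jp, video_id = "video_1", fps = 30)
  expect_identical(back$x, p15$x)
  expect_identical(back$y, p15$y)

  # multi-video CSV round trip, including a missing landmark
  all3 <- dplyr::bind_rows(lapply(1:3, function(i) {
    generate_truth_stream(m, i, layout = "panoptic15")$stream
  }))
  all3$missing[all3$frame == 7 & all3$joint == "RWrist" &
                 all3$video_id == "video_2"] <- TRUE
  cs <- withr::local_tempfile(fileext = ".csv")
  write_keypoints_csv(all3, cs)
  back <- read_keypoints_csv(cs, layout = "panoptic15", fps = 30)
  expect_setequal(unique(back$video_id), paste0("video_", 1:3))
  key <- function(d) d[order(d$video_id, d$frame, d$joint), ]
  b <- key(back); a <- key(all3)
  expect_identical(b$missing, a$missing)
  expect_identical(b$x[!b$missing], a$x[!a$missing])
  expect_identical(b$y[!b$missing], a$y[!a$missing])
})

test_that("panoptic reader handles 15-landmark frames, nulls, and all-null landmarks", {
  set.seed(3)
  fr <- function(drop_head = FALSE) {
    e <- lapply(1:15, function(j) c(runif(1, 1, 100), runif(1, 1, 100), 1))
    if (drop_head) e[2] <- list(NULL)
    e
  }
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(fr()), path, digits = NA)
  s <- read_panoptic_pose(path, fps = 30)
  expect_equal(length(unique(s$frame)), 1L)
  expect_equal(nrow(s), 15L)
  expect_false(any(s$missing))

  # head entry null in every frame: absent, not an error
  jsonlite::write_json(list(fr(TRUE), fr(TRUE)), path, digits = NA,
                       null = "null")
  expect_message(s2 <- read_panoptic_pose(path, fps = 30), "Head")
  expect_true(all(s2$missing[s2$joint == "Head"]))
  expect_false(any(s2$missing[s2$joint != "Head"]))

  jsonlite::write_json(list(fr()[1:14]), path, digits = NA)
  expect_error(read_panoptic_pose(path), class = "poseagree_layout_error")
})

test_that("csv reader builds one stream per video, flags absent rows, rejects duplicates", {
  df <- tidyr::crossing(video_id = c("a", "b"), frame = 0:2,
                        joint_id = skeleton_layout("panoptic15")$joint_names)
  set.seed(8)
  df$x <- runif(nrow(df), 1, 100)
  df$y <- runif(nrow(df), 1, 100)
  # drop one (video, frame, joint) row -> flagged missing on read
  df_drop <- df[!(df$video_id == "a" & df$frame == 1 & df$joint_id == "LKnee"), ]
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(df_drop, path)
  s <- read_keypoints_csv(path, "panoptic15", fps = 25)
  expect_equal(dplyr::n_distinct(s$video_id), 2L)
  expect_equal(nrow(s), 2 * 3 * 15)
  expect_identical(
    s$missing[s$video_id == "a" & s$frame == 1 & s$joint == "LKnee"], TRUE
  )
  expect_equal(sum(s$missing), 1L)
  expect_equal(unique(s$fps), 25)

  readr::write_csv(rbind(df_drop, df_drop[1, ]), path)
  expect_error(read_keypoints_csv(path, "panoptic15"),
               class = "poseagree_parse_error")
})

test_that("custom layouts validate canonical indices", {
  expect_error(skeleton_layout("mystery"), class = "poseagree_layout_error")
  expect_error(
    skeleton_layout("bad", joint_names = c("a", "b"),
                    canonical = c(neck = 1L, head = 3L)),
    class = "poseagree_layout_error"
  )
  lay <- skeleton_layout("mini", joint_names = c("n", "h"),
                         canonical = c(neck = 1L, head = 2L))
  expect_identical(lay$canonical[["pelvis"]], NA_integer_)
})
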