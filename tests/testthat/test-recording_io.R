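test_that("gaze CSV round trip preserves samples and renormalizes directions", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(t = c(0, 1, 2) / 120, gx = c(0, 0, 0), gy = c(0, 0, 0),
                   gz = c(1, 2, 1), px = c(10, 11, 12), py = c(20, 21, 22),
                   label = c(1L, 3L, 1L))
  write.csv(df, path, row.names = FALSE)
  rec <- read_gaze_csv(path)
  expect_s3_class(rec, "gaze_recording")
  expect_equal(nrow(rec$samples), 3)
  expect_equal(rec$samples$label, c(1L, 3L, 1L))
  # gz = 2 renormalized to a unit vector
  expect_equal(rec$samples$gz[2], 1)
  out <- withr::local_tempfile(fileext = ".csv")
  write_gaze_csv(rec, out)
  rec2 <- read_gaze_csv(out)
  expect_equal(rec2$samples$t, rec$samples$t)
  expect_equal(rec2$samples$label, rec$samples$label)
})

test_that("readers reject invariant violations instead of coercing", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(t = c(0, 1, 2), gx = 0, gy = 0, gz = 1,
                   px = 0, py = 0, label = c(1L, 7L, 1L))
  write.csv(df, path, row.names = FALSE)
  expect_error(read_gaze_csv(path), "row 2", class = "gazevents_data_error")

  df$label <- 1L
  df$t <- c(0, 2, 1)
  write.csv(df, path, row.names = FALSE)
  expect_error(read_gaze_csv(path), "increasing", class = "gazevents_data_error")

  df2 <- df[, setdiff(names(df), "px")]
  write.csv(df2, path, row.names = FALSE)
  expect_error(read_gaze_csv(path), "px", class = "gazevents_format_error")
})

test_that("clean_recording removes blinks/unlabeled and flags cuts", {
  rec <- make_label_recording(c(1, 5, 5, 1))
  cl <- clean_recording(rec)
  expect_equal(nrow(cl$samples), 2)
  expect_equal(cl$samples$cut_before, c(FALSE, TRUE))

  rec2 <- make_label_recording(c(1, 1, 1))
  cl2 <- clean_recording(rec2)
  expect_equal(cl2$samples$label, rec2$samples$label)
  expect_false(any(cl2$samples$cut_before))

  rec3 <- make_label_recording(c(0, 0, 5))
  expect_error(clean_recording(rec3), class = "gazevents_data_error")
})

test_that("clean_recording honors calibration windows and is idempotent", {
  labels <- c(1, 1, 2, 2, 5, 3, 3, 0, 4, 4)
  rec <- make_label_recording(labels)
  win <- list(c(rec$samples$t[3], rec$samples$t[4]))  # removes the 2s
  cl <- clean_recording(rec, win)
  expect_equal(cl$samples$label, c(1L, 1L, 3L, 3L, 4L, 4L))
  expect_equal(which(cl$samples$cut_before), c(3L, 5L))
  # count bookkeeping: removed = labels in {0,5} plus windowed samples
  expect_equal(nrow(rec$samples) - nrow(cl$samples),
               sum(labels %in% c(0, 5)) + 2)
  cl2 <- clean_recording(cl, win)
  expect_identical(cl2$samples, cl$samples)
})

test_that("intrinsics JSON round trip and validation", {
  K <- camera_intrinsics(280, 280, 159.5, 119.5, 320, 240)
  path <- withr::local_tempfile(fileext = ".json")
  write_intrinsics(K, path)
  K2 <- read_intrinsics(path)
  expect_equal(unclass(K2), unclass(K))
  expect_error(camera_intrinsics(-1, 280, 160, 120, 320, 240),
               class = "gazevents_validation_error")
  expect_error(camera_intrinsics(280, 280, 400, 120, 320, 240),
               class = "gazevents_validation_error")
})

test_that("scene video directory reader enforces frame/timestamp agreement", {
  dir <- withr::local_tempdir()
  frames_dir <- file.path(dir, "frames")
  dir.create(frames_dir)
  set.seed(7)
  for (i in 1:5) {
    png::writePNG(matrix(runif(24 * 32), 24, 32),
                  file.path(frames_dir, sprintf("frame_%03d.png", i)))
  }
  kpath <- file.path(dir, "intrinsics.json")
  write_intrinsics(camera_intrinsics(30, 30, 15.5, 11.5, 32, 24), kpath)
  # constant-rate declaration
  v <- read_scene_video(frames_dir, kpath, rate = 30)
  expect_equal(v$n_frames, 5)
  expect_equal(v$frame_times, (0:4) / 30)
  expect_equal(dim(get_frame(v, 3)), c(24, 32))
  # sidecar with a mismatched count
  write.csv(data.frame(t = (0:3) / 30), file.path(frames_dir, "frame_times.csv"),
            row.names = FALSE)
  expect_error(read_scene_video(frames_dir, kpath),
               class = "gazevents_format_error")
  # no sidecar and no rate
  file.remove(file.path(frames_dir, "frame_times.csv"))
  expect_error(read_scene_video(frames_dir, kpath),
               class = "gazevents_format_error")
})

test_that("feature table round trip is exact to 1e-12 and checks columns", {
  set.seed(42)
  fm <- make_label_fm(sample(1:4, 10, replace = TRUE))
  for (nm in gazevents:::FEATURE_ORDER) fm[[nm]] <- rnorm(10)
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(fm, path)
  fm2 <- read_feature_table(path)
  for (nm in c("t", gazevents:::FEATURE_ORDER)) {
    expect_lt(max(abs(fm2[[nm]] - fm[[nm]])), 1e-12)
  }
  expect_identical(fm2$label, fm$label)
  expect_identical(fm2$cut_before, fm$cut_before)
  # missing column rejected
  bad <- fm; bad$patch_sim <- NULL
  expect_error(write_feature_table(bad, path),
               class = "gazevents_format_error")
  txt <- readLines(path)
  writeLines(txt[1:1][0], path)  # empty file
  writeLines(sub("patch_sim,", "", txt[1]), path)
  expect_error(read_feature_table(path), class = "gazevents_format_error")
  # empty matrix: header-only file round trips
  write_feature_table(fm[0, ], path)
  fm0 <- read_feature_table(path)
  expect_equal(nrow(fm0), 0)
})
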