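test_that("scene textures are seeded, distinct and textured everywhere", {
  t1 <- build_scene_texture(5, c(512, 256))
  t2 <- build_scene_texture(5, c(512, 256))
  t3 <- build_scene_texture(6, c(512, 256))
  expect_identical(t1, t2)
  expect_false(identical(t1, t3))
  expect_error(build_scene_texture(5, c(100, 100), frame_size = c(64, 48)),
               class = "gazevents_argument_error")
  # local structure on a 16x16 grid so corners are detectable anywhere
  for (by in seq(1, 256 - 16, by = 16)) {
    for (bx in seq(1, 512 - 16, by = 16)) {
      expect_gt(sd(t1[by:(by + 15), bx:(bx + 15)]), 0)
    }
  }
})

test_that("scripted timelines obey the event kinematics", {
  # pure fixation: eye speed stays at the jitter floor
  cfg <- sim_config(duration = 2, seed = 1,
                    event_script = list(list(type = "GFi", duration = 2)))
  gt <- simulate_recording(cfg)
  ser <- compute_eye_series(clean_recording(gt$gaze))
  # jitter-implied pairwise speed: sd of angle diff ~ sqrt(2)*2*noise_sd*rate
  jitter_speed <- sqrt(2) * 2 * cfg$noise_sd * cfg$gaze_rate
  expect_lte(max(ser$eye_vel), 3 * jitter_speed)

  # gaze following at 20 deg/s: the eye counter-rotates at the yaw rate and
  # the reported gaze point stays on the reprojected world target
  cfg2 <- sim_config(duration = 1, seed = 2, noise_sd = 0,
                     event_script = list(list(type = "GFo", duration = 1,
                                              gfo_mode = "yaw",
                                              yaw_rate = 20)))
  gt2 <- simulate_recording(cfg2)
  ser2 <- compute_eye_series(clean_recording(gt2$gaze))
  expect_equal(median(ser2$eye_vel), 20, tolerance = 0.05 * 20)
  ev <- gt2$timeline$events
  W <- c(ev$wx[1], ev$wy[1], gazevents:::WORLD$z_bg)
  K <- gt2$video$intrinsics
  s <- gt2$gaze$samples
  poses <- gazevents:::pose_at_times(ev, s$t)
  for (i in seq(1, nrow(s), by = 17)) {
    C <- t(gazevents:::rot_y(poses$yaw[i]))
    v <- C %*% (W - c(poses$x[i], 0, 0))
    expect_lt(abs(K$fx * v[1] / v[3] + K$cx - s$px[i]), 2)
    expect_lt(abs(K$fy * v[2] / v[3] + K$cy - s$py[i]), 2)
  }

  # a scripted 50 ms gaze shift peaks inside the 200-500 deg/s band
  cfg3 <- sim_config(duration = 1.05, seed = 3, noise_sd = 0,
                     event_script = list(
                       list(type = "GFi", duration = 0.5),
                       list(type = "GS", duration = 0.05, peak_vel = 375),
                       list(type = "GFi", duration = 0.5)))
  gt3 <- simulate_recording(cfg3)
  ser3 <- compute_eye_series(clean_recording(gt3$gaze))
  expect_gte(max(ser3$eye_vel), 200)
  expect_lte(max(ser3$eye_vel), 500)
  # label timeline matches the script to one gaze-sample quantum
  labs <- gt3$gaze$samples$label
  expect_equal(sum(labs == 3), round(0.05 * cfg3$gaze_rate), tolerance = 1)
})

test_that("kinematics out of plausible range are rejected", {
  bad <- sim_config(duration = 1, seed = 1,
                    event_script = list(list(type = "GP", duration = 1,
                                             obj_speed = 90)))
  expect_error(simulate_recording(bad), class = "gazevents_validation_error")
  expect_error(sim_config(duration = 0), class = "gazevents_validation_error")
  mism <- sim_config(duration = 2, seed = 1,
                     event_script = list(list(type = "GFi", duration = 1)))
  expect_error(simulate_recording(mism), class = "gazevents_validation_error")
})

test_that("simulated recordings have the configured shape and determinism", {
  cfg <- sim_config(duration = 10, seed = 0)
  gt <- simulate_recording(cfg)
  expect_equal(nrow(gt$gaze$samples), 1200)
  expect_equal(gt$video$n_frames, 300)
  expect_true(all(gt$gaze$samples$label %in% 1:4))
  # byte-identical rerun: gaze CSV and a rendered frame
  gt2 <- simulate_recording(cfg)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_gaze_csv(gt$gaze, file.path(d1, "g.csv"))
  write_gaze_csv(gt2$gaze, file.path(d2, "g.csv"))
  expect_identical(readLines(file.path(d1, "g.csv")),
                   readLines(file.path(d2, "g.csv")))
  expect_identical(get_frame(gt$video, 137), get_frame(gt2$video, 137))
  # blink injection produces label-5 sections for clean_recording to drop
  cfgb <- sim_config(duration = 5, seed = 1, blink_rate = 0.6)
  gtb <- simulate_recording(cfgb)
  expect_gt(sum(gtb$gaze$samples$label == 5), 0)
  cl <- clean_recording(gtb$gaze)
  expect_false(any(cl$samples$label == 5))
  expect_gt(sum(cl$samples$cut_before), 0)
})

test_that("recovered VO on a scripted yaw clip matches the ground truth", {
  v <- simulate_camera_clip(seed = 9, n_frames = 8, yaw_rate = 15)
  ser <- compute_camera_series(v)
  expect_equal(mean(ser$head_rot_vel[ser$valid]), 15, tolerance = 0.1 * 15)
})

test_that("a written recording round-trips through the disk format", {
  dir <- withr::local_tempdir()
  gt <- simulate_recording(sim_config(duration = 1.2, seed = 4), dir = dir)
  expect_true(file.exists(file.path(dir, "gaze.csv")))
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  rec <- read_gaze_csv(file.path(dir, "gaze.csv"))
  expect_equal(nrow(rec$samples), nrow(gt$gaze$samples))
  video <- read_scene_video(file.path(dir, "frames"),
                            file.path(dir, "intrinsics.json"))
  expect_equal(video$n_frames, gt$video$n_frames)
  # PNG encoding is 8-bit; frames agree to quantization
  expect_lt(max(abs(get_frame(video, 5) - get_frame(gt$video, 5))), 1 / 254)
})
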