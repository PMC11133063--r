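# Ground-truth geometry helpers for this file: project synthetic 3-D points
# through a known relative pose and check what the estimators recover.
make_correspondences <- function(R, t, n = 60, seed = 5) {
  set.seed(seed)
  X <- cbind(runif(n, -1, 1), runif(n, -0.7, 0.7),
             runif(n, 2.5, 6))                     # points in frame a
  Xb <- t(R %*% t(X)) + matrix(t, n, 3, byrow = TRUE)
  list(xa = X[, 1:2] / X[, 3], xb = Xb[, 1:2] / Xb[, 3])
}

test_that("eight-point recovers a known essential matrix and pose", {
  R <- gazevents:::rot_axis(c(0.2, 1, 0.1), 1.5)
  tr <- c(0.04, 0.01, 0.005)
  co <- make_correspondences(R, tr)
  E <- gazevents:::eight_point(co$xa, co$xb)
  E_true <- gazevents:::cross_mat(tr) %*% R
  E_true <- E_true / sqrt(sum(E_true^2))
  E <- E / sqrt(sum(E^2))
  if (sum(E * E_true) < 0) E <- -E
  expect_lt(max(abs(E - E_true)), 1e-6)
  dec <- gazevents:::decompose_essential(E, co$xa, co$xb)
  expect_lt(gazevents:::rotmat_angle_deg(dec$R, R), 0.01)
  t_unit <- tr / sqrt(sum(tr^2))
  expect_lt(max(abs(dec$t - t_unit)), 1e-4)
})

test_that("Kabsch rotation fit is exact on pure-rotation rays", {
  R <- gazevents:::rot_axis(c(0, 1, 0.3), 2)
  set.seed(6)
  A <- gazevents:::normalize_rows(cbind(runif(40, -0.5, 0.5),
                                        runif(40, -0.4, 0.4), 1))
  B <- A %*% t(R)
  Rhat <- gazevents:::kabsch_rotation(A, B)
  expect_lt(gazevents:::rotmat_angle_deg(Rhat, R), 1e-9)
})

test_that("identical frames give an identity pose with full support", {
  v <- simulate_camera_clip(seed = 21, n_frames = 2)
  f <- get_frame(v, 1)
  pose <- estimate_relative_pose(f, f, v$intrinsics)
  expect_true(pose$valid)
  expect_lt(quat_angle_deg(pose$q), 0.05)
  expect_gt(pose$n_inliers, 100)
  expect_identical(pose$model, "rotation")
  expect_true(all(is.na(pose$t_unit)))
})

test_that("a 1-degree yaw between frames is recovered within 0.1 degree", {
  v <- simulate_camera_clip(seed = 22, n_frames = 2, yaw_rate = 30)  # 1 deg/frame
  pose <- estimate_relative_pose(get_frame(v, 1), get_frame(v, 2), v$intrinsics)
  expect_true(pose$valid)
  expect_equal(quat_angle_deg(pose$q), 1.0, tolerance = 0.1)
})

test_that("lateral translation yields near-zero rotation and an essential pose", {
  # 1% of background depth per frame: 0.04 m at 4 m
  v <- simulate_camera_clip(seed = 23, n_frames = 2, trans_vel = 0.04 * 30)
  pose <- estimate_relative_pose(get_frame(v, 1), get_frame(v, 2), v$intrinsics)
  expect_true(pose$valid)
  expect_lte(quat_angle_deg(pose$q), 0.1)
})

test_that("pose-to-feature conversion follows the definitions", {
  idpose <- structure(list(q = c(1, 0, 0, 0), R = diag(3),
                           t_unit = rep(NA_real_, 3), model = "rotation",
                           n_inliers = 50L, valid = TRUE,
                           inlier_residuals_px = rep(0, 50)),
                      class = "relative_pose")
  f <- pose_to_motion_features(idpose, 1 / 30)
  expect_equal(unlist(f), c(head_rot_vel = 0, head_rot_dir = 0,
                            body_trans_vel = 0))
  # 0.5 deg pure rightward yaw over one 30 fps frame -> 15 deg/s, dir 0
  Ry <- t(gazevents:::rot_y(0.5))
  yawpose <- idpose
  yawpose$q <- quat_from_rotmat(Ry); yawpose$R <- Ry
  fy <- pose_to_motion_features(yawpose, 1 / 30)
  expect_equal(fy$head_rot_vel, 15, tolerance = 1e-9)
  expect_equal(fy$head_rot_dir, 0, tolerance = 1e-6)
  # upward pitch maps to 90 deg
  Rx <- t(gazevents:::rot_x(0.5))
  pitchpose <- idpose
  pitchpose$q <- quat_from_rotmat(Rx); pitchpose$R <- Rx
  expect_equal(pose_to_motion_features(pitchpose, 1 / 30)$head_rot_dir, 90,
               tolerance = 1e-6)
  expect_error(pose_to_motion_features(idpose, 0),
               class = "gazevents_argument_error")
})

test_that("camera series on scripted clips recovers the scripted motion", {
  # static clip: negligible rotation everywhere
  vs <- simulate_camera_clip(seed = 24, n_frames = 10)
  ser_s <- compute_camera_series(vs)
  expect_equal(nrow(ser_s), 9)
  expect_true(all(ser_s$valid))
  expect_true(all(ser_s$head_rot_vel < 0.5))
  # 10 deg/s yaw clip at 30 fps
  vy <- simulate_camera_clip(seed = 25, n_frames = 10, yaw_rate = 10)
  ser_y <- compute_camera_series(vy)
  expect_equal(mean(ser_y$head_rot_vel[ser_y$valid]), 10, tolerance = 0.1 * 10)
  # composing per-pair rotations recovers the total yaw within 5%
  expect_equal(sum(ser_y$head_rot_vel[ser_y$valid]) / 30,
               10 * 9 / 30, tolerance = 0.05 * 3)
  # quaternions are canonical
  p <- estimate_relative_pose(get_frame(vy, 1), get_frame(vy, 2), vy$intrinsics)
  expect_gte(p$q[1], 0)
})

test_that("injected ground-truth poses drive the same downstream features", {
  vy <- simulate_camera_clip(seed = 26, n_frames = 6, yaw_rate = 12)
  dyaw <- 12 / 30
  q <- quat_from_rotmat(gazevents:::rot_y(-dyaw))
  poses <- data.frame(frame_pair_index = 1:5, qw = q[1], qx = q[2],
                      qy = q[3], qz = q[4], trans_proxy = 0.2)
  ser <- compute_camera_series(vy, poses = poses)
  expect_true(all(ser$valid))
  expect_equal(ser$head_rot_vel, rep(12, 5), tolerance = 1e-9)
  expect_equal(ser$head_rot_dir, rep(0, 5), tolerance = 1e-6)
  expect_equal(ser$body_trans_vel, rep(0.2 * 30, 5), tolerance = 1e-9)
  # the pose file reader round-trips the injection format
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(poses, path, row.names = FALSE)
  expect_equal(read_pose_csv(path), poses)
})

test_that("downscaled matching recovers the same rotation in full-res units", {
  v <- simulate_camera_clip(seed = 28, n_frames = 2, yaw_rate = 30)
  cfg <- vo_config(downscale = 2)
  pose <- estimate_relative_pose(get_frame(v, 1), get_frame(v, 2),
                                 v$intrinsics, cfg)
  expect_true(pose$valid)
  expect_equal(quat_angle_deg(pose$q), 1.0, tolerance = 0.15)
})

test_that("argument and degeneracy guards", {
  v <- simulate_camera_clip(seed = 27, n_frames = 2)
  f <- get_frame(v, 1)
  expect_error(estimate_relative_pose(f, f[1:100, ], v$intrinsics),
               class = "gazevents_argument_error")
  # a textureless pair yields an invalid pose, not an exception
  flat <- matrix(0.5, 240, 320)
  pose <- estimate_relative_pose(flat, flat, v$intrinsics)
  expect_false(pose$valid)
  ser <- scene_video(list(flat, flat), c(0, 1 / 30), v$intrinsics)
  expect_error(compute_camera_series(ser), class = "gazevents_pipeline_error")
})
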