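# Classical monocular visual odometry over consecutive scene-camera frames.
#
# Each frame pair yields a relative rotation (unit quaternion, canonical
# w >= 0) and a scale-free translation proxy. Because monocular metric scale
# is unobservable, body translation is reported as the median derotated
# image parallax in pixels per second: zero when the wearer is stationary or
# only rotating the head, large when walking.
#
# Two motion models compete per pair: a rotation-only model (Kabsch fit on
# bearing rays inside RANSAC) and a full essential-matrix model (8-point
# inside RANSAC, cheirality-checked decomposition). Under pure rotation the
# essential matrix is degenerate - E = [t]x R satisfies the epipolar
# constraint for arbitrary t - so the rotation model is preferred whenever
# its inlier support reaches a fixed fraction of the essential support.

#' Visual-odometry settings
#'
#' @param max_keypoints keypoint budget per frame.
#' @param thresh_px robust-consensus reprojection threshold in pixels.
#' @param min_inliers minimum inlier count for a valid pose.
#' @param max_disp maximum match displacement in pixels (default 50).
#' @param min_score minimum descriptor ZNCC score for a match.
#' @param desc_half half-width of the descriptor patch.
#' @param ransac_iters RANSAC iteration cap.
#' @param rot_pref rotation model is chosen when its inlier count is at
#'   least this fraction of the essential-model inlier count.
#' @param downscale integer downscale factor applied before matching
#'   (1 = none).
#' @param quality Harris quality level (fraction of the top response).
#' @return list of class `vo_config`.
#' @export
vo_config <- function(max_keypoints = 500, thresh_px = 1.0, min_inliers = 15,
                      max_disp = 50, min_score = 0.6, desc_half = 5,
                      ransac_iters = 250, rot_pref = 0.97, downscale = 1,
                      quality = 0.005) {
  structure(list(max_keypoints = max_keypoints, thresh_px = thresh_px,
                 min_inliers = min_inliers, max_disp = max_disp,
                 min_score = min_score, desc_half = desc_half,
                 ransac_iters = ransac_iters, rot_pref = rot_pref,
                 downscale = downscale, quality = quality),
            class = "vo_config")
}

# Pixels -> unit bearing rays in the camera frame.
pixels_to_rays <- function(x, y, K) {
  normalize_rows(cbind((x - K$cx) / K$fx, (y - K$cy) / K$fy, 1))
}

# Camera-frame points/rays -> pixels.
rays_to_pixels <- function(r, K) {
  cbind(K$fx * r[, 1] / r[, 3] + K$cx, K$fy * r[, 2] / r[, 3] + K$cy)
}

# Least-squares rotation R minimizing sum |b_i - R a_i|^2 (Kabsch).
kabsch_rotation <- function(A, B) {
  H <- crossprod(A, B)          # sum a b^T
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  s$v %*% diag(c(1, 1, d)) %*% t(s$u)
}

# Reprojection residuals (pixels) of the rotation-only model.
rotation_residuals <- function(R, rays_a, px_b, K) {
  pred <- rays_a %*% t(R)
  pp <- rays_to_pixels(pred, K)
  sqrt(rowSums((pp - px_b)^2))
}

fit_rotation_ransac <- function(rays_a, rays_b, px_b, K, thresh_px, iters) {
  n <- nrow(rays_a)
  if (n < 3) return(NULL)
  best <- NULL; best_n <- -1
  it <- 0; max_it <- iters
  while (it < max_it) {
    it <- it + 1
    idx <- sample.int(n, 3)
    R <- kabsch_rotation(rays_a[idx, , drop = FALSE], rays_b[idx, , drop = FALSE])
    res <- rotation_residuals(R, rays_a, px_b, K)
    nin <- sum(res < thresh_px)
    if (nin > best_n) {
      best_n <- nin; best <- R
      ratio <- max(nin / n, 1e-3)
      # adaptive iteration count (99% confidence, minimal sample of 3)
      need <- log(0.01) / log(1 - ratio^3 + 1e-12)
      max_it <- min(iters, max(20, ceiling(need)))
    }
  }
  inl <- rotation_residuals(best, rays_a, px_b, K) < thresh_px
  if (sum(inl) >= 3) {
    best <- kabsch_rotation(rays_a[inl, , drop = FALSE], rays_b[inl, , drop = FALSE])
    inl <- rotation_residuals(best, rays_a, px_b, K) < thresh_px
  }
  list(R = best, inliers = inl)
}

# Normalized 8-point algorithm; xa, xb are n x 2 matrices of normalized
# image coordinates. Returns the rank-2-projected essential matrix with
# the convention x_b^T E x_a = 0.
eight_point <- function(xa, xb) {
  norm_pts <- function(p) {
    ctr <- colMeans(p)
    q <- sweep(p, 2, ctr)
    s <- sqrt(2) / mean(sqrt(rowSums(q^2)))
    T <- matrix(c(s, 0, 0, 0, s, 0, -s * ctr[1], -s * ctr[2], 1), 3, 3)
    list(p = q * s, T = T)
  }
  na <- norm_pts(xa); nb <- norm_pts(xb)
  A <- cbind(nb$p[, 1] * na$p[, 1], nb$p[, 1] * na$p[, 2], nb$p[, 1],
             nb$p[, 2] * na$p[, 1], nb$p[, 2] * na$p[, 2], nb$p[, 2],
             na$p[, 1], na$p[, 2], 1)
  e <- svd(A, nu = 0, nv = 9)$v[, 9]
  E <- matrix(e, 3, 3, byrow = TRUE)
  E <- t(nb$T) %*% E %*% na$T
  s <- svd(E)
  s$u %*% diag(c(1, 1, 0)) %*% t(s$v)
}

# First-order (Sampson) epipolar distance in normalized coordinates.
sampson_dist <- function(E, xa, xb) {
  ha <- cbind(xa, 1); hb <- cbind(xb, 1)
  Ea <- ha %*% t(E)           # rows = E x_a
  Eb <- hb %*% E              # rows = E^T x_b
  num <- rowSums(hb * Ea)^2
  den <- Ea[, 1]^2 + Ea[, 2]^2 + Eb[, 1]^2 + Eb[, 2]^2
  sqrt(num / pmax(den, 1e-300))
}

cross_mat <- function(t) {
  matrix(c(0, t[3], -t[2], -t[3], 0, t[1], t[2], -t[1], 0), 3, 3)
}

# Decompose an essential matrix into (R, t) with X_b = R X_a + t, using the
# cheirality check over the supplied correspondences.
decompose_essential <- function(E, xa, xb) {
  s <- svd(E)
  U <- s$u; V <- s$v
  if (det(U) < 0) U <- -U
  if (det(V) < 0) V <- -V
  W <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  cands <- list(list(R = U %*% W %*% t(V), t = U[, 3]),
                list(R = U %*% W %*% t(V), t = -U[, 3]),
                list(R = U %*% t(W) %*% t(V), t = U[, 3]),
                list(R = U %*% t(W) %*% t(V), t = -U[, 3]))
  ha <- cbind(xa, 1); hb <- cbind(xb, 1)
  best <- NULL; best_n <- -1
  for (cand in cands) {
    Ra <- ha %*% t(cand$R)      # rows = R x_a
    # depth in frame a from [x_b]x (d R x_a + t) = 0, least squares
    cb1 <- hb[, 2] * Ra[, 3] - hb[, 3] * Ra[, 2]
    cb2 <- hb[, 3] * Ra[, 1] - hb[, 1] * Ra[, 3]
    cb3 <- hb[, 1] * Ra[, 2] - hb[, 2] * Ra[, 1]
    tb1 <- hb[, 2] * cand$t[3] - hb[, 3] * cand$t[2]
    tb2 <- hb[, 3] * cand$t[1] - hb[, 1] * cand$t[3]
    tb3 <- hb[, 1] * cand$t[2] - hb[, 2] * cand$t[1]
    den <- cb1^2 + cb2^2 + cb3^2
    d <- -(cb1 * tb1 + cb2 * tb2 + cb3 * tb3) / pmax(den, 1e-300)
    zb <- d * Ra[, 3] + cand$t[3]
    nok <- sum(d > 0 & zb > 0)
    if (nok > best_n) { best_n <- nok; best <- cand }
  }
  best
}

fit_essential_ransac <- function(xa, xb, thresh_n, iters) {
  n <- nrow(xa)
  if (n < 8) return(NULL)
  best_E <- NULL; best_n <- -1
  it <- 0; max_it <- iters
  while (it < max_it) {
    it <- it + 1
    idx <- sample.int(n, 8)
    E <- tryCatch(eight_point(xa[idx, , drop = FALSE], xb[idx, , drop = FALSE]),
                  error = function(e) NULL)
    if (is.null(E)) next
    nin <- sum(sampson_dist(E, xa, xb) < thresh_n)
    if (nin > best_n) {
      best_n <- nin; best_E <- E
      ratio <- max(nin / n, 1e-3)
      need <- log(0.01) / log(1 - ratio^8 + 1e-12)
      max_it <- min(iters, max(30, ceiling(need)))
    }
  }
  if (is.null(best_E)) return(NULL)
  inl <- sampson_dist(best_E, xa, xb) < thresh_n
  if (sum(inl) >= 8) {
    best_E <- eight_point(xa[inl, , drop = FALSE], xb[inl, , drop = FALSE])
    inl <- sampson_dist(best_E, xa, xb) < thresh_n
  }
  list(E = best_E, inliers = inl)
}

#' Detect corners and extract descriptors for one frame
#'
#' Bundles [harris_corners()] with normalized patch descriptors so that a
#' frame shared by two consecutive pairs is only processed once.
#'
#' @param img grayscale matrix.
#' @param cfg a [vo_config()].
#' @param kp optional precomputed corners.
#' @return list with `corners` data.frame and `desc` descriptor matrix.
#' @export
frame_features <- function(img, cfg = vo_config(), kp = NULL) {
  img <- downscale_frame(img, cfg$downscale)
  if (is.null(kp)) kp <- harris_corners(img, cfg$max_keypoints, cfg$quality)
  patch_descriptors(img, kp, cfg$desc_half)
}

# Integer subsampling used by the optional VO downscale; all detector and
# matcher coordinates then live in the downscaled geometry.
downscale_frame <- function(img, ds) {
  ds <- max(1L, as.integer(ds))
  if (ds == 1L) return(img)
  img[seq(1, nrow(img), by = ds), seq(1, ncol(img), by = ds), drop = FALSE]
}

#' Estimate the relative camera pose between two frames
#'
#' Detects Harris corners, matches ZNCC patch descriptors with subpixel
#' refinement, then fits a rotation-only model and an essential-matrix model
#' under RANSAC and keeps the better-supported one (rotation preferred at
#' equal support, since zero-translation pairs make the essential matrix
#' degenerate). The returned quaternion rotates frame-a coordinates into
#' frame-b coordinates and is canonicalized to w >= 0.
#'
#' @param frame_a,frame_b grayscale matrices of identical size.
#' @param K a [camera_intrinsics()] matching the frame size.
#' @param cfg a [vo_config()].
#' @param kp_a,kp_b optional precomputed Harris corners for each frame.
#' @param feat_a,feat_b optional precomputed corner/descriptor bundles from
#'   [frame_features()] (overrides `kp_a`/`kp_b`).
#' @return object of class `relative_pose`: `q`, rotation matrix `R`,
#'   `t_unit` (unit translation direction, NA under the rotation model),
#'   `model` ("rotation" or "essential"), `n_inliers`, `valid`, and the
#'   inlier matches with derotated residuals (pixels) used for the
#'   translation proxy.
#' @export
estimate_relative_pose <- function(frame_a, frame_b, K, cfg = vo_config(),
                                   kp_a = NULL, kp_b = NULL,
                                   feat_a = NULL, feat_b = NULL) {
  if (!all(dim(frame_a) == dim(frame_b)))
    stop_gz("gazevents_argument_error", "frame sizes differ")
  if (nrow(frame_a) != K$height || ncol(frame_a) != K$width)
    stop_gz("gazevents_argument_error",
            "frame size does not match the declared intrinsics")
  ds <- max(1L, as.integer(cfg$downscale))
  if (ds > 1L) {
    frame_a <- downscale_frame(frame_a, ds)
    frame_b <- downscale_frame(frame_b, ds)
    K <- camera_intrinsics(K$fx / ds, K$fy / ds, K$cx / ds, K$cy / ds,
                           ncol(frame_a), nrow(frame_a))
    # thresholds are declared in full-resolution pixels
    cfg$thresh_px <- cfg$thresh_px / ds
    cfg$max_disp <- cfg$max_disp / ds
    cfg$downscale <- 1L   # frames are already downscaled past this point
  }
  invalid <- structure(list(q = c(1, 0, 0, 0), R = diag(3),
                            t_unit = rep(NA_real_, 3), model = "none",
                            n_inliers = 0L, valid = FALSE,
                            inlier_residuals_px = numeric(0)),
                       class = "relative_pose")
  if (is.null(feat_a))
    feat_a <- frame_features(frame_a, cfg, kp = kp_a)
  if (is.null(feat_b))
    feat_b <- frame_features(frame_b, cfg, kp = kp_b)
  m <- match_keypoints(frame_a, feat_a$corners, frame_b, feat_b$corners,
                       max_disp = cfg$max_disp, min_score = cfg$min_score,
                       half = cfg$desc_half,
                       desc_a = feat_a, desc_b = feat_b)
  if (nrow(m) < cfg$min_inliers) return(invalid)
  rays_a <- pixels_to_rays(m$xa, m$ya, K)
  rays_b <- pixels_to_rays(m$xb, m$yb, K)
  px_b <- cbind(m$xb, m$yb)
  rot <- fit_rotation_ransac(rays_a, rays_b, px_b, K, cfg$thresh_px,
                             cfg$ransac_iters)
  if (is.null(rot)) return(invalid)
  n_rot <- sum(rot$inliers)
  # when the rotation-only model already explains nearly all matches, the
  # essential model cannot beat it under the preference rule - skip it
  if (n_rot >= 0.92 * nrow(m)) {
    ess <- NULL
    n_ess <- -1L
  } else {
    xa_n <- cbind((m$xa - K$cx) / K$fx, (m$ya - K$cy) / K$fy)
    xb_n <- cbind((m$xb - K$cx) / K$fx, (m$yb - K$cy) / K$fy)
    thresh_n <- cfg$thresh_px / mean(c(K$fx, K$fy))
    ess <- fit_essential_ransac(xa_n, xb_n, thresh_n, cfg$ransac_iters)
    n_ess <- if (is.null(ess)) -1L else sum(ess$inliers)
  }
  use_rotation <- n_rot >= cfg$rot_pref * n_ess
  if (use_rotation) {
    if (n_rot < cfg$min_inliers) return(invalid)
    R <- rot$R
    resid <- rotation_residuals(R, rays_a, px_b, K)[rot$inliers]
    structure(list(q = quat_from_rotmat(R), R = R,
                   t_unit = rep(NA_real_, 3), model = "rotation",
                   n_inliers = as.integer(n_rot), valid = TRUE,
                   inlier_residuals_px = resid * ds),
              class = "relative_pose")
  } else {
    if (n_ess < cfg$min_inliers) return(invalid)
    dec <- decompose_essential(ess$E, xa_n[ess$inliers, , drop = FALSE],
                               xb_n[ess$inliers, , drop = FALSE])
    if (is.null(dec)) return(invalid)
    R <- dec$R
    resid <- rotation_residuals(R, rays_a, px_b, K)[ess$inliers]
    structure(list(q = quat_from_rotmat(R), R = R,
                   t_unit = dec$t / sqrt(sum(dec$t^2)), model = "essential",
                   n_inliers = as.integer(n_ess), valid = TRUE,
                   inlier_residuals_px = resid * ds),
              class = "relative_pose")
  }
}

#' @export
print.relative_pose <- function(x, ...) {
  cat(sprintf("<relative_pose %s: angle %.3f deg, %d inliers, valid=%s>\n",
              x$model, quat_angle_deg(x$q), x$n_inliers, x$valid))
  invisible(x)
}

# Yaw (positive = camera turns right) and pitch (positive = camera turns up)
# of a relative rotation, via Z-Y-X Euler decomposition; degrees.
rot_yaw_pitch <- function(R) {
  yaw <- asin(max(-1, min(1, R[3, 1]))) * DEG
  pitch <- -atan2(R[3, 2], R[3, 3]) * DEG
  c(yaw = yaw, pitch = pitch)
}

#' Convert a relative pose into the three camera-motion features
#'
#' Head-rotation velocity is the quaternion rotation angle over `dt`;
#' head-rotation direction is `atan2(pitch, yaw)` of the Z-Y-X Euler
#' decomposition mapped to [0, 360) (0 when the rotation angle is zero);
#' body-translation velocity is the median inlier image displacement that
#' remains after removing the rotational flow, in pixels per second.
#'
#' @param pose a valid `relative_pose`.
#' @param dt time between the frames in seconds (> 0).
#' @return list with `head_rot_vel` (deg/s), `head_rot_dir` (deg),
#'   `body_trans_vel` (px/s).
#' @export
pose_to_motion_features <- function(pose, dt) {
  if (!is.numeric(dt) || length(dt) != 1 || !is.finite(dt) || dt <= 0)
    stop_gz("gazevents_argument_error", "dt must be a positive number")
  ang <- quat_angle_deg(pose$q)
  yp <- rot_yaw_pitch(pose$R)
  dir <- if (ang < 1e-9) 0 else wrap360(atan2(yp["pitch"], yp["yaw"]) * DEG)
  proxy <- if (length(pose$inlier_residuals_px) > 0)
    median(pose$inlier_residuals_px) / dt else 0
  list(head_rot_vel = ang / dt, head_rot_dir = unname(dir),
       body_trans_vel = proxy)
}

#' Camera-motion feature series for a scene video
#'
#' Runs the pairwise visual odometry over every consecutive frame pair
#' (corners are detected once per frame and reused) and converts each pose
#' to head-rotation velocity/direction and the body-translation proxy at the
#' pair midpoint time. Invalid pairs are kept as `valid = FALSE` gaps, to be
#' bridged later by interpolation. Alternatively, externally estimated poses
#' can be injected via `poses` (see [read_pose_csv()]), bypassing the
#' internal odometry.
#'
#' @param video a [scene_video()].
#' @param cfg a [vo_config()].
#' @param poses optional data.frame with columns `frame_pair_index`, `qw`,
#'   `qx`, `qy`, `qz`, `trans_proxy` (pixels per pair interval).
#' @return data.frame with `t_mid`, `head_rot_vel`, `head_rot_dir`,
#'   `body_trans_vel`, `valid`, `n_inliers`.
#' @export
compute_camera_series <- function(video, cfg = vo_config(), poses = NULL) {
  n <- video$n_frames
  if (n < 2)
    stop_gz("gazevents_argument_error", "need at least 2 frames")
  out <- data.frame(t_mid = (video$frame_times[-n] + video$frame_times[-1]) / 2,
                    head_rot_vel = NA_real_, head_rot_dir = NA_real_,
                    body_trans_vel = NA_real_, valid = FALSE,
                    n_inliers = 0L)
  dts <- diff(video$frame_times)
  if (!is.null(poses)) {
    for (r in seq_len(nrow(poses))) {
      i <- poses$frame_pair_index[r]
      q <- c(poses$qw[r], poses$qx[r], poses$qy[r], poses$qz[r])
      q <- q / sqrt(sum(q^2)); if (q[1] < 0) q <- -q
      pose <- structure(list(q = q, R = rotmat_from_quat(q),
                             t_unit = rep(NA_real_, 3), model = "injected",
                             n_inliers = NA_integer_, valid = TRUE,
                             inlier_residuals_px = poses$trans_proxy[r]),
                        class = "relative_pose")
      f <- pose_to_motion_features(pose, dts[i])
      out$head_rot_vel[i] <- f$head_rot_vel
      out$head_rot_dir[i] <- f$head_rot_dir
      out$body_trans_vel[i] <- f$body_trans_vel
      out$valid[i] <- TRUE
    }
  } else {
    prev_frame <- get_frame(video, 1)
    prev_ff <- frame_features(prev_frame, cfg)
    for (i in seq_len(n - 1)) {
      cur_frame <- get_frame(video, i + 1)
      cur_ff <- frame_features(cur_frame, cfg)
      pose <- estimate_relative_pose(prev_frame, cur_frame, video$intrinsics,
                                     cfg, feat_a = prev_ff, feat_b = cur_ff)
      if (pose$valid) {
        f <- pose_to_motion_features(pose, dts[i])
        out$head_rot_vel[i] <- f$head_rot_vel
        out$head_rot_dir[i] <- f$head_rot_dir
        out$body_trans_vel[i] <- f$body_trans_vel
        out$valid[i] <- TRUE
        out$n_inliers[i] <- pose$n_inliers
      }
      prev_frame <- cur_frame
      prev_ff <- cur_ff
    }
  }
  if (!any(out$valid))
    stop_gz("gazevents_pipeline_error",
            "no valid frame pair; check scene texture and lighting")
  n_bad <- sum(!out$valid)
  if (n_bad > 0)
    message(sprintf("camera motion: %d/%d invalid frame pair(s) bridged by interpolation",
                    n_bad, n - 1))
  out
}

#' Read externally estimated poses for injection
#'
#' CSV with header `frame_pair_index,qw,qx,qy,qz,trans_proxy`; pair index i
#' refers to frames (i, i+1), `trans_proxy` is the derotated parallax in
#' pixels over the pair interval.
#'
#' @param path CSV file path.
#' @return data.frame suitable for the `poses` argument of
#'   [compute_camera_series()].
#' @export
read_pose_csv <- function(path) {
  if (!file.exists(path))
    stop_gz("gazevents_io_error", "file not found: %s", path)
  df <- read.csv(path)
  needed <- c("frame_pair_index", "qw", "qx", "qy", "qz", "trans_proxy")
  miss <- setdiff(needed, names(df))
  if (length(miss) > 0)
    stop_gz("gazevents_format_error", "pose file missing column(s): %s",
            paste(miss, collapse = ", "))
  df
}
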