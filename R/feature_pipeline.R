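# Multirate fusion: frame-rate channels (camera motion, patch similarity)
# and pair-midpoint eye channels are brought to the gaze timestamps by
# cubic interpolation, yielding one fixed-order six-feature row per sample.

#' Interpolate one feature channel to query timestamps
#'
#' Fits a cubic spline with Forsythe-Malcolm-Moler end conditions (exact for
#' cubic polynomials; linear interpolation is used as a fallback with only
#' 2-3 knots, a constant with a single knot) through the valid knots and
#' evaluates it at `t_query`. Queries outside the knot span are clamped to
#' the boundary knot value. Invalid knots (e.g. odometry or patch gaps) are
#' excluded before fitting, which is how such gaps are bridged.
#'
#' @param t_knots knot timestamps, strictly increasing.
#' @param values channel values at the knots.
#' @param t_query timestamps to evaluate at.
#' @param valid optional logical mask of usable knots.
#' @param channel channel name used in error messages.
#' @return numeric vector of interpolated values at `t_query`.
#' @export
interpolate_channel <- function(t_knots, values, t_query, valid = NULL,
                                channel = "channel") {
  if (!is.null(valid)) {
    t_knots <- t_knots[valid]
    values <- values[valid]
  }
  ok <- is.finite(t_knots) & is.finite(values)
  t_knots <- t_knots[ok]; values <- values[ok]
  n <- length(t_knots)
  if (n < 2)
    stop_gz("gazevents_channel_error",
            "channel '%s' has fewer than 2 valid knots", channel)
  if (any(diff(t_knots) <= 0))
    stop_gz("gazevents_channel_error",
            "channel '%s': knot times not strictly increasing", channel)
  tq <- pmin(pmax(t_query, t_knots[1]), t_knots[n])
  if (n <= 3) {
    approx(t_knots, values, xout = tq, rule = 2)$y
  } else {
    splinefun(t_knots, values, method = "fmm")(tq)
  }
}

# Interpolate an angular channel (degrees): unwrap the knot angles so
# consecutive differences are < 180 deg, spline, re-wrap to [0, 360).
interpolate_angle_channel <- function(t_knots, values, t_query, valid = NULL,
                                      channel = "angle") {
  if (!is.null(valid)) {
    t_knots <- t_knots[valid]
    values <- values[valid]
  }
  wrap360(interpolate_channel(t_knots, unwrap_deg(values), t_query,
                              channel = channel))
}

#' Assemble the per-sample six-feature matrix
#'
#' Interpolates each channel from its own knots to every gaze timestamp of
#' the cleaned recording: eye channels per contiguous (un-cut) gaze segment,
#' frame-rate channels over the whole video with invalid entries excluded.
#' Circular channels (eye and head-rotation direction) are unwrapped before
#' interpolation and re-wrapped to [0, 360). Labels and cut flags carry
#' over. Rows in segments too short to carry eye kinematics (single-sample
#' segments) are dropped with a message.
#'
#' @param rec cleaned [gaze_recording()].
#' @param eye eye kinematics series from [compute_eye_series()].
#' @param cam camera-motion series from [compute_camera_series()].
#' @param patch similarity series from [compute_similarity_series()].
#' @return feature matrix data.frame with columns `t`, `eye_vel`, `eye_dir`,
#'   `head_rot_vel`, `head_rot_dir`, `body_trans_vel`, `patch_sim`, `label`,
#'   `cut_before`; attribute `recording_id`.
#' @export
assemble_feature_matrix <- function(rec, eye, cam, patch) {
  s <- rec$samples
  n <- nrow(s)
  t_gaze <- s$t
  vid_span <- range(cam$t_mid)
  if (max(t_gaze) < vid_span[1] || min(t_gaze) > vid_span[2])
    stop_gz("gazevents_sync_error",
            "video and gaze time spans do not overlap")
  seg_id <- cumsum(s$cut_before | seq_len(n) == 1)
  eye_vel <- rep(NA_real_, n)
  eye_dir <- rep(NA_real_, n)
  # eye channels: per-segment interpolation so cuts never leak across;
  # each knot belongs to the segment of the earlier sample of its pair
  knot_seg <- seg_id[findInterval(eye$t_mid, s$t)]
  for (sid in unique(seg_id)) {
    rows <- which(seg_id == sid)
    knots <- which(knot_seg == sid)
    if (length(knots) == 0) next  # single-sample segment: dropped below
    if (length(knots) == 1) {
      eye_vel[rows] <- eye$eye_vel[knots]
      eye_dir[rows] <- eye$eye_dir[knots]
    } else {
      eye_vel[rows] <- interpolate_channel(eye$t_mid[knots],
                                           eye$eye_vel[knots],
                                           t_gaze[rows], channel = "eye_vel")
      eye_dir[rows] <- interpolate_angle_channel(eye$t_mid[knots],
                                                 eye$eye_dir[knots],
                                                 t_gaze[rows],
                                                 channel = "eye_dir")
    }
  }
  head_rot_vel <- interpolate_channel(cam$t_mid, cam$head_rot_vel, t_gaze,
                                      valid = cam$valid,
                                      channel = "head_rot_vel")
  head_rot_dir <- interpolate_angle_channel(cam$t_mid, cam$head_rot_dir,
                                            t_gaze, valid = cam$valid,
                                            channel = "head_rot_dir")
  body_trans_vel <- interpolate_channel(cam$t_mid, cam$body_trans_vel,
                                        t_gaze, valid = cam$valid,
                                        channel = "body_trans_vel")
  patch_sim <- interpolate_channel(patch$t_mid, patch$score, t_gaze,
                                   valid = patch$valid, channel = "patch_sim")
  fm <- data.frame(t = t_gaze, eye_vel = eye_vel, eye_dir = eye_dir,
                   head_rot_vel = head_rot_vel, head_rot_dir = head_rot_dir,
                   body_trans_vel = body_trans_vel, patch_sim = patch_sim,
                   label = s$label, cut_before = s$cut_before)
  drop <- !is.finite(fm$eye_vel)
  if (any(drop)) {
    message(sprintf("feature matrix: dropping %d row(s) without eye kinematics",
                    sum(drop)))
    keep <- which(!drop)
    gap <- c(FALSE, diff(keep) > 1)
    fm <- fm[keep, , drop = FALSE]
    fm$cut_before <- fm$cut_before | gap
    rownames(fm) <- NULL
  }
  num <- fm[, FEATURE_ORDER]
  if (any(!is.finite(as.matrix(num))))
    stop_gz("gazevents_pipeline_error", "non-finite feature values")
  attr(fm, "recording_id") <- rec$recording_id
  fm
}

#' Run the full feature-extraction pipeline on one recording
#'
#' Convenience wrapper: eye kinematics, camera motion, patch similarity,
#' interpolation, assembly. Frames are fetched once per frame and shared by
#' the odometry and patch stages.
#'
#' @param rec cleaned [gaze_recording()].
#' @param video matching [scene_video()].
#' @param vo a [vo_config()].
#' @param patch_size gaze patch side length (default 64).
#' @param poses optional injected poses (see [compute_camera_series()]).
#' @return feature matrix data.frame (see [assemble_feature_matrix()]).
#' @export
extract_features <- function(rec, video, vo = vo_config(), patch_size = 64,
                             poses = NULL) {
  eye <- compute_eye_series(rec)
  gaze_px <- gaze_at_frame_times(rec, video$frame_times)
  n <- video$n_frames
  if (n < 2)
    stop_gz("gazevents_argument_error", "need at least 2 frames")
  dts <- diff(video$frame_times)
  t_mid <- (video$frame_times[-n] + video$frame_times[-1]) / 2
  cam <- data.frame(t_mid = t_mid, head_rot_vel = NA_real_,
                    head_rot_dir = NA_real_, body_trans_vel = NA_real_,
                    valid = FALSE, n_inliers = 0L)
  pat <- data.frame(t_mid = t_mid, score = NA_real_, valid = FALSE)
  if (!is.null(poses)) {
    cam <- compute_camera_series(video, vo, poses = poses)
    pat_series <- compute_similarity_series(video, gaze_px, size = patch_size)
    pat <- pat_series
  } else {
    prev_frame <- get_frame(video, 1)
    prev_ff <- frame_features(prev_frame, vo)
    prev_patch <- extract_patch(prev_frame, gaze_px[1, ], size = patch_size)
    for (i in seq_len(n - 1)) {
      cur_frame <- get_frame(video, i + 1)
      cur_ff <- frame_features(cur_frame, vo)
      pose <- estimate_relative_pose(prev_frame, cur_frame, video$intrinsics,
                                     vo, feat_a = prev_ff, feat_b = cur_ff)
      if (pose$valid) {
        f <- pose_to_motion_features(pose, dts[i])
        cam$head_rot_vel[i] <- f$head_rot_vel
        cam$head_rot_dir[i] <- f$head_rot_dir
        cam$body_trans_vel[i] <- f$body_trans_vel
        cam$valid[i] <- TRUE
        cam$n_inliers[i] <- pose$n_inliers
      }
      cur_patch <- extract_patch(cur_frame, gaze_px[i + 1, ], size = patch_size)
      if (prev_patch$valid && cur_patch$valid) {
        pat$score[i] <- patch_score(prev_patch, cur_patch)
        pat$valid[i] <- TRUE
      }
      prev_frame <- cur_frame
      prev_ff <- cur_ff
      prev_patch <- cur_patch
    }
    if (!any(cam$valid))
      stop_gz("gazevents_pipeline_error",
              "no valid frame pair; check scene texture and lighting")
    if (!any(pat$valid))
      stop_gz("gazevents_pipeline_error", "no valid gaze-patch pair")
  }
  assemble_feature_matrix(rec, eye, cam, pat)
}
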