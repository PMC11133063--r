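# Gaze-patch extraction and similarity scoring. A fixed-size grayscale
# window is cut around the gaze point in each frame; the similarity of the
# two patches at consecutive frames proxies "the gaze is still on the same
# object": high within a fixation or pursuit, dropping sharply when a gaze
# shift lands on different content. The default backend is zero-normalized
# cross-correlation (ZNCC, range [-1, 1]); learned backends can be plugged
# in through the same score contract.

#' Extract a gaze-centered patch from a frame
#'
#' Cuts a `size` x `size` window centered at the rounded gaze point.
#' Out-of-frame pixels are zero-filled; `frac_inside` is the fraction of the
#' patch area inside the frame and the patch is valid iff
#' `frac_inside >= valid_min`. Out-of-frame gaze never raises an error.
#'
#' @param frame grayscale matrix.
#' @param gaze_px numeric `c(x, y)` gaze point in frame pixels.
#' @param size patch side length in pixels (default 64).
#' @param valid_min validity threshold on `frac_inside` (default 0.5).
#' @return object of class `gaze_patch`: `pixels` (size x size),
#'   `center_px`, `frac_inside`, `valid`.
#' @export
extract_patch <- function(frame, gaze_px, size = 64, valid_min = 0.5) {
  h <- nrow(frame); w <- ncol(frame)
  if (length(gaze_px) != 2 || !all(is.finite(gaze_px))) {
    return(structure(list(pixels = matrix(0, size, size),
                          center_px = c(NA_real_, NA_real_),
                          frac_inside = 0, valid = FALSE),
                     class = "gaze_patch"))
  }
  cx <- round(gaze_px[1]); cy <- round(gaze_px[2])
  half <- size %/% 2
  xs <- (cx - half + 1):(cx - half + size)
  ys <- (cy - half + 1):(cy - half + size)
  px <- matrix(0, size, size)
  xin <- xs >= 1 & xs <= w
  yin <- ys >= 1 & ys <= h
  if (any(xin) && any(yin))
    px[yin, xin] <- frame[ys[yin], xs[xin], drop = FALSE]
  frac <- sum(xin) * sum(yin) / (size * size)
  structure(list(pixels = px, center_px = c(cx, cy),
                 frac_inside = frac, valid = frac >= valid_min),
            class = "gaze_patch")
}

#' Zero-normalized cross-correlation of two gaze patches
#'
#' `score = sum((p - mean_p) (q - mean_q)) / (N * sd_p * sd_q)` with the
#' population standard deviation, so `score(p, p) = 1` for any non-constant
#' patch and a contrast-inverted copy scores -1. A constant (zero-variance)
#' patch scores 0. Symmetric, and invariant to adding a constant or a
#' positive gain to either patch.
#'
#' @param p,q `gaze_patch` objects (must be valid).
#' @return similarity score in [-1, 1].
#' @export
patch_score <- function(p, q) {
  if (!p$valid || !q$valid)
    stop_gz("gazevents_argument_error", "patch_score requires valid patches")
  a <- as.vector(p$pixels); b <- as.vector(q$pixels)
  a <- a - mean(a); b <- b - mean(b)
  sa <- sqrt(mean(a^2)); sb <- sqrt(mean(b^2))
  if (sa < 1e-12 || sb < 1e-12) return(0)
  sum(a * b) / (length(a) * sa * sb)
}

#' Gaze-patch similarity series for a scene video
#'
#' Extracts the gaze patch at every frame (one gaze point per frame: the
#' gaze sample nearest in time) and scores each consecutive patch pair at
#' the pair midpoint time. Pairs involving an invalid patch are marked
#' `valid = FALSE` and bridged later by interpolation.
#'
#' @param video a [scene_video()].
#' @param gaze_at_frames n_frames x 2 matrix of per-frame gaze points (px).
#' @param size patch side length (default 64).
#' @param valid_min patch validity threshold (default 0.5).
#' @param backend score function taking two patches (default [patch_score()]).
#' @return data.frame with `t_mid`, `score`, `valid`.
#' @export
compute_similarity_series <- function(video, gaze_at_frames, size = 64,
                                      valid_min = 0.5, backend = patch_score) {
  n <- video$n_frames
  if (n < 2)
    stop_gz("gazevents_argument_error", "need at least 2 frames")
  if (nrow(gaze_at_frames) != n)
    stop_gz("gazevents_argument_error",
            "need one gaze point per frame (%d != %d)",
            nrow(gaze_at_frames), n)
  out <- data.frame(t_mid = (video$frame_times[-n] + video$frame_times[-1]) / 2,
                    score = NA_real_, valid = FALSE)
  prev <- extract_patch(get_frame(video, 1), gaze_at_frames[1, ],
                        size, valid_min)
  for (i in seq_len(n - 1)) {
    cur <- extract_patch(get_frame(video, i + 1), gaze_at_frames[i + 1, ],
                         size, valid_min)
    if (prev$valid && cur$valid) {
      out$score[i] <- backend(prev, cur)
      out$valid[i] <- TRUE
    }
    prev <- cur
  }
  if (!any(out$valid))
    stop_gz("gazevents_pipeline_error", "no valid gaze-patch pair")
  out
}

#' Nearest-in-time gaze point for each video frame
#'
#' @param rec a [gaze_recording()].
#' @param frame_times video frame timestamps (seconds).
#' @return n_frames x 2 matrix of gaze points in pixels.
#' @export
gaze_at_frame_times <- function(rec, frame_times) {
  s <- rec$samples
  idx <- vapply(frame_times, function(ft) which.min(abs(s$t - ft)), integer(1))
  cbind(s$px[idx], s$py[idx])
}
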