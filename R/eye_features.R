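#' Eye-movement velocity and direction from one sample pair
#'
#' Uses a window of two consecutive samples. Velocity is the great-circle
#' angle between the two head-centered gaze directions divided by `dt`
#' (robust `atan2(|g_i x g_j|, g_i . g_j)` form). Direction is
#' `atan2(delta elevation, delta azimuth)` in degrees mapped to [0, 360),
#' with 0 = rightward and 90 = upward; a zero-motion pair gets direction 0
#' by convention.
#'
#' @param g_i,g_j unit 3-vectors (head-centered gaze directions).
#' @param dt time between the samples in seconds (> 0).
#' @return list with `velocity` (deg/s, >= 0) and `direction` (deg, [0,360)).
#' @export
pairwise_eye_kinematics <- function(g_i, g_j, dt) {
  if (!is.numeric(dt) || length(dt) != 1 || !is.finite(dt) || dt <= 0)
    stop_gz("gazevents_argument_error", "dt must be a positive number")
  for (g in list(g_i, g_j)) {
    if (length(g) != 3 || abs(sqrt(sum(g^2)) - 1) > 1e-6)
      stop_gz("gazevents_argument_error", "gaze directions must be unit 3-vectors")
  }
  cr <- c(g_i[2] * g_j[3] - g_i[3] * g_j[2],
          g_i[3] * g_j[1] - g_i[1] * g_j[3],
          g_i[1] * g_j[2] - g_i[2] * g_j[1])
  ang <- atan2(sqrt(sum(cr^2)), sum(g_i * g_j)) * DEG
  if (ang == 0) return(list(velocity = 0, direction = 0))
  ai <- azel_from_dir(g_i); aj <- azel_from_dir(g_j)
  daz <- wrap180(aj$az - ai$az)
  del <- aj$el - ai$el
  dir <- if (daz == 0 && del == 0) 0 else wrap360(atan2(del, daz) * DEG)
  list(velocity = ang / dt, direction = dir)
}

#' Per-pair eye kinematics for a cleaned recording
#'
#' Computes velocity/direction for every consecutive sample pair within each
#' contiguous segment (segments are delimited by `cut_before` flags); pairs
#' never straddle a cut. Each pair is assigned the midpoint time
#' `(t_i + t_{i+1}) / 2`. Segments of length 1 contribute no pairs (a
#' warning is emitted).
#'
#' @param rec a cleaned [gaze_recording()].
#' @return data.frame with `t_mid`, `eye_vel` (deg/s), `eye_dir` (deg).
#' @export
compute_eye_series <- function(rec) {
  s <- rec$samples
  n <- nrow(s)
  if (n == 0) stop_gz("gazevents_data_error", "empty recording")
  seg_id <- cumsum(s$cut_before | seq_len(n) == 1)
  g <- as.matrix(s[, c("gx", "gy", "gz")])
  # vectorized pair computation, then mask pairs crossing segment boundaries
  i <- seq_len(n - 1)
  if (n < 2) {
    warning("recording has a single sample; no eye kinematics")
    return(data.frame(t_mid = numeric(0), eye_vel = numeric(0),
                      eye_dir = numeric(0)))
  }
  same_seg <- seg_id[i] == seg_id[i + 1]
  gi <- g[i, , drop = FALSE]; gj <- g[i + 1, , drop = FALSE]
  cr <- cbind(gi[, 2] * gj[, 3] - gi[, 3] * gj[, 2],
              gi[, 3] * gj[, 1] - gi[, 1] * gj[, 3],
              gi[, 1] * gj[, 2] - gi[, 2] * gj[, 1])
  ang <- atan2(sqrt(rowSums(cr^2)), rowSums(gi * gj)) * DEG
  dt <- s$t[i + 1] - s$t[i]
  ai <- azel_from_dir(gi); aj <- azel_from_dir(gj)
  daz <- wrap180(aj$az - ai$az)
  del <- aj$el - ai$el
  dir <- wrap360(atan2(del, daz) * DEG)
  dir[ang == 0] <- 0
  out <- data.frame(t_mid = (s$t[i] + s$t[i + 1]) / 2,
                    eye_vel = ang / dt, eye_dir = dir)[same_seg, , drop = FALSE]
  rownames(out) <- NULL
  n_single <- sum(tabulate(seg_id) == 1)
  if (n_single > 0)
    warning(sprintf("%d segment(s) of length 1 contribute no eye kinematics",
                    n_single))
  out
}
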