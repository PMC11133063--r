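#' Gaze recording container
#'
#' A `gaze_recording` holds time-ordered gaze samples: timestamp `t`
#' (seconds, strictly increasing), head-centered unit gaze direction
#' (`gx`, `gy`, `gz`), the gaze point in scene-image pixels (`px`, `py`),
#' an integer event label 0-5 (0 unlabeled, 1 gaze fixation, 2 gaze pursuit,
#' 3 gaze shift, 4 gaze following, 5 blink) and a `cut_before` flag marking
#' a discontinuity immediately before the sample.
#'
#' @param samples data.frame with columns t, gx, gy, gz, px, py, label and
#'   optionally cut_before.
#' @param recording_id string identifying the recording.
#' @param nominal_rate nominal sampling rate in Hz (informative only).
#' @return object of class `gaze_recording`.
#' @export
gaze_recording <- function(samples, recording_id = "rec", nominal_rate = NA_real_) {
  needed <- c("t", "gx", "gy", "gz", "px", "py", "label")
  miss <- setdiff(needed, names(samples))
  if (length(miss) > 0)
    stop_gz("gazevents_format_error", "missing column(s): %s",
            paste(miss, collapse = ", "))
  if (!"cut_before" %in% names(samples)) samples$cut_before <- FALSE
  if (nrow(samples) > 0) {
    bad <- which(diff(samples$t) <= 0)
    if (length(bad) > 0)
      stop_gz("gazevents_data_error",
              "timestamps not strictly increasing at row %d", bad[1] + 1)
    badlab <- which(!samples$label %in% 0:5)
    if (length(badlab) > 0)
      stop_gz("gazevents_data_error",
              "label outside 0-5 at row %d (value %s)", badlab[1],
              samples$label[badlab[1]])
    g <- as.matrix(samples[, c("gx", "gy", "gz")])
    nrm <- sqrt(rowSums(g^2))
    if (any(nrm < 1e-12))
      stop_gz("gazevents_data_error", "zero-length gaze direction at row %d",
              which(nrm < 1e-12)[1])
    g <- g / nrm
    samples$gx <- g[, 1]; samples$gy <- g[, 2]; samples$gz <- g[, 3]
  }
  samples$label <- as.integer(samples$label)
  samples$cut_before <- as.logical(samples$cut_before)
  rownames(samples) <- NULL
  structure(list(samples = samples, recording_id = recording_id,
                 nominal_rate = nominal_rate),
            class = "gaze_recording")
}

#' @export
print.gaze_recording <- function(x, ...) {
  cat(sprintf("<gaze_recording '%s': %d samples, %.2f-%.2f s>\n",
              x$recording_id, nrow(x$samples),
              if (nrow(x$samples)) min(x$samples$t) else NA,
              if (nrow(x$samples)) max(x$samples$t) else NA))
  invisible(x)
}

#' Read a gaze recording from CSV
#'
#' Expected header: `t,gx,gy,gz,px,py,label` (optionally `cut_before`).
#' Gaze directions are renormalized to unit length; timestamps must be
#' strictly increasing and labels in 0-5.
#'
#' @param path CSV file path.
#' @param recording_id id to attach; defaults to the file stem.
#' @param nominal_rate nominal gaze rate in Hz.
#' @return a [gaze_recording()].
#' @export
read_gaze_csv <- function(path, recording_id = NULL, nominal_rate = NA_real_) {
  if (!file.exists(path))
    stop_gz("gazevents_io_error", "file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  gaze_recording(df,
                 recording_id = recording_id %||%
                   sub("\\.[^.]*$", "", basename(path)),
                 nominal_rate = nominal_rate)
}

#' Write a gaze recording to CSV
#'
#' @param rec a [gaze_recording()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gaze_csv <- function(rec, path) {
  df <- rec$samples
  num <- c("t", "gx", "gy", "gz", "px", "py")
  for (nm in num) df[[nm]] <- sprintf("%.12g", df[[nm]])
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pinhole camera intrinsics
#'
#' @param fx,fy focal lengths in pixels (> 0).
#' @param cx,cy principal point in pixels (inside the frame).
#' @param width,height frame size in pixels.
#' @return object of class `camera_intrinsics`.
#' @export
camera_intrinsics <- function(fx, fy, cx, cy, width, height) {
  if (!is.finite(fx) || !is.finite(fy) || fx <= 0 || fy <= 0)
    stop_gz("gazevents_validation_error", "focal lengths must be positive")
  if (cx < 0 || cx >= width || cy < 0 || cy >= height)
    stop_gz("gazevents_validation_error",
            "principal point outside the frame")
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy,
                 width = as.integer(width), height = as.integer(height)),
            class = "camera_intrinsics")
}

#' Read camera intrinsics from JSON
#'
#' Expects keys fx, fy, cx, cy, width, height.
#'
#' @param path JSON file path.
#' @return a [camera_intrinsics()].
#' @export
read_intrinsics <- function(path) {
  if (!file.exists(path))
    stop_gz("gazevents_io_error", "file not found: %s", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  needed <- c("fx", "fy", "cx", "cy", "width", "height")
  miss <- setdiff(needed, names(j))
  if (length(miss) > 0)
    stop_gz("gazevents_format_error", "intrinsics missing key(s): %s",
            paste(miss, collapse = ", "))
  camera_intrinsics(j$fx, j$fy, j$cx, j$cy, j$width, j$height)
}

#' Write camera intrinsics to JSON
#'
#' @param K a [camera_intrinsics()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_intrinsics <- function(K, path) {
  jsonlite::write_json(unclass(K), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Scene-camera video
#'
#' Frames are grayscale matrices in [0, 1], height x width, either stored in
#' a list or produced on demand by a provider function `function(i)` (used by
#' the synthetic renderer and the frame-directory reader so long videos never
#' need to reside in memory).
#'
#' @param frames list of matrices, or a function(i) returning frame i.
#' @param frame_times strictly increasing timestamps (seconds).
#' @param intrinsics a [camera_intrinsics()].
#' @return object of class `scene_video`.
#' @export
scene_video <- function(frames, frame_times, intrinsics) {
  n <- length(frame_times)
  if (is.list(frames) && length(frames) != n)
    stop_gz("gazevents_format_error",
            "frame count (%d) != timestamp count (%d)", length(frames), n)
  if (n >= 2 && any(diff(frame_times) <= 0))
    stop_gz("gazevents_data_error", "frame times not strictly increasing")
  structure(list(frames = frames, frame_times = frame_times,
                 intrinsics = intrinsics, n_frames = n),
            class = "scene_video")
}

#' Fetch one frame of a scene video
#'
#' @param video a [scene_video()].
#' @param i frame index (1-based).
#' @return grayscale matrix (height x width, values in [0, 1]).
#' @export
get_frame <- function(video, i) {
  if (i < 1 || i > video$n_frames)
    stop_gz("gazevents_io_error", "frame index %d out of range", i)
  f <- if (is.function(video$frames)) video$frames(i) else video$frames[[i]]
  if (!is.matrix(f))
    stop_gz("gazevents_io_error", "frame %d unreadable", i)
  f
}

#' Read a scene video from a directory of PNG frames
#'
#' The directory must contain zero-padded numbered PNGs plus either a
#' `frame_times.csv` sidecar (single column `t`) or a constant `rate` (Hz).
#' Frames are decoded lazily and converted to grayscale.
#'
#' @param path directory of frames.
#' @param intrinsics_path path to the intrinsics JSON.
#' @param rate optional constant frame rate (Hz) if no sidecar is present.
#' @return a [scene_video()].
#' @export
read_scene_video <- function(path, intrinsics_path, rate = NULL) {
  if (!dir.exists(path))
    stop_gz("gazevents_io_error", "directory not found: %s", path)
  files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0)
    stop_gz("gazevents_io_error", "no PNG frames in %s", path)
  sidecar <- file.path(path, "frame_times.csv")
  if (file.exists(sidecar)) {
    ft <- read.csv(sidecar)$t
    if (length(ft) != length(files))
      stop_gz("gazevents_format_error",
              "%d frames but %d timestamps", length(files), length(ft))
  } else if (!is.null(rate)) {
    ft <- (seq_along(files) - 1) / rate
  } else {
    stop_gz("gazevents_format_error",
            "no frame_times.csv and no constant rate declared")
  }
  K <- read_intrinsics(intrinsics_path)
  provider <- function(i) {
    img <- png::readPNG(files[i])
    if (length(dim(img)) == 3) {
      img <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    }
    img
  }
  scene_video(provider, ft, K)
}

#' Remove calibration, blink and unlabeled sections from a recording
#'
#' Drops all samples with label 0 (unlabeled) or 5 (blink) and all samples
#' inside the supplied calibration windows, then flags the first retained
#' sample after each removed block with `cut_before = TRUE` so that
#' difference-based features and event segmentation never straddle a removed
#' block. Idempotent.
#'
#' @param rec a [gaze_recording()].
#' @param calibration_windows list of `c(t_start, t_end)` intervals (closed).
#' @return cleaned [gaze_recording()].
#' @export
clean_recording <- function(rec, calibration_windows = list()) {
  s <- rec$samples
  if (nrow(s) == 0)
    stop_gz("gazevents_data_error", "empty recording")
  drop <- s$label %in% c(0L, 5L)
  for (w in calibration_windows) {
    drop <- drop | (s$t >= w[1] & s$t <= w[2])
  }
  keep <- which(!drop)
  if (length(keep) == 0)
    stop_gz("gazevents_data_error",
            "all samples removed while cleaning '%s'", rec$recording_id)
  out <- s[keep, , drop = FALSE]
  # a retained sample directly after a removed block inherits a cut flag
  gap <- c(FALSE, diff(keep) > 1)
  out$cut_before <- out$cut_before | gap
  out$cut_before[1] <- out$cut_before[1] | (keep[1] > 1 && any(drop[seq_len(keep[1] - 1)]))
  rownames(out) <- NULL
  gaze_recording(out, recording_id = rec$recording_id,
                 nominal_rate = rec$nominal_rate)
}

FEATURE_ORDER <- c("eye_vel", "eye_dir", "head_rot_vel", "head_rot_dir",
                   "body_trans_vel", "patch_sim")
FEATURE_TABLE_COLS <- c("t", FEATURE_ORDER, "label", "cut_before")

#' Write a per-sample feature table to CSV
#'
#' Column order is fixed: `t`, the six features (eye-movement velocity and
#' direction, head-rotation velocity and direction, body-translation
#' velocity, gaze-patch similarity), `label`, `cut_before`. Values round-trip
#' through [read_feature_table()] to better than 1e-12.
#'
#' @param fm feature matrix data.frame (see [assemble_feature_matrix()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(fm, path) {
  miss <- setdiff(FEATURE_TABLE_COLS, names(fm))
  if (length(miss) > 0)
    stop_gz("gazevents_format_error", "feature table missing column(s): %s",
            paste(miss, collapse = ", "))
  df <- fm[, FEATURE_TABLE_COLS, drop = FALSE]
  for (nm in c("t", FEATURE_ORDER)) df[[nm]] <- sprintf("%.17g", df[[nm]])
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a per-sample feature table from CSV
#'
#' @param path CSV path written by [write_feature_table()].
#' @param recording_id optional id attached as an attribute.
#' @return feature matrix data.frame.
#' @export
read_feature_table <- function(path, recording_id = NULL) {
  if (!file.exists(path))
    stop_gz("gazevents_io_error", "file not found: %s", path)
  hdr <- names(read.csv(path, nrows = 1))
  if (length(hdr) == 0 || !identical(hdr, FEATURE_TABLE_COLS)) {
    # header check must also hold for empty (header-only) files
    hdr2 <- strsplit(readLines(path, n = 1), ",")[[1]]
    if (!identical(hdr2, FEATURE_TABLE_COLS))
      stop_gz("gazevents_format_error",
              "feature table column order mismatch: got [%s]",
              paste(hdr2, collapse = ","))
  }
  df <- read.csv(path, colClasses = c(rep("numeric", 7), "integer", "logical"))
  df$label <- as.integer(df$label)
  attr(df, "recording_id") <- recording_id %||%
    sub("\\.[^.]*$", "", basename(path))
  df
}
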