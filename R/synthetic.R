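# Seeded synthetic natural-viewing recordings: a scripted observer looks at
# a textured planar world (background plane at 4 m, a sparse layer of
# nearer textured squares at 2.2 m providing translation parallax, and a
# moving textured object at 2 m during pursuit), while the scene camera
# renders what the head sees and the gaze signal follows the scripted
# targets with isotropic angular jitter. Every pipeline stage can thus be
# exercised against known ground truth without any dataset download.
#
# Event kinematics follow the four natural-viewing definitions:
#   GFi (1): camera static, gaze locked on a stationary background point.
#   GP  (2): camera static, gaze tracks an object moving at 5-20 deg/s.
#   GS  (3): 30-80 ms minimum-jerk gaze jump, peak velocity 200-500 deg/s.
#   GFo (4): gaze held on a stationary world point while the head yaws at
#            10-30 deg/s or the body translates laterally at 0.6-1.0 m/s.

EVENT_LABELS <- c(GFi = 1L, GP = 2L, GS = 3L, GFo = 4L)

# world geometry (package choices, see the methods vignette)
WORLD <- list(z_bg = 4.0, z_fg = 2.2, z_obj = 2.0,
              tex_scale = 120,           # texture pixels per world meter
              bg_px = c(1680L, 1024L),   # background texture width x height
              fg_half = 0.19,            # half-size of near squares (m)
              n_fg = 16L,
              obj_half = 0.33,           # half-size of the pursuit object (m)
              yaw_max = 20, ecc_max = 22, el_max = 10, x_max = 1.2)

#' Simulation configuration
#'
#' @param duration recording length in seconds.
#' @param gaze_rate gaze sampling rate in Hz (default 120).
#' @param frame_rate scene-video frame rate in Hz (default 30).
#' @param width,height frame size in pixels (default 320 x 240).
#' @param fx,fy,cx,cy pinhole intrinsics (defaults: f = 280 px, centered
#'   principal point; about 60 deg horizontal field of view).
#' @param noise_sd gaze angular jitter SD in degrees (default 0.1).
#' @param classes event types available to the script generator.
#' @param event_script optional explicit script: list of
#'   `list(type=, duration=, ...)` entries with optional kinematic
#'   parameters `yaw_rate` (deg/s), `gfo_mode` ("yaw"/"translate"),
#'   `trans_vel` (m/s), `obj_speed` (deg/s), `peak_vel` (deg/s).
#' @param blink_rate optional rate (events/s) of injected blink (label 5)
#'   sections, default 0 (off).
#' @param seed integer seed; the complete recording is a deterministic
#'   function of the configuration.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(duration = 60, gaze_rate = 120, frame_rate = 30,
                       width = 320, height = 240,
                       fx = 280, fy = 280, cx = (width - 1) / 2,
                       cy = (height - 1) / 2, noise_sd = 0.1,
                       classes = c("GFi", "GP", "GS", "GFo"),
                       event_script = NULL, blink_rate = 0, seed = 0) {
  if (duration <= 0 || gaze_rate <= 0 || frame_rate <= 0)
    stop_gz("gazevents_validation_error", "rates and duration must be positive")
  if (!all(classes %in% names(EVENT_LABELS)))
    stop_gz("gazevents_validation_error", "unknown event class")
  structure(list(duration = duration, gaze_rate = gaze_rate,
                 frame_rate = frame_rate, width = width, height = height,
                 intrinsics = camera_intrinsics(fx, fy, cx, cy, width, height),
                 noise_sd = noise_sd, classes = classes,
                 event_script = event_script, blink_rate = blink_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Build a seeded multi-region scene texture
#'
#' Multi-scale smoothed noise with block-wise distinct mean and contrast,
#' so that gaze patches from different regions decorrelate while corner
#' detection finds structure everywhere. Deterministic per seed.
#'
#' @param seed integer seed.
#' @param extent `c(width, height)` of the texture in pixels.
#' @param frame_size frame size the texture must comfortably contain
#'   under camera rotation (extent must be at least 4x in width).
#' @param block block side length in pixels for the region structure.
#' @return matrix (height x width) with values in [0.02, 0.98].
#' @export
build_scene_texture <- function(seed, extent, frame_size = c(64, 48),
                                block = 160) {
  if (extent[1] < 4 * frame_size[1] || extent[2] < 4 * frame_size[2])
    stop_gz("gazevents_argument_error",
            "texture extent must be at least 4x the frame size")
  set.seed(as.integer(seed) %% .Machine$integer.max)
  w <- extent[1]; h <- extent[2]
  noise <- function() matrix(rnorm(h * w), h, w)
  smooth_n <- function(m, sigma) {
    s <- conv_sep(m, gaussian_kernel(sigma))
    s / sd(s)
  }
  fine <- smooth_n(noise(), 0.8)
  mid <- smooth_n(noise(), 3)
  coarse <- smooth_n(noise(), 8)
  tex <- 0.45 * fine + 0.35 * mid + 0.2 * coarse
  # block-wise mean / contrast modulation
  nbx <- ceiling(w / block); nby <- ceiling(h / block)
  bmean <- matrix(runif(nbx * nby, -0.8, 0.8), nby, nbx)
  bcontr <- matrix(runif(nbx * nby, 0.6, 1.4), nby, nbx)
  bx <- pmin((col(tex) - 1) %/% block + 1, nbx)
  by <- pmin((row(tex) - 1) %/% block + 1, nby)
  idx <- cbind(as.vector(by), as.vector(bx))
  tex <- tex * bcontr[idx] + bmean[idx]
  lo <- quantile(tex, 0.001); hi <- quantile(tex, 0.999)
  tex <- (tex - lo) / (hi - lo)
  pmin(pmax(tex * 0.96 + 0.02, 0.02), 0.98)
}

# Generate a random event script: main events cycle through the available
# non-shift classes in shuffled order; gaze shifts are rapid 30-80 ms
# bridges inserted at each transition (never standalone multi-second
# events, which would violate their kinematic definition). Assumes the RNG
# is already seeded.
generate_event_script <- function(duration, classes) {
  mains <- setdiff(classes, "GS")
  if (length(mains) == 0)
    stop_gz("gazevents_validation_error",
            "event classes must include at least one non-GS type")
  include_gs <- "GS" %in% classes
  evs <- list(); t <- 0; pool <- character(0); first <- TRUE
  while (t < duration) {
    if (length(pool) == 0) pool <- sample(mains)
    ty <- pool[1]; pool <- pool[-1]
    if (!first && include_gs) {
      evs[[length(evs) + 1]] <- list(type = "GS",
                                     duration = runif(1, 0.03, 0.08),
                                     peak_vel = runif(1, 250, 450))
      t <- t + evs[[length(evs)]]$duration
    }
    # gaze following kept shorter so 10-30 deg/s head turns stay within a
    # plausible eye-in-head eccentricity budget
    ev <- if (ty == "GFo") list(type = ty, duration = runif(1, 0.8, 1.6))
          else list(type = ty, duration = runif(1, 1.5, 3))
    if (ty == "GFo") {
      ev$gfo_mode <- sample(c("yaw", "translate"), 1)
      ev$yaw_rate <- runif(1, 10, 30)
      ev$trans_vel <- runif(1, 0.6, 1.0)
    } else if (ty == "GP") {
      ev$obj_speed <- runif(1, 5, 20)
    } else if (ty == "GS") {
      ev$peak_vel <- runif(1, 250, 450)
    }
    evs[[length(evs) + 1]] <- ev
    t <- t + ev$duration
    first <- FALSE
  }
  # trim events off the tail so durations sum exactly to the requested length
  total <- sum(vapply(evs, `[[`, numeric(1), "duration"))
  while (total - duration > 1e-9) {
    excess <- total - duration
    last <- evs[[length(evs)]]
    if (last$duration > excess + 1e-9) {
      evs[[length(evs)]]$duration <- last$duration - excess
      total <- duration
    } else {
      evs[[length(evs)]] <- NULL
      total <- total - last$duration
    }
  }
  evs
}

validate_script <- function(evs, duration) {
  for (ev in evs) {
    if (!ev$type %in% names(EVENT_LABELS))
      stop_gz("gazevents_validation_error", "unknown event type %s", ev$type)
    if (ev$type == "GFo" && !is.null(ev$yaw_rate) &&
        (ev$yaw_rate < 5 || ev$yaw_rate > 40))
      stop_gz("gazevents_validation_error", "GFo yaw rate out of range")
    if (ev$type == "GP" && !is.null(ev$obj_speed) &&
        (ev$obj_speed < 2 || ev$obj_speed > 30))
      stop_gz("gazevents_validation_error", "GP object speed out of range")
    if (ev$type == "GS" && !is.null(ev$peak_vel) &&
        (ev$peak_vel < 100 || ev$peak_vel > 700))
      stop_gz("gazevents_validation_error", "GS peak velocity out of range")
    if (ev$type == "GS" && ev$duration > 0.2)
      stop_gz("gazevents_validation_error",
              "GS duration %.3f s exceeds the rapid-shift range", ev$duration)
  }
  total <- sum(vapply(evs, `[[`, numeric(1), "duration"))
  if (abs(total - duration) > 1e-6)
    stop_gz("gazevents_validation_error",
            "event durations sum to %.3f, expected %.3f", total, duration)
  evs
}

min_jerk <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5

# World->camera transform for a camera yawed by `yaw` degrees at lateral
# position x (height and depth fixed at 0).
cam_world_to_cam <- function(yaw) t(rot_y(yaw))

dir_to_point <- function(yaw, px, W) {
  v <- cam_world_to_cam(yaw) %*% (W - c(px, 0, 0))
  as.vector(v) / sqrt(sum(v^2))
}

# Intersect the gaze ray (head-frame az/el) with the world plane z = Z.
gaze_ray_hit <- function(yaw, px, az, el, Z) {
  d_head <- as.vector(dir_from_azel(az, el))
  d_world <- rot_y(yaw) %*% d_head
  s <- Z / d_world[3]
  c(px + s * d_world[1], s * d_world[2], Z)
}

#' Script the full event timeline of a synthetic recording
#'
#' Expands the (possibly auto-generated) event script into per-gaze-sample
#' ground truth (label and noise-free head-frame gaze angles), per-event
#' camera-pose parameters and the pursuit-object track, enforcing the
#' event kinematics and keeping gaze transitions continuous. Deterministic
#' per config seed.
#'
#' @param config a [sim_config()].
#' @return list with `gaze` (t, label, az, el), `events` (one row per
#'   scripted event with pose/object parameters), and `script` (the event
#'   list actually used).
#' @export
script_event_timeline <- function(config) {
  set.seed(config$seed)
  evs <- config$event_script %||%
    generate_event_script(config$duration, config$classes)
  evs <- validate_script(evs, config$duration)
  ne <- length(evs)
  w <- WORLD
  events <- data.frame(
    type = vapply(evs, `[[`, character(1), "type"),
    label = EVENT_LABELS[vapply(evs, `[[`, character(1), "type")],
    t0 = NA_real_, t1 = NA_real_,
    yaw0 = NA_real_, yaw_rate = 0, x0 = NA_real_, vx = 0,
    obj = FALSE, obj_x0 = NA_real_, obj_y = NA_real_, obj_vx = 0,
    az0 = NA_real_, el0 = NA_real_, az1 = NA_real_, el1 = NA_real_,
    wx = NA_real_, wy = NA_real_)
  t <- 0; yaw <- 0; px <- 0; g_az <- 0; g_el <- 0
  for (k in seq_len(ne)) {
    ev <- evs[[k]]
    dur <- ev$duration
    events$t0[k] <- t; events$t1[k] <- t + dur
    events$yaw0[k] <- yaw; events$x0[k] <- px
    ty <- ev$type
    if (ty == "GFi") {
      W <- gaze_ray_hit(yaw, px, g_az, g_el, w$z_bg)
      events$wx[k] <- W[1]; events$wy[k] <- W[2]
    } else if (ty == "GFo") {
      W <- gaze_ray_hit(yaw, px, g_az, g_el, w$z_bg)
      events$wx[k] <- W[1]; events$wy[k] <- W[2]
      mode <- ev$gfo_mode %||% sample(c("yaw", "translate"), 1)
      if (mode == "yaw") {
        rate <- ev$yaw_rate %||% runif(1, 10, 30)
        rate <- min(rate, (28 - abs(g_az)) / dur)
        rate <- max(rate, 5)
        sgn <- if (yaw + rate * dur > w$yaw_max) -1
               else if (yaw - rate * dur < -w$yaw_max) 1
               else sample(c(-1, 1), 1)
        events$yaw_rate[k] <- sgn * rate
        yaw <- yaw + sgn * rate * dur
      } else {
        v <- ev$trans_vel %||% runif(1, 0.6, 1.0)
        room_pos <- w$x_max - px; room_neg <- w$x_max + px
        sgn <- if (room_pos >= room_neg) 1 else -1
        room <- if (sgn > 0) room_pos else room_neg
        # keep the held target within +-28 deg of the optical axis
        ecc_room <- if (sgn > 0) W[1] + tan(28 / DEG) * w$z_bg - px
                    else px - (W[1] - tan(28 / DEG) * w$z_bg)
        v <- max(0.2, min(v, room / dur, ecc_room / dur))
        events$vx[k] <- sgn * v
        px <- px + sgn * v * dur
      }
    } else if (ty == "GP") {
      W0 <- gaze_ray_hit(yaw, px, g_az, g_el, w$z_obj)
      speed <- ev$obj_speed %||% runif(1, 5, 20)
      sgn <- if (W0[1] - px > 0) -1 else 1
      # keep the object within the eccentricity budget for the whole event
      avail <- w$z_obj * tan((w$ecc_max - 2) / DEG) - sgn * (W0[1] - px)
      v <- sgn * min(speed / DEG * w$z_obj, avail / dur)
      events$obj[k] <- TRUE
      events$obj_x0[k] <- W0[1]; events$obj_y[k] <- W0[2]
      events$obj_vx[k] <- v
    } else { # GS
      peak <- ev$peak_vel %||% runif(1, 250, 450)
      amp <- peak * dur / 1.875
      ok <- FALSE
      for (try in 1:60) {
        th <- runif(1, 0, 2 * pi)
        az2 <- g_az + amp * cos(th); el2 <- g_el + amp * sin(th)
        if (abs(az2) <= w$ecc_max - 2 && abs(el2) <= w$el_max) { ok <- TRUE; break }
      }
      if (!ok) { # aim at straight ahead
        th <- atan2(-g_el, -g_az)
        az2 <- g_az + amp * cos(th); el2 <- g_el + amp * sin(th)
      }
      events$az0[k] <- g_az; events$el0[k] <- g_el
      events$az1[k] <- az2; events$el1[k] <- el2
    }
    # advance the gaze state to the event end
    t1 <- t + dur
    if (ty %in% c("GFi", "GFo")) {
      W <- c(events$wx[k], events$wy[k], w$z_bg)
      g <- azel_from_dir(dir_to_point(yaw, px, W))
      g_az <- g$az; g_el <- g$el
    } else if (ty == "GP") {
      Wend <- c(events$obj_x0[k] + events$obj_vx[k] * dur, events$obj_y[k],
                w$z_obj)
      g <- azel_from_dir(dir_to_point(yaw, px, Wend))
      g_az <- g$az; g_el <- g$el
    } else {
      g_az <- events$az1[k]; g_el <- events$el1[k]
    }
    t <- t1
  }
  # per-gaze-sample ground truth
  n <- round(config$duration * config$gaze_rate)
  tg <- (seq_len(n) - 1) / config$gaze_rate
  edges <- c(events$t0, config$duration)
  ev_of <- pmin(findInterval(tg, edges, rightmost.closed = FALSE), ne)
  az <- numeric(n); el <- numeric(n)
  for (k in seq_len(ne)) {
    idx <- which(ev_of == k)
    if (length(idx) == 0) next
    ts <- tg[idx]
    ty <- events$type[k]
    yawt <- events$yaw0[k] + events$yaw_rate[k] * (ts - events$t0[k])
    pxt <- events$x0[k] + events$vx[k] * (ts - events$t0[k])
    if (ty != "GS") {
      if (ty == "GP") {
        dx <- events$obj_x0[k] + events$obj_vx[k] * (ts - events$t0[k]) - pxt
        dy <- rep(events$obj_y[k], length(idx))
        dz <- rep(w$z_obj, length(idx))
      } else {
        dx <- events$wx[k] - pxt
        dy <- rep(events$wy[k], length(idx))
        dz <- rep(w$z_bg, length(idx))
      }
      # world -> camera for a yaw-only pose, vectorized over samples
      cth <- cos(yawt / DEG); sth <- sin(yawt / DEG)
      v1 <- cth * dx - sth * dz
      v3 <- sth * dx + cth * dz
      az[idx] <- atan2(v1, v3) * DEG
      el[idx] <- atan2(-dy, sqrt(v1^2 + v3^2)) * DEG
    } else {
      tau <- (ts - events$t0[k]) / (events$t1[k] - events$t0[k])
      s <- min_jerk(tau)
      az[idx] <- events$az0[k] + (events$az1[k] - events$az0[k]) * s
      el[idx] <- events$el0[k] + (events$el1[k] - events$el0[k]) * s
    }
  }
  gaze <- data.frame(t = tg, label = events$label[ev_of], az = az, el = el)
  list(gaze = gaze, events = events, script = evs)
}

# Camera pose (yaw deg, lateral position m) at arbitrary times.
pose_at_times <- function(events, ts) {
  edges <- c(events$t0, events$t1[nrow(events)])
  k <- pmin(findInterval(ts, edges, rightmost.closed = FALSE), nrow(events))
  data.frame(t = ts,
             yaw = events$yaw0[k] + events$yaw_rate[k] * (ts - events$t0[k]),
             x = events$x0[k] + events$vx[k] * (ts - events$t0[k]))
}

# Pursuit-object state at arbitrary times (NA when absent).
object_at_times <- function(events, ts) {
  edges <- c(events$t0, events$t1[nrow(events)])
  k <- pmin(findInterval(ts, edges, rightmost.closed = FALSE), nrow(events))
  act <- events$obj[k]
  data.frame(t = ts, active = act,
             x = ifelse(act, events$obj_x0[k] +
                          events$obj_vx[k] * (ts - events$t0[k]), NA_real_),
             y = ifelse(act, events$obj_y[k], NA_real_))
}

# Textures of the layered world: background plane, high-contrast texture
# shared by the near squares (each with its own texture window), pursuit
# object texture, and the seeded square placements.
make_world_textures <- function(texseed) {
  bg <- build_scene_texture(texseed, WORLD$bg_px)
  set.seed((texseed + 1) %% .Machine$integer.max)
  sharpen <- function(m, sigma) {
    m <- conv_sep(m, gaussian_kernel(sigma))
    m <- (m - min(m)) / (max(m) - min(m))
    m * 0.9 + 0.05
  }
  fg_tex <- sharpen(matrix(rnorm(256 * 256), 256, 256), 0.7)
  obj_sz <- ceiling(2 * WORLD$obj_half * WORLD$tex_scale) + 2
  obj_tex <- sharpen(matrix(rnorm(obj_sz * obj_sz), obj_sz, obj_sz), 1.0)
  fg_half_px <- WORLD$fg_half * WORLD$tex_scale
  # stratified lateral placement (jittered grid) so that every camera view
  # contains several near squares, at varied depths for solid parallax
  n_fg <- WORLD$n_fg
  fg_squares <- data.frame(
    x = -3.3 + (seq_len(n_fg) - 0.5) * 6.6 / n_fg + runif(n_fg, -0.12, 0.12),
    y = runif(n_fg, -1.0, 1.0),
    z = runif(n_fg, 1.8, 2.6),
    offx = runif(n_fg, 1, 256 - 2 * fg_half_px - 1),
    offy = runif(n_fg, 1, 256 - 2 * fg_half_px - 1))
  fg_squares <- fg_squares[order(-fg_squares$z), ]  # painter's order
  rownames(fg_squares) <- NULL
  list(bg = bg, fg = fg_tex, obj = obj_tex, fg_squares = fg_squares)
}

#' Render a synthetic camera-motion clip with directly scripted pose
#'
#' A textured-plane clip (background plane plus the near parallax layer)
#' whose camera yaws and/or translates at constant rates - the ground-truth
#' fixture for validating the visual odometry in isolation.
#'
#' @param seed texture seed.
#' @param n_frames number of frames.
#' @param frame_rate frames per second.
#' @param yaw_rate camera yaw rate in deg/s (positive = rightward).
#' @param trans_vel lateral camera velocity in m/s.
#' @param width,height,fx,fy frame geometry.
#' @return a [scene_video()] with lazily rendered frames.
#' @export
simulate_camera_clip <- function(seed, n_frames = 30, frame_rate = 30,
                                 yaw_rate = 0, trans_vel = 0,
                                 width = 320, height = 240,
                                 fx = 280, fy = 280) {
  dur <- n_frames / frame_rate
  config <- sim_config(duration = dur, frame_rate = frame_rate,
                       width = width, height = height, fx = fx, fy = fy,
                       seed = seed)
  # center the sweep so the pose stays within the rendered world
  events <- data.frame(type = "GFo", label = 4L,
                       t0 = 0, t1 = dur,
                       yaw0 = -yaw_rate * dur / 2, yaw_rate = yaw_rate,
                       x0 = -trans_vel * dur / 2, vx = trans_vel,
                       obj = FALSE, obj_x0 = NA_real_, obj_y = NA_real_,
                       obj_vx = 0, az0 = NA_real_, el0 = NA_real_,
                       az1 = NA_real_, el1 = NA_real_,
                       wx = NA_real_, wy = NA_real_)
  textures <- make_world_textures((seed * 7919 + 13) %% .Machine$integer.max)
  renderer <- make_renderer(config, events, textures)
  tf <- (seq_len(n_frames) - 1) / frame_rate
  scene_video(renderer, tf, config$intrinsics)
}

# Deterministic frame renderer over the layered planar world. The camera
# pose is yaw-about-vertical plus lateral translation, so the ray geometry
# is separable: world-direction x/z components depend only on the pixel
# column and the y component only on the row. Near-layer squares project to
# axis-aligned image rectangles, evaluated on subgrids only.
make_renderer <- function(config, events, textures) {
  K <- config$intrinsics
  w <- WORLD
  nf <- round(config$duration * config$frame_rate)
  tf <- (seq_len(nf) - 1) / config$frame_rate
  poses <- pose_at_times(events, tf)
  objs <- object_at_times(events, tf)
  gxc <- (seq_len(K$width) - 1 - K$cx) / K$fx    # per-column ray x
  gyr <- (seq_len(K$height) - 1 - K$cy) / K$fy   # per-row ray y
  hw_bg <- ncol(textures$bg) / w$tex_scale / 2
  hh_bg <- nrow(textures$bg) / w$tex_scale / 2
  fgs <- textures$fg_squares
  H <- K$height; W_ <- K$width

  # paint one planar square (world center sx, sy at depth z) into img
  paint_square <- function(img, tex, yaw_c, yaw_s, px, sx, sy, z, half,
                           offx, offy) {
    # world -> camera of the square corners (x varies, y vertical)
    ccx <- c(sx - half, sx + half) - px
    v1 <- yaw_c * ccx - yaw_s * z
    v3 <- yaw_s * ccx + yaw_c * z
    if (any(v3 <= 0)) return(img)
    uc <- sort(K$fx * v1 / v3 + K$cx) + 1        # column range
    vc <- sort(K$fy * c(sy - half, sy + half) / v3 + K$cy) + 1
    vc2 <- sort(K$fy * c(sy - half, sy + half) / rev(v3) + K$cy) + 1
    c_lo <- max(1, floor(min(uc)) - 1); c_hi <- min(W_, ceiling(max(uc)) + 1)
    r_lo <- max(1, floor(min(vc, vc2)) - 1)
    r_hi <- min(H, ceiling(max(vc, vc2)) + 1)
    if (c_hi < c_lo || r_hi < r_lo) return(img)
    cols <- c_lo:c_hi
    rows <- r_lo:r_hi
    # exact world hit coordinates on the subgrid
    d1 <- yaw_c * gxc[cols] + yaw_s
    d3 <- -yaw_s * gxc[cols] + yaw_c
    s_col <- z / d3
    hx_col <- px + s_col * d1
    okc <- abs(hx_col - sx) < half & s_col > 0
    if (!any(okc)) return(img)
    cols <- cols[okc]; s_col <- s_col[okc]; hx_col <- hx_col[okc]
    hy <- outer(gyr[rows], s_col)                # rows x cols
    ins <- abs(hy - sy) < half
    if (!any(ins)) return(img)
    tu <- matrix((hx_col - sx + half) * w$tex_scale + offx,
                 length(rows), length(cols), byrow = TRUE)
    tv <- (hy - sy + half) * w$tex_scale + offy
    vals <- bilinear_sample(tex, tu[ins], tv[ins], fill = 0.5)
    sub <- img[rows, cols, drop = FALSE]
    sub[ins] <- vals
    img[rows, cols] <- sub
    img
  }

  function(i) {
    yaw <- poses$yaw[i] / DEG
    yc <- cos(yaw); ys <- sin(yaw)
    px <- poses$x[i]
    # background plane, separable ray geometry
    d1 <- yc * gxc + ys
    d3 <- -ys * gxc + yc
    s_col <- w$z_bg / d3
    tu_col <- (px + s_col * d1 + hw_bg) * w$tex_scale + 1
    tv <- (outer(gyr, s_col) + hh_bg) * w$tex_scale + 1
    tu <- matrix(tu_col, H, W_, byrow = TRUE)
    img <- matrix(bilinear_sample(textures$bg, tu, tv, fill = 0.5), H, W_)
    # near static squares (parallax layer), painted far to near
    for (j in seq_len(nrow(fgs))) {
      img <- paint_square(img, textures$fg, yc, ys, px, fgs$x[j], fgs$y[j],
                          fgs$z[j], w$fg_half, fgs$offx[j], fgs$offy[j])
    }
    # pursuit object (nearest layer)
    if (objs$active[i]) {
      img <- paint_square(img, textures$obj, yc, ys, px, objs$x[i],
                          objs$y[i], w$z_obj, w$obj_half, 1, 1)
    }
    img
  }
}

#' Simulate a complete synthetic natural-viewing recording
#'
#' Scripts the timeline, renders the scene video (lazily, frame by frame)
#' and produces the gaze recording with ground-truth labels and isotropic
#' angular jitter. Optionally writes the dataset to disk in the package's
#' interchange formats (gaze CSV, PNG frames + frame_times.csv, intrinsics
#' JSON, ground_truth.json). Fully reproducible per seed.
#'
#' @param config a [sim_config()].
#' @param dir optional output directory.
#' @return list of class `ground_truth_recording`: `gaze`
#'   ([gaze_recording()]), `video` ([scene_video()]), `timeline` (scripted
#'   events and noise-free gaze), `poses` and `object` per frame, `config`.
#' @export
simulate_recording <- function(config, dir = NULL) {
  tl <- script_event_timeline(config)
  # jitter and derived signals continue the seeded RNG stream
  n <- nrow(tl$gaze)
  az <- tl$gaze$az + rnorm(n, 0, config$noise_sd)
  el <- tl$gaze$el + rnorm(n, 0, config$noise_sd)
  labels <- tl$gaze$label
  if (config$blink_rate > 0) {
    nb <- max(0L, round(config$blink_rate * config$duration))
    for (b in seq_len(nb)) {
      bt <- runif(1, 0, config$duration - 0.2)
      bd <- runif(1, 0.08, 0.2)
      labels[tl$gaze$t >= bt & tl$gaze$t < bt + bd] <- 5L
    }
  }
  dirs <- dir_from_azel(az, el)
  K <- config$intrinsics
  px <- K$fx * dirs[, 1] / dirs[, 3] + K$cx
  py <- K$fy * dirs[, 2] / dirs[, 3] + K$cy
  rec <- gaze_recording(data.frame(t = tl$gaze$t, gx = dirs[, 1],
                                   gy = dirs[, 2], gz = dirs[, 3],
                                   px = px, py = py, label = labels),
                        recording_id = sprintf("sim_seed%d", config$seed),
                        nominal_rate = config$gaze_rate)
  # textures drawn from a dedicated seed offset so the texture of a scene
  # does not depend on script length
  texseed <- (config$seed * 7919 + 13) %% .Machine$integer.max
  textures <- make_world_textures(texseed)
  renderer <- make_renderer(config, tl$events, textures)
  nf <- round(config$duration * config$frame_rate)
  tf <- (seq_len(nf) - 1) / config$frame_rate
  video <- scene_video(renderer, tf, K)
  poses <- pose_at_times(tl$events, tf)
  objs <- object_at_times(tl$events, tf)
  out <- structure(list(gaze = rec, video = video, timeline = tl,
                        poses = poses, object = objs, config = config),
                   class = "ground_truth_recording")
  if (!is.null(dir)) write_ground_truth(out, dir)
  out
}

#' Write a simulated recording to disk
#'
#' @param gt a `ground_truth_recording` from [simulate_recording()].
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_ground_truth <- function(gt, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  frames_dir <- file.path(dir, "frames")
  dir.create(frames_dir, showWarnings = FALSE)
  write_gaze_csv(gt$gaze, file.path(dir, "gaze.csv"))
  write_intrinsics(gt$video$intrinsics, file.path(dir, "intrinsics.json"))
  nf <- gt$video$n_frames
  write.csv(data.frame(t = sprintf("%.9f", gt$video$frame_times)),
            file.path(frames_dir, "frame_times.csv"),
            row.names = FALSE, quote = FALSE)
  for (i in seq_len(nf)) {
    png::writePNG(get_frame(gt$video, i),
                  file.path(frames_dir, sprintf("frame_%05d.png", i)))
  }
  jsonlite::write_json(list(
    seed = gt$config$seed,
    script = gt$timeline$script,
    events = gt$timeline$events,
    poses = gt$poses,
    object = gt$object),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "columns")
  invisible(dir)
}

#' Simulate a multi-recording synthetic dataset
#'
#' @param n_recordings number of recordings.
#' @param seed base seed; recording i uses `seed + i - 1`.
#' @param ... passed to [sim_config()].
#' @return named list of `ground_truth_recording`s.
#' @export
simulate_dataset <- function(n_recordings = 6, seed = 0, ...) {
  out <- lapply(seq_len(n_recordings), function(i)
    simulate_recording(sim_config(seed = seed + i - 1, ...)))
  names(out) <- vapply(out, function(g) g$gaze$recording_id, character(1))
  out
}
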