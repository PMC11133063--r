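# Shared fixture builders. Everything is generated in code at test time.

# A gaze recording with the given labels, unit-z gaze directions and
# uniform 120 Hz timestamps.
make_label_recording <- function(labels, cuts = NULL, id = "fix") {
  n <- length(labels)
  df <- data.frame(t = (seq_len(n) - 1) / 120, gx = 0, gy = 0, gz = 1,
                   px = 160, py = 120, label = labels)
  if (!is.null(cuts)) df$cut_before <- cuts
  gaze_recording(df, recording_id = id, nominal_rate = 120)
}

# A minimal feature-matrix data.frame carrying only labels/cuts (for the
# sampling and evaluation modules, which ignore the feature values).
make_label_fm <- function(labels, cuts = rep(FALSE, length(labels)),
                          id = "fix") {
  n <- length(labels)
  fm <- data.frame(t = (seq_len(n) - 1) / 120,
                   eye_vel = 0, eye_dir = 0, head_rot_vel = 0,
                   head_rot_dir = 0, body_trans_vel = 0, patch_sim = 0,
                   label = as.integer(labels), cut_before = cuts)
  attr(fm, "recording_id") <- id
  fm
}

# Random label sequences with realistic run lengths, plus random cut flags.
random_label_recording <- function(n, classes = 1:4, mean_run = 6,
                                   cut_prob = 0.02) {
  labels <- integer(0)
  while (length(labels) < n) {
    labels <- c(labels, rep(sample(classes, 1), 1 + rpois(1, mean_run)))
  }
  labels <- labels[seq_len(n)]
  cuts <- runif(n) < cut_prob
  cuts[1] <- FALSE
  list(labels = labels, cuts = cuts)
}

# Well-separated synthetic feature clusters, one cluster per class.
make_cluster_fm <- function(n_per_class, classes = 1:4, sd = 0.05,
                            id = "clusters") {
  centers <- list(`1` = c(0, 0, 0, 0, 0, 1),
                  `2` = c(1, 0, 0, 0, 0, 1),
                  `3` = c(5, 0, 0, 0, 0, -1),
                  `4` = c(1, 0, 5, 0, 2, 1))
  rows <- do.call(rbind, lapply(classes, function(cl) {
    m <- matrix(rnorm(n_per_class * 6, sd = sd), n_per_class, 6)
    m <- sweep(m, 2, centers[[as.character(cl)]], `+`)
    cbind(m, cl)
  }))
  fm <- as.data.frame(rows)
  names(fm) <- c(gazevents:::FEATURE_ORDER, "label")
  fm$t <- (seq_len(nrow(fm)) - 1) / 120
  fm$cut_before <- FALSE
  fm$label <- as.integer(fm$label)
  attr(fm, "recording_id") <- id
  fm
}

# A small textured image for patch/vision tests.
make_textured_image <- function(seed, h = 240, w = 320) {
  set.seed(seed)
  m <- matrix(rnorm(h * w), h, w)
  m <- gazevents:::conv_sep(m, gazevents:::gaussian_kernel(1))
  (m - min(m)) / (max(m) - min(m))
}
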