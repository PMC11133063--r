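# Independent brute-force oracles, deliberately written with different
# primitives than the package implementation.

# Sample-level one-vs-all counts by explicit enumeration.
oracle_sample_scores <- function(gt, pred, classes) {
  out <- list()
  for (c_ in classes) {
    tp <- 0L; fp <- 0L; fn <- 0L
    for (i in seq_along(gt)) {
      if (gt[i] == c_ && pred[i] == c_) tp <- tp + 1L
      if (gt[i] != c_ && pred[i] == c_) fp <- fp + 1L
      if (gt[i] == c_ && pred[i] != c_) fn <- fn + 1L
    }
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
    out[[as.character(c_)]] <- c(TP = tp, FP = fp, FN = fn,
                                 precision = p, recall = r, f1 = f1)
  }
  out
}

# Naive event segmentation by a scan loop.
oracle_segments <- function(labels, cuts) {
  segs <- list()
  start <- 1L
  for (i in seq_along(labels)[-1]) {
    if (labels[i] != labels[i - 1] || isTRUE(cuts[i])) {
      segs[[length(segs) + 1]] <- c(labels[start], start, i - 1L)
      start <- i
    }
  }
  segs[[length(segs) + 1]] <- c(labels[start], start, length(labels))
  segs
}

# Event-level counts: per segment, the most frequent predicted class with
# earliest-first-occurrence tie break, counted one-vs-all.
oracle_event_scores <- function(labels, cuts, pred, classes) {
  segs <- oracle_segments(labels, cuts)
  gt_ev <- integer(0); pr_ev <- integer(0)
  for (sg in segs) {
    span <- pred[sg[2]:sg[3]]
    cnt <- sapply(unique(span), function(u) sum(span == u))
    mx <- unique(span)[cnt == max(cnt)]
    if (length(mx) > 1) {
      pos <- sapply(mx, function(u) which(span == u)[1])
      mx <- mx[order(pos)][1]
    }
    gt_ev <- c(gt_ev, sg[1]); pr_ev <- c(pr_ev, mx)
  }
  list(scores = oracle_sample_scores(gt_ev, pr_ev, classes),
       gt_ev = gt_ev, pr_ev = pr_ev)
}

# Pairwise eye kinematics by explicit rotation-matrix composition: rotate
# straight-ahead gaze by the azimuth/elevation increments and measure the
# angle between the composed directions.
oracle_pair_kinematics <- function(az1, el1, az2, el2, dt) {
  mkdir <- function(az, el) {
    R <- gazevents:::rot_y(az) %*% gazevents:::rot_x(el)
    as.vector(R %*% c(0, 0, 1))
  }
  g1 <- mkdir(az1, el1); g2 <- mkdir(az2, el2)
  ang <- acos(min(1, max(-1, sum(g1 * g2)))) * 180 / pi
  list(velocity = ang / dt, g1 = g1, g2 = g2)
}
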