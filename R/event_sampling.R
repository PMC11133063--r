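# Event-preserving sample extraction: the engine behind both balancing
# regimes. Samples are removed (or subset out) from the interiors of events
# so that event boundaries - and therefore event counts and event-level
# scores - are preserved, at a single per-class extraction ratio applied
# across all recordings.

#' Segment a label sequence into events
#'
#' An event is a maximal run of identical labels, additionally split at
#' every `cut_before` flag. The returned segments exactly tile the sequence.
#'
#' @param labels integer per-sample class labels.
#' @param cuts logical per-sample cut flags (discontinuity before sample).
#' @param recording_id id attached to each segment.
#' @return data.frame with `label`, `start_idx`, `end_idx` (inclusive,
#'   1-based), `recording_id`.
#' @export
segment_events <- function(labels, cuts = NULL, recording_id = "rec") {
  n <- length(labels)
  if (n == 0)
    return(data.frame(label = integer(0), start_idx = integer(0),
                      end_idx = integer(0), recording_id = character(0)))
  if (is.null(cuts)) cuts <- rep(FALSE, n)
  new_seg <- c(TRUE, (labels[-1] != labels[-n]) | cuts[-1])
  starts <- which(new_seg)
  ends <- c(starts[-1] - 1L, n)
  data.frame(label = as.integer(labels[starts]), start_idx = starts,
             end_idx = as.integer(ends), recording_id = recording_id)
}

# Largest-remainder integer allocation of `quota` over weights `w`.
largest_remainder <- function(quota, w) {
  if (quota == 0 || sum(w) == 0) return(integer(length(w)))
  share <- quota * w / sum(w)
  base <- floor(share)
  rem <- quota - sum(base)
  if (rem > 0) {
    ord <- order(share - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Within-event random sample extraction
#'
#' Draws a per-class quota of samples across recordings without replacement
#' from event interiors (never the first or last sample of a segment), at a
#' single class-specific extraction ratio `quota / class total` applied to
#' every recording. Every original segment keeps at least one sample, so
#' event counts are preserved. When a class quota cannot be met from
#' interiors alone, boundary samples are drawn as a logged relaxation
#' (still keeping one sample per segment). The extracted samples can either
#' be discarded (`removal` mode, used for balancing) or assembled into a
#' new subset preserving their original order (`subset` mode, used for
#' test-set extraction).
#'
#' @param recordings list; each element needs `label` and `cut_before`
#'   vectors (a feature matrix data.frame works directly).
#' @param quota named integer vector: samples to extract per class.
#' @param seed integer seed driving all randomness.
#' @param mode "removal" or "subset" (informational; the split is the same).
#' @return object of class `sample_split`: per-recording strictly increasing
#'   `kept` and `extracted` index lists, plus `mode`.
#' @export
within_event_extract <- function(recordings, quota, seed = 1,
                                 mode = c("removal", "subset")) {
  mode <- match.arg(mode)
  nr <- length(recordings)
  ids <- names(recordings) %||% as.character(seq_len(nr))
  labs <- lapply(recordings, function(r) as.integer(r$label))
  cuts <- lapply(recordings, function(r)
    if (!is.null(r$cut_before)) r$cut_before else rep(FALSE, length(r$label)))
  segs <- lapply(seq_len(nr), function(i)
    segment_events(labs[[i]], cuts[[i]], ids[i]))
  classes <- sort(unique(names(quota)))
  extracted <- lapply(seq_len(nr), function(i) integer(0))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  for (cl in classes) {
    q <- quota[[cl]]
    if (q == 0) next
    cln <- as.integer(cl)
    counts <- vapply(labs, function(l) sum(l == cln), integer(1))
    if (q > sum(counts))
      stop_gz("gazevents_balancing_error",
              "quota %d for class %s exceeds its %d samples", q, cl, sum(counts))
    per_rec <- largest_remainder(q, counts)
    # eligibility per recording: interior and boundary pools per segment
    pools <- lapply(seq_len(nr), function(i) {
      sg <- segs[[i]]
      sg <- sg[sg$label == cln, , drop = FALSE]
      interior <- integer(0); boundary <- integer(0); segl <- integer(0)
      seg_of_int <- integer(0); seg_of_bnd <- integer(0)
      if (nrow(sg) > 0) {
        for (k in seq_len(nrow(sg))) {
          a <- sg$start_idx[k]; b <- sg$end_idx[k]
          if (b - a >= 2) {
            interior <- c(interior, (a + 1):(b - 1))
            seg_of_int <- c(seg_of_int, rep(k, b - a - 1))
          }
          bnd <- unique(c(a, b))
          boundary <- c(boundary, bnd)
          seg_of_bnd <- c(seg_of_bnd, rep(k, length(bnd)))
          segl <- c(segl, b - a + 1)
        }
      }
      list(interior = interior, seg_of_int = seg_of_int,
           boundary = boundary, seg_of_bnd = seg_of_bnd, seg_len = segl)
    })
    # cap targets by what each recording can yield (len - 1 per segment),
    # redistributing any shortfall to recordings with spare capacity
    cap <- vapply(pools, function(p) sum(pmax(p$seg_len - 1, 0)), numeric(1))
    per_rec <- pmin(per_rec, cap)
    short <- q - sum(per_rec)
    while (short > 0) {
      room <- cap - per_rec
      if (sum(room) == 0)
        stop_gz("gazevents_balancing_error",
                "class %s: quota %d infeasible even with boundary relaxation",
                cl, q)
      add <- largest_remainder(min(short, sum(room)), room)
      add <- pmin(add, room)
      per_rec <- per_rec + add
      short <- q - sum(per_rec)
    }
    relaxed <- FALSE
    for (i in seq_len(nr)) {
      ni <- per_rec[i]
      if (ni == 0) next
      p <- pools[[i]]
      take_int <- min(ni, length(p$interior))
      sel <- if (take_int > 0)
        p$interior[sample.int(length(p$interior), take_int)] else integer(0)
      rem <- ni - take_int
      if (rem > 0) {
        relaxed <- TRUE
        removed_per_seg <- tabulate(p$seg_of_int[match(sel, p$interior)],
                                    nbins = length(p$seg_len))
        cand_ord <- sample.int(length(p$boundary))
        for (ci in cand_ord) {
          if (rem == 0) break
          sk <- p$seg_of_bnd[ci]
          if (removed_per_seg[sk] < p$seg_len[sk] - 1L) {
            sel <- c(sel, p$boundary[ci])
            removed_per_seg[sk] <- removed_per_seg[sk] + 1L
            rem <- rem - 1L
          }
        }
        if (rem > 0)
          stop_gz("gazevents_balancing_error",
                  "class %s: quota infeasible in recording %s", cl, ids[i])
      }
      extracted[[i]] <- c(extracted[[i]], sel)
    }
    if (relaxed)
      message(sprintf("within_event_extract: boundary relaxation used for class %s",
                      cl))
  }
  kept <- lapply(seq_len(nr), function(i)
    setdiff(seq_along(labs[[i]]), extracted[[i]]))
  extracted <- lapply(extracted, sort)
  names(kept) <- ids; names(extracted) <- ids
  structure(list(kept = kept, extracted = extracted, mode = mode),
            class = "sample_split")
}

#' Subset a recording's rows, preserving event structure
#'
#' Rows are kept by index; a `cut_before` flag on any removed row migrates
#' to the next kept row so that events separated by a cut never merge. No
#' new flags are introduced for removed interior samples, so removal-mode
#' extraction leaves the segment count unchanged.
#'
#' @param fm feature matrix data.frame (needs `cut_before`).
#' @param keep strictly increasing row indices to keep.
#' @return the subset data.frame with propagated flags.
#' @export
apply_sample_split <- function(fm, keep) {
  out <- fm[keep, , drop = FALSE]
  if (length(keep) > 0) {
    prev <- c(0L, keep[-length(keep)])
    carried <- vapply(seq_along(keep), function(i) {
      gap <- setdiff(seq(prev[i] + 1L, keep[i]), keep[i])
      length(gap) > 0 && any(fm$cut_before[gap])
    }, logical(1))
    out$cut_before <- out$cut_before | carried
  }
  rownames(out) <- NULL
  attr(out, "recording_id") <- attr(fm, "recording_id")
  out
}

#' Balance leave-one-out training recordings to the smallest class
#'
#' Pools sample counts per class over the training recordings and removes
#' the surplus of every class down to the minimum-class count using
#' [within_event_extract()] in removal mode, preserving per-recording event
#' counts. Classes with zero samples are skipped with a warning.
#'
#' @param recordings list of feature matrices (need `label`, `cut_before`).
#' @param seed integer seed.
#' @return list of feature matrices with surplus rows removed.
#' @export
balance_loo_train <- function(recordings, seed = 1) {
  labs <- unlist(lapply(recordings, function(r) r$label))
  counts <- table(factor(labs))
  if (length(counts) < 2) {
    warning("fewer than 2 classes present; balancing skipped")
    return(recordings)
  }
  m <- min(counts)
  quota <- as.integer(counts) - m
  names(quota) <- names(counts)
  quota <- quota[quota > 0]
  if (length(quota) == 0) return(recordings)
  split <- within_event_extract(recordings, quota, seed = seed,
                                mode = "removal")
  out <- lapply(seq_along(recordings), function(i)
    apply_sample_split(recordings[[i]], split$kept[[i]]))
  names(out) <- names(recordings)
  out
}

#' Balanced train/test split within events
#'
#' Two steps. Balancing: per-class surplus samples are deleted from the
#' start of each recording (allocated across recordings in proportion to
#' their class counts) until pooled class counts are equal; the sample
#' following each deleted block receives a `cut_before` flag so events of
#' the same class never merge. Extraction: [within_event_extract()] in
#' subset mode pulls `test_fraction` of each class's samples as the test
#' set, preserving original sample order; the remainder is the training
#' set. Train and test index sets are disjoint and exhaustive over the
#' balanced recordings.
#'
#' @param recordings list of feature matrices (need `label`, `cut_before`).
#' @param test_fraction fraction of each class extracted for testing
#'   (default 0.20).
#' @param seed integer seed.
#' @return list with `train` and `test` (lists of feature matrices) and
#'   `manifest`: one row per original sample with its assignment
#'   (train / test / removed).
#' @export
split_train_test <- function(recordings, test_fraction = 0.20, seed = 1) {
  nr <- length(recordings)
  ids <- names(recordings) %||%
    vapply(seq_len(nr), function(i)
      attr(recordings[[i]], "recording_id") %||% as.character(i), character(1))
  labs <- lapply(recordings, function(r) as.integer(r$label))
  counts <- table(factor(unlist(labs)))
  m <- min(counts)
  manifest <- do.call(rbind, lapply(seq_len(nr), function(i)
    data.frame(recording_id = ids[i], sample_index = seq_along(labs[[i]]),
               assignment = "train", stringsAsFactors = FALSE)))
  # step 1: head-trim balancing
  balanced <- recordings
  for (cl in names(counts)) {
    surplus <- as.integer(counts[[cl]]) - m
    if (surplus == 0) next
    cln <- as.integer(cl)
    w <- vapply(labs, function(l) sum(l == cln), integer(1))
    per_rec <- pmin(largest_remainder(surplus, w), w)
    short <- surplus - sum(per_rec)
    while (short > 0) {
      room <- w - per_rec
      add <- pmin(largest_remainder(min(short, sum(room)), room), room)
      per_rec <- per_rec + add
      short <- surplus - sum(per_rec)
    }
    for (i in seq_len(nr)) {
      if (per_rec[i] == 0) next
      idx <- which(balanced[[i]]$label == cln)[seq_len(per_rec[i])]
      keep <- setdiff(seq_len(nrow(balanced[[i]])), idx)
      r <- balanced[[i]][keep, , drop = FALSE]
      gap <- c(keep[1] > 1, diff(keep) > 1)
      r$cut_before <- r$cut_before | gap
      rownames(r) <- NULL
      attr(r, "recording_id") <- attr(recordings[[i]], "recording_id")
      balanced[[i]] <- r
      manifest$assignment[manifest$recording_id == ids[i] &
                            manifest$sample_index %in%
                            which(labs[[i]] == cln)[seq_len(per_rec[i])]] <- "removed"
      labs[[i]] <- balanced[[i]]$label
    }
  }
  # step 2: within-event extraction of the test fraction
  counts2 <- table(factor(unlist(labs)))
  quota <- round(test_fraction * as.integer(counts2))
  names(quota) <- names(counts2)
  split <- within_event_extract(balanced, quota, seed = seed, mode = "subset")
  train <- lapply(seq_len(nr), function(i)
    apply_sample_split(balanced[[i]], split$kept[[i]]))
  test <- lapply(seq_len(nr), function(i) {
    r <- balanced[[i]][split$extracted[[i]], , drop = FALSE]
    rownames(r) <- NULL
    attr(r, "recording_id") <- attr(recordings[[i]], "recording_id")
    r
  })
  names(train) <- ids; names(test) <- ids
  # record test assignments in the manifest (indices refer to the balanced
  # recordings; map back through the kept rows of step 1)
  for (i in seq_len(nr)) {
    orig_kept <- which(manifest$assignment[manifest$recording_id == ids[i]] != "removed")
    rows <- which(manifest$recording_id == ids[i])
    manifest$assignment[rows[orig_kept[split$extracted[[i]]]]] <- "test"
  }
  list(train = train, test = test, manifest = manifest)
}
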