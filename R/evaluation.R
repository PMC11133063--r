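# Sample-level and event-level one-vs-all scoring with majority-voting
# event matching, plus the leave-one-out and train-test-split validation
# procedures.
#
# Per class c: TP = #(gt = c & pred = c), FP = #(gt != c & pred = c),
# FN = #(gt = c & pred != c); precision = TP / (TP + FP),
# recall = TP / (TP + FN), F1 = 2PR / (P + R) = TP / (TP + (FP + FN) / 2),
# all with zero-denominator guarded to 0. Event level: each ground-truth
# event is matched to the most frequent predicted class within its span
# (ties broken by the tied class occurring earliest in the span).

f1_from_counts <- function(tp, fp, fn) {
  p <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  r <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(tp + (fp + fn) / 2 > 0, tp / (tp + (fp + fn) / 2), 0)
  data.frame(precision = p, recall = r, f1 = f1)
}

scores_from_counts <- function(tp, fp, fn, classes, weight) {
  cbind(data.frame(class = classes, TP = tp, FP = fp, FN = fn),
        f1_from_counts(tp, fp, fn), data.frame(weight = weight))
}

#' Sample-level one-vs-all precision/recall/F1
#'
#' @param gt integer ground-truth labels.
#' @param pred integer predicted labels (same length).
#' @param classes classes to score (default: union of gt and pred).
#' @return data.frame with one row per class: TP, FP, FN, precision,
#'   recall, f1, and `weight` (relative class frequency in gt).
#' @export
sample_level_scores <- function(gt, pred, classes = NULL) {
  if (length(gt) != length(pred) || length(gt) == 0)
    stop_gz("gazevents_argument_error",
            "gt and pred must be non-empty and of equal length")
  if (is.null(classes)) classes <- sort(unique(c(gt, pred)))
  tp <- fp <- fn <- integer(length(classes))
  for (k in seq_along(classes)) {
    c_ <- classes[k]
    tp[k] <- sum(gt == c_ & pred == c_)
    fp[k] <- sum(gt != c_ & pred == c_)
    fn[k] <- sum(gt == c_ & pred != c_)
  }
  w <- vapply(classes, function(c_) sum(gt == c_), integer(1)) / length(gt)
  scores_from_counts(tp, fp, fn, classes, w)
}

#' Sample-level confusion matrix
#'
#' @param gt,pred integer label vectors.
#' @param classes classes to tabulate.
#' @return class x class count matrix (rows = ground truth).
#' @export
confusion_matrix <- function(gt, pred, classes = NULL) {
  if (is.null(classes)) classes <- sort(unique(c(gt, pred)))
  m <- table(factor(gt, levels = classes), factor(pred, levels = classes))
  unclass(as.matrix(m))
}

# Majority vote over a span of predictions; ties go to the tied class whose
# first occurrence in the span is earliest.
majority_label <- function(span) {
  tab <- table(span)
  top <- as.integer(names(tab)[tab == max(tab)])
  if (length(top) == 1) return(top)
  firsts <- vapply(top, function(c_) match(c_, span), integer(1))
  top[which.min(firsts)]
}

#' Event-level one-vs-all scores with majority-voting matching
#'
#' Each ground-truth event (segment) is assigned the most frequent
#' predicted class within its span; a correct match counts one TP for the
#' event's class, a mismatch one FN for the event's class and one FP for
#' the predicted class.
#'
#' @param gt_segments segments data.frame from [segment_events()].
#' @param pred integer predicted labels covering the segment index range.
#' @param classes classes to score (default: union of segment labels and
#'   predictions).
#' @return list with `scores` (per-class data.frame as in
#'   [sample_level_scores()], `weight` = relative event frequency) and
#'   `confusion` (event-count matrix, rows = ground truth).
#' @export
event_level_scores <- function(gt_segments, pred, classes = NULL) {
  if (nrow(gt_segments) > 0 &&
      (min(gt_segments$start_idx) < 1 || max(gt_segments$end_idx) > length(pred)))
    stop_gz("gazevents_argument_error", "segment indices out of range")
  modes <- vapply(seq_len(nrow(gt_segments)), function(k)
    majority_label(pred[gt_segments$start_idx[k]:gt_segments$end_idx[k]]),
    integer(1))
  gt_ev <- gt_segments$label
  if (is.null(classes)) classes <- sort(unique(c(gt_ev, modes)))
  tp <- fp <- fn <- integer(length(classes))
  for (k in seq_along(classes)) {
    c_ <- classes[k]
    tp[k] <- sum(gt_ev == c_ & modes == c_)
    fp[k] <- sum(gt_ev != c_ & modes == c_)
    fn[k] <- sum(gt_ev == c_ & modes != c_)
  }
  w <- vapply(classes, function(c_) sum(gt_ev == c_), integer(1)) /
    max(1, length(gt_ev))
  list(scores = scores_from_counts(tp, fp, fn, classes, w),
       confusion = confusion_matrix(gt_ev, modes, classes),
       event_pred = modes)
}

#' Frequency-weighted average F1
#'
#' @param scores per-class scores data.frame (needs `f1`).
#' @param weights per-class relative frequencies (>= 0, summing to 1 over
#'   the classes present); defaults to the `weight` column of `scores`.
#' @return weighted average F1 in [0, 1].
#' @export
weighted_average_f1 <- function(scores, weights = NULL) {
  if (is.null(weights)) weights <- scores$weight
  if (any(weights < 0))
    stop_gz("gazevents_argument_error", "negative weight")
  sum(weights * scores$f1)
}

pool_counts <- function(acc, add) {
  if (is.null(acc)) return(add)
  for (cl in rownames(add)) {
    if (!cl %in% rownames(acc)) {
      acc <- rbind(acc, add[cl, , drop = FALSE])
    } else {
      acc[cl, ] <- acc[cl, ] + add[cl, ]
    }
  }
  acc
}

#' Run a full validation procedure over feature matrices
#'
#' `mode = "loo"`: each recording in turn is held out; the remaining
#' recordings are class-balanced with [balance_loo_train()], a classifier
#' is trained and the (unbalanced) held-out recording predicted. TP/FP/FN
#' and confusion counts are pooled across folds before the final scores are
#' computed (robust to folds where a class is absent). `mode = "split"`:
#' all recordings are head-trim balanced, 20% of each class extracted as
#' the test set with [split_train_test()], a single classifier trained on
#' the remainder and scored on the extracted test sequences.
#'
#' @param recordings named list of feature matrices.
#' @param mode "loo" or "split".
#' @param seed integer seed for balancing and training.
#' @param test_fraction test fraction for split mode (default 0.20).
#' @param params classifier hyperparameters.
#' @param merge_map optional named vector merging labels before validation,
#'   e.g. `c("4" = 1)` folds gaze following into gaze fixation.
#' @return object of class `evaluation_report`: per-class `sample_scores`
#'   and `event_scores`, `weighted_sample_f1`, `weighted_event_f1`,
#'   `confusion_sample`, `confusion_event` (raw counts; row-normalized
#'   copies as `*_norm`), per-iteration feature `importances`, and the
#'   seed/mode metadata.
#' @export
run_validation <- function(recordings, mode = c("loo", "split"), seed = 1,
                           test_fraction = 0.20,
                           params = default_rf_params(), merge_map = NULL) {
  mode <- match.arg(mode)
  if (!is.null(merge_map)) {
    recordings <- lapply(recordings, function(r) {
      for (from in names(merge_map))
        r$label[r$label == as.integer(from)] <- as.integer(merge_map[[from]])
      r
    })
  }
  classes <- sort(unique(unlist(lapply(recordings, function(r) r$label))))
  cls_chr <- as.character(classes)
  zero <- matrix(0L, length(classes), 3,
                 dimnames = list(cls_chr, c("TP", "FP", "FN")))
  samp_counts <- zero; ev_counts <- zero
  conf_s <- matrix(0L, length(classes), length(classes),
                   dimnames = list(cls_chr, cls_chr))
  conf_e <- conf_s
  gt_all <- integer(0); ev_all <- integer(0)
  importances <- list()

  score_fold <- function(test_fm, pred) {
    ss <- sample_level_scores(test_fm$label, pred, classes)
    segs <- segment_events(test_fm$label, test_fm$cut_before)
    es <- event_level_scores(segs, pred, classes)
    samp_counts[cls_chr, ] <<- samp_counts[cls_chr, ] +
      as.matrix(ss[, c("TP", "FP", "FN")])
    ev_counts[cls_chr, ] <<- ev_counts[cls_chr, ] +
      as.matrix(es$scores[, c("TP", "FP", "FN")])
    conf_s <<- conf_s + confusion_matrix(test_fm$label, pred, classes)
    conf_e <<- conf_e + es$confusion
    gt_all <<- c(gt_all, test_fm$label)
    ev_all <<- c(ev_all, segs$label)
  }

  if (mode == "loo") {
    if (length(recordings) < 2)
      stop_gz("gazevents_argument_error",
              "leave-one-out needs at least 2 recordings")
    for (i in seq_along(recordings)) {
      res <- tryCatch({
        train <- balance_loo_train(recordings[-i], seed = seed)
        model <- train_classifier(train, seed = seed, params = params)
        pred <- predict_labels(model, recordings[[i]])$label
        importances[[length(importances) + 1]] <- feature_importances_gini(model)
        score_fold(recordings[[i]], pred)
      }, gazevents_error = function(e)
        stop_gz("gazevents_pipeline_error", "fold %d: %s", i, conditionMessage(e)))
    }
  } else {
    sp <- split_train_test(recordings, test_fraction = test_fraction,
                           seed = seed)
    model <- train_classifier(sp$train, seed = seed, params = params)
    importances[[1]] <- feature_importances_gini(model)
    for (i in seq_along(sp$test)) {
      if (nrow(sp$test[[i]]) == 0) next
      pred <- predict_labels(model, sp$test[[i]])$label
      score_fold(sp$test[[i]], pred)
    }
  }
  w_s <- vapply(classes, function(c_) sum(gt_all == c_), integer(1)) /
    length(gt_all)
  w_e <- vapply(classes, function(c_) sum(ev_all == c_), integer(1)) /
    length(ev_all)
  sample_scores <- scores_from_counts(samp_counts[, "TP"], samp_counts[, "FP"],
                                      samp_counts[, "FN"], classes, w_s)
  event_scores <- scores_from_counts(ev_counts[, "TP"], ev_counts[, "FP"],
                                     ev_counts[, "FN"], classes, w_e)
  structure(list(
    mode = mode, seed = seed, classes = classes,
    sample_scores = sample_scores, event_scores = event_scores,
    weighted_sample_f1 = weighted_average_f1(sample_scores),
    weighted_event_f1 = weighted_average_f1(event_scores),
    confusion_sample = conf_s, confusion_event = conf_e,
    confusion_sample_norm = conf_s / pmax(rowSums(conf_s), 1),
    confusion_event_norm = conf_e / pmax(rowSums(conf_e), 1),
    importances = do.call(rbind, importances)),
    class = "evaluation_report")
}

# Importances without refitting: Gini importances are available on any
# fitted forest.
feature_importances_gini <- function(model) {
  imp <- randomForest::importance(model$forest, type = 2)[, 1]
  imp <- imp[model$feature_order]
  imp / sum(imp)
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report (%s): weighted F1 sample %.3f / event %.3f>\n",
              x$mode, x$weighted_sample_f1, x$weighted_event_f1))
  print(x$event_scores, digits = 3)
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' JSON summary plus per-class and confusion CSV tables.
#'
#' @param report an `evaluation_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(list(
    mode = report$mode, seed = report$seed, classes = report$classes,
    weighted_sample_f1 = report$weighted_sample_f1,
    weighted_event_f1 = report$weighted_event_f1),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  write.csv(report$sample_scores, file.path(dir, "sample_scores.csv"),
            row.names = FALSE)
  write.csv(report$event_scores, file.path(dir, "event_scores.csv"),
            row.names = FALSE)
  write.csv(as.data.frame(report$confusion_sample),
            file.path(dir, "confusion_sample.csv"))
  write.csv(as.data.frame(report$confusion_event),
            file.path(dir, "confusion_event.csv"))
  if (!is.null(report$importances))
    write.csv(as.data.frame(report$importances),
              file.path(dir, "importances.csv"), row.names = FALSE)
  invisible(dir)
}
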