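test_that("worked example: sample F1 0.8 per class, event F1 1.0 per class", {
  gt <- c(1, 1, 1, 3, 3)
  pred <- c(1, 1, 3, 3, 3)
  ss <- sample_level_scores(gt, pred)
  expect_equal(ss$precision[ss$class == 1], 1)
  expect_equal(ss$recall[ss$class == 1], 2 / 3)
  expect_equal(ss$f1[ss$class == 1], 0.8)
  expect_equal(ss$precision[ss$class == 3], 2 / 3)
  expect_equal(ss$recall[ss$class == 3], 1)
  expect_equal(ss$f1[ss$class == 3], 0.8)
  segs <- segment_events(gt)
  es <- event_level_scores(segs, pred)
  expect_equal(es$scores$f1, c(1, 1))
})

test_that("both printed F1 forms agree over random count triples", {
  set.seed(60)
  dev <- 0
  for (i in 1:1000) {
    tp <- sample(0:50, 1); fp <- sample(0:50, 1); fn <- sample(0:50, 1)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1_a <- if (p + r > 0) 2 * p * r / (p + r) else 0
    f1_b <- if (tp + (fp + fn) / 2 > 0) tp / (tp + (fp + fn) / 2) else 0
    dev <- max(dev, abs(f1_a - f1_b),
               abs(gazevents:::f1_from_counts(tp, fp, fn)$f1 - f1_b))
  }
  expect_lt(dev, 1e-12)
})

test_that("scores match the brute-force enumerator on random sequences", {
  set.seed(61)
  count_mismatch <- 0L
  f1_dev <- 0
  confusion_bad <- 0L
  for (i in 1:1000) {
    n <- sample(5:50, 1)
    gt <- sample(1:4, n, replace = TRUE)
    pred <- sample(1:4, n, replace = TRUE)
    cuts <- runif(n) < 0.08
    cuts[1] <- FALSE
    classes <- 1:4
    ss <- sample_level_scores(gt, pred, classes)
    o <- oracle_sample_scores(gt, pred, classes)
    segs <- segment_events(gt, cuts)
    es <- event_level_scores(segs, pred, classes)
    oe <- oracle_event_scores(gt, cuts, pred, classes)
    for (k in seq_along(classes)) {
      ok <- o[[as.character(classes[k])]]
      if (!identical(c(ss$TP[k], ss$FP[k], ss$FN[k]),
                     unname(as.integer(ok[c("TP", "FP", "FN")]))))
        count_mismatch <- count_mismatch + 1L
      f1_dev <- max(f1_dev, abs(ss$f1[k] - unname(ok["f1"])))
      oke <- oe$scores[[as.character(classes[k])]]
      if (!identical(c(es$scores$TP[k], es$scores$FP[k], es$scores$FN[k]),
                     unname(as.integer(oke[c("TP", "FP", "FN")]))))
        count_mismatch <- count_mismatch + 1L
      f1_dev <- max(f1_dev, abs(es$scores$f1[k] - unname(oke["f1"])))
    }
    # confusion row sums equal per-class ground-truth counts; event total
    # equals the number of ground-truth segments
    cm <- confusion_matrix(gt, pred, classes)
    if (!identical(unname(rowSums(cm)),
                   as.numeric(vapply(classes, function(c_) sum(gt == c_),
                                     integer(1)))) ||
        sum(es$confusion) != nrow(segs))
      confusion_bad <- confusion_bad + 1L
  }
  expect_identical(count_mismatch, 0L)
  expect_lt(f1_dev, 1e-12)
  expect_identical(confusion_bad, 0L)
})

test_that("majority-vote ties go to the earliest tied class in the span", {
  # class-3 segment spanning indices 1..4 with a 1/3 tie; 1 occurs first
  segs <- data.frame(label = 3L, start_idx = 1L, end_idx = 4L,
                     recording_id = "r")
  es <- event_level_scores(segs, c(1, 3, 1, 3), classes = c(1, 3))
  expect_equal(es$scores$FP[es$scores$class == 1], 1)
  expect_equal(es$scores$FN[es$scores$class == 3], 1)
  expect_equal(es$scores$TP, c(0, 0))
})

test_that("guard rules: absent classes, zero denominators, weights", {
  ss <- sample_level_scores(c(1, 1), c(1, 1), classes = c(1, 3))
  expect_equal(ss$f1[ss$class == 3], 0)
  expect_equal(ss$weight[ss$class == 3], 0)
  expect_error(sample_level_scores(1:3, 1:2),
               class = "gazevents_argument_error")
  expect_error(weighted_average_f1(data.frame(f1 = 0.5), weights = -0.1),
               class = "gazevents_argument_error")
  # weighted averages
  expect_equal(weighted_average_f1(data.frame(f1 = c(0.8, 0.8)),
                                   weights = c(0.6, 0.4)), 0.8)
  expect_equal(weighted_average_f1(data.frame(f1 = c(1, 0)),
                                   weights = c(0.75, 0.25)), 0.75)
  expect_equal(weighted_average_f1(data.frame(f1 = 0.61), weights = 1), 0.61)
})

test_that("perfect predictions give weighted F1 of 1 in both validation modes", {
  # two recordings of trivially separable features
  set.seed(62)
  mk <- function(id) {
    fm <- make_cluster_fm(60, sd = 0.02, id = id)
    fm[order(fm$label), ]
  }
  recs <- list(a = mk("a"), b = mk("b"))
  recs <- lapply(recs, function(r) { rownames(r) <- NULL; r })
  rep_loo <- run_validation(recs, mode = "loo", seed = 1)
  expect_equal(rep_loo$weighted_sample_f1, 1)
  expect_equal(rep_loo$weighted_event_f1, 1)
  expect_true(all(diag(rep_loo$confusion_sample) == rowSums(rep_loo$confusion_sample)))
  rep_sp <- run_validation(recs, mode = "split", seed = 1)
  expect_equal(rep_sp$weighted_sample_f1, 1)
  expect_equal(rep_sp$weighted_event_f1, 1)
})

test_that("validation reports are deterministic and merge labels correctly", {
  set.seed(63)
  recs <- list(a = make_cluster_fm(50, sd = 1.5, id = "a"),
               b = make_cluster_fm(50, sd = 1.5, id = "b"))
  r1 <- run_validation(recs, mode = "loo", seed = 5)
  r2 <- run_validation(recs, mode = "loo", seed = 5)
  expect_identical(r1$sample_scores, r2$sample_scores)
  expect_identical(r1$confusion_event, r2$confusion_event)
  # merging gaze following into gaze fixation leaves classes {1,2,3}
  rm_ <- run_validation(recs, mode = "loo", seed = 5, merge_map = c(`4` = 1))
  expect_equal(rm_$classes, c(1, 2, 3))
  # report files are written
  dir <- withr::local_tempdir()
  write_report(r1, dir)
  expect_true(file.exists(file.path(dir, "report.json")))
  expect_true(file.exists(file.path(dir, "event_scores.csv")))
})
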