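test_that("event segmentation tiles the recording and honors cut flags", {
  s <- segment_events(c(1, 1, 3, 3, 1))
  expect_equal(nrow(s), 3)
  expect_equal(s$label, c(1L, 3L, 1L))
  expect_equal(s$start_idx, c(1L, 3L, 5L))
  expect_equal(s$end_idx, c(2L, 4L, 5L))

  s2 <- segment_events(c(1, 1, 1, 1), cuts = c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(nrow(s2), 2)
  expect_equal(s2$start_idx, c(1L, 3L))

  expect_equal(nrow(segment_events(7L)), 1)
})

test_that("within-event extraction preserves events and meets quotas", {
  labels <- c(1, 1, 1, 1, 3, 3, 1, 1, 1, 1)
  recs <- list(A = make_label_fm(labels))
  split <- within_event_extract(recs, c(`1` = 6L), seed = 1, mode = "removal")
  kept <- recs$A$label[split$kept$A]
  expect_equal(sum(kept == 1), 2)
  expect_equal(sum(kept == 3), 2)
  # kept still contains 3 events tiling two fixation events and the shift
  segs <- segment_events(kept)
  expect_equal(nrow(segs), 3)
  # partition + order invariants
  expect_equal(sort(c(split$kept$A, split$extracted$A)), 1:10)
  expect_true(all(diff(split$extracted$A) > 0))

  # zero quota is the identity
  s0 <- within_event_extract(recs, c(`1` = 0L), seed = 1)
  expect_equal(s0$kept$A, 1:10)
  expect_equal(length(s0$extracted$A), 0)

  # determinism and seed sensitivity with fixed per-class counts
  labels2 <- rep(c(1, 1, 1, 1, 1, 3, 3, 3), 10)
  recs2 <- list(A = make_label_fm(labels2))
  sa <- within_event_extract(recs2, c(`1` = 20L), seed = 7)
  sb <- within_event_extract(recs2, c(`1` = 20L), seed = 7)
  sc_ <- within_event_extract(recs2, c(`1` = 20L), seed = 8)
  expect_identical(sa, sb)
  expect_equal(length(sc_$extracted$A), 20)
  expect_false(identical(sa$extracted$A, sc_$extracted$A))

  # infeasible quota errors, naming the class
  expect_error(within_event_extract(recs, c(`3` = 5L), seed = 1),
               "class 3", class = "gazevents_balancing_error")
})

test_that("LOO balancing matches the smallest class across recordings", {
  set.seed(41)
  recs <- list(
    r1 = make_label_fm(unlist(lapply(1:40, function(i) rep(1, 25)))),
    r2 = make_label_fm(c(rep(3, 50), rep(1, 100), rep(3, 50))))
  # pooled: class 1 = 1100, class 3 = 100
  bal <- balance_loo_train(recs, seed = 2)
  counts <- table(unlist(lapply(bal, function(r) r$label)))
  expect_equal(unname(diff(range(counts))), 0)
  expect_equal(unname(counts[["3"]]), 100)
  # per-recording event counts unchanged
  for (id in names(recs)) {
    expect_equal(nrow(segment_events(bal[[id]]$label, bal[[id]]$cut_before)),
                 nrow(segment_events(recs[[id]]$label, recs[[id]]$cut_before)))
  }
  # already balanced input unchanged
  even <- list(make_label_fm(rep(c(1, 1, 1, 3, 3, 3), 5)))
  expect_equal(balance_loo_train(even, seed = 1)[[1]]$label, even[[1]]$label)
  # single class: warning, unchanged
  single <- list(make_label_fm(rep(1, 20)))
  expect_warning(out <- balance_loo_train(single, seed = 1), "classes")
  expect_equal(out[[1]]$label, single[[1]]$label)
})

test_that("train-test split balances head-first then extracts 20% in order", {
  # single class, one recording: plain 20/80 split
  recs <- list(A = make_label_fm(rep(1, 100)))
  sp <- split_train_test(recs, seed = 3)
  expect_equal(nrow(sp$test$A), 20)
  expect_equal(nrow(sp$train$A), 80)
  expect_true(all(diff(sp$test$A$t) > 0))

  # two classes 150/50: balancing trims class 1 to 50, then 10+10 to test
  labels <- c(rep(1, 75), rep(3, 25), rep(1, 75), rep(3, 25))
  recs2 <- list(A = make_label_fm(labels))
  sp2 <- split_train_test(recs2, seed = 4)
  all_lab <- c(sp2$train$A$label, sp2$test$A$label)
  expect_equal(sum(all_lab == 1), 50)
  expect_equal(sum(all_lab == 3), 50)
  expect_equal(sum(sp2$test$A$label == 1), 10)
  expect_equal(sum(sp2$test$A$label == 3), 10)
  # head-trim removed the first class-1 samples and left a cut flag
  expect_equal(sum(sp2$manifest$assignment == "removed"), 100)
  expect_identical(sp2$manifest$assignment[1], "removed")

  # same seed reproduces the split
  sp2b <- split_train_test(recs2, seed = 4)
  expect_identical(sp2$manifest, sp2b$manifest)
})

test_that("sampling invariants hold over 200 random recordings", {
  set.seed(90)
  for (trial in 1:200) {
    r <- random_label_recording(n = sample(80:200, 1))
    fm <- make_label_fm(r$labels, r$cuts)
    recs <- list(A = fm)
    counts <- table(factor(fm$label))
    cl <- names(counts)[which.max(counts)]
    segs0 <- segment_events(fm$label, fm$cut_before)
    seg_before <- nrow(segs0)
    # preserving every event caps removable samples at count - #segments
    cap <- as.integer(counts[cl]) - sum(segs0$label == as.integer(cl))
    quota <- stats::setNames(min(max(0L, as.integer(counts[cl]) -
                                       as.integer(min(counts))), cap), cl)
    if (quota > 0) {
      sp <- within_event_extract(recs, quota, seed = trial, mode = "removal")
      kept <- apply_sample_split(fm, sp$kept$A)
      # tiling and order
      expect_equal(sort(c(sp$kept$A, sp$extracted$A)), seq_len(nrow(fm)))
      expect_true(all(diff(sp$kept$A) > 0))
      # event preservation in removal mode
      expect_equal(nrow(segment_events(kept$label, kept$cut_before)),
                   seg_before)
    }
  }
})

test_that("LOO balance and split quotas hold over random multi-recordings", {
  set.seed(91)
  for (trial in 1:40) {
    recs <- lapply(1:3, function(i) {
      r <- random_label_recording(n = sample(150:300, 1), mean_run = 8)
      make_label_fm(r$labels, r$cuts, id = paste0("r", i))
    })
    names(recs) <- paste0("r", 1:3)
    bal <- balance_loo_train(recs, seed = trial)
    counts <- table(unlist(lapply(bal, function(r) r$label)))
    expect_lte(diff(range(counts)), length(recs))

    sp <- split_train_test(recs, seed = trial)
    for (cl in names(table(unlist(lapply(sp$train, function(r) r$label))))) {
      n_test <- sum(unlist(lapply(sp$test, function(r) r$label)) == cl)
      n_tot <- n_test + sum(unlist(lapply(sp$train, function(r) r$label)) == cl)
      expect_lte(abs(n_test - 0.2 * n_tot), 1)
    }
    for (id in names(sp$test)) {
      if (nrow(sp$test[[id]]) > 1) expect_true(all(diff(sp$test[[id]]$t) > 0))
    }
  }
})
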