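test_that("confusion counts tally predictions correctly", {
  truth <- c(a = "nuclear", b = "nuclear", c = "nuclear",
             d = "non_nuclear", e = "non_nuclear")
  cc <- confusion_from_predictions(truth, truth)
  expect_equal(unlist(cc[c("tp", "tn", "fp", "fn")]),
               c(tp = 3, tn = 2, fp = 0, fn = 0))
  flipped <- ifelse(truth == "nuclear", "non_nuclear", "nuclear")
  names(flipped) <- names(truth)
  cc2 <- confusion_from_predictions(truth, flipped)
  expect_equal(unlist(cc2[c("tp", "tn", "fp", "fn")]),
               c(tp = 0, tn = 0, fp = 2, fn = 3))

  truth6 <- c(p1 = "nuclear", p2 = "nuclear", p3 = "nuclear",
              p4 = "non_nuclear", p5 = "non_nuclear", p6 = "non_nuclear")
  pred6 <- c(p1 = "nuclear", p2 = "non_nuclear", p3 = "nuclear",
             p4 = "nuclear", p5 = "non_nuclear", p6 = "non_nuclear")
  cc3 <- confusion_from_predictions(truth6, pred6)
  expect_equal(unlist(cc3[c("tp", "tn", "fp", "fn")]),
               c(tp = 2, tn = 2, fp = 1, fn = 1))

  expect_error(confusion_from_predictions(truth, truth[-1]),
               "id mismatch")
})

test_that("metric formulas, symmetry and edge cases are exact", {
  k <- compute_metrics(confusion_counts(4, 4, 4, 4))
  expect_equal(k$sensitivity, 0.5)
  expect_equal(k$specificity, 0.5)
  expect_equal(k$accuracy, 0.5)
  expect_equal(k$mcc, 0)

  # undefined metrics are NA, never 0
  no_pos <- compute_metrics(confusion_counts(0, 5, 0, 0))
  expect_true(is.na(no_pos$sensitivity))
  expect_true(is.na(no_pos$mcc))
  expect_equal(no_pos$specificity, 1)

  # MCC endpoint characterization
  expect_equal(compute_metrics(confusion_counts(3, 4, 0, 0))$mcc, 1)
  expect_equal(compute_metrics(confusion_counts(0, 0, 4, 3))$mcc, -1)

  # symmetric under (tp,tn) and (fp,fn) swap
  m1 <- compute_metrics(confusion_counts(7, 3, 2, 5))
  m2 <- compute_metrics(confusion_counts(3, 7, 5, 2))
  expect_equal(m1$mcc, m2$mcc)

  expect_error(compute_metrics(confusion_counts(0, 0, 0, 0)), "N must be")
  expect_error(confusion_counts(-1, 0, 0, 2), "nonnegative")
})

test_that("metrics agree with an independent oracle on random counts", {
  # oracle: MCC is the Pearson correlation of the 0/1 truth/prediction
  # vectors; Sens/Spec/Acc recomputed from first principles
  set.seed(123)
  for (rep in 1:300) {
    cts <- as.list(setNames(sample(1:30, 4, replace = TRUE),
                            c("tp", "tn", "fp", "fn")))
    truth <- c(rep(1, cts$tp + cts$fn), rep(0, cts$tn + cts$fp))
    pred <- c(rep(1, cts$tp), rep(0, cts$fn),
              rep(0, cts$tn), rep(1, cts$fp))
    m <- compute_metrics(confusion_counts(cts$tp, cts$tn, cts$fp, cts$fn))
    expect_equal(m$mcc, suppressWarnings(cor(truth, pred)),
                 tolerance = 1e-12)
    expect_equal(m$sensitivity, mean(pred[truth == 1]))
    expect_equal(m$specificity, mean(1 - pred[truth == 0]))
    expect_equal(m$accuracy, mean(truth == pred))
  }
})

test_that("cross-validation partitions correctly and pools all proteins", {
  fx <- tiny_cv_fixture(n_per_class = 5, seed = 21)
  cv <- suppressWarnings(
    cross_validate(fx$features, fx$labels, mode = "plsi", folds = 5,
                   seed = 4, topics = 3, grid = small_grid(),
                   tune_folds = 2, plsi_max_iter = 30))
  # each fold holds out exactly one protein per class
  for (f in 1:5) expect_equal(cv$per_fold[[f]]$n_test, 2)
  expect_equal(cv$confusion$N, 10)
  expect_identical(sort(cv$predictions$id),
                   sort(names(fx$labels)))
  expect_equal(anyDuplicated(cv$predictions$id), 0)
  expect_error(
    cross_validate(fx$features, fx$labels, folds = 6, topics = 3),
    "minority class")
})

test_that("signature selection in CV uses only the training split", {
  fx <- tiny_cv_fixture(n_per_class = 6, seed = 31)
  cv <- suppressWarnings(
    cross_validate(fx$features, fx$labels, mode = "signatures", folds = 3,
                   seed = 9, topics = 4, topics_per_class = 2,
                   words_per_topic = 5, grid = small_grid(),
                   tune_folds = 2, plsi_max_iter = 40))
  ids <- names(fx$labels)
  for (f in 1:3) {
    tr_ids <- ids[cv$fold_assignment != f]
    # independent re-derivation from the training split alone
    model <- train_plsi(build_corpus(fx$features[tr_ids]), K = 4,
                        max_iter = 40, tol = 1e-6, seed = 9 + f)
    prefs <- compute_topic_preferences(model, fx$labels[tr_ids])
    sigs <- suppressWarnings(select_signatures(model, prefs, 2, 5))
    expect_identical(cv$per_fold[[f]]$signatures, sigs$word)
  }
})

test_that("cross-validation reports write per-fold and pooled rows", {
  fx <- tiny_cv_fixture(n_per_class = 4, seed = 41)
  cv <- suppressWarnings(
    cross_validate(fx$features, fx$labels, mode = "plsi", folds = 2,
                   seed = 2, topics = 3, grid = small_grid(),
                   tune_folds = 2, plsi_max_iter = 20))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  jsn <- withr::local_tempfile(fileext = ".json")
  rows <- write_cv_report(cv, tsv, jsn)
  expect_equal(nrow(rows), 3)  # 2 folds + pooled
  expect_identical(rows$split[3], "pooled")
  expect_equal(sum(rows$tp[1:2]), rows$tp[3])
  expect_true(file.exists(tsv) && file.exists(jsn))
})
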