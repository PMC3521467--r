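#' Confusion counts from truth and predictions
#'
#' Nuclear is the positive class.
#'
#' @param truth,predicted named character vectors over the same protein
#'   ids, values `nuclear` / `non_nuclear`.
#' @return a `confusion_counts` list with `tp`, `tn`, `fp`, `fn`, `N`.
#' @export
confusion_from_predictions <- function(truth, predicted) {
  extra <- setdiff(names(predicted), names(truth))
  miss <- setdiff(names(truth), names(predicted))
  if (length(extra) || length(miss)) {
    stop("input error: id mismatch; missing predictions: [",
         paste(miss, collapse = ","), "]; unexpected ids: [",
         paste(extra, collapse = ","), "]")
  }
  predicted <- predicted[names(truth)]
  confusion_counts(
    tp = sum(truth == "nuclear" & predicted == "nuclear"),
    tn = sum(truth == "non_nuclear" & predicted == "non_nuclear"),
    fp = sum(truth == "non_nuclear" & predicted == "nuclear"),
    fn = sum(truth == "nuclear" & predicted == "non_nuclear"))
}

#' @rdname confusion_from_predictions
#' @param tp,tn,fp,fn nonnegative integer counts.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0) || any(counts != trunc(counts))) {
    stop("input error: counts must be nonnegative integers")
  }
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn,
                 N = tp + tn + fp + fn),
            class = "confusion_counts")
}

#' Sensitivity, specificity, accuracy and MCC from confusion counts
#'
#' Sens = TP/(TP+FN); Spec = TN/(TN+FP); Acc = (TP+TN)/N;
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FN)(TP+FP)(TN+FP)(TN+FN)).
#' A metric whose denominator is zero is reported as `NA` (undefined),
#' never as 0.
#'
#' @param cc a `confusion_counts`.
#' @return a `metric_report` list with `sensitivity`, `specificity`,
#'   `accuracy`, `mcc`.
#' @export
compute_metrics <- function(cc) {
  if (cc$N < 1) stop("input error: N must be >= 1")
  rat <- function(num, den) if (den > 0) num / den else NA_real_
  denom <- sqrt(prod(c(cc$tp + cc$fn, cc$tp + cc$fp,
                       cc$tn + cc$fp, cc$tn + cc$fn)))
  structure(list(
    sensitivity = rat(cc$tp, cc$tp + cc$fn),
    specificity = rat(cc$tn, cc$tn + cc$fp),
    accuracy = rat(cc$tp + cc$tn, cc$N),
    mcc = if (denom > 0) (cc$tp * cc$tn - cc$fp * cc$fn) / denom
          else NA_real_),
    class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("Sens %.3f  Spec %.3f  Acc %.3f  MCC %.3f\n",
              x$sensitivity, x$specificity, x$accuracy, x$mcc))
  invisible(x)
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("tp %d  tn %d  fp %d  fn %d  (N = %d)\n",
              x$tp, x$tn, x$fp, x$fn, x$N))
  invisible(x)
}

#' Five-fold (or k-fold) cross-validation of the full pipeline
#'
#' Per fold, the entire learning pipeline is fitted on the training split
#' only: the aspect model is trained on training proteins, held-out
#' proteins are folded in with frozen `P(w|t)` (in plsi mode training
#' documents are re-featurized by the same folding-in so train and test
#' features share one geometry), signatures (if used) are selected from
#' training labels only, and the SVM is tuned on the training split.  Held-out confusion counts are pooled over folds before
#' metrics are computed (micro-averaging).
#'
#' @param features list of `gd_feature_vector`, one per protein.
#' @param labels named character vector (`nuclear` / `non_nuclear`).
#' @param mode `"plsi"` (topic-weight features) or `"signatures"`
#'   (signature-restricted gapped-dipeptide weights).
#' @param folds number of outer folds (default 5).
#' @param seed seed; per-fold seeds are derived as `seed + fold`.
#' @param topics number of latent topics (standard operating point: 80).
#' @param topics_per_class,words_per_topic signature selection sizes.
#' @param grid,tune_folds SVM tuning controls.
#' @param plsi_max_iter,plsi_tol aspect-model EM controls.
#' @return list with pooled `confusion`, `metrics`, per-protein
#'   `predictions` (data.frame), `fold_assignment` and `per_fold` details.
#' @export
cross_validate <- function(features, labels, mode = c("plsi", "signatures"),
                           folds = 5L, seed = 1L, topics = 80L,
                           topics_per_class = 10L, words_per_topic = 20L,
                           grid = default_svm_grid(), tune_folds = 3L,
                           plsi_max_iter = 200L, plsi_tol = 1e-6) {
  mode <- match.arg(mode)
  ids <- vapply(features, `[[`, "", "protein_id")
  names(features) <- ids
  lab <- check_labels(labels, ids)
  if (folds < 2L) stop("parameter error: folds must be >= 2")
  if (folds > min(table(lab))) {
    stop("parameter error: folds exceed the minority class size")
  }
  fold_of <- stratified_folds(lab, folds, seed)

  preds <- character(0); probs <- numeric(0)
  per_fold <- vector("list", folds)
  for (f in seq_len(folds)) {
    tr_ids <- ids[fold_of != f]
    te_ids <- ids[fold_of == f]
    fseed <- as.integer(seed + f)
    corpus <- build_corpus(features[tr_ids])
    model <- train_plsi(corpus, K = topics, max_iter = plsi_max_iter,
                        tol = plsi_tol, seed = fseed)
    sigs <- NULL
    if (mode == "plsi") {
      # Training documents are folded in with frozen P(w|t) exactly like
      # held-out ones, so train and test features share one geometry.
      xtr <- t(vapply(tr_ids, function(id) {
        fold_in(model, features[[id]]$weights)
      }, numeric(model$K)))
      xte <- t(vapply(te_ids, function(id) {
        fold_in(model, features[[id]]$weights)
      }, numeric(model$K)))
      colnames(xtr) <- colnames(xte) <- paste0("t", seq_len(model$K))
      feature_mode <- "plsi_topics"
    } else {
      prefs <- compute_topic_preferences(model, lab[tr_ids])
      sigs <- select_signatures(model, prefs,
                                topics_per_class = topics_per_class,
                                words_per_topic = words_per_topic)
      xtr <- signature_matrix(features[tr_ids], sigs)
      xte <- signature_matrix(features[te_ids], sigs)
      feature_mode <- "signatures"
    }
    clf <- tune_and_train(xtr, lab[tr_ids], grid = grid,
                          folds = tune_folds, seed = fseed,
                          feature_mode = feature_mode)
    pr <- predict_localization(clf, xte)
    preds <- c(preds, stats::setNames(pr$class, te_ids))
    probs <- c(probs, stats::setNames(pr$probability, te_ids))
    per_fold[[f]] <- list(
      n_test = length(te_ids),
      confusion = confusion_from_predictions(lab[te_ids],
                                             stats::setNames(pr$class,
                                                             te_ids)),
      cost = clf$cost, gamma = clf$gamma,
      signatures = if (!is.null(sigs)) sigs$word)
  }
  cc <- confusion_from_predictions(lab, preds[ids])
  list(confusion = cc, metrics = compute_metrics(cc),
       predictions = data.frame(id = ids, truth = unname(lab),
                                predicted = unname(preds[ids]),
                                probability = unname(probs[ids]),
                                fold = unname(fold_of),
                                stringsAsFactors = FALSE),
       fold_assignment = fold_of, per_fold = per_fold,
       mode = mode, seed = as.integer(seed))
}

#' Write a cross-validation report
#'
#' TSV with per-fold and pooled counts plus metrics, and a JSON twin.
#'
#' @param cv result of [cross_validate()].
#' @param path_tsv,path_json output paths (either may be `NULL`).
#' @export
write_cv_report <- function(cv, path_tsv = NULL, path_json = NULL) {
  row_of <- function(name, cc) {
    m <- compute_metrics(cc)
    data.frame(split = name, tp = cc$tp, tn = cc$tn, fp = cc$fp,
               fn = cc$fn, sensitivity = m$sensitivity,
               specificity = m$specificity, accuracy = m$accuracy,
               mcc = m$mcc, stringsAsFactors = FALSE)
  }
  rows <- do.call(rbind, c(
    lapply(seq_along(cv$per_fold), function(f) {
      row_of(paste0("fold", f), cv$per_fold[[f]]$confusion)
    }),
    list(row_of("pooled", cv$confusion))))
  if (!is.null(path_tsv)) {
    utils::write.table(rows, path_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(path_json)) {
    jsonlite::write_json(rows, path_json, digits = NA, auto_unbox = TRUE)
  }
  invisible(rows)
}
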