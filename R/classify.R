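#' RBF kernel between row sets
#'
#' @param x,y numeric matrices with the same number of columns (`y = NULL`
#'   means `x` vs itself).
#' @param gamma RBF width parameter.
#' @return `nrow(x)` x `nrow(y)` kernel matrix `exp(-gamma * ||a - b||^2)`.
#' @export
rbf_kernel <- function(x, y = NULL, gamma) {
  if (is.null(y)) y <- x
  d2 <- outer(rowSums(x^2), rowSums(y^2), "+") - 2 * tcrossprod(x, y)
  d2[d2 < 0] <- 0
  exp(-gamma * d2)
}

# Platt sigmoid fit: P(y = +1 | f) = 1 / (1 + exp(A f + B)), fitted by
# regularized maximum likelihood with Newton + backtracking.
platt_fit <- function(f, y, max_iter = 100L, min_step = 1e-10,
                      sigma = 1e-12) {
  prior1 <- sum(y > 0); prior0 <- sum(y <= 0)
  hi <- (prior1 + 1) / (prior1 + 2)
  lo <- 1 / (prior0 + 2)
  t0 <- ifelse(y > 0, hi, lo)
  a <- 0; b <- log((prior0 + 1) / (prior1 + 1))
  fval <- function(a, b) {
    fApB <- a * f + b
    sum(ifelse(fApB >= 0,
               t0 * fApB + log1p(exp(-fApB)),
               (t0 - 1) * fApB + log1p(exp(fApB))))
  }
  fv <- fval(a, b)
  for (it in seq_len(max_iter)) {
    fApB <- a * f + b
    p <- ifelse(fApB >= 0, exp(-fApB) / (1 + exp(-fApB)),
                1 / (1 + exp(fApB)))
    q <- 1 - p
    d1 <- t0 - p
    d2 <- p * q
    g1 <- sum(f * d1); g2 <- sum(d1)
    if (abs(g1) < 1e-5 && abs(g2) < 1e-5) break
    h11 <- sum(f * f * d2) + sigma
    h22 <- sum(d2) + sigma
    h21 <- sum(f * d2)
    det <- h11 * h22 - h21 * h21
    dA <- -(h22 * g1 - h21 * g2) / det
    dB <- -(-h21 * g1 + h11 * g2) / det
    gd <- g1 * dA + g2 * dB
    step <- 1
    while (step >= min_step) {
      na <- a + step * dA; nb <- b + step * dB
      nf <- fval(na, nb)
      if (nf < fv + 1e-4 * step * gd) {
        a <- na; b <- nb; fv <- nf
        break
      }
      step <- step / 2
    }
    if (step < min_step) break
  }
  c(A = a, B = b)
}

svm_fit_binary <- function(x, ynum, cost, gamma, tol = 1e-3) {
  kk <- rbf_kernel(x, gamma = gamma)
  sol <- smo_train(kk, ynum, cost, tol,
                   max_updates = max(200000L, 1000L * nrow(x)))
  sv <- which(sol$alpha > 1e-12)
  list(sv_x = x[sv, , drop = FALSE], sv_y = ynum[sv],
       sv_alpha = sol$alpha[sv], b = sol$b, gamma = gamma, cost = cost)
}

svm_decision <- function(fit, newx) {
  kk <- rbf_kernel(newx, fit$sv_x, gamma = fit$gamma)
  as.vector(kk %*% (fit$sv_alpha * fit$sv_y)) + fit$b
}

#' Default hyperparameter grid for SVM tuning
#'
#' The customary exponential grid: cost 2^-5, 2^-3, ..., 2^15 and gamma
#' 2^-15, 2^-13, ..., 2^3.
#'
#' @export
default_svm_grid <- function() {
  expand.grid(cost = 2^seq(-5, 15, by = 2), gamma = 2^seq(-15, 3, by = 2))
}

stratified_folds <- function(labels, folds, seed) {
  fold_of <- integer(length(labels))
  names(fold_of) <- names(labels)
  with_seed(seed, {
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      idx <- idx[sample.int(length(idx))]
      fold_of[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  fold_of
}

label_to_num <- function(labels) {
  bad <- !(labels %in% LOCALIZATION_CLASSES)
  if (any(bad)) stop("input error: unknown label '", labels[bad][1], "'")
  ifelse(labels == "nuclear", 1, -1)
}

#' Tune and train the nuclear/non-nuclear SVM
#'
#' Grid-searches (cost, gamma) of an RBF-kernel C-SVC by seeded stratified
#' cross-validation on the training data, picks the pair maximizing mean CV
#' accuracy (ties: smaller cost, then smaller gamma), refits on all data
#' and fits a Platt sigmoid for probability estimates.
#'
#' @param features numeric matrix, one row per protein (any feature mode:
#'   PLSI topic weights or signature weights).
#' @param labels character vector / named vector of `nuclear` /
#'   `non_nuclear`, aligned with the rows.
#' @param grid data.frame with `cost` and `gamma` columns.
#' @param folds number of tuning folds.
#' @param seed RNG seed for the fold shuffle.
#' @param feature_mode recorded metadata: `"plsi_topics"` or
#'   `"signatures"`.
#' @return a `nuc_svm` classifier.
#' @export
tune_and_train <- function(features, labels, grid = default_svm_grid(),
                           folds = 5L, seed = 1L,
                           feature_mode = c("plsi_topics", "signatures")) {
  feature_mode <- match.arg(feature_mode)
  features <- as.matrix(features)
  labels <- as.character(labels)
  if (nrow(grid) == 0L) stop("parameter error: empty tuning grid")
  if (folds < 2L) stop("parameter error: folds must be >= 2")
  tab <- table(factor(labels, levels = LOCALIZATION_CLASSES))
  if (any(tab < 2L)) {
    stop("input error: need at least 2 proteins per class (got ",
         paste(tab, collapse = "/"), ")")
  }
  if (folds > min(tab)) {
    stop("parameter error: folds exceed the minority class size")
  }
  ynum <- label_to_num(labels)
  fold_of <- stratified_folds(labels, folds, seed)

  grid <- grid[order(grid$cost, grid$gamma), , drop = FALSE]
  acc <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    correct <- 0L
    for (f in seq_len(folds)) {
      tr <- fold_of != f
      fit <- svm_fit_binary(features[tr, , drop = FALSE], ynum[tr],
                            grid$cost[g], grid$gamma[g])
      pred <- sign(svm_decision(fit, features[!tr, , drop = FALSE]))
      pred[pred == 0] <- 1
      correct <- correct + sum(pred == ynum[!tr])
    }
    acc[g] <- correct / length(ynum)
  }
  best <- which.max(acc)  # grid pre-sorted: ties favour smaller c, gamma
  fit <- svm_fit_binary(features, ynum, grid$cost[best], grid$gamma[best])
  platt <- platt_fit(svm_decision(fit, features), ynum)
  structure(list(fit = fit, cost = grid$cost[best],
                 gamma = grid$gamma[best], platt = platt,
                 feature_mode = feature_mode,
                 feature_dimension = ncol(features),
                 feature_names = colnames(features),
                 tuning_record = cbind(grid, cv_accuracy = acc),
                 fold_assignment = fold_of, seed = as.integer(seed)),
            class = "nuc_svm")
}

#' Predict localization class and confidence
#'
#' @param clf a `nuc_svm`.
#' @param features numeric vector (one protein) or matrix (one row per
#'   protein) with `clf$feature_dimension` columns.
#' @return data.frame with `class`, `probability` (of the predicted
#'   class, at least 0.5), `prob_nuclear` and the raw SVM `decision`
#'   value.
#' @export
predict_localization <- function(clf, features) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1L)
  features <- as.matrix(features)
  if (ncol(features) != clf$feature_dimension) {
    stop("input error: feature dimension mismatch (got ", ncol(features),
         ", expected ", clf$feature_dimension, ")")
  }
  f <- svm_decision(clf$fit, features)
  fApB <- clf$platt["A"] * f + clf$platt["B"]
  p_nuc <- 1 / (1 + exp(fApB))
  cls <- ifelse(p_nuc >= 0.5, "nuclear", "non_nuclear")
  data.frame(class = cls, probability = pmax(p_nuc, 1 - p_nuc),
             prob_nuclear = p_nuc, decision = f,
             row.names = rownames(features), stringsAsFactors = FALSE)
}

#' Classifier bundle serialization
#'
#' Persists the SVM (support vectors, coefficients, Platt sigmoid, feature
#' ordering and metadata) as JSON so prediction is self-contained.
#'
#' @param clf a `nuc_svm`.
#' @param path file path.
#' @export
write_classifier <- function(clf, path) {
  obj <- list(cost = clf$cost, gamma = clf$gamma,
              platt = as.list(clf$platt),
              feature_mode = clf$feature_mode,
              feature_dimension = clf$feature_dimension,
              feature_names = clf$feature_names,
              seed = clf$seed,
              sv_x = as.vector(clf$fit$sv_x),
              sv_n = nrow(clf$fit$sv_x),
              sv_y = clf$fit$sv_y, sv_alpha = clf$fit$sv_alpha,
              b = clf$fit$b,
              tuning_record = clf$tuning_record)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  sv_x <- matrix(obj$sv_x, obj$sv_n, obj$feature_dimension)
  colnames(sv_x) <- obj$feature_names
  structure(list(fit = list(sv_x = sv_x, sv_y = obj$sv_y,
                            sv_alpha = obj$sv_alpha, b = obj$b,
                            gamma = obj$gamma, cost = obj$cost),
                 cost = obj$cost, gamma = obj$gamma,
                 platt = c(A = obj$platt$A, B = obj$platt$B),
                 feature_mode = obj$feature_mode,
                 feature_dimension = obj$feature_dimension,
                 feature_names = obj$feature_names,
                 tuning_record = obj$tuning_record,
                 seed = as.integer(obj$seed)),
            class = "nuc_svm")
}
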