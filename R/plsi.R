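#' Build a weighted word-document corpus from feature vectors
#'
#' Documents are proteins; words are gapped-dipeptides; counts are the
#' (continuous, nonnegative) weighting-scheme values.
#'
#' @param fvs list of `gd_feature_vector` objects.
#' @return a `gd_corpus`: list with `documents`, `vocabulary` and a dense
#'   documents x vocabulary `counts` matrix.
#' @export
build_corpus <- function(fvs) {
  if (length(fvs) == 0L) stop("input error: empty corpus")
  docs <- vapply(fvs, `[[`, "", "protein_id")
  present <- unique(unlist(lapply(fvs, function(fv) names(fv$weights))))
  vocab <- all_gapped_dipeptides(max(vapply(fvs, `[[`, 0L, "d_max")))
  vocab <- vocab[vocab %in% present]
  counts <- matrix(0, length(docs), length(vocab),
                   dimnames = list(docs, vocab))
  for (k in seq_along(fvs)) {
    w <- fvs[[k]]$weights
    common <- intersect(names(w), vocab)
    counts[k, common] <- w[common]
  }
  as_corpus(counts)
}

#' @rdname build_corpus
#' @param counts a nonnegative documents x words matrix with dimnames.
#' @export
as_corpus <- function(counts) {
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("corpus counts need document rownames and word colnames")
  }
  if (any(counts < 0)) stop("corpus counts must be nonnegative")
  if (any(rowSums(counts) <= 0)) {
    stop("input error: document(s) with no positive weight: ",
         paste(rownames(counts)[rowSums(counts) <= 0], collapse = ", "))
  }
  structure(list(documents = rownames(counts),
                 vocabulary = colnames(counts),
                 counts = counts),
            class = "gd_corpus")
}

normalize_columns <- function(m) {
  cs <- colSums(m)
  zero <- cs <= 0
  if (any(zero)) {
    m[, zero] <- 1 / nrow(m)
    cs[zero] <- 1
  }
  sweep(m, 2L, cs, "/")
}

#' Fit a probabilistic latent semantic indexing (aspect) model by EM
#'
#' The aspect model factorizes the word-document joint as
#' `P(w, d) = P(d) * sum_t P(w|t) P(t|d)`.  The E-step computes the topic
#' posterior `P(t|d,w)`; the M-step re-estimates `P(w|t)` and `P(t|d)`.
#' `P(d)` is fixed at the document share of total corpus weight (its ML
#' estimate).  Initialization is a seeded uniform draw, so runs are
#' bit-reproducible.
#'
#' @param corpus a `gd_corpus`.
#' @param K number of latent topics (the standard operating point is 80).
#' @param max_iter maximum EM iterations.
#' @param tol stop when the relative log-likelihood improvement falls below
#'   this.
#' @param seed integer seed for the random initialization.
#' @param beta tempering exponent on the E-step posterior; 1 (default) is
#'   plain EM.
#' @return a `plsi_model`: list with `K`, `vocabulary`, `documents`,
#'   `word_given_topic` (|W| x K, column-stochastic), `topic_given_doc`
#'   (K x |D|, column-stochastic), `doc_prior`, `log_likelihood_trace`,
#'   `seed`, `beta`.
#' @export
train_plsi <- function(corpus, K, max_iter = 200L, tol = 1e-6, seed = 1L,
                       beta = 1) {
  if (!inherits(corpus, "gd_corpus")) stop("input error: not a gd_corpus")
  if (K < 1) stop("parameter error: K must be >= 1")
  if (tol <= 0) stop("parameter error: tol must be > 0")
  n_wd <- t(corpus$counts)                       # |W| x |D|
  W <- nrow(n_wd); D <- ncol(n_wd)
  doc_prior <- colSums(n_wd) / sum(n_wd)
  doc_totals <- colSums(n_wd)

  init <- with_seed(seed, list(
    pwt = matrix(runif(W * K), W, K),
    ptd = matrix(runif(K * D), K, D)
  ))
  pwt <- normalize_columns(init$pwt)
  ptd <- normalize_columns(init$ptd)

  loglik <- function(pwt, ptd) {
    pwd <- pwt %*% ptd
    sum(n_wd * log(pmax(pwd, LIKELIHOOD_FLOOR))) +
      sum(doc_totals * log(pmax(doc_prior, LIKELIHOOD_FLOOR)))
  }

  trace <- numeric(0)
  ll_prev <- -Inf
  for (iter in seq_len(max_iter)) {
    if (beta == 1) {
      a <- pwt; b <- ptd
      s <- a %*% b
    } else {
      a <- pwt^beta; b <- ptd^beta
      s <- a %*% b
    }
    r <- n_wd / pmax(s, 1e-300)
    pwt_new <- normalize_columns(a * (r %*% t(b)))
    ptd_new <- normalize_columns(b * crossprod(a, r))
    pwt <- pwt_new; ptd <- ptd_new
    ll <- loglik(pwt, ptd)
    trace <- c(trace, ll)
    if (is.finite(ll_prev) &&
        (ll - ll_prev) < tol * abs(ll_prev)) break
    ll_prev <- ll
  }
  dimnames(pwt) <- list(corpus$vocabulary, NULL)
  dimnames(ptd) <- list(NULL, corpus$documents)
  structure(list(K = as.integer(K), vocabulary = corpus$vocabulary,
                 documents = corpus$documents,
                 word_given_topic = pwt, topic_given_doc = ptd,
                 doc_prior = doc_prior, log_likelihood_trace = trace,
                 seed = as.integer(seed), beta = beta),
            class = "plsi_model")
}

#' Fold a new document into a trained aspect model
#'
#' Runs EM with `P(w|t)` frozen, updating only the new document's topic
#' distribution.  Words absent from the training vocabulary are ignored;
#' if no word overlaps, a warning is raised and the uniform distribution is
#' returned with attribute `uniform_fallback = TRUE`.
#'
#' @param model a `plsi_model`.
#' @param new_doc_weights named nonnegative numeric vector of word weights.
#' @param max_iter,tol folding-in EM controls.
#' @return length-K probability vector `P(t|d')`.
#' @export
fold_in <- function(model, new_doc_weights, max_iter = 50L, tol = 1e-8) {
  nw <- numeric(length(model$vocabulary))
  names(nw) <- model$vocabulary
  common <- intersect(names(new_doc_weights), model$vocabulary)
  nw[common] <- new_doc_weights[common]
  K <- model$K
  if (sum(nw) <= 0) {
    warning("folding-in: no overlap with training vocabulary; ",
            "returning uniform topic distribution")
    out <- rep(1 / K, K)
    attr(out, "uniform_fallback") <- TRUE
    return(out)
  }
  pwt <- model$word_given_topic
  ptd <- rep(1 / K, K)
  for (iter in seq_len(max_iter)) {
    s <- as.vector(pwt %*% ptd)
    r <- nw / pmax(s, 1e-300)
    ptd_new <- ptd * as.vector(crossprod(pwt, r))
    ptd_new <- ptd_new / sum(ptd_new)
    delta <- max(abs(ptd_new - ptd))
    ptd <- ptd_new
    if (delta < tol) break
  }
  ptd
}

#' Corpus log-likelihood under a fitted aspect model
#'
#' `sum_{d,w} n(d,w) log P(w,d)` with `P(w,d) = P(d) sum_t P(w|t) P(t|d)`;
#' probabilities are floored at 1e-12 inside the log.
#'
#' @param model a `plsi_model`.
#' @param corpus a `gd_corpus` over the same vocabulary; its documents must
#'   be a subset of the model's.
#' @export
corpus_log_likelihood <- function(model, corpus) {
  if (!identical(corpus$vocabulary, model$vocabulary)) {
    stop("input error: corpus/model vocabulary mismatch")
  }
  if (!all(corpus$documents %in% model$documents)) {
    stop("input error: corpus documents unknown to the model")
  }
  n_wd <- t(corpus$counts)
  ptd <- model$topic_given_doc[, corpus$documents, drop = FALSE]
  pd <- model$doc_prior[corpus$documents]
  pwd <- model$word_given_topic %*% ptd
  sum(n_wd * log(pmax(pwd, LIKELIHOOD_FLOOR))) +
    sum(colSums(n_wd) * log(pmax(pd, LIKELIHOOD_FLOOR)))
}

#' Serialize / restore a fitted aspect model as JSON
#'
#' Round-trips losslessly (to full double precision).
#'
#' @param model a `plsi_model`.
#' @param path file path.
#' @export
write_plsi <- function(model, path) {
  obj <- list(K = model$K, vocabulary = model$vocabulary,
              documents = model$documents,
              word_given_topic = as.vector(model$word_given_topic),
              topic_given_doc = as.vector(model$topic_given_doc),
              doc_prior = unname(model$doc_prior),
              log_likelihood_trace = model$log_likelihood_trace,
              seed = model$seed, beta = model$beta)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_plsi
#' @export
read_plsi <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  W <- length(obj$vocabulary); D <- length(obj$documents)
  structure(list(K = as.integer(obj$K), vocabulary = obj$vocabulary,
                 documents = obj$documents,
                 word_given_topic = matrix(obj$word_given_topic, W, obj$K,
                                           dimnames = list(obj$vocabulary,
                                                           NULL)),
                 topic_given_doc = matrix(obj$topic_given_doc, obj$K, D,
                                          dimnames = list(NULL,
                                                          obj$documents)),
                 doc_prior = stats::setNames(obj$doc_prior, obj$documents),
                 log_likelihood_trace = obj$log_likelihood_trace,
                 seed = as.integer(obj$seed), beta = obj$beta),
            class = "plsi_model")
}
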