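make_counts <- function(m, docs = NULL, words = NULL) {
  if (is.null(docs)) docs <- paste0("d", seq_len(nrow(m)))
  if (is.null(words)) words <- paste0("w", seq_len(ncol(m)))
  dimnames(m) <- list(docs, words)
  m
}

test_that("degenerate single-document single-word corpus is exact", {
  corpus <- as_corpus(make_counts(matrix(3, 1, 1)))
  model <- train_plsi(corpus, K = 4, max_iter = 10, seed = 1)
  expect_equal(unname(model$word_given_topic), matrix(1, 1, 4))
  expect_equal(sum(model$topic_given_doc), 1)
  # |D| = 1 so P(d) = 1 and the log-likelihood is exactly 0
  expect_equal(corpus_log_likelihood(model, corpus), 0)
})

test_that("block-diagonal two-topic corpus recovers empirical mixtures", {
  counts <- make_counts(rbind(c(6, 2, 0, 0), c(0, 0, 3, 9)))
  corpus <- as_corpus(counts)
  model <- train_plsi(corpus, K = 2, max_iter = 500, tol = 1e-12, seed = 5)
  recon <- model$word_given_topic %*% model$topic_given_doc  # P(w|d)
  empirical <- t(counts / rowSums(counts))
  expect_equal(unname(recon), unname(empirical), tolerance = 1e-6)
})

test_that("EM is monotone, column-stochastic and seed-deterministic", {
  set.seed(42)
  for (rep in 1:20) {
    counts <- make_counts(matrix(rexp(5 * 8), 5, 8))
    corpus <- as_corpus(counts)
    model <- train_plsi(corpus, K = 3, max_iter = 40, seed = rep)
    tr <- model$log_likelihood_trace
    expect_true(all(diff(tr) >= -1e-8 * abs(tr[-length(tr)])))
    expect_equal(colSums(model$word_given_topic), rep(1, 3),
                 tolerance = 1e-9, ignore_attr = TRUE)
    expect_equal(colSums(model$topic_given_doc), rep(1, 5),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
  corpus <- as_corpus(make_counts(matrix(rexp(24), 4, 6)))
  m1 <- train_plsi(corpus, K = 2, max_iter = 30, seed = 9)
  m2 <- train_plsi(corpus, K = 2, max_iter = 30, seed = 9)
  expect_identical(m1$word_given_topic, m2$word_given_topic)
  expect_identical(m1$topic_given_doc, m2$topic_given_doc)
})

test_that("corpus log-likelihood matches a dense brute-force sum", {
  set.seed(3)
  for (rep in 1:5) {
    counts <- make_counts(matrix(rexp(24), 4, 6))
    corpus <- as_corpus(counts)
    model <- train_plsi(corpus, K = 3, max_iter = 25, seed = rep)
    pd <- model$doc_prior
    brute <- 0
    for (d in seq_len(4)) {
      for (w in seq_len(6)) {
        pwd <- sum(model$word_given_topic[w, ] *
                     model$topic_given_doc[, d])
        brute <- brute + counts[d, w] *
          (log(max(pwd, 1e-12)) + log(max(pd[d], 1e-12)))
      }
    }
    expect_equal(corpus_log_likelihood(model, corpus), brute,
                 tolerance = 1e-8)
  }
})

test_that("folding-in freezes P(w|t) and honours forced assignments", {
  counts <- make_counts(matrix(rexp(40, rate = 0.3), 5, 8))
  corpus <- as_corpus(counts)
  model <- train_plsi(corpus, K = 3, max_iter = 60, seed = 2)
  pwt_before <- model$word_given_topic

  ptd <- fold_in(model, counts[2, ])
  expect_length(ptd, 3)
  expect_equal(sum(ptd), 1)
  expect_identical(model$word_given_topic, pwt_before)

  # self-consistency: reconstructed likelihood of a training document is
  # close to its training value
  nw <- counts[2, ]
  ll_train <- sum(nw * log(pmax(
    as.vector(model$word_given_topic %*% model$topic_given_doc[, 2]),
    1e-12)))
  ll_fold <- sum(nw * log(pmax(
    as.vector(model$word_given_topic %*% ptd), 1e-12)))
  expect_gte(ll_fold, ll_train - 1e-4 * abs(ll_train))

  # a word emitted by exactly one topic forces all mass onto it
  forced <- model
  forced$word_given_topic <- matrix(c(1, 0, 0,
                                      0, 1, 0,
                                      0, 0, 1),
                                    3, 3, byrow = TRUE,
                                    dimnames = list(c("w1", "w2", "w3"),
                                                    NULL))
  forced$vocabulary <- c("w1", "w2", "w3")
  out <- fold_in(forced, c(w3 = 5))
  expect_equal(unname(out), c(0, 0, 1), tolerance = 1e-9)

  expect_warning(res <- fold_in(model, c(zzz = 1)), "no overlap")
  expect_equal(as.vector(res), rep(1 / 3, 3))
  expect_true(attr(res, "uniform_fallback"))
})

test_that("model JSON serialization round-trips losslessly", {
  corpus <- as_corpus(make_counts(matrix(rexp(30), 5, 6)))
  model <- train_plsi(corpus, K = 3, max_iter = 20, seed = 8)
  path <- withr::local_tempfile(fileext = ".json")
  write_plsi(model, path)
  back <- read_plsi(path)
  expect_equal(back$word_given_topic, model$word_given_topic,
               tolerance = 1e-12)
  expect_equal(back$topic_given_doc, model$topic_given_doc,
               tolerance = 1e-12)
  expect_equal(back$doc_prior, model$doc_prior, tolerance = 1e-12)
  expect_identical(back$K, model$K)
  expect_identical(back$vocabulary, model$vocabulary)
})

test_that("input validation catches bad corpora and parameters", {
  expect_error(build_corpus(list()), "empty corpus")
  counts <- make_counts(matrix(c(1, 0, 0, 0), 2, 2))
  expect_error(as_corpus(counts), "no positive weight")
  corpus <- as_corpus(make_counts(matrix(1, 2, 2)))
  expect_error(train_plsi(corpus, K = 0), "K must be")
  expect_error(train_plsi(corpus, K = 2, tol = 0), "tol")
  other <- as_corpus(make_counts(matrix(1, 2, 3)))
  model <- train_plsi(corpus, K = 2, max_iter = 5, seed = 1)
  expect_error(corpus_log_likelihood(model, other), "vocabulary mismatch")
})
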