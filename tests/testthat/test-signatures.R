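fake_model <- function(ptd, pwt = NULL, vocab = NULL) {
  K <- nrow(ptd)
  docs <- colnames(ptd)
  if (is.null(pwt)) {
    vocab <- vocab %||% paste0("w", 1:4)
    pwt <- matrix(1 / length(vocab), length(vocab), K,
                  dimnames = list(vocab, NULL))
  }
  structure(list(K = K, vocabulary = rownames(pwt), documents = docs,
                 word_given_topic = pwt, topic_given_doc = ptd,
                 doc_prior = setNames(rep(1 / length(docs), length(docs)),
                                      docs),
                 log_likelihood_trace = numeric(0), seed = 1L, beta = 1),
            class = "plsi_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("topic preferences are class means of topic weights", {
  ptd <- matrix(c(0.9, 0.1,   # doc n1
                  0.7, 0.3,   # doc n2
                  0.2, 0.8,   # doc c1
                  0.4, 0.6),  # doc c2
                nrow = 2, dimnames = list(NULL, c("n1", "n2", "c1", "c2")))
  labels <- c(n1 = "nuclear", n2 = "nuclear",
              c1 = "non_nuclear", c2 = "non_nuclear")
  prefs <- compute_topic_preferences(fake_model(ptd), labels)
  expect_equal(prefs$mean_weight_nuclear, c(0.8, 0.2))
  expect_equal(prefs$mean_weight_non_nuclear, c(0.3, 0.7))
  expect_equal(prefs$confidence, c(0.5, 0.5))
  expect_identical(prefs$preferred_class, c("nuclear", "non_nuclear"))
})

test_that("extreme and uniform topic weights give confidence 1 and 0", {
  ptd <- matrix(c(1, 0, 1, 0, 0, 1, 0, 1), nrow = 2,
                dimnames = list(NULL, c("n1", "n2", "c1", "c2")))
  labels <- c(n1 = "nuclear", n2 = "nuclear",
              c1 = "non_nuclear", c2 = "non_nuclear")
  prefs <- compute_topic_preferences(fake_model(ptd), labels)
  expect_equal(prefs$confidence[1], 1)
  expect_identical(prefs$preferred_class[1], "nuclear")

  unif <- matrix(0.5, 2, 4, dimnames = list(NULL, colnames(ptd)))
  prefs_u <- compute_topic_preferences(fake_model(unif), labels)
  expect_equal(prefs_u$confidence, c(0, 0))

  expect_error(compute_topic_preferences(
    fake_model(ptd), c(n1 = "nuclear", n2 = "nuclear",
                       c1 = "nuclear", c2 = "nuclear")),
    "both classes")
  expect_error(compute_topic_preferences(fake_model(ptd),
                                         labels[1:3]), "unlabeled")
})

test_that("signature selection equals a brute-force sort of P(w|t)", {
  set.seed(11)
  vocab <- paste0(sample(c("A", "K", "R", "L"), 30, replace = TRUE),
                  rep(0:4, 6),
                  sample(c("A", "K", "R", "L"), 30, replace = TRUE))
  vocab <- unique(vocab)
  pwt <- matrix(rexp(length(vocab) * 4), length(vocab), 4,
                dimnames = list(vocab, NULL))
  pwt <- sweep(pwt, 2, colSums(pwt), "/")
  ptd <- matrix(c(0.7, 0.1, 0.1, 0.1,
                  0.1, 0.7, 0.1, 0.1,
                  0.1, 0.1, 0.7, 0.1,
                  0.1, 0.1, 0.1, 0.7),
                4, 4, dimnames = list(NULL, c("n1", "n2", "c1", "c2")))
  model <- fake_model(ptd, pwt = pwt)
  labels <- c(n1 = "nuclear", n2 = "nuclear",
              c1 = "non_nuclear", c2 = "non_nuclear")
  prefs <- compute_topic_preferences(model, labels)
  sigs <- suppressWarnings(
    select_signatures(model, prefs, topics_per_class = 1,
                      words_per_topic = 5))
  # brute force: for each class, the single highest-confidence topic's
  # top-5 words by P(w|t) (ties lexicographic); a word already claimed by
  # the nuclear class is flagged and dropped from the later class
  top5 <- function(cls) {
    cand <- prefs[prefs$preferred_class == cls, ]
    topic <- cand$topic[order(-cand$confidence, cand$topic)][1]
    p <- pwt[, topic]
    names(p)[order(-p, names(p))][1:5]
  }
  exp_nuc <- top5("nuclear")
  exp_non <- setdiff(top5("non_nuclear"), exp_nuc)
  expect_identical(sigs$word[sigs$class == "nuclear"], exp_nuc)
  expect_identical(sigs$word[sigs$class == "non_nuclear"], exp_non)
  expect_lte(nrow(sigs), 2 * 1 * 5)

  one <- select_signatures(model, prefs, topics_per_class = 1,
                           words_per_topic = 1)
  expect_equal(nrow(one), 2)
})

test_that("selection is invariant to document order and topic labels", {
  fx <- tiny_cv_fixture(n_per_class = 4, seed = 3)
  corpus <- build_corpus(fx$features)
  model <- train_plsi(corpus, K = 4, max_iter = 50, seed = 2)
  prefs <- compute_topic_preferences(model, fx$labels)
  s1 <- suppressWarnings(select_signatures(model, prefs, 2, 5))

  # permuting document columns must not change preferences or selection
  perm_docs <- rev(seq_along(model$documents))
  m2 <- model
  m2$documents <- model$documents[perm_docs]
  m2$topic_given_doc <- model$topic_given_doc[, perm_docs, drop = FALSE]
  prefs2 <- compute_topic_preferences(m2, fx$labels)
  expect_equal(prefs2, prefs)

  # relabeling topics permutes rows of the preference table but selects
  # the same word sets per class
  perm_topics <- c(3, 1, 4, 2)
  m3 <- model
  m3$word_given_topic <- model$word_given_topic[, perm_topics]
  m3$topic_given_doc <- model$topic_given_doc[perm_topics, , drop = FALSE]
  prefs3 <- compute_topic_preferences(m3, fx$labels)
  s3 <- suppressWarnings(select_signatures(m3, prefs3, 2, 5))
  for (cls in c("nuclear", "non_nuclear")) {
    expect_setequal(s3$word[s3$class == cls], s1$word[s1$class == cls])
  }
})

test_that("feature vectors project onto signature sets", {
  sigs <- as_signature_set(data.frame(
    word = c("K2K", "R0R", "L2L"),
    class = c("nuclear", "nuclear", "non_nuclear"),
    stringsAsFactors = FALSE))
  fv <- structure(list(protein_id = "p", weights = c(K2K = 0.7, A0A = 0.4),
                       d_max = 2L), class = "gd_feature_vector")
  red <- reduce_to_signatures(fv, sigs)
  expect_equal(red, c(K2K = 0.7, R0R = 0, L2L = 0))
  fv2 <- structure(list(protein_id = "q", weights = c(A0A = 1),
                        d_max = 2L), class = "gd_feature_vector")
  expect_equal(unname(reduce_to_signatures(fv2, sigs)), c(0, 0, 0))
  m <- signature_matrix(list(fv, fv2), sigs)
  expect_identical(dim(m), c(2L, 3L))
})

test_that("the bundled curated signature set has 366 disjoint words", {
  sigs <- reference_signatures()
  expect_equal(nrow(sigs), 366)
  expect_equal(sum(sigs$class == "nuclear"), 183)
  expect_equal(sum(sigs$class == "non_nuclear"), 183)
  expect_equal(anyDuplicated(sigs$word), 0)
  fv <- build_feature_vector(
    smooth_profile(pseudo_profile("p", strrep("MKRLS", 10)), 7), 13)
  expect_length(reduce_to_signatures(fv, sigs), 366)
})

test_that("composition profiles count letters and partition residues", {
  sigs <- as_signature_set(data.frame(
    word = c("K1K", "R2R"), class = "nuclear", stringsAsFactors = FALSE))
  comp <- composition_profile(sigs)
  expect_equal(comp["nuclear", "K"], 0.5)
  expect_equal(comp["nuclear", "R"], 0.5)
  grouped <- composition_profile(sigs, grouping = "physicochemical")
  expect_equal(grouped["nuclear", "charged"], 1)
  expect_equal(rowSums(comp), c(nuclear = 1))

  # the 4-way grouping partitions the 20 residues into 3/5/6/6
  tab <- table(nucsig:::AA_GROUPS_4WAY)
  expect_equal(sort(as.numeric(tab)), c(3, 5, 6, 6))
  expect_setequal(names(nucsig:::AA_GROUPS_4WAY), nucsig:::AA_ALPHABETICAL)

  # curated lists: nuclear signatures are far richer in R/H/K
  ref <- composition_profile(reference_signatures())
  basic <- c("R", "H", "K")
  expect_gt(sum(ref["nuclear", basic]), sum(ref["non_nuclear", basic]))
})

test_that("signature TSV round-trips and duplicates are rejected", {
  sigs <- as_signature_set(data.frame(
    word = c("K1K", "L2L"), class = c("nuclear", "non_nuclear"),
    stringsAsFactors = FALSE))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_signatures(sigs, path)
  back <- read_signatures(path)
  expect_identical(back$word, sigs$word)
  expect_error(as_signature_set(data.frame(
    word = c("K1K", "K1K"), class = "nuclear")), "duplicate")
})
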