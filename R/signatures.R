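LOCALIZATION_CLASSES <- c("nuclear", "non_nuclear")

# Four-way physicochemical partition of the 20 standard residues.
AA_GROUPS_4WAY <- c(
  F = "aromatic", Y = "aromatic", W = "aromatic",
  D = "charged", E = "charged", H = "charged", K = "charged", R = "charged",
  A = "nonpolar", I = "nonpolar", G = "nonpolar", L = "nonpolar",
  M = "nonpolar", V = "nonpolar",
  C = "polar", N = "polar", P = "polar", Q = "polar", S = "polar",
  T = "polar")

# Derived translocation-oriented view: basic / polar / hydrophobic residues
# (with the two acidic residues kept apart so the map stays a partition).
AA_GROUPS_TRANSLOCATION <- c(
  H = "basic", K = "basic", R = "basic",
  C = "polar", G = "polar", N = "polar", Q = "polar", S = "polar",
  T = "polar", Y = "polar",
  A = "hydrophobic", F = "hydrophobic", I = "hydrophobic",
  L = "hydrophobic", M = "hydrophobic", P = "hydrophobic",
  V = "hydrophobic", W = "hydrophobic",
  D = "acidic", E = "acidic")

check_labels <- function(labels, documents) {
  missing <- setdiff(documents, names(labels))
  if (length(missing) > 0L) {
    stop("input error: unlabeled document(s): ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  lab <- labels[documents]
  bad <- !(lab %in% LOCALIZATION_CLASSES)
  if (any(bad)) {
    stop("input error: labels must be 'nuclear' or 'non_nuclear' (got '",
         lab[bad][1], "')")
  }
  lab
}

#' Localization preference of each latent topic
#'
#' The localization-topic preference of a topic for a class is the average
#' of its topic weights `P(t|d)` over the documents of that class; the
#' topic's confidence is the absolute difference of the two class means,
#' and its preferred class is the one with the larger mean.
#'
#' @param model a `plsi_model` trained on labeled documents.
#' @param labels named character vector (`nuclear` / `non_nuclear`) covering
#'   every model document.
#' @return data.frame with columns `topic`, `mean_weight_nuclear`,
#'   `mean_weight_non_nuclear`, `confidence`, `preferred_class`.
#' @export
compute_topic_preferences <- function(model, labels) {
  lab <- check_labels(labels, model$documents)
  if (!all(LOCALIZATION_CLASSES %in% lab)) {
    stop("input error: both classes must have at least one document")
  }
  ptd <- model$topic_given_doc
  mn <- rowMeans(ptd[, lab == "nuclear", drop = FALSE])
  mc <- rowMeans(ptd[, lab == "non_nuclear", drop = FALSE])
  data.frame(topic = seq_len(model$K),
             mean_weight_nuclear = mn,
             mean_weight_non_nuclear = mc,
             confidence = abs(mn - mc),
             preferred_class = ifelse(mn >= mc, "nuclear", "non_nuclear"),
             stringsAsFactors = FALSE)
}

#' Select gapped-dipeptide signatures from localization-preferred topics
#'
#' Per class, the `topics_per_class` topics with that preferred class and
#' the highest confidence are kept (ties broken by lower topic index); from
#' each, the `words_per_topic` words with the largest `P(w|t)` ("most
#' abundant"; ties broken lexicographically).  Duplicate words across
#' topics of a class are kept once, at their first occurrence; a word
#' selected by both classes is flagged with a warning and kept for the
#' class that selected it first (nuclear before non-nuclear).
#'
#' @param model a `plsi_model`.
#' @param prefs output of [compute_topic_preferences()].
#' @param topics_per_class,words_per_topic selection sizes (defaults 10
#'   and 20, i.e. at most 400 signatures).
#' @return a `signature_set`: data.frame with columns `word`, `class`,
#'   `topic`, `rank_in_topic`, `p_word_given_topic`.
#' @export
select_signatures <- function(model, prefs, topics_per_class = 10L,
                              words_per_topic = 20L) {
  if (topics_per_class < 1 || words_per_topic < 1) {
    stop("parameter error: selection sizes must be >= 1")
  }
  pwt <- model$word_given_topic
  pick_class <- function(cls) {
    cand <- prefs[prefs$preferred_class == cls, , drop = FALSE]
    cand <- cand[order(-cand$confidence, cand$topic), , drop = FALSE]
    if (nrow(cand) < topics_per_class) {
      warning("only ", nrow(cand), " ", cls, "-preferred topics available ",
              "(requested ", topics_per_class, ")")
    }
    cand <- utils::head(cand, topics_per_class)
    seen <- character(0)
    rows <- list()
    for (tk in cand$topic) {
      p <- pwt[, tk]
      ord <- order(-p, names(p))
      top <- utils::head(ord, words_per_topic)
      keep <- !(names(p)[top] %in% seen)
      top <- top[keep]
      if (length(top) == 0L) next
      seen <- c(seen, names(p)[top])
      rows[[length(rows) + 1L]] <-
        data.frame(word = names(p)[top], class = cls, topic = tk,
                   rank_in_topic = match(top, ord),
                   p_word_given_topic = unname(p[top]),
                   stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  }
  out <- rbind(pick_class("nuclear"), pick_class("non_nuclear"))
  dup <- duplicated(out$word)
  if (any(dup)) {
    warning("cross-class duplicate signature(s) dropped from the later ",
            "class: ", paste(unique(out$word[dup]), collapse = ", "))
    out <- out[!dup, , drop = FALSE]
  }
  rownames(out) <- NULL
  structure(out, class = c("signature_set", "data.frame"))
}

#' Construct a signature set from a plain table
#'
#' Validates and upgrades a data.frame with at least `word` and `class`
#' columns (e.g. a hand-curated list) into a `signature_set`; selection
#' metadata columns are filled with `NA` when absent.
#'
#' @param df data.frame with columns `word`, `class` and optionally
#'   `topic`, `rank_in_topic`, `p_word_given_topic`.
#' @export
as_signature_set <- function(df) {
  need <- c("word", "class")
  if (!all(need %in% names(df))) stop("signature table needs word + class")
  if (anyDuplicated(df$word)) {
    stop("duplicate signature words: ",
         paste(unique(df$word[duplicated(df$word)]), collapse = ", "))
  }
  if (is.null(df$topic)) df$topic <- NA_integer_
  if (is.null(df$rank_in_topic)) df$rank_in_topic <- NA_integer_
  if (is.null(df$p_word_given_topic)) df$p_word_given_topic <- NA_real_
  invisible(lapply(df$word, parse_gapped_dipeptide))  # validates
  structure(df, class = c("signature_set", "data.frame"))
}

#' Restrict a feature vector to a signature set
#'
#' Projects a protein's gapped-dipeptide weights onto the (stable) ordering
#' of a signature set; missing words get weight 0.
#'
#' @param fv a `gd_feature_vector`.
#' @param sigs a `signature_set`.
#' @return named numeric vector of length `nrow(sigs)`.
#' @export
reduce_to_signatures <- function(fv, sigs) {
  if (nrow(sigs) == 0L) stop("input error: empty signature set")
  out <- stats::setNames(numeric(nrow(sigs)), sigs$word)
  common <- intersect(names(fv$weights), sigs$word)
  out[common] <- fv$weights[common]
  out
}

#' @rdname reduce_to_signatures
#' @param fvs list of `gd_feature_vector`.
#' @return `signature_matrix()`: proteins x signatures numeric matrix.
#' @export
signature_matrix <- function(fvs, sigs) {
  t(vapply(fvs, reduce_to_signatures, numeric(nrow(sigs)), sigs = sigs))
}

#' Amino-acid composition of a signature set
#'
#' Counts both letters of every signature word (gaps ignored) per class and
#' normalizes to frequencies summing to 1.  `grouping = "physicochemical"`
#' maps residues to aromatic (FYW), charged (DEHKR), nonpolar (AIGLMV) and
#' polar (CNPQST); `"translocation"` is a derived basic / polar /
#' hydrophobic / acidic view.
#'
#' @param sigs a `signature_set`.
#' @param grouping `"none"`, `"physicochemical"` or `"translocation"`.
#' @return matrix of frequencies, one row per class.
#' @export
composition_profile <- function(sigs,
                                grouping = c("none", "physicochemical",
                                             "translocation")) {
  grouping <- match.arg(grouping)
  if (nrow(sigs) == 0L) stop("input error: empty signature set")
  map <- switch(grouping,
                none = stats::setNames(AA_ALPHABETICAL, AA_ALPHABETICAL),
                physicochemical = AA_GROUPS_4WAY,
                translocation = AA_GROUPS_TRANSLOCATION)
  lvl <- unique(unname(map[AA_ALPHABETICAL]))
  classes <- unique(sigs$class)
  out <- matrix(0, length(classes), length(lvl),
                dimnames = list(classes, lvl))
  for (cls in classes) {
    words <- sigs$word[sigs$class == cls]
    letters <- unlist(lapply(words, function(wd) {
      p <- parse_gapped_dipeptide(wd)
      c(p$first, p$second)
    }))
    tab <- table(factor(unname(map[letters]), levels = lvl))
    out[cls, ] <- as.numeric(tab) / sum(tab)
  }
  out
}

#' Signature list TSV I/O
#'
#' Columns: `word`, `class`, `topic`, `rank_in_topic`,
#' `p_word_given_topic`.  The loader also accepts hand-curated lists with
#' only `word` and `class` columns.
#'
#' @param sigs a `signature_set`.
#' @param path file path.
#' @export
write_signatures <- function(sigs, path) {
  utils::write.table(as.data.frame(sigs), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_signatures
#' @export
read_signatures <- function(path) {
  as_signature_set(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Bundled curated gapped-dipeptide signature set
#'
#' Loads the published curated lists of gapped-dipeptide signatures for
#' nuclear and non-nuclear proteins shipped with the package (183 words per
#' class, 366 distinct signatures in total).
#'
#' @return a `signature_set`.
#' @export
reference_signatures <- function() {
  nuc <- utils::read.delim(system.file("extdata",
                                       "signatures_nuclear.tsv",
                                       package = "nucsig"),
                           stringsAsFactors = FALSE)
  non <- utils::read.delim(system.file("extdata",
                                       "signatures_non_nuclear.tsv",
                                       package = "nucsig"),
                           stringsAsFactors = FALSE)
  as_signature_set(rbind(nuc, non))
}
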