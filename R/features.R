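#' Gapped-dipeptide word utilities
#'
#' A gapped-dipeptide `AdB` is the pattern "amino acid A, d intervening
#' residues, amino acid B"; its canonical string form is e.g. `"K2K"`.
#'
#' @param first,second standard amino-acid letters.
#' @param d gap length, integer >= 0.
#' @return `gapped_dipeptide()` returns the canonical word string;
#'   `parse_gapped_dipeptide()` returns a list with `first`, `d`, `second`.
#' @export
gapped_dipeptide <- function(first, d, second) {
  if (!(first %in% PSSM_COLUMNS) || !(second %in% PSSM_COLUMNS)) {
    stop("gapped-dipeptide letters must be standard amino acids")
  }
  if (any(d < 0) || any(d != trunc(d))) stop("gap d must be an integer >= 0")
  paste0(first, d, second)
}

#' @rdname gapped_dipeptide
#' @param word canonical word string, e.g. `"K2K"`.
#' @export
parse_gapped_dipeptide <- function(word) {
  m <- regmatches(word, regexec("^([A-Z])([0-9]+)([A-Z])$", word))[[1]]
  if (length(m) != 4L) stop("malformed gapped-dipeptide word: ", word)
  first <- m[2]; second <- m[4]
  if (!(first %in% PSSM_COLUMNS) || !(second %in% PSSM_COLUMNS)) {
    stop("non-standard letter in gapped-dipeptide word: ", word)
  }
  list(first = first, d = as.integer(m[3]), second = second)
}

#' Enumerate all gapped-dipeptide words up to a maximum gap
#'
#' Stable ordering: first letter alphabetical, then gap ascending, then
#' second letter alphabetical.  The dense feature dimension is
#' 20 x 20 x (d_max + 1).
#'
#' @param d_max maximum gap (default 13, giving 5,600 words).
#' @export
all_gapped_dipeptides <- function(d_max = 13L) {
  if (d_max < 0) stop("parameter error: d_max must be >= 0")
  grid <- expand.grid(second = AA_ALPHABETICAL, d = 0:d_max,
                      first = AA_ALPHABETICAL, stringsAsFactors = FALSE)
  paste0(grid$first, grid$d, grid$second)
}

#' Positions contributing to a gapped-dipeptide weight
#'
#' For a protein of length n and gap d the weighting sum runs over pairs
#' (i, i + d + 1) for i = 1 .. n - (d + 1).
#'
#' @param n protein length.
#' @param d gap.
#' @return a two-column integer matrix of (i, j) pairs (possibly 0 rows).
#' @export
enumerate_term_positions <- function(n, d) {
  if (n < 1 || d < 0) stop("require n >= 1 and d >= 0")
  k <- max(0L, as.integer(n) - (as.integer(d) + 1L))
  i <- seq_len(k)
  cbind(i = i, j = i + d + 1L)
}

#' Weight of one gapped-dipeptide in a smoothed profile
#'
#' Computes `W(AdB, P) = sum_i sf(i, A) * sf(i+d+1, B)` over all in-range
#' positions i, where `sf` is the logistic-normalized smoothed profile.
#' The sum runs over every position regardless of the residues actually
#' there: the profile columns, not the sequence letters, carry the signal.
#'
#' @param profile a `smoothed_profile`.
#' @param word canonical word string.
#' @export
weight_gapped_dipeptide <- function(profile, word) {
  wd <- parse_gapped_dipeptide(word)
  m <- profile$normalized
  n <- nrow(m)
  if (n < wd$d + 2L) return(0)
  idx <- seq_len(n - wd$d - 1L)
  sum(m[idx, wd$first] * m[idx + wd$d + 1L, wd$second])
}

#' Build the gapped-dipeptide feature vector of a protein
#'
#' Computes the weighting-scheme value for every word with gap <= `d_max`,
#' then rescales the vector into \[0, 1\] by dividing by its maximum
#' (an all-zero vector is left as is).  Zero-weight words are dropped from
#' the sparse storage.
#'
#' @param profile a `smoothed_profile`.
#' @param d_max maximum gap considered (default 13).
#' @param normalize `"max"` (default) or `"none"`.
#' @return a `gd_feature_vector`: list with `protein_id`, named numeric
#'   `weights` (sparse, nonzero entries only) and `d_max`.
#' @export
build_feature_vector <- function(profile, d_max = 13L,
                                 normalize = c("max", "none")) {
  if (d_max < 0) stop("parameter error: d_max must be >= 0")
  normalize <- match.arg(normalize)
  m <- profile$normalized
  n <- nrow(m)
  vals <- vector("list", d_max + 1L)
  for (d in 0:d_max) {
    if (n >= d + 2L) {
      idx <- seq_len(n - d - 1L)
      s <- crossprod(m[idx, , drop = FALSE], m[idx + d + 1L, , drop = FALSE])
    } else {
      s <- matrix(0, 20L, 20L, dimnames = list(PSSM_COLUMNS, PSSM_COLUMNS))
    }
    s <- s[AA_ALPHABETICAL, AA_ALPHABETICAL]
    v <- as.vector(t(s))  # first letter major, then second letter
    names(v) <- paste0(rep(AA_ALPHABETICAL, each = 20L), d, AA_ALPHABETICAL)
    vals[[d + 1L]] <- v
  }
  weights <- unlist(vals)
  weights <- weights[all_gapped_dipeptides(d_max)]
  if (normalize == "max" && max(weights) > 0) {
    weights <- weights / max(weights)
  }
  weights <- weights[weights > 0]
  structure(list(protein_id = profile$protein_id, weights = weights,
                 d_max = as.integer(d_max)),
            class = "gd_feature_vector")
}

#' Dense feature matrix from a list of feature vectors
#'
#' @param fvs list of `gd_feature_vector` objects.
#' @param words column order; defaults to the stable full word ordering at
#'   the vectors' `d_max`.
#' @return numeric matrix, one row per protein.
#' @export
feature_matrix <- function(fvs, words = NULL) {
  if (length(fvs) == 0L) stop("empty feature list")
  if (is.null(words)) words <- all_gapped_dipeptides(fvs[[1]]$d_max)
  out <- matrix(0, length(fvs), length(words),
                dimnames = list(vapply(fvs, `[[`, "", "protein_id"), words))
  for (k in seq_along(fvs)) {
    w <- fvs[[k]]$weights
    common <- intersect(names(w), words)
    out[k, common] <- w[common]
  }
  out
}

#' Sparse feature TSV I/O
#'
#' Three columns: `protein_id`, `word`, `weight`.
#'
#' @param fvs list of `gd_feature_vector`.
#' @param path file path.
#' @export
write_feature_tsv <- function(fvs, path) {
  df <- do.call(rbind, lapply(fvs, function(fv) {
    data.frame(protein_id = fv$protein_id, word = names(fv$weights),
               weight = unname(fv$weights), stringsAsFactors = FALSE)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_tsv
#' @param d_max maximum gap recorded in the vectors; inferred from the data
#'   when `NULL`.
#' @export
read_feature_tsv <- function(path, d_max = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (is.null(d_max)) {
    d_max <- max(vapply(df$word,
                        function(w) parse_gapped_dipeptide(w)$d, 0L))
  }
  lapply(split(df, factor(df$protein_id, levels = unique(df$protein_id))),
         function(g) {
           structure(list(protein_id = g$protein_id[1],
                          weights = stats::setNames(g$weight, g$word),
                          d_max = as.integer(d_max)),
                     class = "gd_feature_vector")
         })
}
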