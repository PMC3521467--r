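#' Read protein sequences from a FASTA file
#'
#' Identifiers are taken from the description line up to the first
#' whitespace.  Sequences are uppercased; `*` stop codons are stripped from
#' the end if present.
#'
#' @param path path to a (multi-record) protein FASTA file.
#' @return a `data.frame` with columns `id` and `sequence`.
#' @export
read_proteins <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(aa))
  seqs <- toupper(as.character(aa))
  seqs <- sub("\\*$", "", seqs)
  if (any(!nzchar(ids))) stop("empty sequence identifier in ", path)
  if (anyDuplicated(ids)) {
    stop("duplicate identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (any(!nzchar(seqs))) {
    stop("zero-length sequence for: ",
         paste(ids[!nzchar(seqs)], collapse = ", "))
  }
  data.frame(id = ids, sequence = unname(seqs), stringsAsFactors = FALSE)
}

#' Write protein records to FASTA
#'
#' @param records data.frame with `id` and `sequence` columns.
#' @param path output path.
#' @export
write_proteins <- function(records, path) {
  aa <- Biostrings::AAStringSet(records$sequence)
  names(aa) <- records$id
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

new_pssm_profile <- function(protein_id, matrix, sequence) {
  stopifnot(ncol(matrix) == 20L, nrow(matrix) == nchar(sequence))
  colnames(matrix) <- PSSM_COLUMNS
  rownames(matrix) <- NULL
  structure(list(protein_id = protein_id, matrix = matrix,
                 sequence = sequence),
            class = "pssm_profile")
}

#' Parse a PSI-BLAST ASCII PSSM
#'
#' Reads the first 20-column block (the per-position substitution
#' log-likelihoods) of the ASCII matrix dump produced by
#' `psiblast -out_ascii_pssm`.  The residue column of the profile must match
#' `expected_sequence`.
#'
#' @param text the file content as a single string or a character vector of
#'   lines.
#' @param expected_sequence the protein sequence the profile belongs to.
#' @param protein_id identifier stored in the returned profile.
#' @return a `pssm_profile`: list with `protein_id`, an n x 20 `matrix`
#'   (columns in PSI-BLAST order A R N D C Q E G H I L K M F P S T W Y V)
#'   and `sequence`.
#' @export
parse_pssm <- function(text, expected_sequence, protein_id = "protein") {
  if (length(text) == 1L) text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  text <- text[nzchar(trimws(text))]
  if (length(text) == 0L) stop("PSSM parse error: empty input")
  if (!nzchar(expected_sequence)) stop("expected_sequence must be non-empty")

  toks <- lapply(text, function(l) strsplit(trimws(l), "\\s+")[[1]])
  header_idx <- which(vapply(toks, function(tk) {
    length(tk) >= 20L && all(grepl("^[A-Z]$", tk[1:20]))
  }, logical(1)))
  if (length(header_idx) == 0L) {
    stop("PSSM parse error: no column-header line found")
  }
  header <- toks[[header_idx[1]]]
  if (!identical(header[1:20], PSSM_COLUMNS)) {
    stop("PSSM parse error: unexpected column order in header line ",
         header_idx[1])
  }

  is_row <- vapply(toks, function(tk) {
    length(tk) >= 22L && grepl("^[0-9]+$", tk[1]) &&
      grepl("^[A-Za-z]$", tk[2]) &&
      !anyNA(suppressWarnings(as.numeric(tk[3:22])))
  }, logical(1))
  is_row[seq_len(header_idx[1])] <- FALSE
  rows <- toks[is_row]
  if (length(rows) == 0L) stop("PSSM parse error: no matrix rows found")

  pos <- as.integer(vapply(rows, `[`, character(1), 1L))
  if (!identical(pos, seq_along(pos))) {
    bad <- which(pos != seq_along(pos))[1]
    stop("PSSM parse error: non-consecutive position at row ", bad)
  }
  res <- toupper(vapply(rows, `[`, character(1), 2L))
  mat <- t(vapply(rows, function(tk) as.numeric(tk[3:22]), numeric(20)))

  exp_res <- strsplit(toupper(expected_sequence), "")[[1]]
  if (length(exp_res) != length(res)) {
    stop("PSSM consistency error: profile has ", length(res),
         " rows but sequence has ", length(exp_res), " residues")
  }
  mism <- which(res != exp_res)
  if (length(mism) > 0L) {
    stop("PSSM consistency error at position ", mism[1], ": profile has '",
         res[mism[1]], "' but sequence has '", exp_res[mism[1]], "'")
  }
  new_pssm_profile(protein_id, mat, expected_sequence)
}

#' Read a PSI-BLAST ASCII PSSM file
#'
#' @inheritParams parse_pssm
#' @param path path to the ASCII PSSM file.
#' @export
read_pssm <- function(path, expected_sequence,
                      protein_id = sub("\\.[^.]*$", "", basename(path))) {
  parse_pssm(readLines(path, warn = FALSE), expected_sequence, protein_id)
}

#' Write a profile in PSI-BLAST-like ASCII format
#'
#' Emits a header plus one row per residue with the 20 log-likelihood
#' columns, readable by [parse_pssm()].
#'
#' @param pssm a `pssm_profile`.
#' @param path output path.
#' @export
write_pssm <- function(pssm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("Position-specific scoring matrix (log-likelihood block)",
               paste(c("   ", sprintf("%6s", PSSM_COLUMNS)), collapse = "")),
             con)
  res <- strsplit(pssm$sequence, "")[[1]]
  vals <- formatC(round(pssm$matrix, 3), format = "g", width = 6)
  for (i in seq_len(nrow(pssm$matrix))) {
    writeLines(paste0(sprintf("%4d %s ", i, res[i]),
                      paste(vals[i, ], collapse = " ")), con)
  }
  invisible(path)
}

blosum62_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Build a substitution-matrix pseudo-profile
#'
#' Offline stand-in for a PSI-BLAST PSSM: row i is the substitution-matrix
#' row of residue i (BLOSUM62 by default), so the whole pipeline runs with
#' no database search.  Ambiguity codes B/Z/U map to D/E/C; X and J use
#' their own BLOSUM62 rows (they are later excluded from word formation but
#' still contribute to smoothing).
#'
#' @param protein_id identifier.
#' @param sequence amino-acid sequence.
#' @param substitution_matrix a square scoring matrix with amino-acid
#'   dimnames; defaults to BLOSUM62.
#' @return a `pssm_profile`.
#' @export
pseudo_profile <- function(protein_id, sequence,
                           substitution_matrix = NULL) {
  if (is.null(substitution_matrix)) substitution_matrix <- blosum62_matrix()
  res <- strsplit(toupper(sequence), "")[[1]]
  if (length(res) == 0L) stop("empty sequence for ", protein_id)
  mapped <- ifelse(res %in% names(AMBIGUITY_MAP),
                   AMBIGUITY_MAP[res], res)
  bad <- which(!(mapped %in% rownames(substitution_matrix)))
  if (length(bad) > 0L) {
    stop("unmappable residue '", res[bad[1]], "' at position ", bad[1],
         " in ", protein_id)
  }
  mat <- substitution_matrix[mapped, PSSM_COLUMNS, drop = FALSE]
  new_pssm_profile(protein_id, unname(as.matrix(mat)), sequence)
}

#' Logistic normalization of log-likelihoods
#'
#' Maps a (smoothed) log-likelihood x to 1 / (1 + exp(-x)), the open
#' interval (0, 1).
#'
#' @param x finite numeric vector.
#' @export
logistic_normalize <- function(x) {
  if (!all(is.finite(x))) stop("logistic_normalize: non-finite input")
  1 / (1 + exp(-x))
}

#' Smooth a PSSM with a sliding window
#'
#' Each row of the smoothed profile is the sum of the `w` source rows
#' centred on it; `(w-1)/2` zero rows pad both termini.  The normalized
#' matrix applies the logistic function entrywise to the raw window sums.
#'
#' @param pssm a `pssm_profile`.
#' @param w odd window size in residues (default 7, the standard operating
#'   point).
#' @return a `smoothed_profile`: list with `protein_id`, `w`,
#'   `raw_smoothed` and `normalized` n x 20 matrices, and `sequence`.
#' @export
smooth_profile <- function(pssm, w = 7L) {
  if (length(w) != 1L || !is.finite(w) || w < 1 || w %% 2 == 0) {
    stop("parameter error: window w must be a positive odd integer")
  }
  w <- as.integer(w)
  m <- pssm$matrix
  n <- nrow(m)
  h <- (w - 1L) %/% 2L
  padded <- rbind(matrix(0, h, 20L), m, matrix(0, h, 20L))
  cs <- rbind(0, apply(padded, 2L, cumsum))
  raw <- cs[seq_len(n) + w, , drop = FALSE] - cs[seq_len(n), , drop = FALSE]
  dimnames(raw) <- list(NULL, PSSM_COLUMNS)
  structure(list(protein_id = pssm$protein_id, w = w,
                 raw_smoothed = raw,
                 normalized = logistic_normalize(raw),
                 sequence = pssm$sequence),
            class = "smoothed_profile")
}
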