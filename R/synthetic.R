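# Average amino-acid background composition (Swiss-Prot-like frequencies).
BACKGROUND_COMPOSITION <- c(
  A = 0.083, R = 0.055, N = 0.040, D = 0.054, C = 0.014, Q = 0.039,
  E = 0.067, G = 0.071, H = 0.023, I = 0.059, L = 0.096, K = 0.058,
  M = 0.024, F = 0.039, P = 0.047, S = 0.066, T = 0.053, W = 0.011,
  Y = 0.029, V = 0.069)

#' Configuration for the planted-motif dataset generator
#'
#' The generator emulates labeled nuclear / non-nuclear proteins: random
#' background sequences in which, with probability `signal_strength`, a
#' class motif is planted at a uniform random position.  Nuclear motifs
#' are contiguous basic (K/R/H-rich) runs resembling classical NLSs;
#' non-nuclear motifs are spaced hydrophobic (L/I/V/F/M) anchor patterns
#' resembling NESs.  The motif alphabets are a test fixture, not a
#' biological claim.
#'
#' @param n_nuclear,n_non_nuclear class sizes (defaults 100 each).
#' @param length_range min/max protein length in residues.
#' @param signal_strength probability in \[0, 1\] that a protein carries
#'   its class motif (default 0.9).
#' @param nuclear_motif_alphabet,non_nuclear_motif_alphabet named
#'   probability vectors over residues.
#' @param motif_length_range range of the number of motif letters.
#' @param spacer_range range of background residues between non-nuclear
#'   hydrophobic anchors.
#' @param background named residue composition (normalized internally).
#' @param profile_noise_sd sd of seeded Gaussian noise added to the
#'   pseudo-profile rows (0 = none).
#' @param seed integer seed; the generator is a pure function of the
#'   config.
#' @export
generator_config <- function(n_nuclear = 100L, n_non_nuclear = 100L,
                             length_range = c(60L, 120L),
                             signal_strength = 0.9,
                             nuclear_motif_alphabet =
                               c(K = 0.5, R = 0.35, H = 0.15),
                             non_nuclear_motif_alphabet =
                               c(L = 0.4, I = 0.2, V = 0.15, F = 0.15,
                                 M = 0.1),
                             motif_length_range = c(6L, 10L),
                             spacer_range = c(1L, 2L),
                             background = BACKGROUND_COMPOSITION,
                             profile_noise_sd = 0,
                             seed = 1L) {
  if (signal_strength < 0 || signal_strength > 1) {
    stop("config error: signal_strength must be in [0, 1]")
  }
  max_motif <- motif_length_range[2] * (1 + spacer_range[2])
  if (length_range[1] < max_motif) {
    stop("config error: minimum length ", length_range[1],
         " cannot hold a motif of up to ", max_motif, " residues")
  }
  list(n_nuclear = n_nuclear, n_non_nuclear = n_non_nuclear,
       length_range = length_range, signal_strength = signal_strength,
       nuclear_motif_alphabet =
         nuclear_motif_alphabet / sum(nuclear_motif_alphabet),
       non_nuclear_motif_alphabet =
         non_nuclear_motif_alphabet / sum(non_nuclear_motif_alphabet),
       motif_length_range = motif_length_range,
       spacer_range = spacer_range,
       background = background / sum(background),
       profile_noise_sd = profile_noise_sd,
       seed = as.integer(seed))
}

sample_letters <- function(n, alphabet) {
  sample(names(alphabet), n, replace = TRUE, prob = alphabet)
}

#' Generate a labeled planted-motif protein dataset
#'
#' @param config a [generator_config()].
#' @return list with `records` (data.frame `id`, `sequence`, `label`),
#'   `labels` (named vector), `profiles` (list of `pssm_profile`
#'   pseudo-profiles, with optional seeded noise) and `config`.
#' @export
generate_dataset <- function(config = generator_config()) {
  n_total <- config$n_nuclear + config$n_non_nuclear
  labels <- rep(LOCALIZATION_CLASSES, c(config$n_nuclear,
                                        config$n_non_nuclear))
  ids <- sprintf("%s_%03d", ifelse(labels == "nuclear", "nuc", "non"),
                 unlist(lapply(c(config$n_nuclear, config$n_non_nuclear),
                               seq_len)))
  seqs <- with_seed(config$seed, {
    vapply(seq_len(n_total), function(k) {
      len <- sample(seq(config$length_range[1], config$length_range[2]), 1)
      res <- sample_letters(len, config$background)
      if (runif(1) < config$signal_strength) {
        mlen <- sample(seq(config$motif_length_range[1],
                           config$motif_length_range[2]), 1)
        motif <- if (labels[k] == "nuclear") {
          sample_letters(mlen, config$nuclear_motif_alphabet)
        } else {
          anchors <- sample_letters(mlen,
                                    config$non_nuclear_motif_alphabet)
          spacers <- lapply(seq_len(mlen - 1), function(s) {
            sample_letters(sample(seq(config$spacer_range[1],
                                      config$spacer_range[2]), 1),
                           config$background)
          })
          out <- anchors[1]
          for (s in seq_len(mlen - 1)) {
            out <- c(out, spacers[[s]], anchors[s + 1])
          }
          out
        }
        if (length(motif) <= len) {
          start <- sample(seq_len(len - length(motif) + 1), 1)
          res[seq(start, start + length(motif) - 1)] <- motif
        }
      }
      paste(res, collapse = "")
    }, character(1))
  })
  records <- data.frame(id = ids, sequence = seqs, label = labels,
                        stringsAsFactors = FALSE)
  profiles <- lapply(seq_len(n_total), function(k) {
    p <- pseudo_profile(ids[k], seqs[k])
    if (config$profile_noise_sd > 0) {
      noise <- with_seed(config$seed + k, {
        matrix(rnorm(length(p$matrix), sd = config$profile_noise_sd),
               nrow(p$matrix))
      })
      p$matrix <- p$matrix + noise
    }
    p
  })
  names(profiles) <- ids
  list(records = records,
       labels = stats::setNames(labels, ids),
       profiles = profiles, config = config)
}

#' Write a generated dataset in the pipeline's input formats
#'
#' FASTA sequences, a two-column labels TSV (`id`, `label`) and one
#' `<id>.pssm` ASCII profile per protein.
#'
#' @param dataset result of [generate_dataset()].
#' @param dir output directory (created if needed).
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_proteins(dataset$records, file.path(dir, "proteins.fasta"))
  utils::write.table(data.frame(id = dataset$records$id,
                                label = dataset$records$label),
                     file.path(dir, "labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  prof_dir <- file.path(dir, "profiles")
  dir.create(prof_dir, showWarnings = FALSE)
  for (p in dataset$profiles) {
    write_pssm(p, file.path(prof_dir, paste0(p$protein_id, ".pssm")))
  }
  invisible(dir)
}

rdirichlet_one <- function(n, alpha) {
  g <- matrix(rgamma(n * length(alpha), shape = alpha), length(alpha), n)
  sweep(g, 2L, colSums(g), "/")
}

#' Generate a corpus from a known aspect model
#'
#' Draws true `P(w|t)` and `P(t|d)` from symmetric Dirichlets and emits
#' either noise-free expected counts
#' `n(d, w) = weight_per_doc * sum_t P(w|t) P(t|d)` (default; each document
#' totals exactly `weight_per_doc`) or multinomial-sampled counts.
#' The ground-truth model is returned for recovery tests.
#'
#' @param K_true number of generating topics.
#' @param n_docs,vocab_size corpus dimensions.
#' @param weight_per_doc total word weight per document.
#' @param seed RNG seed.
#' @param mode `"expected"` or `"sampled"`.
#' @param alpha_words,alpha_topics Dirichlet concentrations.
#' @return list with `corpus` (a `gd_corpus`) and `truth`
#'   (`word_given_topic`, `topic_given_doc`).
#' @export
generate_aspect_corpus <- function(K_true, n_docs, vocab_size,
                                   weight_per_doc = 200, seed = 1L,
                                   mode = c("expected", "sampled"),
                                   alpha_words = 0.5, alpha_topics = 0.5) {
  mode <- match.arg(mode)
  if (K_true < 1) stop("parameter error: K_true must be >= 1")
  if (vocab_size < K_true) stop("parameter error: vocab_size < K_true")
  out <- with_seed(seed, {
    pwt <- rdirichlet_one(K_true, rep(alpha_words, vocab_size))
    ptd <- rdirichlet_one(n_docs, rep(alpha_topics, K_true))
    pwd <- pwt %*% ptd                       # vocab x docs
    counts <- if (mode == "expected") {
      t(pwd) * weight_per_doc
    } else {
      t(apply(pwd, 2L, function(p) {
        as.numeric(stats::rmultinom(1, size = round(weight_per_doc),
                                    prob = p))
      }))
    }
    list(pwt = pwt, ptd = ptd, counts = counts)
  })
  vocab <- sprintf("w%04d", seq_len(vocab_size))
  docs <- sprintf("d%04d", seq_len(n_docs))
  dimnames(out$counts) <- list(docs, vocab)
  dimnames(out$pwt) <- list(vocab, NULL)
  dimnames(out$ptd) <- list(NULL, docs)
  list(corpus = as_corpus(out$counts),
       truth = list(word_given_topic = out$pwt,
                    topic_given_doc = out$ptd))
}
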