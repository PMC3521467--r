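# Shared fixtures and independent brute-force oracles.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

make_pssm <- function(mat, sequence, id = "prot") {
  colnames(mat) <- AA20
  structure(list(protein_id = id, matrix = mat, sequence = sequence),
            class = "pssm_profile")
}

# profile with all-zero raw scores: every normalized entry is exactly 0.5
const_profile <- function(n) {
  smooth_profile(make_pssm(matrix(0, n, 20), strrep("A", n)), w = 1)
}

random_pssm <- function(n, seed) {
  set.seed(seed)
  make_pssm(matrix(sample(-5:8, n * 20, replace = TRUE), n, 20),
            paste(sample(AA20, n, replace = TRUE), collapse = ""))
}

# brute-force window sum: double loop over in-range neighbours
bf_smooth <- function(m, w) {
  n <- nrow(m)
  h <- (w - 1) / 2
  out <- matrix(0, n, ncol(m))
  for (i in seq_len(n)) {
    for (k in (i - h):(i + h)) {
      if (k >= 1 && k <= n) out[i, ] <- out[i, ] + m[k, ]
    }
  }
  out
}

# brute-force gapped-dipeptide weight: explicit position loop
bf_weight <- function(norm, a, d, b) {
  n <- nrow(norm)
  tot <- 0
  i <- 1
  while (i <= n - (d + 1)) {
    tot <- tot + unname(norm[i, a] * norm[i + d + 1, b])
    i <- i + 1
  }
  tot
}

# PSI-BLAST-like ASCII PSSM text for a small integer matrix
ascii_pssm <- function(mat, residues) {
  lines <- c(
    "",
    "Last position-specific scoring matrix computed",
    paste(c("          ", sprintf("%3s", AA20)), collapse = " "))
  for (i in seq_len(nrow(mat))) {
    lines <- c(lines, paste(c(sprintf("%5d %s", i, residues[i]),
                              sprintf("%3d", mat[i, ])), collapse = " "))
  }
  paste(lines, collapse = "\n")
}

# mean total-variation distance between topic sets under the best
# permutation (K small: enumerate all)
best_perm_tv <- function(est, truth) {
  K <- ncol(truth)
  perms <- gtools_permutations(K)
  best <- Inf
  for (r in seq_len(nrow(perms))) {
    tv <- mean(colSums(abs(est[, perms[r, ], drop = FALSE] - truth)) / 2)
    best <- min(best, tv)
  }
  best
}

gtools_permutations <- function(k) {
  if (k == 1) return(matrix(1, 1, 1))
  sub <- gtools_permutations(k - 1)
  out <- NULL
  for (i in seq_len(k)) {
    rest <- (1:k)[-i]
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

# tiny labeled feature set for fast cross-validation tests
tiny_cv_fixture <- function(n_per_class = 5, seed = 7, d_max = 2) {
  cfg <- generator_config(n_nuclear = n_per_class,
                          n_non_nuclear = n_per_class,
                          signal_strength = 1, seed = seed)
  ds <- generate_dataset(cfg)
  fvs <- lapply(ds$profiles, function(p) {
    build_feature_vector(smooth_profile(p, 7), d_max = d_max)
  })
  list(features = fvs, labels = ds$labels, dataset = ds)
}

small_grid <- function() expand.grid(cost = c(1, 32), gamma = c(0.01, 0.5))
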