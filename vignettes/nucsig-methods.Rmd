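---
title: "nucsig: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{nucsig: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Many nuclear proteins shuttle between nucleus and cytoplasm, directed by
short sequence elements: basic, K/R-rich nuclear localization signals
(NLSs) and hydrophobic, often leucine-rich nuclear export signals (NESs).
Experimentally characterized signals cover only a fraction of the
proteome, so sequence-based prediction of nuclear vs. non-nuclear
localization — and interpretable candidate signal motifs — is of
practical value.  `nucsig` treats this as a document-classification
problem: a protein is a "document", short sequence patterns are its
"words", and the localization class is the document category.

## The model

**Words.** A gapped-dipeptide `AdB` is the pattern "residue `A`, then `d`
arbitrary residues, then residue `B`" (canonical string `"K2K"`).  With
gaps `0..d_max` there are `400 * (d_max + 1)` possible words; the default
`d_max = 13` gives 5,600.

**Word weights from smoothed profiles.**  Each protein has an `n x 20`
position-specific scoring matrix (PSSM) of substitution log-likelihoods.
Row `i` of the *smoothed* profile is the sum of the `w` source rows
centred on `i` (zero rows pad the termini; default `w = 7`), so each
position carries homology information from its sequence neighbourhood.
Entries are mapped to `(0, 1)` by the logistic function
`f(x) = 1 / (1 + exp(-x))`, giving `sf(i, A)`.  The weight of word `AdB`
in protein `P` of length `n` is

```
W(AdB, P) = sum_{i = 1}^{n - (d + 1)} sf(i, A) * sf(i + d + 1, B)
```

Note the sum runs over *all* positions, not only occurrences of the
literal pattern — every position pair contributes its profile support
for `A` and `B`.  The per-protein weight vector is rescaled into
`[0, 1]` by dividing by its maximum ("max-scaling"; the simplest reading
of normalizing "to a range of 0 to 1"; min-max scaling could be swapped
in at one site in `build_feature_vector()`).

When no PSI-BLAST profile is available, `pseudo_profile()` substitutes
the BLOSUM62 row of each residue, which keeps the whole pipeline
deterministic and offline.  The PSI-BLAST parameters conventionally used
to produce real profiles (3 iterations, E-value 1e-3, nr database) are
recorded in the pipeline configuration for users who generate their own,
but nothing in the package requires them.

**Topic model.**  The weighted word-document matrix `n(d, w)` is
factorized by probabilistic latent semantic indexing (PLSI), the aspect
model

```
P(w, d) = P(d) * sum_t P(w|t) P(t|d),    t = 1..K
```

fitted by expectation-maximization: the E-step forms the topic posterior
`P(t|d, w)` proportional to `P(w|t) P(t|d)`; the M-step re-estimates both
conditional tables from posterior-weighted counts.  `K = 80` is the
default operating point.  Unseen proteins are *folded in*: EM is run
with `P(w|t)` frozen, estimating only the new document's `P(t|d')`.

**Classification.**  Two feature modes feed a binary RBF-kernel SVM with
probability outputs:

* `plsi` — the length-`K` topic distribution of each protein;
* `signatures` — the raw weights of a small set of gapped-dipeptide
  *signatures*.

Signatures are mined from the fitted model: a topic's localization
preference for a class is its mean `P(t|d)` over that class's proteins;
its confidence is the absolute difference of the two class means.  Per
class, the 10 most confident preferred topics each contribute up to 20
words with the largest `P(w|t)`.  A curated published signature set
(183 nuclear + 183 non-nuclear words) ships in `inst/extdata` and loads
via `reference_signatures()`.

**Evaluation.**  Confusion counts (nuclear = positive) give sensitivity
`TP/(TP+FN)`, specificity `TN/(TN+FP)`, accuracy `(TP+TN)/N` and
Matthews correlation.  Cross-validation is stratified and seeded; counts
are pooled (micro-averaged) over folds before metrics are computed.
Within each fold the full pipeline — topic model, signature selection,
SVM tuning — sees training labels only.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `w` | 7 residues | smoothing window; 1 disables smoothing |
| `d_max` | 13 | maximum gap; feature space `400 * (d_max + 1)` |
| `K` (`topics`) | 80 | latent topics retained by PLSI |
| `folds` | 5 | outer cross-validation folds |
| `topics_per_class` | 10 | preferred topics mined per class |
| `words_per_topic` | 20 | top words kept per preferred topic |
| SVM grid | `2^-5..2^15` × `2^-15..2^3` | cost × gamma, log-spaced |

The defaults are the method's standard operating point; tests and
examples scale `d_max`, `K` and the grid down purely for runtime, and
say so where they do.

## Design choices where the design was open

* **Feature-vector normalization** is per-protein max-scaling (divide by
  the vector maximum; an all-zero vector is left untouched).
* **EM initialization** draws both conditionals from a seeded uniform
  and normalizes; identical seeds give bit-identical models.  Plain EM
  is used; a tempering exponent `beta` is exposed (default 1) but the
  package does not temper.
* **`P(d)`** is fixed at the document's share of total corpus weight,
  its maximum-likelihood value; word weights are continuous and EM only
  needs nonnegativity.
* **Stopping**: at most 200 iterations or relative log-likelihood
  improvement below `1e-6` (folding-in: 50 iterations, `1e-8` on the
  topic vector).  Probabilities are floored at `1e-12` inside
  logarithms, so structural zeros cannot produce `-Inf`.
* **Consistent featurization in plsi mode**: training documents are
  re-featurized by the same frozen-`P(w|t)` folding-in used for unseen
  documents, rather than taking `P(t|d)` from joint training.  The two
  estimates differ systematically (joint training co-adapts `P(w|t)` to
  its training documents), and a classifier trained on one geometry and
  applied to the other mixes two feature distributions.
* **Tie-breaks** are all deterministic: topic confidence ties go to the
  lower topic index, word-rank ties to the lexicographically smaller
  word, SVM tuning ties to the smaller cost then smaller gamma.  A word
  selected by both classes is kept where it was selected first and
  flagged with a warning, never silently dropped.
* **Ambiguity codes**: B, Z, U map to D, E, C; X and J keep their own
  substitution rows (so smoothing arithmetic and position indexing are
  unaffected) but never form words.  Reported positions are 1-based.
* **The 6,400 question**: the feature-dimension formula is
  `20 * 20 * (u + 1)`; an illustration of "6,400 dimensions" is
  consistent with 16 *distinct gap values* (gaps 0..15) rather than
  `u = 16`.  The package implements the formula and exposes `d_max`;
  both readings are reachable by setting `d_max` to 15 or 16.
* **The SVM solver is implemented in-package** (an SMO dual solver with
  maximal-violating-pair selection in `src/smo.cpp`, plus Platt sigmoid
  scaling fitted on training decision values by regularized Newton
  iteration) because no SVM library is available in the target
  environment.  Probability estimates satisfy the documented contracts
  (both classes sum to 1; reported probability is that of the predicted
  class, at least 0.5); their calibration beyond that is
  implementation-defined.

## What the synthetic generator does and does not emulate

`generate_dataset()` produces labeled background sequences (Swiss-Prot-
like residue composition, lengths 60–120) in which, with probability
`signal_strength` (default 0.9), a class motif is planted at a uniform
position: a contiguous 6–10-residue run drawn from `{K: .5, R: .35,
H: .15}` for nuclear proteins, or 6–10 hydrophobic anchors from
`{L: .4, I: .2, V: .15, F: .15, M: .1}` separated by 1–2 background
residues for non-nuclear proteins.  The motif alphabets echo the
residue preferences of known NLSs/NESs but are a test fixture, not a
biological claim.  Profiles are BLOSUM62 pseudo-profiles with optional
seeded Gaussian noise.

What this establishes — and what it does not: a green end-to-end test
shows the pipeline recovers a planted, localized, composition-based
signal from profile-weighted features at realistic sequence lengths.
It does not establish benchmark accuracy on real proteomes: real
homology profiles, real signal diversity (bipartite NLSs,
context-dependent NESs) and real class imbalance are all absent, and
published benchmark figures additionally depend on external sequence
sets and database searches that this package deliberately does not
require.  Published confusion-count tables are instead used directly as
inputs to verify the metric arithmetic.

## Numerical notes

* Logistic normalization saturates in double precision: for raw sums
  beyond about ±36, `f(x)` rounds to exactly 0 or 1, so the "strictly
  inside (0,1)" property holds only away from saturation.  BLOSUM62
  pseudo-profiles smoothed with `w = 7` do reach this regime.
* Window sums are computed by cumulative sums (exact for integer
  profiles); the Eq.-style weight of every word at a given gap is one
  20×20 cross-product of profile blocks.
* EM's monotone log-likelihood is asserted per iteration in tests with
  a relative slack of `1e-8` for floating-point accumulation.
* All randomness (generators, EM initialization, fold shuffles) flows
  from explicit integer seeds; per-fold seeds derive as `seed + fold`.

## Known limitations

* PLSI has no generative account of unseen documents; folding-in is a
  heuristic (the standard one).  LDA-style models are out of scope.
* The number of topics is taken as a configured constant, not selected
  by the package (the originating analysis justified ~80 via an LSI
  singular-value criterion).
* Signature selection assumes topics separate classes; on corpora where
  no topic prefers a class, fewer topics are used and a warning is
  raised.
* Real PSI-BLAST profile generation is intentionally out of scope; the
  parser reads its ASCII output if provided.
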