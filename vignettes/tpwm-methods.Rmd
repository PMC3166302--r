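---
title: "Tree-based position weight matrices: model, training and benchmark design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tree-based position weight matrices: model, training and benchmark design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tpwm)
```

## The problem

A position weight matrix (PWM) models a transcription factor binding site
as a product of independent per-position nucleotide distributions.  Real
binding sites violate that independence: the 3-D geometry of the
protein–DNA complex couples positions, including non-adjacent ones, and a
factor may bind a mixture of site subclasses.  Scanning with a plain PWM
then produces avoidably many false positives.

This package models a fixed-width motif as a **tree-based PWM (TPWM)**: a
rooted tree whose internal nodes partition the training sites by the
nucleotide at a *maximal dependent position* and whose leaves carry PWMs
conditional on the root-to-leaf path.  The composite model is a mixture of
conditional PWMs, weighted by the empirical nucleotide distributions at
the internal nodes.  A discriminative training loop (**TPD**) builds the
TPWM from a positive sequence set (e.g. ChIP-Seq peak sequences), a
negative set (e.g. shuffled sequences), and an initial PWM such as a
TRANSFAC or JASPAR matrix.

## Dependency statistic and tree construction

Given `n` aligned sites of width `W`, for each position pair `(i, j)` we
compare the empirical joint dinucleotide distribution with the product of
the marginals by their L1 distance

    D(i, j) = sum over (a, b) of | p_ij(a, b) − p_i(a) p_j(b) |,

estimated from raw frequencies without pseudocount, so that observed
absence stays absence in the splitting logic.  `D` is zero for independent
columns and at most 1.5 (attained by uniform, perfectly correlated
columns).  A chi-square test of independence would be the classical
alternative, but it degenerates when the 4×4 contingency table contains
zeros — common in conserved motif columns — so the distance statistic is
used instead.  We use the plain L1 distance rather than the halved
total-variation variant; the factor of two only rescales the threshold,
which is configurable (`threshold` / `--dep-threshold`).

Each position gets a dependency sum `S_i = sum_j D(i, j)`.  A position
qualifies for splitting when it is dependent with at least one other
position, i.e. `max_j D(i, j) > threshold`; among qualifying positions the
one with maximal `S_i` (lowest index on ties) becomes the split position.
Sites are partitioned into at most four subsets by their nucleotide at
that position; only subsets with at least `min_leaf` sites become
children, which guards the conditional estimates in deeper nodes.  The
procedure recurses until no dependency passes the gate or no subset is
large enough, and every leaf stores a PWM over all positions fitted to its
sites (with pseudocount).  No position repeats along a root-to-leaf path,
so the height is at most `W`.

### Defaults and their rationale

* `threshold = 0.1` (L1 scale, dimensionless).  Under the independence
  null, `D` concentrates around `c / sqrt(n)` with `c ≈ 2.4` for uniform
  columns and considerably less for conserved ones.  With the site counts
  at which splitting is allowed at all (`min_leaf = 100` per subset, so
  hundreds to thousands of sites per node in practice) the null
  distribution of `D` sits well below 0.1, while genuinely correlated
  motif positions in our benchmarks produce `D` in the 0.3–1.2 range.
  For very small alignments (a few hundred sites of near-uniform columns)
  0.1 is permissive and the threshold should be raised; this regime is
  outside the method's intended use.
* `min_leaf = 100` sites.  Below roughly 100 sites the 4×W conditional
  frequencies in a child are too noisy to be worth a dedicated leaf.
* `pseudocount = 0.5` per cell for leaf and fallback PWMs (Jeffreys-style
  half count), keeping every probability positive so that log-odds scores
  and divergences are finite.  Branch probabilities and the dependency
  statistic always use raw frequencies.

### Absent branches and the composite distribution

A word whose nucleotide at a split position had fewer than `min_leaf`
training sites routes to a missing child.  To keep the composite model a
proper distribution over all `4^W` words, each internal node stores a
fallback PWM fitted to **all** its sites; an absent-branch word is scored
by the branch probability at the split position times the fallback columns
over the remaining unfixed positions.  Summed over words this contributes
exactly the missing branch mass, so the composite normalizes to 1 (checked
by enumeration for widths up to 6 in the test suite).  A consequence worth
knowing: with pseudocount 0 the position-wise marginals of the composite
model reproduce the raw training-column frequencies exactly only when
every positive-probability branch became a child — the fallback
deliberately replaces, rather than reproduces, the unreliable conditional
frequencies of sub-`min_leaf` subsets.

## Scanning and cutoff calibration

Windows are scored as `log2` odds of the composite model probability
against an order-0 background (uniform by default, configurable or
estimable from the negative set with `background_from_sequences()`).  The
simulator's background is order-3, but order-0 scanning is the standard
PWM practice and keeps scores comparable across models; the mismatch costs
sensitivity equally to all models under comparison.  Both strands are
scanned by default because ChIP-Seq peaks are unstranded
(`both_strands = FALSE` / `--single-strand` to disable).  Each sequence
contributes exactly one best-hit window — the modelling assumption is at
most one site per bound sequence — with ties broken toward the smaller
offset, then the forward strand.  Windows containing non-ACGT letters are
skipped.

The score cutoff at false positive rate `r` is the `k`-th largest of the
negative-set best-hit scores with `k = floor(r m)`; classification uses
`score >= cutoff`, tied scores can push the empirical rate above `r`, and
the realized rate is recorded.  With `k = 0` the cutoff sits above the
largest negative score.  The false positive rate is sequence-level, not
window-level, mirroring the one-site-per-sequence assumption.

## The TPD training loop

For each rate `r` in a grid (default
`{0.005, 0.01, 0.02, 0.05, 0.1, 0.2, 0.3}`):

1. scan the negative set with the current model and derive the cutoff at
   `r` (the negative set is rescanned every iteration so the cutoff tracks
   the evolving model);
2. scan the positive set; the best-hit words of sequences clearing the
   cutoff form the aligned site set;
3. rebuild the TPWM from that alignment;
4. declare convergence when the position-averaged symmetric
   Kullback–Leibler divergence between the marginal PWMs of consecutive
   models falls below 0.001 (natural-log scale).  Marginals are compared
   because tree topologies may differ between iterations; cells are
   clamped at 1e-9 before the divergence since raw branch probabilities
   may contain honest zeros.

Iteration 1 scans with the flat initial PWM (TRANSFAC/JASPAR matrix or
IUPAC consensus).  A safety cap of 50 inner iterations (never reached in
our benchmarks, where 2–4 iterations suffice) warns and keeps the last
model.  Confusion counts are reported under the final model and its own
cutoff.  The model with the largest Matthews correlation coefficient
(MCC) across the grid is returned, the lowest rate winning ties; rates
whose loop loses every aligned site are marked failed and excluded rather
than aborting the run.  Training is fully deterministic: identical inputs
and configuration reproduce the result bit for bit.

The predicted true positive rate `tp / (tp + fn)` is part of the result:
on data whose sequences carry a site with probability `a`, a
well-separated model recovers approximately `a`.

## What the synthetic benchmark emulates

`make_dataset()` reproduces the structure of a ChIP-Seq-scale motif
benchmark: by default 3000 positive sequences of 200 bp from an order-3
Markov background, each carrying one implanted site with probability 0.8
("abundant") or 0.5 ("weak"), and negatives obtained by one Fisher–Yates
pass per positive sequence (exactly preserving per-sequence composition).
Implantation overwrites a uniformly chosen window rather than inserting,
keeping all sequences exactly 200 bp.  The background transition table is
a user input (64×4 TSV, promoter-like tables can be supplied); the shipped
default is uniform, which is the only neutral choice given that no
published table is redistributed here.

`builtin_motif()` ships surrogate benchmark models built for this package:

* independent models of widths 10 and 20 at two conservation levels,
  defined through the information content `sum_i (2 + sum_a p log2 p)`:
  "strong" columns carry ≈1.63 bits (dominant base 0.95), "weak" columns
  ≈0.92 bits (0.75).  Strong conservation is deliberately placed in the
  regime where essentially every implanted site is recoverable above an
  MCC-optimal cutoff, which is the regime in which abundance recovery is a
  meaningful check.
* dependent models generated by latent-subtype mixtures: given the
  subtype, block positions are independent with subtype-specific columns;
  mixing distinct profiles induces the joint dependency.  `dep10`
  correlates positions {3, 8}; `dep20c4` correlates {5, 6, 14, 15} (two
  subtypes); `dep20c6` correlates {3, 4, 12, 13, 19, 20} with three
  subtypes whose separation is sharpest at position 20 (0.95), so position
  20 carries the largest dependency sum and is the expected first split —
  conditioning on it resolves most of the subtype identity, and residual
  splits stay inside the correlated set.  The exact joint tables are this
  package's own surrogates; only the correlated-position layout follows
  the published benchmark design.

What the simulator does **not** emulate: peak-height or peak-shape
information, sequence composition heterogeneity across peaks, overlapping
or multiple sites per sequence, variable-width or gapped motifs, and
genomic repeat structure.  Passing benchmarks here therefore demonstrates
correct recovery of the generating model under the stated assumptions, not
performance on real ChIP-Seq data.

## Evaluation metrics

* **Pattern prediction accuracy** `Δ = sum_{i,a} |p_ia − p̂_ia|` between
  true and estimated marginal probability matrices (range `[0, 2W]`).
  Because a motif can be recovered in either orientation, the estimate is
  compared as-is and reverse-complemented and the minimum reported with an
  orientation flag; no column-shift search is performed since TPD fixes
  the width and phase through the initial PWM.  Two error sources shape
  Δ in the discriminative setting: sampling noise, shrinking with the
  aligned-site count, and an n-independent floor from selection truncation
  (true sites below the cutoff are censored, slightly inflating apparent
  conservation) plus the ~1–3% of aligned words that are best-scoring
  background windows.  Comparisons of Δ across sample sizes in the test
  suite therefore use nested subsets of one draw, the standard paired
  design.
* **ROC/AUC** on sequence-level best-hit scores; the trapezoidal AUC of
  the stored curve equals the Mann–Whitney statistic with ties counted
  one half.  `crossval_enrichment()` implements the two-fold scheme:
  random halves of the positive set, per-fold negatives created by
  shuffling that fold's positives, train on one half, score the held-out
  half, swap, and average the two AUCs.
* **Information content** in bits, `sum_i (2 + sum_a p log2 p)` with
  `0 log 0 = 0`, as the conservation summary.

## Numerical and design notes

* Positions are 1-based everywhere a human reads them (split positions,
  serialized trees); sequence offsets in hit tables and truth tables are
  0-based half-open, matching BED conventions.
* Tie-breaks are deterministic everywhere: lowest position index, then
  alphabetical nucleotide order A < C < G < T; smaller offset, then
  forward strand in scanning.
* The scanner's inner loop is compiled (Rcpp) and decomposes the tree
  into disjoint root-to-leaf and absent-branch paths; the pure-R tree
  walk `composite_probability()` serves as its independent oracle in the
  tests.
* `pwm_kld()` refuses zero cells rather than silently regularizing;
  training clamps marginals at 1e-9 only for its convergence check.
* Problem sizes in the test suite (10 training runs at n = 1000 for the
  independent checks, 10 at n = 3000 for dependent-structure recovery,
  width ≤ 6 for exhaustive enumeration) were chosen as the smallest sizes
  at which the statistical claims are stable across seeds.
* Serialized TPWMs (JSON) round-trip probabilities at full precision;
  matrix text formats accept both TRANSFAC `P0`/`PO` blocks and JASPAR
  bracket rows.

## Known limitations

* Fixed motif width; no shifting, gaps or variable spacers.
* The dependency gate is a fixed threshold, not a calibrated test; for
  alignments of a few hundred near-uniform sites it will fire on noise,
  and for very large alignments it may miss weak true dependencies.
  Scaling the threshold with `1/sqrt(n)` would be a natural refinement.
* Scoring ignores the order-3 structure of realistic backgrounds.
* The negative-set construction (per-sequence shuffling) preserves only
  mononucleotide composition; dinucleotide-preserving shuffles would be a
  stricter null for real genomic sequence.
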