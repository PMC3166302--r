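# tpwm — tree-based position weight matrices for binding-site discovery

Transcription factors bind short, degenerate DNA words. The standard
model of such a motif, the position weight matrix (PWM), assumes every
position contributes independently — an assumption real binding sites
violate, both through direct base–base coupling in the protein–DNA
complex and because a factor may bind a mixture of site subclasses.
`tpwm` models a fixed-width motif as a **tree-based PWM (TPWM)**: a
rooted tree that recursively partitions aligned sites at the *maximal
dependent position* — the position `i` maximizing the dependency sum

    S_i = Σ_j D(i, j),   D(i, j) = Σ_{a,b} | p̂_ij(a,b) − p̂_i(a) p̂_j(b) |,

subject to `max_j D(i, j)` exceeding a threshold — and fits a conditional
PWM at every leaf. The composite model is a mixture of conditional PWMs
weighted by the branch (nucleotide) probabilities at the internal nodes,
so it captures non-adjacent dependencies and subclass structure while
degenerating gracefully to a plain PWM when positions are independent.

The package is intended for regulatory genomicists who have a positive
sequence set enriched in binding sites (ChIP-Seq peak sequences), a
negative set (typically shuffled positives), and an initial matrix from
TRANSFAC/JASPAR or an IUPAC consensus. The **TPD** training loop refines
that matrix discriminatively: for each false positive rate `r` on a grid
it alternates cutoff calibration on the negatives, one-best-hit alignment
of the positives, and tree rebuilding until the symmetrized
Kullback–Leibler divergence between consecutive marginal PWMs drops below
0.001, then returns the model with the largest Matthews correlation
coefficient

    MCC = (TP·TN − FP·FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)).

Also included: log-odds scanning with one best hit per sequence, a
synthetic benchmark generator (order-k Markov backgrounds, independent or
position-correlated motif models, abundance-controlled implantation,
Fisher–Yates shuffled negatives), and evaluation utilities (pattern
prediction accuracy Δ, sequence-level ROC/AUC, two-fold cross-validated
enrichment, information content).

## Worked example

Simulate a benchmark with a dependent motif (width 10, positions 3 and 8
jointly distributed through a two-subtype mixture), train TPD from the
consensus, and inspect the result:

```r
library(tpwm)

mod  <- builtin_motif("dep10")
sim  <- make_dataset(n = 1500, length = 200, model = mod,
                     abundance = 0.8, seed = 42)
init <- consensus_to_pwm(motif_consensus(mod))
fit  <- tpd(sim$pos, sim$neg, init)
print(fit)
#> tpd_result: best fpr 0.05, MCC 0.7173, predicted TP rate 0.753, 1130 site(s)
#>     fpr iterations    final_kld   tp  fn  fp   tn       mcc n_sites
#> 1 0.005          3 0.0000000000  513 987   9 1491 0.4431438     513
#> 2 0.010          3 0.0007699542  565 935  15 1485 0.4642383     565
#> 3 0.020          4 0.0009655228 1058 442  31 1469 0.7119117    1058
#> 4 0.050          3 0.0001212761 1130 370  75 1425 0.7173427    1130
#> 5 0.100          3 0.0002476708 1179 321 150 1350 0.6905016    1179
#> 6 0.200          3 0.0002381831 1240 260 300 1200 0.6268896    1240
#> 7 0.300          3 0.0006195360 1272 228 450 1050 0.5541021    1272
print(fit$best_model)
#> tpwm: width 10, 1128 sites, 1 split node(s) (min_leaf 100, threshold 0.1)
#>   split at position 8 (n=1128)
#>    G:
#>     leaf (n=547)
#>    T:
#>     leaf (n=506)
```

Reading this: the grid rate 0.05 maximizes the MCC; under that model and
cutoff, 1130 of 1500 positive sequences contain a predicted site, i.e. a
predicted true positive rate of 0.753 against a simulated site abundance
of 0.8. The learned tree splits at position 8 — one of the two truly
correlated positions — into the two subtype branches (G and T); the other
two branches held fewer than `min_leaf = 100` sites. Accuracy against the
generating model:

```r
acc <- pattern_accuracy(mod, fit$best_model)
sprintf("delta = %.3f (%s)", acc$delta, acc$orientation)
#> "delta = 0.327 (forward)"
sprintf("IC: truth %.2f bits, fitted %.2f bits",
        information_content(mod), information_content(fit$best_model))
#> "IC: truth 14.37 bits, fitted 15.16 bits"
```

Δ sums the absolute differences between true and estimated marginal
probabilities over all 40 matrix cells (0 = perfect, 20 = maximal), here
about 0.8% per cell on average; the slight excess of fitted information
content reflects the truncation of weak sites below the cutoff.

Models serialize to JSON (`tpwm_to_json()` / `tpwm_from_json()`), and
`best_hits()` scans new sequences with one BED-style hit per sequence.

## Command line

A thin wrapper around the same functions is installed at
`inst/cli/tpwm`:

```sh
tpwm simulate --n 3000 --length 200 --model motif.yaml --abundance 0.8 \
              --seed 1 --out-prefix bench
tpwm train --pos bench_pos.fa --neg bench_neg.fa --consensus TGACTCAGGT \
           --out model.json --trace trace.tsv
tpwm scan --model model.json --fasta bench_pos.fa --out hits.bed
tpwm evaluate roc --model model.json --pos bench_pos.fa --neg bench_neg.fa
```

Flags may also come from a YAML file via `--config` (flags win).

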