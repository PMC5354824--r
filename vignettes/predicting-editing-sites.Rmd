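---
title: "Predicting A-to-I RNA editing sites from sequence windows"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting A-to-I RNA editing sites from sequence windows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inosine)
```

## The problem and the model

Adenosine deaminases acting on RNA (ADAR) convert adenosine (A) to inosine
(I), which the cellular machinery reads as guanosine. Knowing which adenosines
in a transcript can be edited matters for interpreting RNA-seq variants and
for studying editing-linked disease, but experimental mapping is slow and
A-to-G SNPs confound read-based calling. `inosine` predicts, from sequence
alone, whether the adenosine at the center of a fixed-length RNA window is an
editing site.

A candidate site is a window of 2ξ+1 nucleotides with `A` at its center
(ξ = 25, i.e. 51 nt, by default — the flank size at which windowed
editing-site classifiers of this family perform best). Each position *i* of
the window is encoded by four channels:

* three binary **chemical-property indicators** — ring structure (purine
  A,G = 1; pyrimidine C,U = 0), functional group (amino A,C = 1; keto
  G,U = 0), and hydrogen bonding (weak-pairing A,U = 1; strong-pairing
  C,G = 0). The triplets (A → 111, C → 010, G → 100, U → 001) are injective,
  so the sequence is recoverable from the encoding;
* the **sliding occurrence density** — the count of the occupying nucleotide
  within the prefix ending at *i*, divided by *i*. For `ACGUA` the densities
  are 1, 1/2, 1/3, 1/4, 2/5: the final `A` is the second `A` among five
  residues. This channel injects position-dependent, long-range composition
  information that plain one-hot encodings lose.

A window thus becomes a 4(2ξ+1)-dimensional vector in [0,1] (204 dimensions
at ξ = 25); this is a pseudo nucleotide composition (PseKNC) in the general
sense — a fixed-length vector retaining sequence-order information. No
further scaling is applied before classification: every channel already lies
in [0,1], and rescaling binary indicators against densities would distort
their relative weighting.

Classification uses a C-SVM with radial basis kernel. Cost C and kernel
width γ are tuned by exhaustive search over the classical exponent lattice
C ∈ {2⁻⁵, …, 2¹⁵}, γ ∈ {2⁻¹⁵, …, 2⁻⁵} with integer exponent steps — 21 × 11 =
231 candidate pairs. The step sizes quoted for this lattice ("ΔC = 2",
"Δγ = 2⁻¹") are multiplicative: additive steps spanning 2⁻⁵..2¹⁵ would give
tens of thousands of points and make a step of 2⁻¹ meaningless. Each pair is
scored by stratified inner k-fold (default 5) accuracy on the training data
only, so tuning never sees held-out samples; ties break toward the smallest
C, then the smallest γ, favoring the least complex model among equals.

## Evaluation metrics

With class totals N⁺, N⁻ and misclassification counts fn (true sites called
non-sites) and fp (non-sites called sites):

* Sn = 1 − fn/N⁺
* Sp = 1 − fp/N⁻
* Acc = 1 − (fn+fp)/(N⁺+N⁻)
* MCC = (1 − (fn/N⁺ + fp/N⁻)) / √((1 + (fp−fn)/N⁺)(1 + (fn−fp)/N⁻))

This "intuitive" formulation is algebraically identical to the conventional
TP/TN/FP/FN formulas — `equivalence_check()` verifies the identity
numerically, and the test suite brute-forces it across a lattice of counts.
The extremes behave as expected: zero errors give Acc = MCC = 1,
misclassifying half of each class gives Acc = 0.5 and MCC = 0, and total
misclassification gives Acc = 0 and MCC = −1. When every sample is assigned
to one class and class sizes are unequal, the MCC denominator vanishes; we
report MCC = 0 with a warning, the standard convention for the degenerate
case.

Three protocols are provided. The **jackknife** (leave-one-out) is the
default headline protocol because it yields a unique result for a fixed
dataset and parameters — `jackknife()` additionally sorts samples into a
canonical order before fitting, since libsvm's optimizer is order-sensitive
in ties, making the output provably permutation-invariant. **k-fold**
cross-validation trades uniqueness for speed; folds are stratified per class
(sizes within a class differ by at most one) and drawn once from an explicit
seed. `k` equal to the dataset size is dispatched to the jackknife — that is
the leave-one-out limit, where per-class stratification is no longer
meaningful; any other `k` exceeding the smaller class count is an error.
An **independent test** applies a trained model to a disjoint dataset;
disjointness (no shared residue string) is checked when the training windows
are available.

A caveat worth knowing: at strongly *underfitting* parameter pairs (very
small γ, where the RBF kernel is nearly flat) the leave-one-out estimate can
fall well below the k-fold estimate, because removing a sample from a
majority-vote-like classifier biases the prediction against that sample's
own class. This is a property of leave-one-out itself, not of the
implementation; the tuned parameter pairs selected on informative data are
far from this regime.

## Benchmark construction

`build_benchmark()` mirrors the standard construction for editing-site
benchmarks: extract every full-flank adenosine-centered window, label
centers from an annotation table (experimentally confirmed sites positive,
confirmed non-sites negative — nothing is inferred about unannotated
adenosines unless explicitly requested), remove redundancy, and balance
classes by uniform subsampling, holding leftover positives out for an
independent set.

Redundancy reduction replaces CD-HIT: because all samples are equal-length
ungapped windows, pairwise identity is simply the fraction of matching
columns, and a greedy first-come clustering removes any later sample whose
identity with a retained same-label sample exceeds 0.60 (strict inequality;
the convention is documented so users can match alternatives). CD-HIT's word
heuristics exist to make variable-length clustering tractable at scale and
add nothing here. Groups are processed per label, so an identical string may
legitimately appear in both classes. The operation is idempotent and the
tests verify by all-pairs scan that no same-label pair above the threshold
survives.

Windows whose flanks would run past a sequence end are skipped rather than
padded — published benchmark samples are all full-length windows, and any
padding symbol would need an encoding the feature map does not define. The
CLI's `predict` reports only eligible adenosines, so users can see which
candidates were not scored. Ambiguity codes (e.g. `N`) are tolerated on
input but any window containing one is dropped with a warning, since the
encoders are defined on {A,C,G,U} only.

## The synthetic generator

`simulate_editing_windows()` exists so that every stage — extraction,
encoding, tuning, all three protocols — can be exercised end-to-end with no
external data. Negative windows draw each non-center position i.i.d. from a
background composition (uniform by default). Positive windows bias the ten
flank positions −5..−1 and +1..+5 around the center toward a fixed
G-enriched preference profile (A,C,G,U) = (0.05, 0.05, 0.85, 0.05),
linearly interpolated with the background according to `signal_strength`
∈ [0, 1]; the center is forced to `A` in both classes. The profile is a
frozen constant so generated datasets are stable across versions.

At `signal_strength = 0` the classes are exchangeable by construction; at 1,
ten near-independent positions with G-probability 0.85 vs 0.25 make the
Bayes accuracy ≈ 0.98, so a competently tuned classifier should exceed 0.9 —
these two endpoints, plus consistency between jackknife and an independent
draw from the same generator, are the package's pipeline-level checks (the
test suite runs them at 200+200 samples and ξ = 25). What the generator does
*not* emulate: double-stranded RNA context, ADAR substrate structure, real
editing motifs, or the class imbalance of real transcriptomes. Passing these
checks therefore demonstrates that the machinery is correct and calibrated,
not that real-data accuracy will match published benchmark figures — those
depend on the curated benchmark sets, which users must supply (any labeled
FASTA in the `>{id}|label={pos|neg}` convention runs through the same
pipeline).

## Numerical and design choices

* Densities are kept at full double precision; printed values like 0.33 are
  display rounding only, and rounding features would corrupt the classifier
  input.
* The decision threshold is fixed at 0 on the signed SVM decision value
  (positive score ⇒ editing site); no probability calibration is performed,
  as the classifier is evaluated on hard labels.
* Channel order within a position is fixed as (ring, functional group,
  hydrogen bonding, density); the CSV and sparse exporters preserve it
  bit-exactly.
* Every randomized operation (balancing, fold assignment, generation) takes
  an explicit integer seed and is reproducible from it; nothing consumes the
  global RNG state ambiently.
* Reported problem sizes in the tests (e.g. 200+200 windows at ξ = 25 for
  the pipeline checks, 1000-sequence oracle sweeps) were chosen as the
  smallest sizes at which the statistical claims are comfortably outside
  sampling noise.

## Limitations

* The greedy identity clustering is O(n²) in the per-label group size;
  adequate for curated benchmark scales, not for clustering whole
  transcriptomes.
* Training is single-threaded libsvm; the 231-pair grid on thousands of
  samples is a batch job, not interactive.
* No genome alignment, BAM/VCF ingestion, or SNP-vs-editing disambiguation:
  input is sequence plus (optionally) per-position annotations.
* Metrics are single-label; multi-label editing systems need a different
  metric family.

## A minimal run

```{r example, eval = FALSE}
bench <- simulate_editing_windows(n_pos = 200, n_neg = 200, xi = 25,
                                  signal_strength = 1, seed = 202)
gs <- grid_search(bench, seed = 202)       # 231-pair lattice, inner 5-fold
jk <- jackknife(bench, C = gs$C, gamma = gs$gamma)
glance(jk)
autoplot(gs)                               # accuracy surface
plot_score_distribution(jk)
```

The same flow is available from the shell via the installed script
(`system.file("cli", "inosine", package = "inosine")`): `simulate`,
`build-dataset`, `encode`, `tune`, `train`, `evaluate`, `predict`, each
writing its artifacts and a run log under `--out`.
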