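---
title: "Classifying pre-miRNA hairpins under class imbalance with ROC-select"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying pre-miRNA hairpins under class imbalance with ROC-select}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirhunt)
```

## The problem

A microRNA precursor (pre-miRNA) is a short transcript that folds back on
itself into a stem-loop. Genomes contain millions of sequences that fold
into similar stem-loops without ever producing a mature miRNA — *pseudo
hairpins*. Telling the two apart from sequence alone is a binary
classification problem with two defining difficulties:

1. **Extreme class imbalance.** Real candidate pools contain tens of
   thousands of pseudo hairpins per true precursor. A classifier trained
   and thresholded conventionally maximises accuracy by sacrificing the
   minority class: specificity approaches 100% while sensitivity collapses.
2. **Structure matters as much as sequence.** Discriminative signal lives
   in the predicted secondary structure (pairing density, folding energy,
   loop architecture), so feature extraction requires a folding step.

The evaluation metric used throughout is the geometric mean of sensitivity
and specificity on the percent scale,

$$G_m = \sqrt{SE \cdot SP}, \qquad
  SE = 100\,\frac{TP}{TP+FN}, \quad SP = 100\,\frac{TN}{TN+FP},$$

which is zero when either class is fully sacrificed, and therefore rewards
balanced operating points. The positive class is the miRNA class
everywhere in this package; that orientation is fixed.

## ROC-select

Most classifiers expose a continuous score $s(x)$ — a vote fraction, a
posterior probability — where higher means "more miRNA-like". Any
threshold $T$ on that score defines a classifier ("miRNA iff
$s(x) \ge T$"), and sweeping $T$ from $+\infty$ to $-\infty$ traces the
full ROC curve. As long as $s$ ranks instances correctly, some point on
that curve balances the two classes far better than the default threshold
does, and classification with unequal misclassification costs is exactly
thresholding at a different quantile.

ROC-select chooses that point without touching held-out data:

1. Split the training data into $k_1$ stratified folds (default
   $k_1 = 10$).
2. For each fold, train the base classifier on the other folds and score
   the held-out instances, so each instance is scored by a model that
   never saw it.
3. Pool all out-of-fold `(score, label)` pairs into one set, sort by
   score, and update TP/FP counts at each distinct score: one ROC point
   per distinct value plus the all-negative point. Tied scores move
   together, so the points are exactly the achievable confusion matrices.
4. Select the point maximising $G_m$ (or any other metric functional) and
   store its threshold; retrain the classifier on the full training data.

Pooling (rather than averaging fold-wise curves vertically) is used
because only the selected operating point matters, not the curve's
variance. The final retraining step is the package's resolution of a
genuinely open design point: the alternative — keeping the fold-ensemble —
complicates the model bundle for no measurable benefit at the scale the
synthetic experiments probe.

Three smaller decisions are worth recording:

* **Decision rule orientation** is $s(x) \ge T$, applied identically in
  curve construction and classification.
* **Ties** on the metric break towards the highest sensitivity (the
  lowest maximising threshold): in screening, a missed precursor costs
  more than a false candidate.
* **The stored threshold** is the midpoint between the selected distinct
  score and the next higher distinct score. The selected score itself sits
  exactly on training instances; the midpoint makes classification robust
  to small score jitter after the final retraining.

`select_threshold()` reports the achieved score value (so that worked
examples on explicit score sets read naturally), while the fitted model
stores the midpoint; both induce the same confusion on the pooled scores.

## Parameter tuning

Parameter selection precedes threshold selection: a declared grid of
parameter values (`param_grid()`, size $\lambda$) is scanned with a
$k_2$-fold stratified internal cross-validation (default $k_2 = 5$; cheaper
than $k_1$-fold because tuning dominates the runtime), every point scored
by mean $G_m$ at the classifier's *default* threshold on one shared fold
split. The default random-forest grid is 10, 21, …, 219 trees
($\lambda = 20$).

Whether threshold selection should be nested *inside* the tuning loop is
ambiguous in the method's own description; this package reads "preceding
step" literally and tunes at the default threshold, which costs
$\lambda k_2$ rather than $\lambda k_2 k_1$ trainings. The nested variant
is available behind `grid_search(threshold = "roc_select")` for users who
accept the cost.

## The base classifier

The default classifier is a random forest — bootstrap-aggregated CART
trees, gini splits, a random feature subset drawn at every node — with the
score defined as the fraction of trees voting for the miRNA class. No tree
learner is available in the dependency environment, so the forest is
implemented in compiled code inside the package, with its own
deterministic generator so that a seed fully determines the model. Any
score-producing classifier can be substituted through `make_trainer()`;
only the ranking property of the score is assumed.

## Features

Each candidate is represented by a fixed-order numeric vector
(`feature_spec()`).

**The seven extended features**: frequencies of the four
secondary-structure triplet elements with the highest discriminative value
(`tri_a`, `tri_u`, `tri_g`, `tri_c`: after mapping `)` to `(`, the
fraction of interior positions whose structure window is `(((` with the
given middle nucleotide, normalised by the $L-2$ interior windows); the
longest stop-codon-free codon run over the three forward reading frames in
codons (`orf`; hairpin candidates have a defined orientation, so the
reverse strand is not scanned); the cumulative number of unpaired bases in
internal loops and bulges (`loops`); and the DUST low-complexity masked
percentage (`dm`).

**The base set** stands in for the 21 microPred-selected attributes, whose
identity is not enumerated in the source literature. It is tiered by
backend capability: Tier A (always computable from an MFE structure)
comprises GC content, normalised folding energy $dG = \mathrm{MFE}/L$, the
MFE indices $dG/\mathrm{GC}$, $dG/n_{stems}$, $\mathrm{MFE}/n_{bp}$,
pairing density $n_{bp}/L$, per-type pair densities (A-U, G-C, G-U per
length) and mean stem length. Tier B (ensemble features) requires a
partition-function backend and errors without one. Tier C adds z-scores of
$dG$ and pairing density against $n = 100$ dinucleotide-preserving
shuffles (Altschul-Erickson; the dinucleotide multiset is asserted on
every shuffle, and a zero shuffle standard deviation defines $z = 0$).
Users with their own feature pipelines can classify from a precomputed
feature table; the bundle refuses tables whose columns do not match its
spec.

**DUST.** The symmetric variant with a 64-nt window: every subwindow is
scored $\sum_t c_t (c_t - 1)/2 \,/\, (l - 1)$ over its triplet counts
$c_t$ ($l$ triplets), masked when the score exceeds `level/10`, and masked
intervals are merged (so `dm` counts merged-interval coverage, the natural
reading when overlapping subwindows both fire). The subwindow threshold is
15 — deliberately more aggressive than DUST's usual 20 — because
low-complexity content is itself discriminative for hairpins. Masked runs
shorter than 3 nt are discarded. The implementation is validated against
the external `dustmasker` tool on clear-cut fixtures in the test suite.

**Degenerate structures** (no pairs, no stems) define all
division-by-zero features as 0 rather than erroring, so genome-window
negatives never abort extraction; records containing `N` are skipped and
reported, since folding is undefined on `N`.

## The folding backend

No thermodynamic folding engine is available in the dependency
environment, so the package ships a maximum base-pairing dynamic program
(Nussinov-style): canonical Watson-Crick plus G-U wobble pairs, a minimum
hairpin loop of 3 unpaired bases, deterministic traceback preferring
pairing, and an energy proxy of $-1$ per pair (so `mfe = -n_bp`). Multi-loop
structures are allowed — the method makes no prior assumption that a
candidate folds into a single hairpin.

This backend choice has consequences a user should know:

* Energies are proxies. Features built on them (`dg`, `mfei*`) remain
  monotone transforms of pairing counts, which is what the classifier
  consumes; absolute kcal/mol values are not comparable with thermodynamic
  folders.
* Maximum pairing pairs random RNA heavily (roughly 0.3–0.45 pairings per
  base), so the structural QC thresholds (`mfe/L < -0.05`,
  `n_bp/L > 0.15`) that a thermodynamic folder would fail on shuffled
  sequence pass under this backend for most inputs. The QC report is
  still informative directionally (homopolymers fail, mismatched stems
  score lower), and the test suite asserts those directional properties
  rather than absolute pass rates for degraded hairpins.

Every feature table and model bundle carries a backend tag, and mixing
backends between training and classification is refused outright rather
than warned about. Structures from an external folder can be supplied as
3-line records via `read_structures()` and flow through the same
extraction path.

## Negative-set construction

`sample_negatives()` draws genome windows whose lengths are resampled from
the empirical positive length distribution — the practical reading of
"same length distribution", since exact distributional equality is
ill-defined for finite random draws; a Kolmogorov-Smirnov property test
guards it. Windows are drawn from the given strand, starts uniform within
a length-proportionally chosen sequence, and windows containing `N` are
rejected (assembly gaps do not fold). Candidates resembling known
precursors are removed by `homology_filter()`: by external BLASTN at an
E-value of $10^{-2}$ when the executable is configured (E-values are
database- and version-dependent, so this mode never silently degrades), or
by a deterministic built-in seed-and-extend scan (shared 11-mers extended
to a maximal exact run, removal at ≥ 20 nt) when it is not.

## Evaluation harness

`evaluate_pipeline()` wraps the full procedure — tuning, then threshold
selection, then scoring — in an outer stratified $k$-fold cross-validation
(default 10), asserting per fold that training and test ids are disjoint.
Outer-fold confusion counts are pooled before computing SE/SP/$G_m$
(micro-averaging), which stays stable when folds contain only a handful of
positives; macro-averaging is a flag. Whether published evaluations of
this design micro- or macro-average is not stated in the source
literature; micro was chosen for that stability and the choice only
matters at extreme imbalance.

Classifier comparisons use the Friedman rank test with the Nemenyi
critical difference $CD = q_\alpha \sqrt{k(k+1)/(6N)}$ ($q_\alpha$
tabulated for $k \le 10$, $\alpha \in \{0.05, 0.10\}$), and paired
Wilcoxon signed-rank tests (exact null from the signed-rank distribution
for $n \le 25$ untied pairs, normal approximation with tie correction
otherwise). One known discrepancy is recorded rather than matched: for
five all-positive paired differences the exact two-sided p-value is
$2/2^5 = 0.0625$, and this package reports that value; the 0.0952
sometimes quoted for such a comparison cannot be reproduced from the
stated inputs by exact or standard approximate computation.

## What the synthetic generators state, and what a green test means

The fixtures module is first-class, tested code; its defaults are a stated
world, not tuned values:

* `make_hairpin()` builds a 5' arm, loop, and reverse-complement 3' arm
  with a configurable number of mismatches and bulges. Default stem 15–30
  bp, loop 3–10 nt, ≤ 4 mismatches, ≤ 2 bulges, GC 30–70% in
  `make_dataset()` — short but structurally faithful precursor mimics
  whose expected properties (length arithmetic, near-perfect folding when
  mismatch-free) are derivable by construction.
* `make_negative_seq()` is i.i.d. sequence with a GC bias: the strongest
  possible contrast to a hairpin, deliberately easier to separate than
  real genome windows.
* `make_score_problem()` draws scores directly from two Gaussians,
  exercising ROC-select without any classifier; its optima have closed
  forms (e.g. equal-variance classes crossing at the midpoint give
  $SE = SP = 100\,\Phi(\delta/2\sigma)$).
* Every generator derives its RNG stream from `(seed, call-site tag)`, so
  adding new calls never perturbs existing fixtures, and regeneration is
  byte-identical.

Synthetic positives versus random negatives are nearly separable, so a
green end-to-end test establishes that the pipeline is correctly wired and
that ROC-select finds the balanced operating point where a default
threshold does not — it does *not* establish deployment-grade accuracy on
real precursors, which depends on miRBase-scale data and a thermodynamic
folder, both outside this package's test environment. Imbalance-behaviour
tests are scaled to desk size (e.g. 50 positives vs 2500 negatives, 20
repetitions, reduced tree counts and fold counts in the heavier suites)
to keep the default run inside minutes; the scaling is stated at each
site.

## Numerical and degenerate-input choices

* Scores must be finite; ROC construction errors on single-class input.
* A constant score degenerates to a majority/minority rule without
  crashing (two ROC points, threshold at the constant).
* `Gm` identities hold to 1e-9 internally; public values are percents.
* Stratified folds deal shuffled class members round-robin, so per-class
  fold counts deviate from perfection by at most 1; fold assignment in the
  evaluation harness is keyed by sorted instance id, making aggregate
  results invariant to input row order.
* Seeds are 32-bit; all derived streams stay below $2^{31}$.

## Limitations

* The built-in folding backend is a pairing-count maximiser, not an
  energy model (see above); for publication-grade features, feed
  structures from a thermodynamic folder through `read_structures()`.
* Tier B ensemble features are declared but require a partition-function
  backend this environment cannot provide.
* The 21-attribute base representation referenced by the original
  pipeline is approximated by the tiered set; no claim of column-level
  equivalence is made.
* Melting-temperature features and comparison baselines (SMOTE, APLSC)
  are out of scope; external classifiers can be plugged in through the
  trainer contract.
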