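---
title: "Compact domain-profile encoding and RAKEL classification of enzyme family classes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compact domain-profile encoding and RAKEL classification of enzyme family classes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecfam)
```

## The problem

Enzymes are catalogued by EC numbers, whose first digit places an enzyme in
one of seven family classes: 1 Oxidoreductases, 2 Transferases, 3 Hydrolases,
4 Lyases, 5 Isomerases, 6 Ligases, 7 Translocases. Assigning this first digit
from annotation data is a *multi-label* problem — a minority of enzymes carry
two (rarely more) classes — and the canonical input signal is the set of
functional-domain terms (InterPro `IPR` accessions) annotated to the protein.

The classical representation, functional-domain composition (FDC), is a
binary presence/absence vector over the whole term vocabulary. It works, but
its dimension equals the vocabulary size (thousands of terms), which makes
training slow. `ecfam` implements a compact alternative: each protein is
encoded into just `L` numbers (one per class) derived from the
class-conditional distribution of its terms in the training set, and the
resulting vectors are classified by a random k-labelsets (RAKEL) ensemble.

## The encoding

Let `S_tr` be a training set of `n` annotated, labelled proteins, and let
`IPR(p)` denote protein `p`'s term set. For every term `t` seen in training:

* `N(t)` — the number of training proteins annotated by `t`;
* `N_j(t)` — the number of those that carry class `j` (a protein with labels
  {1, 3} contributes to `N_1` and `N_3`, but to `N` once);
* `R_j(t) = N_j(t) / N(t)` — the proportion of `t`'s carriers in class `j`.

`R_j(t)` lies in `[0, 1]`; a value near 1 marks a term almost diagnostic of
class `j`. A protein `p` is then encoded as

```
X_j(p) = max { R_j(t) : t in IPR(p), t seen in training },   j = 1..L
```

the most class-`j`-specific evidence among its terms. `build_profile()`
computes the `(N, N_j, R_j)` table, `encode_protein()` /
`encode_dataset()` apply the max rule, and `encode_binary_fdc()` provides
the classical binary baseline for comparison.

Two boundary conventions matter and are deliberate:

* **Unseen terms are skipped.** `R` is a training-set statistic; a term
  without a training row has no ratio to contribute. A test protein none of
  whose terms are known encodes to the zero vector (flagged via
  `n_known_terms = 0`) rather than erroring — the classifier must still
  emit a prediction, it is simply less reliable, which is exactly what the
  annotation-count stratification (`stratify_by_annotation_count()`)
  quantifies.
* **No smoothing by default.** The ratios are raw proportions. A hook for
  additive smoothing (`(N_j + a) / (N + 2a)`) exists for experimentation
  but defaults to `a = 0`.

A consequence worth internalising: the encoding is a function of the
*training* labels. Any evaluation must therefore rebuild the profile inside
each cross-validation fold; computing features once on the full dataset
would leak held-out labels into the features. `run_cv()` enforces this
per-fold recomputation unconditionally, and the test suite checks the
leakage property by injecting sentinel terms into held-out folds and
asserting the training profile is bit-identical.

## The classifier

The Label Powerset (LP) transformation treats each observed labelset as one
class of a single-label problem. Plain LP suffers when `L` is large (class
explosion) — with `L = 7` this is mild, but RAKEL is the general device: draw
`m` random size-`k` subsets of the labels (duplicates allowed, every label
covered at least once, enforced by redrawing the collection), fit one LP
classifier per subset, and integrate by per-label voting. For label `l`,

```
score(l) = (# covering members that voted l) / (# covering members)
```

and `l` is predicted when `score(l) >= 0.5` (positive at equality —
the threshold is configurable). If the thresholded set is empty the single
highest-scoring label is assigned, ties toward the lowest class index:
every enzyme carries at least one class, and the overall measures are
undefined for an empty pair of sets, so the contract "predictions are never
empty" is part of the model.

With `k = L` there is only one possible subset and RAKEL degenerates to
plain LP regardless of `m`; the suite asserts bitwise identity of the two
routes on shared seeds.

Base learners are pluggable behind a fit / predict / predict-probability
contract. Provided adapters: random forest (`base_rf(ntree)`, via the
randomForest package) and SVM (`base_svm()`, via kernlab) with four
kernels — polynomial `(x·y + 1)^e`, normalised polynomial, RBF, and the
Pearson VII ("Puk") kernel supplied as a custom kernel function. The two
Puk shape parameters default to 1.0; published work using this kernel often
relies on toolkit defaults that are not reproducible from the papers, so the
values are explicit and configurable here. An LP subproblem whose training
data exhibit a single class is fitted as a constant predictor. SVM
probability models occasionally fail to calibrate on small classes; such
members fall back to hard votes in the soft-score path, with a warning.

Graded per-label scores for ROC/PR analysis come from
`rakel_scores_soft()`: a member's score for label `l` is the summed
probability of its LP classes whose labelset contains `l`, averaged over
covering members. Set prediction always uses the hard vote fractions; soft
scores exist only for curve analyses, since vote thresholds and probability
sums need not agree near the boundary.

### Reproducibility

One master seed drives everything: `rakel_fit()` derives the
labelset-sampling seed and one fitting seed per member through a fixed
splitting scheme; `run_cv()` derives one fitting seed per fold;
the synthetic generator derives per-stage seeds the same way. Two runs with
the same data, configuration and seed produce byte-identical reports
(`write_cv_report()` omits wall time by default for exactly this reason).

## Evaluation

Two measurement sets are implemented in `overall_metrics()` and
`per_class_metrics()`:

* **Overall** (set arithmetic on observed `L_k` vs predicted `L*_k`):
  aiming `|∩|/|L*_k|`, coverage `|∩|/|L_k|`, accuracy (Jaccard) `|∩|/|∪|`,
  absolute true (exact-match fraction), absolute false (symmetric
  difference over `M`; identical to Hamming loss). Per sample,
  `absolute_true ≤ accuracy ≤ min(aiming, coverage)` — the suite fuzzes
  this chain and the Hamming identity against independent bitwise
  implementations.
* **Per class** (one-vs-rest): confusion counts, accuracy, recall,
  precision, F1, MCC (0/0 defined as 0), plus AUROC (tie-aware rank
  statistic) and AUPR. For AUPR the headline number is stepwise average
  precision; a trapezoidal variant is exported as well because published
  results rarely state their curve integrator, and the two differ under
  heavy ties.

Cross-validation supports the general scheme (uniform random near-equal
folds) and a stratified scheme that first splits proteins into `L + 2`
groups — exact singletons of each class, an exact designated pair (default
{2, 3}: transferases/hydrolases, the dominant shared pair in human enzyme
data), and a remainder — and then splits each group across the folds. The
pair group is configurable because its choice is a property of the data at
hand, not of the method.

`grid_search()` evaluates a configuration lattice on *fixed* folds (the
comparison is paired; re-randomising folds per lattice point would confound
parameter effects with partition noise) and ranks by accuracy, ties broken
by absolute true then absolute false. The default lattice mirrors the
standard tuning ranges for this method family: `k ∈ {3, 5, 7}`, `m = 10`,
forest sizes spanning 80–500 trees, SVM `C ∈ {0.5, 1, 3, 5, 7}` with the
four kernels.

## The synthetic corpus generator

Real benchmarks for this task require downloading enzyme lists and an
InterPro release; `generate_dataset()` instead produces corpora with the
statistical structure the method exploits, so the whole pipeline is testable
offline:

* per-class pools of enriched terms, a fraction `1 - exclusivity` of which
  leak to a second class;
* shared (class-unspecific) terms and off-class terms, entering proteins
  only through a uniform noise channel (`noise_terms`) — this design makes
  the `exclusivity = 1, noise = 0` configuration *exactly* separable: the
  encoding of every protein is then the indicator vector of its classes,
  which the tests assert;
* skewed class weights, defaulting to the human benchmark breakdown
  (288, 1080, 747, 113, 80, 86, 51 across EC 1–7), so the imbalance regime
  (transferases ≫ translocases) is represented;
* a second label with probability `multi_label_rate` (default 0.026,
  matching the benchmark's multiplicity degree of 1.026; tests of the
  recovery pipeline use 0.03);
* per-protein term counts drawn from a truncated geometric on 1–25, so most
  proteins carry fewer than ten terms, mimicking the right-skewed
  annotation-count spread of real enzymes.

What the generator does **not** emulate: real InterPro term co-occurrence
topology, term-hierarchy (parent/child) structure, and annotation biases
that correlate with sequence families. Passing tests on synthetic corpora
therefore demonstrate correctness of the machinery and recoverability under
the model's own assumptions — not field performance on real proteomes,
which depends on how sharply real domain distributions concentrate per
class.

`generate_worked_example()` returns a fixed 8-protein, 3-class, 5-term
corpus whose profile is small enough to verify by hand:

```{r worked}
we <- generate_worked_example()
prof <- build_profile(we)
round(prof$R, 4)
round(encode_dataset(we, prof), 4)
```

For instance `IPR000004` occurs only in class-3 proteins (`R = (0, 0, 1)`),
so its carriers p6 and p7 have `X_3 = 1`; `IPR000001`'s three carriers all
have class 1 and one (p8) also class 3, giving `R = (1, 0, 1/3)`.

## Numerical and design choices

* Vocabulary order is sorted, so profiles are invariant to input row order.
* Report tables round to 4 decimals; JSON carries full precision.
* Labelset keys are canonical sorted strings, with `{}` for the empty
  projection (a legitimate LP class).
* `sample_labelsets()` redraws whole collections with an advanced seed
  until coverage holds, within a budget of 1000 redraws (the worst standard
  case, `k = 1, m = L = 7`, needs about 160 expected redraws).
* Annotation-count strata break ties by dataset order via a single stable
  ascending sort, so "most/least annotated" groups are deterministic.
* The problem sizes used by the shipped checks (1000-protein corpora,
  ten-fold CV, 100-tree forests) were chosen as the smallest at which the
  recovery behaviour is stable across seeds.

## Limitations

* Terms are opaque IDs: no InterPro hierarchy expansion, no propagation of
  parent/child term evidence.
* The encoder discards within-protein term multiplicity and term count;
  two proteins with different numbers of equally class-specific terms can
  encode identically.
* Proteins with few or no known terms receive weakly informed (or zero)
  encodings; their predictions are intrinsically less reliable.
* Only the family class (first EC digit) is modelled — no sub-class digits
  and no enzyme/non-enzyme gate.
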