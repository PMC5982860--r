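---
title: "Wrist-worn accelerometer fall detection: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wrist-worn accelerometer fall detection: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wristfall)
```

## The problem

A fall, seen by an accelerometer worn on the wrist, has a characteristic
magnitude signature: the magnitude `a = sqrt(ax^2 + ay^2 + az^2)` rests near
1 g, dips below gravity during the free-fall instant, spikes sharply at
impact (typically past 3 g), and settles back to baseline. `wristfall`
implements a detection pipeline built on that template: threshold-based
candidate detection on the magnitude channel, an eight-feature description
of each candidate's dynamics, and a classifier that separates true falls
from vigorous daily activities (jumping, running, seizure-like shaking)
that also throw super-threshold peaks.

Everything operates on the magnitude channel, in multiples of g = 9.8 m/s²,
with all interval arithmetic done in **milliseconds on timestamps**, never
in sample indices. This makes mixed sampling rates (the package's synthetic
cohorts rotate 100/50/20 Hz; public wrist datasets range from 16 to
204.8 Hz) uniform to handle, at the cost of treating every printed interval
as a closed interval on timestamps — the convention used throughout.

## Peak detection

A sample is a candidate peak when its magnitude strictly exceeds `th1`
(default 3 g) and no later sample within the following 2500 ms quiet period
also exceeds `th1`. Within a burst of super-threshold samples closer
together than the quiet period this selects the **last** exceedance — the
only reading under which the quiet-period condition is satisfiable at all.
A `burst = "first"` variant is exposed for sensitivity analyses, since one
could also anchor a burst at its onset. Two deliberate boundary choices:

* strict inequality (`a > th1`), so a sample at exactly the threshold is
  not a peak;
* an exceedance inside the final quiet window of a recording is still
  reported when nothing later exceeds the threshold — otherwise falls at
  the end of a recording would silently vanish.

## Event anchors and the eight features

Around each peak time `pt` the extractor locates four anchor times:

* **impact end** `ie`: last time in `(pt, pt + 1000 ms]` with `a > th2`
  (1.5 g), falling back to `pt + 1000 ms`. The published rule gives only
  the fallback; a bounded search horizon equal to that fallback is the
  only reading under which the fallback is coherent, so the search is
  confined to that window.
* **impact start** `is`: scanning forward from `max(ie − 1200 ms, start)`
  to `pt`, the first sample at or below `th3` (0.8 g) that is followed, no
  later than `ie`, by a sample at or above `th2`; fallback `pt`. The
  anchor is the *low* (free-fall) sample, not the later high one.
* **peak bounds** `ps`, `pe`: the last sub-1.8 g sample before `pt` and the
  first after it, with the recording boundaries as fallbacks.

The eight features, all computed on the magnitude channel with windows
clipped at recording boundaries:

| Feature | Definition | Unit |
|---|---|---|
| AAMV | mean absolute consecutive-sample change over `[is, ie]` | g / step |
| IDI  | `ie − is` | ms |
| MPI  | max magnitude over `[is, ie]` | g |
| MVI  | min magnitude over `[is − 500 ms, ie]` | g |
| PDI  | `pe − ps` | ms |
| ARI  | fraction of samples outside [0.85, 1.3] g in the 700 ms window centred on `(is + ie)/2` | — |
| FFI  | mean magnitude over `[tFFI, pt]` | g |
| SCI  | step peaks in `[pt − 2200 ms, pt]` | count |

Three definitions needed a decision:

* **AAMV's denominator** counts *differences* (samples − 1), making the
  index a mean per-step change, which is what "average variation" names; a
  window with fewer than two samples yields 0 with a flag rather than NaN.
* **FFI's anchor** `tFFI` is the first sub-0.8 g sample met scanning
  *backward* from `pt` within `[pt − 200 ms, pt)` — i.e. the latest
  free-fall sample before the impact — with fallback `pt − 200 ms`
  (flagged). The interval `[tFFI, pt]` necessarily includes the rising
  impact edge, so FFI on a canonical fall sits well above the free-fall
  level (about 2 g on the default template); that is a property of the
  definition, consistent with published fall-feature summaries, not a bug.
* **SCI's "peak"** has no published definition. Here: a local maximum
  strictly above `thSCI` (default 1.5 g, the impact-end threshold), counted
  greedily in time order with at least 250 ms separation (a 4 Hz cadence
  ceiling). Both parameters are exposed in `feature_thresholds()`.

Every feature is verified, on a thousand generated traces, against an
independent window-materialising recomputation that shares no code with the
implementation.

## Balancing

Peak extraction labels every candidate with its recording's label, so fall
recordings dominate the event dataset whenever daily activities rarely
cross the threshold. `smote_balance()` oversamples the minority class to at
least a 40/60 split (the configurable `target`): each synthetic row is
`x + u (x_nn − x)`, `u ~ U(0, 1)`, with `x_nn` one of the `k = 5` nearest
minority neighbours. Two details matter: neighbour search runs on
**z-scored** features (ms-scaled and g-scaled features differ by orders of
magnitude, and an unstandardised distance would be dominated by IDI/PDI),
while the interpolation itself runs on the raw scale so synthetic rows are
exact convex combinations of original minority rows. Distance ties break by
row order; generation is deterministic under a seed; overshoot past the
target is bounded by one row, so the minority fraction lands in
[target, 0.5].

## Threshold tuning

The peak threshold is tuned over [2.0, 3.5] g by a real-coded genetic
algorithm (population 10, 10 generations, crossover 0.8, mutation 0.2) or
simulated annealing (T from 1.0 to 0.1, α = 0.9, 5 proposals per
temperature, acceptance `exp(ΔG/T)` for deteriorations). The fitness of a
candidate threshold is the recording-level geometric mean `sqrt(Se · Sp)`:
a recording counts as predicted-FALL when the detector fires at least once.
No classifier sits in the tuning loop — a classifier-in-the-loop fitness
would be underdetermined (which family, which folds?) and far costlier.

Scheduling of the GA operators is implemented as **one exclusive draw per
individual per generation**: crossover with probability 0.8, otherwise
mutation with probability 0.2. With these defaults the two probabilities
sum to one, each individual costs exactly one fitness evaluation per
generation, and a run costs exactly `pop × (generations + 1) = 110`
evaluations; sequential independent draws would make the cost stochastic
(up to double) for no search benefit. Mutation uses a zero-mean Gaussian
with σ = 0.05 g — about 3% of the search range, small enough to act as a
local refinement consistent with tight clustering of tuned thresholds —
clamped to the range, and replaces the current individual unconditionally
to preserve diversity. Because of that unconditional replacement, the
returned optimum is the **best threshold ever evaluated**, not the final
population's best. Ties on the (frequently flat) fitness plateau resolve to
the **lowest** tied threshold: among equally fit candidates the most
sensitive one is kept, because a missed fall is the costly error. SA costs
`1 + 5 × 22 = 111` evaluations with the default cooling schedule.

Single runs of either algorithm are local (SA especially: a σ = 0.05
random walk explores only a neighbourhood of its random start), so
`tune_threshold()` runs the optimiser repeatedly — 10 runs by default,
matching standard repeated-runs practice — and reports the median of the
per-run best thresholds, which is also what `run_pipeline()` uses.

## Evaluation

`classification_metrics()` computes accuracy, Cohen's kappa, sensitivity,
specificity, precision and `G = sqrt(Se · Sp)` from a confusion matrix.
Kappa uses the standard normalised form, `(p0 − pe)/(1 − pe)` with
`p0 = (TP + TN)/N` and
`pe = [(TP+FN)(TP+FP) + (TN+FP)(TN+FN)]/N²`. Published formulations of the
agreement terms sometimes omit the `1/N` and `1/N²` normalisations as a
typesetting loss; only the normalised form reproduces published kappa
columns from their confusion matrices, and the package's regression tests
pin exactly that. Degenerate ratios (0/0) surface as `NaN` with a warning
rather than a silent 0 — except inside optimiser fitness, where the
documented 0 convention applies.

Cross-validation is **participant-wise** everywhere: `make_folds()` builds
10-fold, 5×2 (five repeated half/half splits) and 15% hold-out plans over
participant ids, and all of a participant's recordings follow the
participant. The hold-out reserves `ceiling(0.15 n)` participants per
source dataset. End-to-end validation walks each held-out recording
through detection, extraction and prediction; a recording is declared FALL
when *any* of its detected peaks is classified FALL (the multiplicity rule
is unstated in the published pseudocode; any-peak is the conservative
reading for a detector whose purpose is raising alarms). With an oracle
that labels every peak FALL, `validate_end_to_end()` reduces exactly to
recording-level peak detection — a property test that ties the modules
together.

Of the four classifier families, the neural network (`nnet`, single hidden
layer, softmax) and Gaussian-kernel SVM (`kernlab`, `sigma`/`C`
parameterisation) are standard. The tree and rule-list families stand in
for proprietary boosted-tree/rule learners: `TREE` is a committee of
`trials` CART trees (first on the full data, the rest on bootstrap
resamples, majority vote), and `RULES` distils each committee tree into an
ordered conjunctive rule list (rules sorted by training purity, then
brevity; majority-class default). They honour the same contract — train,
predict, grid-search — without claiming bit-compatibility with any
commercial learner.

## The synthetic-data generator

`generate_fall()` synthesises the magnitude directly (every downstream
computation consumes magnitude only; a random fixed-orientation 3-axis
decomposition is available for format tests): baseline 1 g, a 0.5 g dip for
300 ms, a linear 80 ms rise to a 3.5 g apex, an exponential settle starting
at 2.5 g (below the detection threshold, so with zero noise the apex is
provably the unique detected peak and ground truth equals detector output
exactly), and i.i.d. Gaussian magnitude noise (σ = 0.05 g by default)
clipped at zero. `generate_adl()` covers sitting (baseline), walking
(≤ 0.4 g sinusoid at step frequency), running and jumping (periodic
triangular bursts; jumping defaults to 3.6 g so the negative class
generates genuine false-alarm candidates) and seizure-like shaking
(sustained 6 Hz oscillation). `generate_cohort()` adds per-participant
multiplicative "style" factors, ±20% on impact peak and dip depth, so
cautious participants produce sub-3 g impacts and participant-wise
cross-validation faces real between-subject structure.

What the generator deliberately does **not** emulate: wrist-orientation
effects, arm-protection movements during real falls, walking-then-falling
transitions that shift the anchor windows, and the statistical texture of
real elderly falls — which published comparisons show differ significantly
from simulated ones. Passing tests on this generator therefore demonstrate
the pipeline's internal correctness and its behaviour under the assumed
fall template, not field performance on elderly wearers.

## Dataset comparison

`compare_distributions()` reproduces the standard two-collection feature
comparison: per-feature Shapiro–Wilk normality within each collection
(features are generally non-normal, hence a rank test) and a two-sided
Mann–Whitney–Wilcoxon test between collections — exact enumeration when
both arms have ≤ 20 observations without ties, the tie-corrected normal
approximation with continuity correction otherwise. Raw per-feature
p-values are reported by default (matching how such tables are usually
published); Holm adjustment is a flag. The suite verifies the test holds
its nominal 5% type-I error within [0.03, 0.07] over a thousand null
replicates at n = 30 per arm.

## Problem sizes and numerical choices

The shipped tests exercise: oracle equivalence on 1000 random traces
(detector) and 1000 generated traces (all eight features, tolerance
1e−12); threshold recovery on a 20-recording separable cohort over 10
seeded runs per algorithm with the exact evaluation budgets (110 GA / 111
SA); and the full pipeline on a 20-participant × 10-recording cohort at
mixed 100/50/20 Hz rates — sizes chosen so the whole suite runs in well
under a minute on one core while still crossing every module boundary.
Other conventions: thresholds are validated strictly positive; resampling
is linear interpolation (the simplest defensible choice; no published
statement selects another) with the final original timestamp appended when
the span is not an integer number of target periods; empty window slices
are legal results, not errors; and all randomness flows through explicit
seeds, restored on exit, so no function disturbs the caller's RNG stream.

## Known limitations

* The fall template is phenomenological, not biomechanical; impact shape
  and settle dynamics are stylised.
* Per-user threshold adaptation is out of scope; the tuned threshold is
  population-level.
* The rule-list learner is a faithful stand-in for commercial rule-based
  systems at the contract level only.
* Feature definitions assume the fall interrupts a quasi-stationary
  activity; long walking run-ups can shift `is`/`ie` and would need
  revised anchor definitions.
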