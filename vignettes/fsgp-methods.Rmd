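---
title: "Feature-selecting genetic programming: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feature-selecting genetic programming: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fsgp)
```

## The problem and the model

fsgp targets two-class classification of small, wide feature tables of the
kind consumer EEG hardware produces: 14 channels times 5 spectral-band
summaries = 70 continuous features per sample, a few dozen samples, and a
binary label (positive vs negative emotional state). At that sample-to-feature
ratio most features are noise or redundant, and removing them is as important
as fitting the classifier.

The classifier is a single arithmetic expression tree: internal nodes come
from the function set `{+, -, *, protected /}`, leaves are feature references
or real constants, and a sample is labelled positive iff the tree's output is
`>= 0`. Fitness is training-set classification accuracy. Evolution is
generational with elitism (the single best individual is always copied
forward) and hill-climbing variation operators: crossover and mutation each
retry up to a cap and a child only takes its parent's slot if it is *strictly*
fitter, so the best-of-population fitness never decreases under plain
evolution.

Feature selection happens inside the same run, in three phases:

1. **Weighting (first half of the run).** In every generation, the
   classifiers whose fitness is strictly above the population mean (the
   "above-average" set, Cgaa) are walked, and every feature-terminal
   occurrence adds one to that feature's weight. All weights start at zero.
2. **Partition and purge (midpoint).** The mean weight over the *full*
   feature set splits features into a kept subset **Fso** (weight strictly
   above the mean) and a purged subset **Fno**. Every tree in the population
   is then rewritten: each Fno terminal is replaced by a randomly drawn Fso
   feature, re-evaluating the tree per draw, keeping the first strictly
   improving draw or, failing that, the best draw found. The Fno terminal is
   replaced unconditionally, so the purged population contains no Fno
   reference at all.
3. **Plain evolution (second half).** After the purge, mutation draws fresh
   feature terminals only from Fso, so purged features cannot re-enter
   through new subtrees (crossover only recombines existing, already purged
   material). The distinct features referenced by the final best classifier
   are the selected feature set.

The run stops the moment any individual reaches training accuracy 1.0, or
when the evaluation budget is exhausted (never more than one generation
over).

## Budget accounting and the midpoint

The unit of computational cost is one **fitness evaluation** — a single
computation of a tree's training accuracy. Every evaluation counts against
the budget: initial-population evaluations, every hill-climbing retry, and
every purge-time candidate draw. A generation therefore costs a multiple of
the population size (typically 5–8x with the default retry cap of 10), and
the number of generations a budget buys is an emergent quantity, not
`budget / population_size`.

Because of this, "the first half of the run" is defined in budget units: the
weighting phase lasts until the evaluation counter reaches half the budget,
and the partition/purge step fires once, at the end of the first generation
where that happens. Defining the midpoint in planned-generation units instead
would place it beyond the end of the run whenever retries are charged, and
the purge would never execute.

Two consequences are worth knowing. First, the purge is a forced rewrite:
when no improving replacement exists, the best replacement found is adopted
even if it loses fitness, so the population best may dip at exactly the
replacement generation (and nowhere else). The reported best classifier is
the best individual seen *from the purged population onward*, which keeps
the selected features inside Fso and matches the intent of running the life
cycle to completion after selection. Second, on easily separable training
sets a run may hit accuracy 1.0 before the midpoint; the run then ends
without a purge and is indistinguishable from plain GP — the algorithm never
pays for selection it did not get to perform.

## Parameters

| Parameter | Default | Notes |
|---|---|---|
| `population_size` | 100 | generational, constant size |
| `p_crossover` / `p_reproduction` / `p_mutation` | 0.60 / 0.20 / 0.20 | per-slot operator draw; crossover fills two slots |
| `init_min_depth` .. `init_max_depth` | 5 .. 10 | ramped half-and-half depth ramp |
| `max_tree_depth` | 17 | hard cap on evolved trees (Koza's convention) |
| `tournament_size` | 7 | with-replacement tournaments; ties favour smaller trees |
| `evaluation_budget` | 80000 | total fitness evaluations; the weighting phase ends at half |
| `hc_max_retries` | 10 | attempt cap per hill-climbing operator application and per purge draw |
| `function_set` | `+ - * /` | `/` is protected: denominator within `1e-9` of zero (or a non-finite quotient) yields 1 |
| `constant_range`, `constant_prob` | `[-1, 1]`, 0.1 | ephemeral constants, pre-rounded to 6 significant digits so serialization round-trips exactly |
| `classification_threshold` | 0 | output `>= 0` means positive |
| `weight_per_tree` | `FALSE` | occurrence counting; `TRUE` counts presence once per tree |
| `weight_average` | `"all"` | mean weight over all features; `"nonzero"` raises the bar |

The evolutionary parameters (population, operator probabilities, depth ramp,
the 80000-evaluation default budget) are the conditions of the motivating
EEG experiments. Where that source was silent we used field conventions and
made them configurable: the Koza function set and depth cap, tournament
selection of size 7, sign thresholding at zero for a single-tree binary
classifier, ephemeral constants in `[-1, 1]`, and a retry cap of 10 giving
the hill-climbing loops a guaranteed exit. Structural diversity at
initialization means *no two trees share a canonical serialization*;
semantic equivalence (e.g. `(+ f1 f2)` vs `(+ f2 f1)`) is deliberately not
detected.

Data-side defaults: stratified hold-out splitting with
`|train| = floor(0.8 n + 0.5)` (largest-remainder allocation per class), and
z-scoring of all features by *training* statistics before evolution.
Standardization matters because constants live in `[-1, 1]`: commensurate
feature ranges keep constant/feature comparisons meaningful. Both are
togglable.

## The synthetic benchmark and its oracle

The generator emulates the shape of the private study data without
pretending to be EEG: `n_samples = 45`, 70 features named
`<channel>_<band>`, labels Bernoulli(0.5), every feature i.i.d.
`N(0, noise_sd)` except a known informative subset whose class-conditional
means sit at `+/- effect_size / 2` (default: 8 informative features at
effect size 2). Optional redundant features are correlated copies of a
source column. For k independent informative features at balance 0.5 the
Bayes accuracy has the closed form `pnorm(sqrt(k) * effect / (2 * sd))` —
about 99.8% for the default benchmark, with ~84% achievable from any single
informative feature. That gap is what makes the benchmark informative: a
feature-blind search can reach decent accuracy on noise features by
overfitting 36 training samples, while recovering truly informative features
is rewarded on the held-out 9.

What the generator does *not* model: participant-level clustering (the real
data's samples are not exchangeable across subjects), non-Gaussian
band-power distributions (real band powers are right-skewed), channel
covariance, and label noise. Passing recovery tests on this benchmark
therefore shows the selection mechanism works where ground truth is known —
it does not certify accuracy figures on real EEG.

## Numerical and degenerate-case choices

* **Protected division** returns 1 when `|denominator| < 1e-9` or the
  quotient overflows; a non-finite value surviving to the root (e.g.
  `Inf - Inf` from products of large subtrees) is clamped to 0, so tree
  outputs are always finite.
* **Constant serialization** is exact by construction: constants are drawn
  uniformly then rounded to 6 significant digits, and `%.6g` printing
  round-trips those doubles bit-for-bit through the s-expression parser.
* **Degenerate weight ledger** (no above-average classifier ever observed,
  so all weights are zero): the driver warns, skips the purge, and continues
  as plain GP rather than partitioning on noise.
* **All-equal weights**: no feature clears the strict mean cutoff, so the
  partition falls back to keeping the maximal-weight features (= all of
  them), purging nothing.
* **Constant training columns** standardize to zero rather than dividing by
  a zero standard deviation.
* **Tie-breaks**: tournament and elitism ties go to the smaller tree
  (parsimony pressure costs nothing), then uniformly at random / first
  encountered, respectively.
* **Mann–Whitney**: exact two-tailed p (via the enumerative null
  distribution) when the combined sample size is at most 16 and there are no
  ties; otherwise a normal approximation with midranks, tie correction and
  continuity correction. Identical samples yield p = 1.

## Problem sizes used by the test-suite experiments

The packaged experiments are sized for a desk-scale laptop run while keeping
the study's structure: the recovery benchmark uses the default 45-sample
table with a 20000-evaluation budget over 10 paired seeds (FSGP vs the
plain-GP baseline); purge-completeness and monotonicity audits use 20 runs
at a 5000-evaluation budget on a 200-sample, effect-size-1 table (hard
enough that no run terminates before the midpoint, so the purge always
fires). The weighting/purge machinery is identical at every budget; only
the number of generations changes.

## Known limitations

* A single expression tree is a low-capacity classifier; with 36 training
  samples it routinely reaches training accuracy 1.0, which both triggers
  early termination (sometimes before the purge) and caps how much the
  embedded selection can show on easy problems.
* Feature weights measure *presence in above-average classifiers*, which is
  confounded with tree size early in a run; the strict above-mean cutoffs
  (for Cgaa and for Fso) are the only guards against drift.
* The purge is one-shot. Features that become useful only in combination
  with post-purge material cannot return.
* The evaluation budget is the only cost model; wall-clock per evaluation
  grows with tree size, which the depth cap bounds only loosely.
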