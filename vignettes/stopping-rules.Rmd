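---
title: "Dispersion-based stopping rules for regression random forests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dispersion-based stopping rules for regression random forests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stoprf)
```

## The model

A regression random forest averages `ntree` CART regression trees, each
grown on a bootstrap resample (size $n$, with replacement) of the training
data, with `mtry` candidate features drawn uniformly without replacement at
every node.  Each tree partitions feature space by recursive binary splits;
a leaf predicts the mean outcome of the in-bag observations it holds, and
the forest prediction is the unweighted mean over trees.

Splits are chosen to maximise the reduction in the within-node sum of
squared errors,
$$\Delta = \mathrm{SSE}(\text{parent}) - \mathrm{SSE}(\text{left}) -
\mathrm{SSE}(\text{right}),$$
over all candidate features and all thresholds at midpoints of adjacent
distinct feature values.  How long the recursion runs is governed by a
stopping rule, and that choice is the subject of this package.  Five rules
are available, any combination of which may be enabled
(`stopping_control()`); a node is made terminal as soon as **any** enabled
rule triggers:

| rule | parameter | semantics |
|---|---|---|
| variance | `theta_variance` $\in [0,1]$ | halt when $\mathrm{Var}(y_{\text{node}}) \le \theta \cdot \mathrm{Var}(y_{\text{train}})$ |
| range | `theta_range` $\in [0,1]$ | halt when $\mathrm{range}(y_{\text{node}}) \le \theta \cdot \mathrm{range}(y_{\text{train}})$ |
| intercentile range | `theta_icr` $\in [0,1]$, `icr_centile` $= X$ | halt when $\mathrm{ICR}_X(y_{\text{node}}) \le \theta \cdot \mathrm{ICR}_X(y_{\text{train}})$ |
| parent size | `min_parent` $\ge 2$ | halt when the node holds fewer than `min_parent` observations |
| leaf size | `min_leaf` $\ge 1$ | a *split constraint*: splits leaving a child below `min_leaf` are invalid |

$\mathrm{ICR}_X$ is the intercentile range $[X, 100-X]$, the difference
between the $(100-X)$th and $X$th percentiles; $X = 10$ and $X = 25$ are the
interesting cases in practice.  The dispersion rules express a node's
remaining outcome spread as a proportion of the spread *in the full training
set*: a node whose outcome dispersion is already a small fraction of the
total has little left to gain from splitting.  Because they are ratios of
identically computed statistics, the rules are invariant to shifting or
rescaling the outcome.

The parent- and leaf-size rules are deliberately not equivalent.  Requiring
leaves of size at least $n$ forces every split parent to hold at least $2n$
observations, but a parent-size limit of $2n$ still admits splits as
lopsided as $1/(2n-1)$.  The leaf rule therefore acts on candidate splits
(a node whose every split would violate it becomes terminal), while the
other four act on the node before any split is attempted.  This asymmetry
is visible in the API: `node_halt()` reports the halting rules, and
`split_respects_leaf_size()` the split constraint.

## Conventions that pin the procedure down

Several details are left open by the general description above; the package
fixes them as follows, and the test suite asserts each one.

* **Variance divisor.**  Population variance (divide by $n$).  The rule
  compares a ratio of variances, so the choice cancels as long as node and
  total use the same divisor; they share one compiled routine here.
* **Percentiles.**  Linear interpolation between order statistics (the
  "type 7" convention: rank $h = (n-1)q$, zero-based, interpolated).  The
  definition is centralised in one routine used by both the tree grower and
  `outcome_summary()`, so it can be swapped in one place.
* **Non-strict comparisons.**  All dispersion halts use $\le$, which gives
  both limits exact meaning: $\theta = 0$ halts exactly the constant-outcome
  nodes, and $\theta = 1$ halts a node whose statistic equals the training
  total.  Because node and total statistics go through the same code path,
  a tree grown directly on the training sample is root-only at
  $\theta = 1$, bit-exactly.
* **Bagging caveat.**  In a bootstrap-resampled tree the root holds the
  in-bag multiset, whose variance (and intercentile range) can *exceed* the
  full-training value; only the range is guaranteed not to.  So in a bagged
  forest `theta_range = 1` forces every tree to a root-only stump, while
  `theta_variance = 1` merely comes close.  The reference ("total dataset")
  statistics are deliberately computed once, on the full un-bootstrapped
  training outcome.
* **Tie-breaks.**  Split candidates are scanned in ascending (feature
  index, threshold) order, and a candidate replaces the incumbent only if
  its criterion exceeds it by a relative tolerance of $10^{-9}$.  Exact
  ties — common with few-valued features and rounded outcomes — therefore
  resolve to the lowest feature index and smallest threshold, independent of
  floating-point summation order.  Splits with zero SSE reduction are still
  taken when they are the best valid candidate; termination is guaranteed
  because children are strictly smaller.
* **Routing.**  Prediction routes a value equal to the threshold to the
  left child.
* **maxnodes.**  Counts *terminal* nodes and is enforced during
  breadth-first (FIFO) expansion: a node becomes a leaf if splitting it
  would push the terminal count over the cap.
* **Randomness.**  All randomness flows from the `seed` argument through an
  internal splitmix64 generator; fits are bit-reproducible and leave the
  session RNG untouched.  Each tree's bootstrap draw gets its own stream
  keyed by (seed, tree index), and each node's feature draw is keyed by the
  node's *path* from the root rather than by expansion order.  The path
  keying is what makes the pruning property exact: tightening a halt
  threshold removes subtrees without re-randomising the feature draws of
  surviving nodes, so a tighter threshold can never yield a larger tree.
  No such guarantee is possible for `min_leaf`, which changes *which* split
  is chosen; its own invariant (every leaf at least `min_leaf`) is what the
  tests assert instead.

## Evaluation and tuning

Prediction error is the weighted mean square prediction error
$$\mathrm{MSPE} = \frac{\sum_i w_i (y_i - \hat y_i)^2}{\sum_i w_i},$$
with unit weights by default.  Weights exist for survey data (e.g. sampling
weights attached to health-examination records) and enter *only* here —
never in bootstrap sampling or split selection.

`cv_mspe()` implements $k$-fold cross-validation (default tenfold) with a
seeded uniform fold assignment.  The pooled form above is computed over all
folds jointly (sum of weighted squared errors over total weight), which is
exact under unequal fold sizes, rather than averaging per-fold MSEs.

`tune_stoprf()` sweeps one rule's threshold over a grid with every other
rule disabled, and reports the minimum MSPE (minMSPE) and its argmin, ties
going to the smaller threshold.  The default grids are

* parent sizes $\{2, 5, 10, 25, 50, 100\}$,
* leaf sizes $\{1, 2, 5, 10, 25, 50\}$,
* dispersion proportions $\{0.001, 0.005, 0.01, 0.05, 0.1, 0.2, 0.5\}$,

chosen to bracket the defaults common in packaged implementations (leaf
size 5 is the usual regression default).  The fold partition is shared
across the grid, and each (grid point, fold) forest receives its own
deterministically derived seed, so sweep curves are comparable and
reproducible.  `relative_excess()` turns a rule-by-dataset matrix of MSPE
values into percentage excess over each dataset's best rule, the form in
which the rules are most easily compared.

## Synthetic generators, and what passing tests show

`gen_piecewise()` draws one uniform feature and a step-function outcome
with Gaussian noise: with zero noise the true tree is known exactly, which
tests split recovery, and with noise it gives a realistic tuning target.
`gen_friedman1()` is the standard nonlinear benchmark
$y = 10\sin(\pi x_1 x_2) + 20(x_3 - 0.5)^2 + 10 x_4 + 5 x_5 + \varepsilon$
with five inert features, exercising `mtry` and multi-feature splits.
`gen_oracle_suite()` produces tiny datasets (at most 30 rows, 4 features,
mixed continuous and few-valued columns, forced outcome ties) on which the
compiled grower is compared node-for-node against an independent exhaustive
CART written in plain R.

These generators emulate known tree structure and controlled noise; they do
not emulate heavy-tailed outcomes, correlated or high-dimensional features,
survey design, or missingness patterns of real data.  Tests passing on them
establish the *mechanics* — split optimality, halting semantics,
reproducibility, the evaluation arithmetic — not performance claims on any
particular real dataset.

The package also ships a previously reported benchmark table
(`benchmark_mspe()`): minimum cross-validated MSPE for five public
regression datasets (NHANES glycohemoglobin, Tasmanian Abalone, Boston
Housing per-capita crime rate, Los Angeles ozone, MIT servo rise time)
under all six tree-limitation methods.  Of those datasets only Boston
Housing is bundled with an installed R package (`MASS::Boston`, outcome
`crim`, 13 features, `mtry = 7`), so it is the one used for desk-scale
reproduction: `scripts/acceptance.R` reruns the leaf-size and parent-size
sweeps at `ntree = 1000`, `maxnodes = 1000`, tenfold CV.  Reproduced minima
land within roughly ten percent of the reported values and preserve the
qualitative finding (leaf-size limiting beats parent-size limiting there);
exact agreement is not expected, since fold assignment, threshold grids and
RNG all differ from the original runs, and minimum-over-grid values on a
heavy-tailed outcome carry several units of cross-validation noise.

## Problem sizes used in the checks

The shipped tests grow forests of 8–300 trees on 10–250 synthetic
observations for the mechanical properties, 50 oracle datasets of up to 30
rows for the exhaustive-search comparison, and two full Boston Housing
sweeps (6 grid points × 10 folds × 1000 trees each) for the reproduction —
a few minutes end to end on one core.  The compiled grower fits 1000 trees
on ~500 rows in about a second, so full-size analyses of datasets like
those in the benchmark table are routine.

## Known limitations

* Categorical features must be numerically coded by the caller; splits
  treat the codes as ordered (the loader enforces all-numeric input).
* Rows with missing values are dropped at load with a reported count; no
  imputation or surrogate splits.
* No out-of-bag error machinery: evaluation is by held-out test set or
  cross-validation.
* Weights affect evaluation only; weighted bootstrap or weighted split
  criteria are out of scope.
* Hold-out evaluation with the NHANES-style train/test split is supported
  (`holdout_mspe()`, `check_schema()`), but the survey structure beyond a
  single weight column (strata, PSUs) is not represented.

```{r example}
d <- gen_piecewise(150, noise_sd = 1, seed = 7)
sw <- tune_stoprf(d, rule = "variance", ntree = 50, k = 10, seed = 7)
sw
```
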