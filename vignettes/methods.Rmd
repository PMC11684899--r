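---
title: "Overestimation-adjusted multi-objective feature selection: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Overestimation-adjusted multi-objective feature selection: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moadjust)
```

## The problem and the model

Wrapper feature selection scores candidate feature panels by training and
cross-validating a predictive model on each one. When a multi-objective
genetic algorithm explores thousands of panels and returns the apparent
Pareto front, the front's cross-validated fitness is biased upward: the
solutions were selected *because* their estimates were high, so part of
each estimate is noise that will not replicate on new samples (the
winner's curse). `moadjust` treats this overestimation as a learnable
quantity and corrects it during the optimization itself.

The dual-stage wrapper works on any list of objectives that are maximized
and normalized to $[0,1]$:

1. **Collect evidence.** Partition the training data into `k_outer` folds.
   On each fold's training part run a reduced-budget genetic algorithm;
   measure every solution of the fold's front on the fold's left-out part.
   The gap between a solution's inner-CV fitness and its left-out fitness
   is its observed overestimation.
2. **Learn the bias.** For each objective, regress the overestimation on
   three meta-features of a solution: its inner-CV fitness, the bootstrap
   standard deviation of that fitness, and the number of features in the
   panel. Samples are weighted by the partial derivative of the fold
   front's hypervolume with respect to that solution and objective,
   rescaled to sum to one per fold: solutions with a large marginal
   contribution to the front (the ones a user would actually pick) drive
   the fit. The loss is the weighted absolute error wherever the backend
   allows it, because the effect of a small fitness error on the
   hypervolume is approximately linear.
3. **Optimize with corrected eyes.** Re-run the main genetic algorithm on
   all training data, with each objective replaced by
   $\mathrm{clip}(\text{fitness} - \widehat{\text{overestimation}},\ 0,\ 1)$.
   The returned front's reported fitness is this adjusted expectation; the
   final models are refit on all training samples, so no data is withheld.

### Estimation-error metrics

Let $X$ be the $n \times m$ matrix of train-side fitness of a solution
set and $X'$ the matching fitness measured on new samples. With the
reference point at the origin and the hypervolume $H(\cdot)$:

* the **cross-hypervolume** $\mathrm{CHV}(X, X') = H(\upsilon(X, X'))$
  applies a cross-function entrywise; any $\upsilon$ with
  $\upsilon(x,x) = x$ is admissible and the default takes the test value
  (clipped to $[0,1]$), so the CHV is the test-side hypervolume of the
  train-selected set;
* the **multi-objective performance error** is
  $E = \lvert H(X) - \mathrm{CHV}(X, X') \rvert$;
* the **Pareto delta** is
  $P_\Delta = \frac{1}{m} \sum_{j=1}^m \sum_{i=1}^n
  \lvert x_{ij} - x'_{ij} \rvert \, \partial H / \partial x_{ij}$,
  defined as exactly 0 for $n = 0$ or $m = 0$. Unlike $E$, opposite-sign
  errors cannot cancel in $P_\Delta$, and it weights each solution's
  error by how much that solution actually shapes the front.

## Tunable parameters

| Parameter | Default | Why |
|---|---|---|
| `k_inner` (inner CV folds) | 5, stratified | the field's convention; pooled out-of-fold predictions are scored once, which is stabler than averaging per-fold metrics when folds hold only a handful of samples |
| `B` (bootstrap resamples) | 100 | the SD of the fitness is estimated by resampling the pooled (prediction, truth) pairs and re-scoring — no model refits, so it stays affordable inside a GA evaluation; 100 resamples put the SD's own noise well below the fitness noise |
| `k_outer` (stage-1 folds) | 3 | each stage-1 run must itself be a full GA; 3 folds give three independent overestimation measurements at two-thirds training size while keeping stage 1 about as expensive as the final run |
| `population_size`, `generations` | 20, 10 | desk-scale defaults; the tuning optimizer uses half of each, which bounds stage-1 cost at roughly the cost of the main run |
| `mutation_strength` | 1 | one expected feature removal and one expected addition per offspring, independent of panel size, so small panels are not shredded |
| `crossover_rate` | 0.9 | uniform crossover on the feature masks; standard for binary-coded NSGA-style GAs |
| `init_max_features` | 30 | initial panels draw their size uniformly in 1..30; biomarker panels of interest are small, and mutation can still grow them |
| `clone_retry_budget` | 3 | a duplicated offspring mask is re-mutated up to 3 times, then dropped: duplicate panels waste evaluations and distort selection pressure |
| root-leanness `cap` | 100 | parsimony fitness $\max(0, 1-\sqrt{k/\text{cap}})$: 1 for an empty panel, 0 at 100 features; the square-root shape keeps selection pressure strong among small panels, where a one-gene difference matters most |
| adjuster kinds | `zero`, `dummy`, `ptree`, `rfreg`, `svr`, `rsvr` | each is an isolated factory so a different regressor configuration can be swapped in without touching the pipeline |

## Numerical choices

* **Reference point and normalization.** All objectives live in $[0,1]$
  with the hypervolume reference fixed at the origin. Values outside the
  unit interval are a contract violation, never silently clipped inside
  the hypervolume code; the clipping of adjusted fitness happens in the
  adjusted objective.
* **Exact hypervolume and derivatives, $m \le 4$.** Two objectives use a
  sort-and-sweep; three and four use a recursive dimension sweep over
  slices. The gradient entry $(i,j)$ is the $(m{-}1)$-dimensional measure
  of box $i$'s exclusive cross-section at height $x_{ij}$, computed as
  the box's face volume minus the hypervolume of its intersections with
  all boxes reaching strictly higher in objective $j$.
* **Ties and duplicates.** At tied coordinates the *right* partial
  derivative is used (the exclusive-slice measure above). Rows that
  exactly duplicate an earlier row carry zero derivative — the first copy
  takes the whole contribution — matching the non-dominated front's rule
  of collapsing duplicate fitness rows to the lowest index. Both rules
  exist purely to make results deterministic.
* **Degenerate inputs.** Empty fronts have hypervolume 0; the Pareto
  delta of zero solutions or zero objectives is exactly 0; an all-zero
  gradient column yields uniform sample weights; a fold with an empty
  front is skipped with a warning (all folds empty aborts).
* **Weighted median.** The constant (`dummy`) adjuster predicts the
  weighted median of the observed overestimations — the exact minimizer
  of the weighted absolute error; when the minimizer is an interval, the
  lowest sample value is returned for determinism. The median rather
  than the mean keeps the constant consistent with the absolute-error
  loss used everywhere else.
* **Weights in SVR.** The epsilon-SVR backend accepts no per-observation
  weights, so the HV-derivative weights enter by deterministic integer
  replication of rows (about one replica per $1/\max(n,50)$ of weight
  mass); `rsvr` additionally uses the exact weights when scoring its
  random search by cross-validated weighted absolute error.
* **Pruning the tree adjuster.** The regression tree is grown with
  squared-error splits (the only criterion the backend offers), then
  cost-complexity pruned by choosing the complexity parameter that
  minimizes weighted 5-fold-CV *absolute* error, restoring the intended
  loss at the model-selection level.
* **Determinism.** Every stochastic step takes an explicit seed:
  per-fold GA seeds derive from the master seed plus the fold index, and
  each feature set's evaluation seed derives from a hash of its indices,
  so fitness values do not depend on evaluation order and identical runs
  are byte-identical in serial mode. Evaluations are cached per feature
  set; the hall of fame records every evaluated solution and the
  returned set is the non-dominated front of all of them.
* **Fallbacks.** A failed inner-model fit predicts the majority class
  (classification) or zero risk (survival) for that fold, with a logged
  warning; an undefined metric resample in the bootstrap is redrawn (up
  to $10B$ attempts); a c-index with no comparable pairs returns 0.5
  with a warning.

## The synthetic data generator

`generate_classification()` plants `n_informative` features with
class-dependent Gaussian mean shifts (`separation`, in noise-SD units,
default 2) among pure-noise features, optionally exponentiated to a
positive, log-normal-like expression scale. `generate_survival()` draws
exponential event times with a log-hazard linear in the informative
features and independent uniform censoring whose upper bound is solved
numerically to hit the target censoring fraction in expectation. Both are
deterministic given a seed and expose the ground truth (informative
indices, true risk score).

The generator reproduces the regime that makes overestimation adjustment
necessary — many features, few samples, a small informative subset — and
the package's tests verify on it that inner-CV estimates of GA-selected
panels exceed held-out performance on average. It does *not* emulate
gene–gene correlation blocks, batch effects, heavy-tailed counts, or
label noise; tests passing on it show the machinery is correct and the
bias is learnable in the Gaussian-shift world, not that any particular
adjuster wins on a given real cohort.

## Design decisions that were genuinely open

* **The reference optimizer.** The spec of the wrapped optimizer is an
  interface (anything with `optimize(objectives, data)` semantics); the
  bundled implementation is an NSGA-II-style GA — non-dominated sorting
  with crowding-distance tie-breaks — plus clone handling and the
  size-neutral mutation above. For two or three objectives crowding
  distance is adequate; reference-direction niching would matter only
  beyond that, and any other optimizer can be plugged in.
* **Stage-1 test fitness** of a solution is the metric of the model
  trained on the fold's full training part, measured once on the fold's
  left-out samples — no nesting beyond the inner CV that produced the
  original fitness.
* **Stratification.** Classification folds stratify on the class label,
  survival folds on the event indicator; a stratum smaller than `k`
  falls back to unstratified folds with a warning.
* **Cross-function.** The default $\upsilon$ simply takes the test
  coordinate; it satisfies $\upsilon(x,x)=x$, which all identities used
  in the tests rely on, and is replaceable by any user function of
  (train, test) for variants that blend the two coordinates.

## Problem sizes used by the test suite

Unit tests run on fronts of up to 50 solutions and datasets of 20–60
samples with 10–60 features. The end-to-end comparison uses the
package's chosen study condition: 60 samples, 500 features, 3 informative,
a GA of population 20 for 10 generations, 3 evaluation folds, five seeds.
Exact hypervolume oracles (inclusion–exclusion, finite differences,
Monte-Carlo volume) cover up to 4 objectives.

## Known limitations

* **The moving-target effect at small n.** The adjusters are trained on
  fronts produced from `k_outer`-fold training parts — two-thirds of the
  available samples at the default. With very small cohorts (tens of
  samples) the stage-1 fronts overfit more than the final full-data run
  does, so the learned correction tends to be too large, and the
  adjusted expectation can undershoot. The package's own end-to-end test
  measures exactly this: at 60 samples the constant adjuster lowers the
  Pareto delta versus the unadjusted baseline only in a minority of
  seeds, while halving it on favorable seeds (as in the README example).
  The adjustment also changes the optimizer's exploration path, so the
  solutions being adjusted drift away from the distribution the
  regressors were trained on. Both effects shrink as cohorts grow toward
  the hundreds-of-samples regime the method targets.
* **Hypervolume dimensionality.** Exact computation and derivatives are
  implemented for at most 4 objectives; the algorithms are exact but not
  asymptotically optimal, sized for fronts of tens of solutions.
* **Serial determinism only.** Parallel evaluation is not implemented;
  determinism guarantees assume serial execution.
* **Inner learners are fixed-form.** Gaussian naive Bayes, linear SVM
  and Cox proportional hazards, without hyperparameter tuning; the
  learner interface (`fit`/`predict`) accepts replacements.
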