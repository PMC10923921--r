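---
title: "Post-projection calibration: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Post-projection calibration: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the model, its assumptions, the tunable parameters, the synthetic data
used to validate it, and the numerical and design choices made where the
method leaves room.

## The problem

An experimental retention time (RT) is tied to the chromatographic method
(CM) that produced it. Two reversed-phase methods with the same mobile
phase chemistry differ mostly by a smooth monotone time warp (gradient
shape, column dimensions, flow), which a one-dimensional regression of RT
on RT captures well. Once the mobile-phase additives differ, however, a
subset of molecules changes *elution order* — "outgeneral" retention
behavior — and no smooth 1-D map of RTs can represent a swap. Direct RT
projection therefore degrades exactly when it would be most useful:
transferring a public library or QSRR predictions onto an unrelated local
method.

Post-projection calibration does not try to model the order changes.
Instead it changes the *reference* against which a projected RT is judged.
A reference input method (ReICM), run locally and chosen to share elution
order with the input method (ICM), provides each unknown an experimental
RT; projecting that RT onto the output method (OCM) gives the
reference-projected RT (RePRT). Both the candidate projection (ICM→OCM)
and the reference projection (ReICM→OCM) are fit on the same calibrants
and therefore share the same systematic distortion; comparing the two
projections cancels it. The residual comparison error is dominated by
measurement noise and GP fit error rather than by LC-setup effects.

Assumptions worth stating explicitly:

- the ICM→ReICM relationship is close to order-preserving (checked by
  `r2_c`, the squared Pearson correlation of calibrant RTs; the automatic
  ReICM choice is the `r2_c` argmax, with lexicographic tie-break);
- calibrants span the RT range and the retention behaviors of the
  molecules of interest — a behavior-blind calibrant set invalidates the
  `r2_b`/`r2_c` quality bands (`quality_estimate()` flags such sets);
- every unknown has an experimental RT in the ReICM. That is the cost of
  the method: one locally run reference method per input library.

## Projection model

`fit_projection()` is a 1-D Gaussian process with a constant mean fitted
jointly with the kernel, a rational quadratic covariance
$k(x,x') = \sigma_f^2\,(1 + (x-x')^2 / (2\alpha\ell^2))^{-\alpha}$,
and additive noise $\sigma_n^2$. The RQ kernel is a scale mixture of
squared exponentials: it accommodates both the flat dead-time region and
the steep mid-gradient part of an elution warp without committing to one
length scale. Hyperparameters maximize the log marginal likelihood by
L-BFGS-B from multiple starts.

Numerical choices, all visible in the code:

- **Standardization.** `x` and `y` are centered and scaled to unit
  variance before fitting; predictions are de-standardized. GP
  hyperparameter optimization is scale-sensitive, and methods run from 10
  to 100 minutes. Tests verify that predictions are invariant to affine
  rescaling of the inputs.
- **Noise floor.** $\sigma_n^2$ is a fitted hyperparameter with floor
  $10^{-6}$ (standardized units). Calibrant RTs are measurements; exact
  interpolation is deliberately unattainable, but the floor is low enough
  that noiseless synthetic data is reproduced to well under 0.01 min.
- **$\alpha$ bounded in $[0.5, 10^6]$.** At small $\alpha$ the RQ kernel
  degenerates into a near-constant long-range covariance with a spike at
  zero distance. With ~35 training points the marginal likelihood can
  prefer that solution — it "explains" structured calibrant scatter by
  interpolating it — while the posterior oscillates wildly between
  calibrants. The lower bound removes this mode; it is an identifiability
  constraint on the kernel family, not a tuning knob. The upper bound
  only matters for the squared-exponential limit, which the tests check
  at $\alpha = 10^6$.
- **Restarts.** Default 5: one fixed unit-scale start plus seeded
  log-uniform draws. The best marginal likelihood wins; per-pair fits in
  the all-pairs validation use 2 restarts (the maps are mild warps and
  the first start nearly always wins; the number of pairs, not fit
  difficulty, dominates runtime there).
- **Predictive sd.** `project()` reports the predictive standard
  deviation of a new observation (latent posterior variance plus noise),
  and flags extrapolation outside the training RT range rather than
  refusing it.

## Error metrics

All transfer errors are expressed relative to the **elution time** of the
OCM, defined as the maximum calibrant RT there. Relative errors on raw RT
explode near the dead time; normalizing by elution time keeps early and
late eluters comparable and makes 10-minute and 100-minute methods
commensurable. `summarize_errors()` reports RMSE and median absolute
error as percent of elution time, plus a *signed* mean error (ME_Ret) as
the bias measure — the mean absolute error is reported separately in
minutes, and a flag switches ME to absolute-mean for sensitivity checks.
`r_squared()` is always the squared Pearson correlation, never a
coefficient of determination of some fit.

## Retention behavior clustering and calibrant selection

`som_cluster()` is a classic online self-organizing map on elution-
normalized RT profiles (each method column divided by its elution time,
so long methods do not dominate distances): rectangular grid (default
5×5, hence up to 25 behavior groups), Gaussian neighborhood, learning
rate and radius decaying linearly over 5000 single-sample iterations, and
a mandatory seed that fixes both prototype initialization and sample
presentation, making runs bit-reproducible. The map is implemented in the
package (~50 lines) because no installed SOM implementation exposes a
Gaussian neighborhood with controlled decay; a brute-force
nearest-prototype oracle validates assignments in the tests. Exact group
memberships are initialization-dependent and not meaningful on their own;
what matters downstream is coverage.

`select_calibrants()` is a deterministic greedy: pass 1 takes each
non-empty group's medoid (profile nearest the prototype), pass 2 adds
molecules that most extend per-method RT-range coverage until the target
size; all ties break lexicographically on molecule id. Calibrant sets are
generated from whatever dataset is at hand rather than shipped as fixed
id lists — any particular published set is reproducible only with its
underlying database, and the selection contract (cover behaviors, cover
the range, exist in every method) is what the rest of the package relies
on. A 35-molecule set is the default study size: large enough to cover
~20+ behavior groups and the full RT range, small enough to measure in
one local run.

## QSRR module

`fit_qsrr()` is a single-hidden-layer perceptron (default 10 hidden
units, linear output) on standardized precomputed molecular descriptors,
trained by `nnet` with L2 weight decay; `reg_strength = "auto"` picks the
decay on an internal seeded 75/25 holdout over a small grid and refits on
all rows. The hidden activation is the logistic sigmoid (`nnet`'s
choice), equivalent to tanh up to an affine reparameterization of the
weights. Descriptor computation is out of scope: the module consumes a
molecules × named-descriptors matrix, drops zero-variance columns with a
message, aligns prediction inputs by column name, and refuses missing
values. A zero-variance RT target short-circuits to a constant predictor.
The regressor contract (fit/predict/seed on a numeric matrix) is
deliberately plain so another tabular regressor can stand in.

## Candidate filtering and ranking

The filter threshold is twice the RMSE_Ret observed for the OCM, so each
method's threshold reflects its own transfer accuracy. An error exactly
at the threshold is *positive*: only errors strictly above it are
rejected. Ranking is by ascending absolute RT difference with
lexicographic candidate-id tie-break — a deterministic total order, so
permuting input rows cannot change a rank. Confusion rates follow the
standard definitions (TPR = TP/(TP+FN), FPR = FP/(FP+TN), TNR = 1−FPR,
accuracy = (TP+TN)/total); unlabeled candidates are excluded with a
message, and unknowns whose candidates are all rejected remain visible in
the output rather than being dropped.

## Synthetic data: what it emulates and what it does not

`generate_dataset()` draws a latent hydrophobicity $u \in [0,1]$ per
molecule and maps it through a per-method monotone sigmoid warp
$t_0 + (T - t_0)\,\mathrm{sigmoid}(a(u - b))$ — dead-time plateau, steep
mid-gradient, late plateau — with warp parameters drawn around
mobile-phase-family means. Elution-order changes between families are
additive (group × family) offsets, zero for general groups and for the
reference family, scaled to the method's retained-time span
(`delta_scale`, default 0.15 — offsets of up to a few minutes on a
45-minute method, the magnitude at which order swaps become visible).
Non-retained molecules sit at the dead time. Offsets that would push a
deterministic RT outside the run are halved with a message; observed RTs
add Gaussian noise (default 0.05 min) and are clipped to $(0, T]$.

Defaults describe the study conditions used throughout the tests and the
acceptance script: 330 molecules, 30 methods, 4 additive families, 25
behavior groups, 8 % non-retained molecules, 30 % outgeneral groups.
Test-time experiments scale down (e.g. 250 molecules × 8 methods for the
cross-family experiment; one ICM per family in the all-pairs validation)
purely to keep the suite brisk; the generator itself is the first-class,
tested module.

What the generator does **not** emulate: physico-chemical retention
(no log Kow → retention mapping, no solvent-strength theory), peak-shape
or signal-level effects, missingness patterns from adduct formation, and
descriptor→RT structure beyond a linear map in the QSRR benchmark.
Passing tests on this generator therefore demonstrate that the pipeline
recovers the structure the method assumes — monotone warps plus
family-level order changes — not that any particular laboratory dataset
will reach the same error levels.

## OCM similarity classes

The all-pairs validation groups output methods into classes A–D by the
distance between additive-family labels declared in the method metadata
(same family → A, one step → B, two → C, three or more → D). The classes
are declared input, not inferred chemistry: with real data the grouping
encodes the analyst's knowledge of which mobile phases are "similar", and
the metadata field is the place to express it.

## Known limitations

- Projections are strictly 1-D RT→RT; no covariates, no chaining through
  more than one intermediate method.
- The ReICM argmax-`r2_c` rule can differ from a curated choice on
  near-ties; the tie-break is deterministic but arbitrary.
- GP marginal-likelihood fitting at n ≈ 35 has local optima; the restart
  scheme plus the $\alpha$ bound handles the modes observed in testing,
  but pathological calibrant geometries can still produce poor fits —
  `r2_b`/`r2_c` and the low-similarity warning are the intended guard.
- The QSRR module's accuracy claims are property-based (recoverable
  synthetic maps); descriptor quality dominates real-world performance
  and is outside the package's control.
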