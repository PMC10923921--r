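# rtcal — post-projection calibration of LC retention times

Retention time (RT) is orthogonal evidence for molecule annotation in
LC–HRMS untargeted analysis, but an RT is only meaningful for the exact
chromatographic method (CM) it was measured on: change the column, mobile
phase, or gradient and both the time scale and — for some molecules — the
elution *order* change. `rtcal` implements **post-projection calibration**,
a method for transferring experimental and predicted RTs between CMs that
stays accurate even when the mobile-phase chemistry differs:

1. **Projection.** Calibrant molecules with known RT in both an input
   method (ICM) and the local output method (OCM) train a 1-D Gaussian
   process (constant mean, rational-quadratic kernel, fitted noise) that
   maps RTs from ICM to OCM.
2. **Reference projection (RePRT).** A locally run reference method
   (ReICM), chosen to share elution order with the ICM, trains a second GP
   onto the same OCM. Each unknown's experimental ReICM RT is projected to
   the OCM, giving its *reference-projected RT* (RePRT).
3. **Calibration.** Candidate RTs projected from the ICM are compared
   against RePRT instead of against the OCM experimental RT. A molecule
   that deviates from the calibrant trend deviates the same way in both
   projections, so LC-setup-specific distortions cancel.

Errors are reported relative to the OCM **elution time** (the maximum
calibrant RT in the OCM): `E_Ret = 100·|pred − ref|/et`, with RMSE_Ret,
MedE_Ret, and the signed ME_Ret as summary statistics. Two squared Pearson
correlations of calibrant RTs diagnose a transfer before it is used:
`r2_b` (ICM vs OCM) tracks projection accuracy and `r2_c` (ICM vs ReICM)
tracks calibration accuracy; `r2_c ≥ 0.992` with a behavior-covering
calibrant set predicts calibration RMSE_Ret below 3 %.

The package also provides:

- SOM classification of retention behavior from multi-CM RT profiles
  (5×5 grid → up to 25 groups: non-retained, weak, general, strong,
  "outgeneral"), and a greedy calibrant selector that covers behaviors and
  the RT range;
- a single-hidden-layer QSRR network (descriptors → RT) for molecules with
  no measured RT in the input method;
- RT-based candidate filtering (threshold = 2 × OCM RMSE_Ret) and ranking,
  with confusion rates (TPR/TNR/accuracy) and N-top-5 summaries;
- a synthetic multi-method RT generator (monotone sigmoid gradient warps,
  mobile-phase family effects that reorder elution, measurement noise) so
  every stage is testable end to end without external data.

Intended users: metabolomics / environmental screening labs that want to
reuse public RT libraries or QSRR predictions on their own LC method.

## Worked example

Simulate an 8-method panel in two mobile-phase families, select calibrants
by retention behavior, and transfer RTs from `CM01` (family 1) to `CM06`
(family 2) with and without calibration:

```r
library(rtcal)

cfg <- synthetic_config(n_molecules = 250, n_cms = 8, n_families = 2,
                        n_groups = 12, seed = 11)
ds  <- generate_dataset(cfg)
w   <- to_wide(ds$rt_table)

som <- som_cluster(normalize_profiles(w), grid = c(3, 4), epochs = 3000, seed = 7)
cal <- select_calibrants(som, ds$rt_table, target_size = 35, name = "B")

sel <- select_reference("CM01", paste0("CM0", 2:4), ds$rt_table, cal)
#> $reicm: "CM02"   $r2_c: 0.9990687

ctx <- build_context("CM01", sel$reicm, "CM06", ds$rt_table, cal, seed = 1)
#> r2_b = 0.989   r2_c = 0.999   elution time = 19.73 min

mols <- rownames(w)
res <- calibrate(ctx, setNames(w[, "CM01"], mols),
                 setNames(w[, sel$reicm], mols),
                 rt_ocm = setNames(w[, "CM06"], mols))

summarize_errors(res$projected_rt, res$rt_ocm, ctx$elution_time)  # before
#>     n elution_time rmse_min rmse_ret mede_ret me_ret mae_min    r2
#> 1 250       19.726    0.459    2.327    1.208 -0.453   0.336 0.995
summarize_errors(res$projected_rt, res$reprt, ctx$elution_time)   # after
#>     n elution_time rmse_min rmse_ret mede_ret me_ret mae_min r2
#> 1 250       19.726    0.123    0.621    0.378 -0.114   0.094  1
```

Calibration cuts the cross-family transfer error almost four-fold
(RMSE_Ret 2.33 % → 0.62 %; median 1.21 % → 0.38 % of the 19.7-min elution
time). The advisory band agrees with the diagnostics:

```r
quality_estimate(ctx$r2_b, ctx$r2_c, "B")$message
#> "calibration RMSE_Ret expected < 3.0%"
```

`run_validation()` repeats this over every (ICM, OCM) pair and pools errors
by OCM similarity class (A–D, declared via the additive families in the
method metadata); `run_annotation()` runs the candidate filtering/ranking
workflow before vs after calibration. A thin command-line wrapper with
`simulate`, `fit-projection`, `project`, `calibrate` and `validate`
subcommands is installed under `inst/cli/rtcal.R`.

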