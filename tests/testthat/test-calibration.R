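test_that("reference selection maximizes calibrant r2 with deterministic ties", {
  # CMB is an exact affine map of CMA; CMC is a noisy scramble
  tab <- tiny_table(n_mol = 10, cms = c("CMA", "CMB", "CMC"))
  w <- to_wide(tab)
  set.seed(2)
  tab_noisy <- rt_table(data.frame(
    molecule_id = rep(rownames(w), 3),
    cm_id = rep(c("CMA", "CMB", "CMC"), each = nrow(w)),
    rt = c(w[, "CMA"], 2 * w[, "CMA"] + 1,
           sample(w[, "CMC"]) + runif(nrow(w)))))
  cs <- calibrant_set("t", sprintf("M%02d", 1:10))
  sel <- select_reference("CMA", c("CMB", "CMC"), tab_noisy, cs)
  expect_equal(sel$reicm, "CMB")
  expect_equal(sel$r2_c, 1.0)

  # exact tie between two affine-mapped candidates -> smaller id wins
  tab_tie <- rt_table(data.frame(
    molecule_id = rep(rownames(w), 3),
    cm_id = rep(c("CMA", "CMB", "CMD"), each = nrow(w)),
    rt = c(w[, "CMA"], 2 * w[, "CMA"] + 1, 3 * w[, "CMA"] + 2)))
  expect_equal(select_reference("CMA", c("CMD", "CMB"), tab_tie, cs)$reicm,
               "CMB")

  # candidates missing calibrant coverage are rejected
  tab_gap <- tab_tie[!(tab_tie$cm_id == "CMB" &
                         tab_tie$molecule_id == "M01"), ]
  expect_error(
    select_reference("CMA", "CMB", rt_table(tab_gap), cs),
    "complete calibrant")
})

test_that("build_context fits both models and records diagnostics", {
  set.seed(41)
  n <- 30
  u <- sort(runif(n, 1, 19))
  tab <- rt_table(data.frame(
    molecule_id = rep(sprintf("M%02d", 1:n), 3),
    cm_id = rep(c("ICM", "REF", "OCM"), each = n),
    rt = c(u, 1.1 * u + 0.3 + rnorm(n, sd = 0.02),
           8 + 12 * plogis(0.5 * (u - 10)) + rnorm(n, sd = 0.02))))
  cs <- calibrant_set("t", sprintf("M%02d", seq(1, 30, by = 2)))
  ctx <- build_context("ICM", "REF", "OCM", tab, cs, seed = 1,
                       n_restarts = 2)
  w <- to_wide(tab)
  ids <- cs$molecule_ids
  expect_equal(ctx$r2_c, r_squared(w[ids, "ICM"], w[ids, "REF"]))
  expect_equal(ctx$r2_b, r_squared(w[ids, "ICM"], w[ids, "OCM"]))
  expect_equal(ctx$elution_time, max(w[ids, "OCM"]))
  expect_false(ctx$low_similarity)

  # ICM-side overrides replace the main model's training inputs only
  ov <- c(M01 = 3.3, M05 = 7.7)
  ctx_ov <- build_context("ICM", "REF", "OCM", tab, cs,
                          calibrant_rt_overrides = ov, seed = 1,
                          n_restarts = 2)
  expect_equal(ctx_ov$main_model$train_x[match(c("M01", "M05"), ids)],
               unname(ov))
  expect_equal(ctx_ov$re_model$train_x, ctx$re_model$train_x)

  # low-similarity reference trips the warning flag
  set.seed(4)
  tab_bad <- rt_table(data.frame(
    molecule_id = rep(sprintf("M%02d", 1:n), 3),
    cm_id = rep(c("ICM", "REF", "OCM"), each = n),
    rt = c(u, sample(u), u + 1)))
  expect_warning(
    ctx_bad <- build_context("ICM", "REF", "OCM", tab_bad, cs, seed = 1,
                             n_restarts = 2),
    "low ICM-ReICM similarity")
  expect_true(ctx_bad$low_similarity)

  # insufficient calibrant coverage is an error naming the missing ids
  tab_small <- rt_table(data.frame(
    molecule_id = rep(c("M01", "M03"), 3),
    cm_id = rep(c("ICM", "REF", "OCM"), each = 2),
    rt = rep(c(2, 3), 3)))
  expect_error(build_context("ICM", "REF", "OCM", tab_small, cs),
               "insufficient calibrants")
})

test_that("identical methods everywhere give near-zero calibrated error", {
  u <- seq(1, 18, length.out = 25)
  ids <- sprintf("M%02d", 1:25)
  tab <- rt_table(data.frame(
    molecule_id = rep(ids, 3),
    cm_id = rep(c("ICM", "REF", "OCM"), each = 25),
    rt = rep(u, 3)))
  cs <- calibrant_set("t", ids[seq(1, 25, by = 2)])
  ctx <- build_context("ICM", "REF", "OCM", tab, cs, seed = 1,
                       n_restarts = 2)
  res <- calibrate(ctx, setNames(u, ids), setNames(u, ids),
                   rt_ocm = setNames(u, ids))
  expect_lt(max(res$err_after_pct), 0.1)
  expect_lt(max(res$err_before_pct), 0.1)
  expect_equal(ctx$r2_c, 1.0)
})

test_that("when the reference method is the output method, calibration is a no-op", {
  # RePRT then projects OCM experimental RTs onto the OCM itself, so the
  # after-error must track the before-error on every molecule
  set.seed(43)
  n <- 40
  u <- sort(runif(n, 1, 19))
  ocm_rt <- 2 + 15 * plogis(0.45 * (u - 9)) + rnorm(n, sd = 0.03)
  ids <- sprintf("M%02d", 1:n)
  tab <- rt_table(data.frame(
    molecule_id = rep(ids, 2),
    cm_id = rep(c("ICM", "OCM"), each = n),
    rt = c(u, ocm_rt)))
  cs <- calibrant_set("t", ids[seq(1, n, by = 2)])
  ctx <- build_context("ICM", "OCM", "OCM", tab, cs, seed = 1,
                       n_restarts = 3)
  res <- calibrate(ctx, setNames(u, ids), setNames(ocm_rt, ids),
                   rt_ocm = setNames(ocm_rt, ids))
  expect_lt(median(abs(res$err_after_pct - res$err_before_pct)), 0.5)
})

test_that("calibrate is equivariant to molecule relabeling and skips partial unknowns", {
  tab <- tiny_table(n_mol = 20, cms = c("ICM", "REF", "OCM"))
  w <- to_wide(tab)
  cs <- calibrant_set("t", rownames(w)[seq(1, 20, by = 2)])
  ctx <- build_context("ICM", "REF", "OCM", tab, cs, seed = 1,
                       n_restarts = 2)
  mols <- rownames(w)
  r1 <- calibrate(ctx, setNames(w[, "ICM"], mols),
                  setNames(w[, "REF"], mols))
  relabel <- setNames(paste0("X", mols), mols)
  r2 <- calibrate(ctx, setNames(w[, "ICM"], relabel[mols]),
                  setNames(w[, "REF"], relabel[mols]))
  expect_equal(r2$projected_rt[match(relabel[r1$molecule_id],
                                     r2$molecule_id)],
               r1$projected_rt)
  expect_warning(
    r3 <- calibrate(ctx, setNames(w[1:5, "ICM"], mols[1:5]),
                    setNames(w[3:8, "REF"], mols[3:8])),
    "skipping")
  expect_equal(r3$molecule_id, mols[3:5])
})

test_that("quality bands are monotone in r2_c and flag limited-behavior sets", {
  expect_equal(quality_estimate(0.99, 0.999)$band, "high")
  expect_match(quality_estimate(0.99, 0.999)$message, "< 3.0%")
  expect_equal(quality_estimate(0.9, 0.97)$band, "moderate")
  expect_equal(quality_estimate(0.9, 0.5)$band, "low")
  qe <- quality_estimate(0.99, 0.999, calibrant_set_name = "E")
  expect_false(qe$reliable)
  expect_match(qe$message, "unreliable")
  expect_error(quality_estimate(1.2, 0.5))
})
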