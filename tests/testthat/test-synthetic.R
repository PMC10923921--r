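test_that("generation is deterministic given the seed", {
  cfg <- synthetic_config(n_molecules = 40, n_cms = 4, n_groups = 5,
                          seed = 8)
  d1 <- suppressMessages(generate_dataset(cfg))
  d2 <- suppressMessages(generate_dataset(cfg))
  expect_identical(d1$rt_table, d2$rt_table)
  expect_identical(d1$truth$delta, d2$truth$delta)
  d3 <- suppressMessages(generate_dataset(
    synthetic_config(n_molecules = 40, n_cms = 4, n_groups = 5, seed = 9)))
  expect_false(identical(d1$rt_table$rt, d3$rt_table$rt))
})

test_that("RTs follow the declared warp model exactly (independent recomputation)", {
  cfg <- synthetic_config(n_molecules = 50, n_cms = 4, n_families = 2,
                          n_groups = 5, frac_outgeneral = 0.5,
                          frac_nonretained = 0, noise_sd = 0, seed = 19)
  ds <- suppressMessages(generate_dataset(cfg))
  w <- to_wide(ds$rt_table)
  tr <- ds$truth
  for (c in seq_len(cfg$n_cms)) {
    wp <- tr$warp[c, ]
    span <- wp$run_time - wp$dead_time
    u <- tr$u[rownames(w)]
    g <- tr$group[rownames(w)]
    expected <- wp$dead_time + span * plogis(wp$a * (u - wp$b)) +
      tr$delta[cbind(g, rep(wp$family, length(g)))] * span
    expected <- pmin(pmax(expected, 1e-3), wp$run_time)
    expect_equal(unname(w[, wp$cm_id]), unname(expected), tolerance = 1e-12)
  }
  # molecules sharing (group, family) share their offset exactly
  og <- which(tr$group_type == "outgeneral")[1]
  mols <- names(tr$group)[tr$group == og]
  expect_gte(length(mols), 2)
  fam2_cm <- tr$warp$cm_id[tr$warp$family == 2][1]
  wp <- tr$warp[tr$warp$cm_id == fam2_cm, ]
  base <- wp$dead_time +
    (wp$run_time - wp$dead_time) * plogis(wp$a * (tr$u[mols] - wp$b))
  offsets <- (w[mols, fam2_cm] - base) / (wp$run_time - wp$dead_time)
  expect_equal(unname(offsets), rep(tr$delta[og, 2], length(mols)),
               tolerance = 1e-9)
})

test_that("a single family without outgeneral groups preserves elution order", {
  cfg <- synthetic_config(n_molecules = 60, n_cms = 5, n_families = 1,
                          n_groups = 6, frac_outgeneral = 0,
                          frac_nonretained = 0, noise_sd = 0, seed = 23)
  ds <- suppressMessages(generate_dataset(cfg))
  w <- to_wide(ds$rt_table)
  for (i in 2:ncol(w)) {
    expect_equal(cor(w[, 1], w[, i], method = "spearman"), 1.0)
  }
})

test_that("family changes degrade calibrant correlation (r2 across vs within)", {
  cfg <- synthetic_config(n_molecules = 100, n_cms = 6, n_families = 2,
                          n_groups = 8, frac_outgeneral = 0.5,
                          frac_nonretained = 0, noise_sd = 0.02, seed = 27)
  ds <- suppressMessages(generate_dataset(cfg))
  w <- to_wide(ds$rt_table)
  fam <- ds$truth$warp$family
  within <- r_squared(w[, which(fam == 1)[1]], w[, which(fam == 1)[2]])
  across <- r_squared(w[, which(fam == 1)[1]], w[, which(fam == 2)[1]])
  expect_gt(within, across)
})

test_that("elution time of any method never exceeds its run time", {
  cfg <- synthetic_config(n_molecules = 50, n_cms = 6, n_groups = 5,
                          seed = 31)
  ds <- suppressMessages(generate_dataset(cfg))
  w <- to_wide(ds$rt_table)
  for (cm in colnames(w)) {
    expect_lte(elution_time(w[, cm]), ds$cm_meta[[cm]]$run_time)
  }
})

test_that("candidate generation labels one true identity and is reproducible", {
  cfg <- synthetic_config(n_molecules = 40, n_cms = 3, n_groups = 4,
                          seed = 37)
  ds <- suppressMessages(generate_dataset(cfg))
  unknowns <- sprintf("M%03d", 1:10)
  cand <- generate_candidates(ds, unknowns, n_per_unknown = 5, icm = "CM01",
                              seed = 2)
  expect_equal(nrow(cand), 50L)
  per <- table(cand$unknown_id, cand$is_true)
  expect_true(all(per[, "TRUE"] == 1))
  expect_true(all(per[, "FALSE"] == 4))
  cand2 <- generate_candidates(ds, unknowns, n_per_unknown = 5,
                               icm = "CM01", seed = 2)
  expect_identical(cand, cand2)
  expect_error(generate_candidates(ds, unknowns, 1, "CM01"), "at least 2")
  expect_error(generate_candidates(ds, "M999", 3, "CM01"), "not in dataset")

  pair <- generate_candidates(ds, unknowns, n_per_unknown = 2, icm = "CM01",
                              seed = 3)
  expect_equal(sum(!pair$is_true), 10L)  # exactly one decoy each
})

test_that("true candidates outrank uniform decoys when prediction error is small", {
  cfg <- synthetic_config(n_molecules = 60, n_cms = 3, n_groups = 5,
                          seed = 41)
  ds <- suppressMessages(generate_dataset(cfg))
  w <- to_wide(ds$rt_table)
  unknowns <- sprintf("M%03d", 1:30)
  cand <- generate_candidates(ds, unknowns, n_per_unknown = 11,
                              icm = "CM01", qsrr_sd = 0.1, seed = 5)
  ref <- setNames(w[unknowns, "CM01"], unknowns)
  cand$projected_rt <- cand$predicted_rt  # ranked in the input method itself
  rk <- rank_candidates(cand, ref)
  true_ranks <- rk$rank[rk$is_true]
  expect_lt(median(true_ranks), 6)  # chance median for 11 candidates
})
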