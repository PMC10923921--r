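test_that("profile normalization modes behave as documented", {
  w <- cbind(CMA = c(1, 2, 4), CMB = c(2, 5, 10))
  rownames(w) <- c("M1", "M2", "M3")
  expect_equal(normalize_profiles(w, "per_cm_elution")[, "CMA"],
               c(M1 = 0.25, M2 = 0.5, M3 = 1.0))
  expect_equal(normalize_profiles(w, "none"), w)
  mm <- normalize_profiles(w, "per_cm_minmax")
  expect_equal(unname(mm[, "CMA"]), c(0, 1 / 3, 1))
  expect_equal(range(mm), c(0, 1))
  # supplied elution times take precedence over the column max
  et <- normalize_profiles(w, "per_cm_elution",
                           elution_times = c(CMA = 8, CMB = 20))
  expect_equal(unname(et[, "CMA"]), c(1, 2, 4) / 8)
  w_na <- w; w_na[1, 1] <- NA
  expect_error(normalize_profiles(w_na), "missing")
})

test_that("SOM separates well-separated profile blobs", {
  set.seed(21)
  blob1 <- matrix(0.2 + rnorm(10 * 4, sd = 0.02), 10, 4)
  blob2 <- matrix(0.8 + rnorm(10 * 4, sd = 0.02), 10, 4)
  X <- rbind(blob1, blob2)
  rownames(X) <- sprintf("M%02d", 1:20)
  colnames(X) <- sprintf("CM%02d", 1:4)
  som <- som_cluster(X, grid = c(1, 2), epochs = 2000, seed = 5)
  g1 <- som$assignment[1:10]
  g2 <- som$assignment[11:20]
  expect_equal(length(unique(g1)), 1L)
  expect_equal(length(unique(g2)), 1L)
  expect_false(unique(g1) == unique(g2))
  # oracle: every molecule sits with its nearest prototype
  d <- as.matrix(dist(rbind(som$prototypes, X)))[1:2, -(1:2)]
  expect_equal(unname(som$assignment), unname(apply(d, 2, which.min)))
})

test_that("degenerate SOM inputs behave predictably", {
  X <- matrix(0.5, 8, 3, dimnames = list(sprintf("M%d", 1:8), NULL))
  som <- som_cluster(X, grid = c(2, 2), epochs = 500, seed = 1)
  expect_equal(length(unique(som$assignment)), 1L)  # identical profiles
  expect_warning(
    som_cluster(X[1:3, ], grid = c(2, 2), epochs = 100, seed = 1),
    "fewer molecules")
  expect_error(som_cluster(X, grid = c(2, 2), epochs = 100), "seed")
})

test_that("SOM training is bit-reproducible for a fixed seed", {
  set.seed(33)
  X <- matrix(runif(30 * 6), 30, 6,
              dimnames = list(sprintf("M%02d", 1:30), sprintf("C%d", 1:6)))
  s1 <- som_cluster(X, grid = c(2, 3), epochs = 1000, seed = 9)
  s2 <- som_cluster(X, grid = c(2, 3), epochs = 1000, seed = 9)
  expect_identical(s1, s2)
})

test_that("forced calibrant selection returns the exact covering set", {
  tab <- tiny_table(n_mol = 6, cms = c("CMA", "CMB"))
  w <- to_wide(tab)
  prof <- normalize_profiles(w)
  som <- manual_som(
    assignment = setNames(1:6, rownames(w)),
    prototypes = prof, grid = c(2, 3))
  sel <- select_calibrants(som, tab, target_size = 6)
  expect_setequal(sel$molecule_ids, rownames(w))
  expect_equal(attr(sel, "groups_covered"), 6L)
})

test_that("greedy calibrant selection covers groups and the RT range", {
  cfg <- synthetic_config(n_molecules = 80, n_cms = 4, n_families = 2,
                          n_groups = 5, frac_nonretained = 0, seed = 17)
  ds <- suppressMessages(generate_dataset(cfg))
  w <- to_wide(ds$rt_table)
  som <- som_cluster(normalize_profiles(w), grid = c(1, 5), epochs = 2000,
                     seed = 3)
  sel10 <- select_calibrants(som, ds$rt_table, target_size = 10)
  expect_equal(length(sel10$molecule_ids), 10L)
  n_groups_present <- length(unique(som$assignment))
  expect_equal(attr(sel10, "groups_covered"), n_groups_present)
  expect_gte(attr(sel10, "range_coverage"), 0.9)
  # monotone group coverage in the target size
  covered <- vapply(seq(n_groups_present, 20, by = 2), function(k) {
    attr(select_calibrants(som, ds$rt_table, target_size = k),
         "groups_covered")
  }, 0L)
  expect_true(all(diff(covered) >= 0))
})

test_that("SOM groups recover synthetic behavior structure above chance", {
  cfg <- synthetic_config(n_molecules = 120, n_cms = 6, n_families = 2,
                          n_groups = 6, frac_outgeneral = 0.5,
                          frac_nonretained = 0, noise_sd = 0, seed = 29)
  ds <- suppressMessages(generate_dataset(cfg))
  w <- to_wide(ds$rt_table)
  som <- som_cluster(normalize_profiles(w), grid = c(2, 3), epochs = 4000,
                     seed = 13)
  truth <- ds$truth$group[rownames(w)]
  purity <- function(assign) {
    mean(vapply(split(truth, assign), function(g) {
      max(table(g)) / length(g)
    }, 0))
  }
  obs <- purity(som$assignment)
  null <- vapply(1:20, function(i) {
    set.seed(100 + i)
    purity(sample(som$assignment))
  }, 0)
  expect_gt(obs, max(null))
})
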