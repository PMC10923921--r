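#' Normalize RT profiles ahead of clustering
#'
#' Retention behavior clustering compares a molecule's RT profile across all
#' methods; without normalization, long-gradient methods would dominate the
#' distance. `per_cm_elution` (default downstream) divides each method
#' column by that method's elution time, mapping values into (0, ~1];
#' `per_cm_minmax` rescales each column to \[0, 1\].
#'
#' @param wide Fully observed molecules x methods matrix ([to_wide()]).
#' @param mode `"per_cm_elution"`, `"per_cm_minmax"` or `"none"`.
#' @param elution_times Optional named vector of per-method elution times
#'   (minutes); defaults to each column's maximum.
#' @return Normalized matrix, same shape and dimnames.
#' @export
normalize_profiles <- function(wide,
                               mode = c("per_cm_elution", "per_cm_minmax",
                                        "none"),
                               elution_times = NULL) {
  mode <- match.arg(mode)
  if (anyNA(wide)) {
    stop("normalize_profiles: matrix has missing cells; ",
         "restrict to fully observed molecules first", call. = FALSE)
  }
  if (mode == "none") return(wide)
  if (mode == "per_cm_elution") {
    et <- if (is.null(elution_times)) {
      apply(wide, 2L, max)
    } else {
      et <- elution_times[colnames(wide)]
      if (anyNA(et)) {
        stop("normalize_profiles: elution_times missing for some methods",
             call. = FALSE)
      }
      et
    }
    return(sweep(wide, 2L, et, `/`))
  }
  # per_cm_minmax
  mins <- apply(wide, 2L, min)
  rng <- apply(wide, 2L, max) - mins
  rng[rng == 0] <- 1
  sweep(sweep(wide, 2L, mins, `-`), 2L, rng, `/`)
}

#' Classify retention behavior with a self-organizing map
#'
#' Clusters molecules by their normalized RT profiles across methods on a
#' rectangular SOM grid, so that each unit ("group") collects molecules with
#' a shared retention behavior: non-retained, weakly/strongly retained, the
#' general monotone trend, or "outgeneral" behavior whose elution order
#' flips between mobile-phase families. Training is the classic online rule
#' with a Gaussian neighborhood; the learning rate and radius both decay
#' linearly over the iterations. With the default 5x5 grid this yields up to
#' 25 behavior groups.
#'
#' @param profiles Normalized, fully observed molecules x methods matrix.
#' @param grid `c(rows, cols)` of the map (default `c(5, 5)`).
#' @param epochs Number of single-sample training iterations (default 5000).
#' @param seed Integer seed (mandatory): fixes prototype initialization and
#'   sample presentation order, making the fit bit-reproducible.
#' @param alpha Initial learning rate, decaying linearly to ~0.
#' @return A `behavior_som` with `assignment` (named group index per
#'   molecule, in `1..rows*cols`), `prototypes` (units x methods matrix),
#'   `grid`, and `n_groups`.
#' @export
som_cluster <- function(profiles, grid = c(5L, 5L), epochs = 5000L, seed,
                        alpha = 0.5) {
  if (missing(seed)) stop("som_cluster: seed is mandatory", call. = FALSE)
  if (anyNA(profiles)) {
    stop("som_cluster: profiles must be fully observed", call. = FALSE)
  }
  X <- as.matrix(profiles)
  n <- nrow(X)
  n_units <- grid[1L] * grid[2L]
  if (n < n_units) {
    warning("som_cluster: fewer molecules (", n, ") than grid cells (",
            n_units, "); empty groups expected")
  }
  # unit coordinates on the rectangular grid, row-major
  coords <- cbind(rep(seq_len(grid[1L]), each = grid[2L]),
                  rep(seq_len(grid[2L]), times = grid[1L]))
  grid_d2 <- as.matrix(stats::dist(coords))^2

  with_seed(seed, {
    W <- X[sample.int(n, n_units, replace = n < n_units), , drop = FALSE] +
      matrix(stats::rnorm(n_units * ncol(X), sd = 1e-4), n_units)
    order_idx <- sample.int(n, epochs, replace = TRUE)
    r0 <- max(grid) / 2
    for (t in seq_len(epochs)) {
      frac <- (t - 1) / epochs
      lr <- alpha * (1 - frac)
      radius <- max(r0 * (1 - frac), 0.5)
      xi <- X[order_idx[t], ]
      d2 <- rowSums(sweep(W, 2L, xi, `-`)^2)
      bmu <- which.min(d2)
      h <- exp(-grid_d2[bmu, ] / (2 * radius^2))
      W <- W + lr * h * sweep(-W, 2L, xi, `+`)
    }
    d <- as.matrix(stats::dist(rbind(W, X)))[seq_len(n_units),
                                             n_units + seq_len(n),
                                             drop = FALSE]
    assignment <- apply(d, 2L, which.min)
    names(assignment) <- rownames(X)
    rownames(W) <- paste0("unit", seq_len(n_units))
    structure(list(assignment = assignment, prototypes = W, grid = grid,
                   n_groups = n_units, epochs = epochs, seed = seed),
              class = "behavior_som")
  })
}

#' Select calibrants covering behaviors and the RT range
#'
#' Greedy two-pass selection of a calibrant set from a behavior clustering:
#' pass 1 takes, from each non-empty group, the molecule whose profile is
#' closest to the group prototype (the group medoid); pass 2 then adds
#' molecules that most extend the per-method RT-range coverage until
#' `target_size` is reached. Only molecules measured in every method of the
#' table are eligible (a calibrant must be observable everywhere). Ties are
#' broken by lexicographic molecule id, so selection is deterministic.
#'
#' @param som A [som_cluster()] result.
#' @param table An [rt_table()] containing the clustered molecules.
#' @param target_size Number of calibrants wanted.
#' @param min_groups_covered Minimum number of non-empty behavior groups the
#'   set must cover (default: all of them, capped at `target_size`).
#' @param name Name for the resulting set (default `"auto"`).
#' @return A [calibrant_set()].
#' @export
select_calibrants <- function(som, table, target_size,
                              min_groups_covered = NULL, name = "auto") {
  wide <- to_wide(table)
  eligible <- rownames(wide)[stats::complete.cases(wide)]
  eligible <- intersect(names(som$assignment), eligible)
  if (length(eligible) < target_size) {
    stop("select_calibrants: only ", length(eligible),
         " molecules measured in every method; cannot select ", target_size,
         call. = FALSE)
  }
  assign_el <- som$assignment[eligible]
  groups <- sort(unique(assign_el))
  if (is.null(min_groups_covered)) {
    min_groups_covered <- min(length(groups), target_size)
  }
  if (target_size < min_groups_covered) {
    stop("select_calibrants: target_size < min_groups_covered", call. = FALSE)
  }
  uncoverable <- setdiff(sort(unique(som$assignment)), groups)
  if (length(groups) < min_groups_covered) {
    stop("select_calibrants: cannot cover ", min_groups_covered,
         " groups; group(s) without fully observed molecules: ",
         paste(uncoverable, collapse = ", "), call. = FALSE)
  }

  # pass 1: group medoids (nearest to prototype; lexicographic tie-break)
  # distances computed on elution-normalized profiles, same space as the SOM
  prof <- normalize_profiles(wide[eligible, , drop = FALSE],
                             mode = "per_cm_elution")
  medoid <- function(g) {
    ids <- sort(names(assign_el)[assign_el == g])
    d <- sqrt(rowSums(sweep(prof[ids, , drop = FALSE], 2L,
                            som$prototypes[g, ], `-`)^2))
    ids[which.min(d)]  # which.min: first index, ids sorted -> deterministic
  }
  picked <- vapply(groups, medoid, "")
  if (length(picked) > target_size) {
    # keep the medoids of the largest groups (tie: smaller group index)
    sizes <- table(assign_el)[as.character(groups)]
    picked <- picked[order(-as.integer(sizes), groups)][seq_len(target_size)]
  }

  # pass 2: extend per-method RT range coverage
  full_rng <- apply(wide[eligible, , drop = FALSE], 2L, range)
  coverage <- function(ids) {
    sel <- wide[ids, , drop = FALSE]
    covered <- apply(sel, 2L, max) - apply(sel, 2L, min)
    span <- full_rng[2L, ] - full_rng[1L, ]
    span[span == 0] <- 1
    mean(covered / span)
  }
  remaining <- sort(setdiff(eligible, picked))
  while (length(picked) < target_size && length(remaining) > 0L) {
    gains <- vapply(remaining, function(id) coverage(c(picked, id)), 0)
    best <- remaining[which.max(gains)]  # remaining sorted -> lexicographic tie
    picked <- c(picked, best)
    remaining <- setdiff(remaining, best)
  }
  set <- calibrant_set(name, picked)
  attr(set, "groups_covered") <- length(unique(assign_el[picked]))
  attr(set, "range_coverage") <- coverage(picked)
  set
}
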