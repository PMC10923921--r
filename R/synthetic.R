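#' Configuration for the synthetic multi-method RT generator
#'
#' Defines the study conditions the generator emulates: a panel of
#' reversed-phase methods split into mobile-phase families, molecules with a
#' latent hydrophobicity driving a monotone gradient-elution warp per
#' method, behavior groups of which a fraction are "outgeneral" (their
#' elution order shifts between families), a non-retained fraction pinned at
#' the dead time, and measurement noise. Defaults are sized like a 30-method
#' / 330-molecule multi-method RT database with 25 behavior groups.
#'
#' @param n_molecules,n_cms,n_families,n_groups Counts.
#' @param frac_outgeneral Fraction of retained behavior groups given
#'   family-dependent RT offsets (elution-order changes between families).
#' @param frac_nonretained Fraction of molecules eluting at the dead time.
#' @param noise_sd Measurement noise sd, minutes.
#' @param run_times Per-method run times, minutes (recycled/sampled from a
#'   typical 10-60 min panel when `NULL`).
#' @param dead_time_frac Dead time as a fraction of run time.
#' @param delta_scale Magnitude of outgeneral offsets, as a fraction of the
#'   method's retained RT span.
#' @param seed Integer seed; the whole dataset is deterministic given it.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_molecules = 330L, n_cms = 30L,
                             n_families = 4L, n_groups = 25L,
                             frac_outgeneral = 0.3, frac_nonretained = 0.08,
                             noise_sd = 0.05, run_times = NULL,
                             dead_time_frac = 0.05, delta_scale = 0.15,
                             seed = 1L) {
  stopifnot(n_molecules >= 1, n_cms >= 2, n_families >= 1,
            n_groups >= 1, n_groups <= n_molecules,
            frac_outgeneral >= 0, frac_outgeneral <= 1,
            frac_nonretained >= 0, frac_nonretained <= 1,
            noise_sd >= 0, dead_time_frac > 0, dead_time_frac < 0.5,
            delta_scale >= 0, n_families <= 5)
  if (!is.null(run_times)) {
    stopifnot(length(run_times) == n_cms, all(run_times > 0))
  }
  structure(list(n_molecules = as.integer(n_molecules),
                 n_cms = as.integer(n_cms),
                 n_families = as.integer(n_families),
                 n_groups = as.integer(n_groups),
                 frac_outgeneral = frac_outgeneral,
                 frac_nonretained = frac_nonretained,
                 noise_sd = noise_sd, run_times = run_times,
                 dead_time_frac = dead_time_frac,
                 delta_scale = delta_scale, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a synthetic multi-method RT dataset
#'
#' Each molecule carries a latent hydrophobicity `u` in \[0, 1\]; its RT in
#' method `c` is `t0_c + (T_c - t0_c) * sigmoid(a_c * (u - b_c)) +
#' delta(group, family_c) + noise`, where `t0_c` is the dead time, `T_c` the
#' run time, and `(a_c, b_c)` a per-method monotone warp drawn around
#' family-level means. The additive `delta` term is zero for general groups
#' and for the first family (the reference family) and nonzero for
#' outgeneral groups in other families -- the minimal mechanism producing
#' elution-order swaps between mobile-phase families. Non-retained molecules
#' sit at the dead time. Offsets that would push a deterministic RT outside
#' the run are shrunk (halved, with a message) before noise is added; final
#' RTs are clipped to (0, T_c].
#'
#' @param config A [synthetic_config()].
#' @return List with `rt_table` ([rt_table()]), `cm_meta` (list of
#'   [chrom_method()]) and `truth` (latent `u`, group assignment and types,
#'   the `delta` fraction matrix, per-method warp parameters and family
#'   ids).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  with_seed(cfg$seed, {
    cm_ids <- sprintf("CM%02d", seq_len(cfg$n_cms))
    mol_ids <- sprintf("M%03d", seq_len(cfg$n_molecules))
    family_of_cm <- sort(rep_len(seq_len(cfg$n_families), cfg$n_cms))
    T_c <- if (is.null(cfg$run_times)) {
      sample(c(10, 15, 20, 21, 30, 45, 60), cfg$n_cms, replace = TRUE)
    } else cfg$run_times
    t0_c <- cfg$dead_time_frac * T_c

    a_f <- stats::runif(cfg$n_families, 5, 9)
    b_f <- stats::runif(cfg$n_families, 0.35, 0.6)
    a_c <- a_f[family_of_cm] * exp(stats::rnorm(cfg$n_cms, sd = 0.1))
    b_c <- b_f[family_of_cm] + stats::rnorm(cfg$n_cms, sd = 0.03)

    u <- stats::runif(cfg$n_molecules)
    # groups ordered by hydrophobicity: equal-frequency bins of u
    group <- as.integer(cut(rank(u, ties.method = "first"),
                            breaks = cfg$n_groups, labels = FALSE))
    n_nr <- if (cfg$frac_nonretained > 0) {
      max(1L, round(cfg$frac_nonretained * cfg$n_groups))
    } else 0L
    group_type <- rep("general", cfg$n_groups)
    if (n_nr > 0L) group_type[seq_len(n_nr)] <- "nonretained"
    retained_groups <- which(group_type == "general")
    n_og <- round(cfg$frac_outgeneral * length(retained_groups))
    if (n_og > 0L) {
      og <- sample(retained_groups, n_og)
      group_type[og] <- "outgeneral"
    }
    delta <- matrix(0, cfg$n_groups, cfg$n_families)
    if (cfg$n_families > 1L) {
      for (g in which(group_type == "outgeneral")) {
        delta[g, -1L] <- stats::runif(cfg$n_families - 1L,
                                      -cfg$delta_scale, cfg$delta_scale)
      }
    }

    nonret <- group_type[group] == "nonretained"
    rt <- matrix(NA_real_, cfg$n_molecules, cfg$n_cms,
                 dimnames = list(mol_ids, cm_ids))
    for (c in seq_len(cfg$n_cms)) {
      span <- T_c[c] - t0_c[c]
      base <- t0_c[c] + span * stats::plogis(a_c[c] * (u - b_c[c]))
      base[nonret] <- t0_c[c]
      f <- family_of_cm[c]
      det <- base + delta[group, f] * span
      # shrink offsets whose deterministic RT escapes the run window
      bad_g <- unique(group[det <= 0.01 * T_c[c] | det > 0.99 * T_c[c]])
      bad_g <- bad_g[delta[bad_g, f] != 0]
      while (length(bad_g)) {
        message("generate_dataset: shrinking outgeneral offset for group(s) ",
                paste(bad_g, collapse = ", "), " in ", cm_ids[c])
        delta[bad_g, f] <- delta[bad_g, f] / 2
        det <- base + delta[group, f] * span
        bad_g <- unique(group[det <= 0.01 * T_c[c] | det > 0.99 * T_c[c]])
        bad_g <- bad_g[delta[bad_g, f] != 0]
      }
      obs <- det + stats::rnorm(cfg$n_molecules, sd = cfg$noise_sd)
      rt[, c] <- pmin(pmax(obs, 1e-3), T_c[c])
    }

    fam_labels <- c("A1B1", "A2B2", "A3B3", "A4B4", "A5B5")
    cm_meta <- lapply(seq_len(cfg$n_cms), function(c) {
      Tt <- T_c[c]
      chrom_method(cm_id = cm_ids[c], column = "C18 synthetic",
                   mobile_phase_a = "H2O", mobile_phase_b = "MeOH",
                   additive_family = fam_labels[family_of_cm[c]],
                   gradient = rbind(c(0, 0.3, 5),
                                    c(round(0.1 * Tt, 2), 0.3, 5),
                                    c(round(0.8 * Tt, 2), 0.3, 100),
                                    c(Tt, 0.3, 100)),
                   run_time = Tt, temperature = 30)
    })
    names(cm_meta) <- cm_ids

    list(
      rt_table = to_long(rt),
      cm_meta = cm_meta,
      truth = list(u = stats::setNames(u, mol_ids),
                   group = stats::setNames(group, mol_ids),
                   group_type = group_type, delta = delta,
                   warp = data.frame(cm_id = cm_ids, family = family_of_cm,
                                     run_time = T_c, dead_time = t0_c,
                                     a = a_c, b = b_c),
                   config = cfg)
    )
  })
}

#' Generate synthetic candidate lists for unknown features
#'
#' For each unknown, emits one true candidate whose predicted RT is the
#' unknown's true RT in the input method plus a QSRR-like error draw, and
#' `n_per_unknown - 1` decoys with RTs drawn either uniformly over the
#' method's elution window or clustered near the true RT.
#'
#' @param dataset A [generate_dataset()] result.
#' @param unknowns Molecule ids to treat as unknown features.
#' @param n_per_unknown Candidates per unknown (>= 2).
#' @param icm Input method id the predicted RTs refer to.
#' @param decoy_rt_model `"uniform"` or `"near_true"`.
#' @param qsrr_sd Prediction error sd for the true candidate, minutes.
#' @param seed Integer seed.
#' @return Data frame `unknown_id`, `candidate_id`, `predicted_rt`,
#'   `is_true`.
#' @export
generate_candidates <- function(dataset, unknowns, n_per_unknown, icm,
                                decoy_rt_model = c("uniform", "near_true"),
                                qsrr_sd = 0.3, seed = 1L) {
  decoy_rt_model <- match.arg(decoy_rt_model)
  if (n_per_unknown < 2L) {
    stop("generate_candidates: need at least 2 candidates per unknown",
         call. = FALSE)
  }
  wide <- to_wide(dataset$rt_table)
  missing_u <- setdiff(unknowns, rownames(wide))
  if (length(missing_u)) {
    stop("generate_candidates: unknown(s) not in dataset: ",
         paste(missing_u, collapse = ", "), call. = FALSE)
  }
  w <- dataset$truth$warp
  row <- w[w$cm_id == icm, ]
  if (nrow(row) != 1L) {
    stop("generate_candidates: method ", icm, " not in dataset", call. = FALSE)
  }
  with_seed(seed, {
    out <- lapply(unknowns, function(uid) {
      true_rt <- wide[uid, icm]
      n_dec <- n_per_unknown - 1L
      dec_rt <- switch(decoy_rt_model,
        uniform = stats::runif(n_dec, row$dead_time, row$run_time),
        near_true = pmax(true_rt + stats::rnorm(n_dec, sd = 3 * qsrr_sd),
                         1e-3))
      data.frame(
        unknown_id = uid,
        candidate_id = c(paste0(uid, "_true"),
                         sprintf("%s_d%02d", uid, seq_len(n_dec))),
        predicted_rt = c(true_rt + stats::rnorm(1L, sd = qsrr_sd), dec_rt),
        is_true = c(TRUE, rep(FALSE, n_dec))
      )
    })
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}
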