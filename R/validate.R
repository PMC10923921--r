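# Map additive families to an OCM similarity class relative to the ICM:
# distance 0 (same mobile phase) -> A, 1 -> B, 2 -> C, >= 3 -> D.
ocm_class_of <- function(icm, ocm, cm_meta) {
  if (is.null(cm_meta)) return(NA_character_)
  fam <- function(cm) match(cm_meta[[cm]]$additive_family,
                            c("A1B1", "A2B2", "A3B3", "A4B4", "A5B5"))
  d <- abs(fam(icm) - fam(ocm))
  c("A", "B", "C", "D")[pmin(d + 1L, 4L)]
}

#' All-pairs projection/calibration validation
#'
#' Runs the full experimental-RT transfer study: every method in `icms` is
#' used as input method (ICM); a reference method (ReICM) is chosen for it
#' by calibrant-RT similarity (or taken from `reicm`); every remaining
#' method serves as output method (OCM). For each (ICM, OCM) pair all
#' molecules measured in ICM, ReICM and OCM are projected, and errors are
#' summarized before calibration (projected vs experimental OCM RT) and
#' after (projected vs RePRT), in percent of the OCM elution time. Pairs
#' whose models cannot be fitted are recorded as failed rows and the run
#' continues.
#'
#' @param table An [rt_table()] covering the calibrants in all methods.
#' @param calibrants A [calibrant_set()].
#' @param cm_meta Optional named list of [chrom_method()]; supplies the
#'   additive families that define OCM similarity classes A-D.
#' @param icms Methods to use as ICM (default: all in the table).
#' @param reicm `"auto"` (argmax r2_c selection) or a named character
#'   vector mapping ICM id -> ReICM id.
#' @param seed,n_restarts GP fitting controls ([fit_projection()]).
#' @return `data.frame`, one row per (ICM, OCM) pair: ids, `ocm_class`,
#'   `r2_b`, `r2_c`, `elution_time`, `n`, RMSE/median/mean errors relative
#'   to elution time before and after calibration, and `failed`.
#' @export
run_validation <- function(table, calibrants, cm_meta = NULL, icms = NULL,
                           reicm = "auto", seed = 1L, n_restarts = 2L) {
  cms <- sort(unique(table$cm_id))
  if (is.null(icms)) icms <- cms
  if (length(cms) < 3L) {
    warning("run_validation: need at least 3 methods (ICM, ReICM, OCM); ",
            "empty report")
    return(data.frame())
  }
  wide <- to_wide(table)
  rows <- list()
  for (icm in icms) {
    re_id <- if (identical(reicm, "auto")) {
      select_reference(icm, setdiff(cms, icm), table, calibrants)$reicm
    } else {
      unname(reicm[icm])
    }
    for (ocm in setdiff(cms, c(icm, re_id))) {
      row <- tryCatch({
        ctx <- suppressWarnings(
          build_context(icm, re_id, ocm, table, calibrants,
                        seed = seed, n_restarts = n_restarts))
        keep <- stats::complete.cases(wide[, c(icm, re_id, ocm)])
        mols <- rownames(wide)[keep]
        res <- calibrate(ctx,
                         rt_icm = stats::setNames(wide[mols, icm], mols),
                         rt_reicm = stats::setNames(wide[mols, re_id], mols),
                         rt_ocm = stats::setNames(wide[mols, ocm], mols))
        before <- summarize_errors(res$projected_rt, res$rt_ocm,
                                   ctx$elution_time)
        after <- summarize_errors(res$projected_rt, res$reprt,
                                  ctx$elution_time)
        data.frame(icm = icm, reicm = re_id, ocm = ocm,
                   ocm_class = ocm_class_of(icm, ocm, cm_meta),
                   r2_b = ctx$r2_b, r2_c = ctx$r2_c,
                   elution_time = ctx$elution_time, n = before$n,
                   rmse_ret_before = before$rmse_ret,
                   rmse_ret_after = after$rmse_ret,
                   mede_ret_before = before$mede_ret,
                   mede_ret_after = after$mede_ret,
                   me_ret_before = before$me_ret,
                   me_ret_after = after$me_ret,
                   failed = FALSE)
      }, error = function(e) {
        data.frame(icm = icm, reicm = re_id, ocm = ocm,
                   ocm_class = ocm_class_of(icm, ocm, cm_meta),
                   r2_b = NA_real_, r2_c = NA_real_,
                   elution_time = NA_real_, n = NA_integer_,
                   rmse_ret_before = NA_real_, rmse_ret_after = NA_real_,
                   mede_ret_before = NA_real_, mede_ret_after = NA_real_,
                   me_ret_before = NA_real_, me_ret_after = NA_real_,
                   failed = TRUE)
      })
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pool validation errors by OCM similarity class
#'
#' Pools the per-pair squared errors across all pairs in each OCM class, so
#' the reported RMSE is over every (molecule, pair) error in the class --
#' not an average of per-pair RMSEs.
#'
#' @param results Output of [run_validation()].
#' @return `data.frame` per class: pooled `rmse_ret_before`,
#'   `rmse_ret_after` (percent of elution time), number of pairs and of
#'   pooled errors.
#' @export
pool_validation <- function(results) {
  res <- results[!results$failed & !is.na(results$ocm_class), , drop = FALSE]
  if (nrow(res) == 0L) return(data.frame())
  pooled <- lapply(split(res, res$ocm_class), function(d) {
    data.frame(ocm_class = d$ocm_class[1L],
               n_pairs = nrow(d),
               n_errors = sum(d$n),
               rmse_ret_before = sqrt(sum(d$n * d$rmse_ret_before^2) /
                                        sum(d$n)),
               rmse_ret_after = sqrt(sum(d$n * d$rmse_ret_after^2) /
                                       sum(d$n)))
  })
  out <- do.call(rbind, pooled)
  rownames(out) <- NULL
  out
}

#' Candidate annotation with and without post-projection calibration
#'
#' End-to-end annotation workflow for one ICM (where candidate RTs are
#' predicted) against a panel of OCMs: builds the calibration context per
#' OCM, projects candidate predicted RTs onto the OCM, derives each
#' unknown's reference RT both ways (experimental OCM RT = before; RePRT =
#' after), filters at twice the corresponding OCM RMSE_Ret and ranks by RT
#' agreement, reporting confusion rates and top-5 counts for both modes.
#'
#' @param table An [rt_table()] with RTs for calibrants and unknowns.
#' @param calibrants A [calibrant_set()].
#' @param candidates Candidate table (`unknown_id`, `candidate_id`,
#'   `predicted_rt` in the ICM, `is_true`); see [read_candidates()].
#' @param icm,reicm Method ids (reicm `"auto"` allowed).
#' @param ocms Output methods (default: all methods except ICM and ReICM).
#' @param seed,n_restarts GP fitting controls.
#' @return List: `summary` (per-OCM thresholds, confusion rates and Ntop5,
#'   before vs after) and `candidates` (per-OCM annotated tables, after
#'   calibration).
#' @export
run_annotation <- function(table, calibrants, candidates, icm,
                           reicm = "auto", ocms = NULL, seed = 1L,
                           n_restarts = 2L) {
  cms <- sort(unique(table$cm_id))
  re_id <- if (identical(reicm, "auto")) {
    select_reference(icm, setdiff(cms, icm), table, calibrants)$reicm
  } else reicm
  if (is.null(ocms)) ocms <- setdiff(cms, c(icm, re_id))
  wide <- to_wide(table)
  unknowns <- unique(candidates$unknown_id)
  missing_re <- unknowns[!unknowns %in% rownames(wide) |
                           is.na(wide[unknowns, re_id])]
  if (length(missing_re)) {
    warning("run_annotation: skipping unknown(s) without ReICM RT: ",
            paste(missing_re, collapse = ", "))
    candidates <- candidates[!candidates$unknown_id %in% missing_re, ,
                             drop = FALSE]
    unknowns <- setdiff(unknowns, missing_re)
  }
  summaries <- list()
  annotated <- list()
  for (ocm in ocms) {
    ctx <- suppressWarnings(
      build_context(icm, re_id, ocm, table, calibrants,
                    seed = seed, n_restarts = n_restarts))
    # per-OCM transfer accuracy from all molecules known in all three
    keep <- stats::complete.cases(wide[, c(icm, re_id, ocm)])
    mols <- rownames(wide)[keep]
    val <- calibrate(ctx,
                     rt_icm = stats::setNames(wide[mols, icm], mols),
                     rt_reicm = stats::setNames(wide[mols, re_id], mols),
                     rt_ocm = stats::setNames(wide[mols, ocm], mols))
    rmse_before <- summarize_errors(val$projected_rt, val$rt_ocm,
                                    ctx$elution_time)$rmse_ret
    rmse_after <- summarize_errors(val$projected_rt, val$reprt,
                                   ctx$elution_time)$rmse_ret

    cand <- candidates
    cand$projected_rt <- project(ctx$main_model, cand$predicted_rt)$mean
    ref_before <- stats::setNames(wide[unknowns, ocm], unknowns)
    ref_after <- stats::setNames(
      project(ctx$re_model, wide[unknowns, re_id])$mean, unknowns)

    one_mode <- function(ref, rmse) {
      thr <- filter_threshold(rmse)
      dec <- filter_candidates(cand, ref, ctx$elution_time, thr)
      ranked <- rank_candidates(dec, ref)
      list(threshold_pct = thr, confusion = confusion(dec),
           ranked = ranked, ntop5 = top_n_summary(ranked, 5L))
    }
    before <- one_mode(ref_before, rmse_before)
    after <- one_mode(ref_after, rmse_after)
    summaries[[ocm]] <- data.frame(
      ocm = ocm, n_unknowns = length(unknowns),
      n_candidates = nrow(cand),
      rmse_ret_before = rmse_before, rmse_ret_after = rmse_after,
      threshold_before_pct = before$threshold_pct,
      threshold_after_pct = after$threshold_pct,
      tnr_before = before$confusion$tnr, tnr_after = after$confusion$tnr,
      tpr_before = before$confusion$tpr, tpr_after = after$confusion$tpr,
      accuracy_before = before$confusion$accuracy,
      accuracy_after = after$confusion$accuracy,
      ntop5_before = before$ntop5, ntop5_after = after$ntop5
    )
    annotated[[ocm]] <- after$ranked
  }
  summary <- do.call(rbind, summaries)
  rownames(summary) <- NULL
  list(summary = summary, candidates = annotated)
}
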