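#' RT error threshold for candidate filtering
#'
#' The filtering threshold is twice the RMSE relative to elution time
#' observed for the corresponding OCM, so each output method gets a
#' threshold matched to its own transfer accuracy.
#'
#' @param ocm_rmse_ret RMSE_Ret of the OCM's projections, percent (> 0).
#' @return Threshold in percent of elution time.
#' @export
filter_threshold <- function(ocm_rmse_ret) {
  if (!is.numeric(ocm_rmse_ret) || any(ocm_rmse_ret <= 0) ||
      anyNA(ocm_rmse_ret)) {
    stop("filter_threshold: RMSE_Ret must be positive", call. = FALSE)
  }
  2 * ocm_rmse_ret
}

#' Filter candidates by RT agreement
#'
#' A candidate is positive when its projected RT lies within the threshold
#' of the unknown's reference RT (experimental RT before calibration, RePRT
#' after), measured in percent of elution time. An error exactly at the
#' threshold counts as positive: only errors strictly above the threshold
#' are deemed negative.
#'
#' @param candidates Data frame with columns `unknown_id`, `candidate_id`,
#'   `projected_rt` (minutes) and optionally `is_true`.
#' @param reference_rt Named numeric vector: reference RT per unknown.
#' @param et Elution time of the OCM, minutes.
#' @param threshold_pct Threshold in percent of elution time (> 0).
#' @return The input with added `ref_rt`, `err_pct` and logical `decision`.
#' @export
filter_candidates <- function(candidates, reference_rt, et, threshold_pct) {
  stopifnot(threshold_pct > 0)
  missing_ref <- setdiff(unique(candidates$unknown_id), names(reference_rt))
  if (length(missing_ref)) {
    stop("filter_candidates: no reference RT for unknown(s): ",
         paste(missing_ref, collapse = ", "), call. = FALSE)
  }
  out <- candidates
  out$ref_rt <- unname(reference_rt[out$unknown_id])
  out$err_pct <- error_ret(out$projected_rt, out$ref_rt, et)
  out$decision <- out$err_pct <= threshold_pct
  out
}

#' Confusion counts and rates for filtering decisions
#'
#' True positives are true identities accepted by the filter; true negatives
#' are false identities rejected; and so on. Rates follow the usual
#' definitions: TPR = TP/(TP+FN), FPR = FP/(FP+TN), TNR = 1 - FPR, accuracy
#' = (TP+TN)/(TP+FP+TN+FN). Rows without an `is_true` label are excluded
#' (their count is messaged).
#'
#' @param decisions Output of [filter_candidates()] with an `is_true`
#'   column.
#' @return List with counts `tp`, `fp`, `tn`, `fn` and rates `tpr`, `fpr`,
#'   `tnr`, `accuracy` (rates are `NaN` when undefined).
#' @export
confusion <- function(decisions) {
  if (!"is_true" %in% names(decisions)) {
    stop("confusion: decisions lack an is_true column", call. = FALSE)
  }
  unlabeled <- sum(is.na(decisions$is_true))
  if (unlabeled > 0L) {
    message("confusion: excluding ", unlabeled, " unlabeled candidate(s)")
    decisions <- decisions[!is.na(decisions$is_true), , drop = FALSE]
  }
  tp <- sum(decisions$is_true & decisions$decision)
  fn <- sum(decisions$is_true & !decisions$decision)
  fp <- sum(!decisions$is_true & decisions$decision)
  tn <- sum(!decisions$is_true & !decisions$decision)
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       tpr = tp / (tp + fn),
       fpr = fp / (fp + tn),
       tnr = tn / (fp + tn),
       accuracy = (tp + tn) / (tp + fp + tn + fn))
}

#' Rank candidates by RT agreement
#'
#' Within each unknown, candidates are ranked by ascending absolute RT
#' difference from the reference (rank 1 = best match). Exact ties are
#' broken by lexicographic candidate id, so the ranking is a deterministic
#' total order regardless of input row order.
#'
#' @param candidates Data frame with `unknown_id`, `candidate_id`,
#'   `projected_rt`.
#' @param reference_rt Named numeric vector: reference RT per unknown.
#' @return The input with added `ref_rt`, `abs_err` (minutes) and `rank`,
#'   ordered by unknown then rank.
#' @export
rank_candidates <- function(candidates, reference_rt) {
  missing_ref <- setdiff(unique(candidates$unknown_id), names(reference_rt))
  if (length(missing_ref)) {
    stop("rank_candidates: no reference RT for unknown(s): ",
         paste(missing_ref, collapse = ", "), call. = FALSE)
  }
  out <- candidates
  out$ref_rt <- unname(reference_rt[out$unknown_id])
  out$abs_err <- abs(out$projected_rt - out$ref_rt)
  out <- out[order(out$unknown_id, out$abs_err, out$candidate_id), ,
             drop = FALSE]
  out$rank <- stats::ave(seq_len(nrow(out)), out$unknown_id,
                         FUN = seq_along)
  rownames(out) <- NULL
  out
}

#' Count true identities ranked in the top n
#'
#' @param ranked Output of [rank_candidates()] with an `is_true` column.
#' @param n Rank cutoff (e.g. 5 for an Ntop5 count).
#' @return Integer: number of unknowns whose true identity has rank <= n.
#' @export
top_n_summary <- function(ranked, n) {
  if (!"is_true" %in% names(ranked)) {
    stop("top_n_summary: ranked table lacks an is_true column", call. = FALSE)
  }
  hits <- ranked[!is.na(ranked$is_true) & ranked$is_true &
                   ranked$rank <= n, , drop = FALSE]
  length(unique(hits$unknown_id))
}
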