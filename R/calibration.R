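#' Select a reference input method (ReICM)
#'
#' For a given input method (ICM), picks from the candidate methods the one
#' whose calibrant RTs correlate best with the ICM's (argmax of the squared
#' Pearson correlation, r2_c). Calibration accuracy decreases with
#' decreasing elution-order similarity between ICM and ReICM, so r2_c is
#' both the selection criterion and the quality diagnostic. Ties are broken
#' by the lexicographically smaller method id.
#'
#' @param icm Input method id.
#' @param candidate_cms Character vector of candidate reference method ids.
#' @param table An [rt_table()] with calibrant RTs in the ICM and candidates.
#' @param calibrants A [calibrant_set()].
#' @return List with `reicm` (chosen id) and `r2_c`.
#' @export
select_reference <- function(icm, candidate_cms, table, calibrants) {
  wide <- to_wide(table)
  ids <- intersect(calibrants$molecule_ids, rownames(wide))
  if (!icm %in% colnames(wide)) {
    stop("select_reference: ICM ", icm, " not in table", call. = FALSE)
  }
  x <- wide[ids, icm]
  ok <- !is.na(x)
  r2 <- vapply(candidate_cms, function(cm) {
    if (!cm %in% colnames(wide)) return(NA_real_)
    y <- wide[ids, cm]
    keep <- ok & !is.na(y)
    if (sum(keep) < length(ids)) return(NA_real_)  # incomplete coverage
    r_squared(x[keep], y[keep])
  }, 0)
  if (all(is.na(r2))) {
    stop("select_reference: no candidate method has complete calibrant ",
         "coverage", call. = FALSE)
  }
  best <- max(r2, na.rm = TRUE)
  chosen <- sort(candidate_cms[!is.na(r2) & r2 == best])[1L]
  list(reicm = chosen, r2_c = best)
}

#' Build a calibration context (ICM, ReICM, OCM + fitted models)
#'
#' Fits the two Gaussian-process models the post-projection calibration
#' needs: the main projection model (calibrant RTs: ICM -> OCM) and the
#' ReProjection model (ReICM -> OCM), on the same calibrant ids. Also
#' records the diagnostics r2_b (calibrant RT correlation^2, ICM vs OCM:
#' tracks projection accuracy) and r2_c (ICM vs ReICM: tracks calibration
#' accuracy), and the OCM elution time (max calibrant RT in the OCM).
#'
#' `calibrant_rt_overrides` substitutes RTs on the ICM side only -- the use
#' case is an ICM from an external dataset where a few calibrants have no
#' experimental RT and a QSRR-predicted RT stands in.
#'
#' @param icm,reicm,ocm Method ids.
#' @param table An [rt_table()] covering the calibrants in all three methods.
#' @param calibrants A [calibrant_set()].
#' @param calibrant_rt_overrides Optional named numeric vector
#'   (molecule_id -> RT minutes) overriding ICM-side calibrant RTs.
#' @param seed,n_restarts Passed to [fit_projection()].
#' @return A `calibration_context`; carries a `low_similarity` flag when
#'   r2_c < 0.95.
#' @export
build_context <- function(icm, reicm, ocm, table, calibrants,
                          calibrant_rt_overrides = NULL, seed = 1L,
                          n_restarts = 5L) {
  wide <- to_wide(table)
  ids <- calibrants$molecule_ids
  missing_ids <- setdiff(ids, rownames(wide))
  get_col <- function(cm) {
    if (!cm %in% colnames(wide)) {
      stop("build_context: method ", cm, " not in table", call. = FALSE)
    }
    v <- rep(NA_real_, length(ids))
    present <- intersect(ids, rownames(wide))
    v[match(present, ids)] <- wide[present, cm]
    v
  }
  x_icm <- get_col(icm)
  if (!is.null(calibrant_rt_overrides)) {
    ov <- intersect(names(calibrant_rt_overrides), ids)
    x_icm[match(ov, ids)] <- calibrant_rt_overrides[ov]
  }
  x_reicm <- get_col(reicm)
  y_ocm <- get_col(ocm)
  keep <- !is.na(x_icm) & !is.na(x_reicm) & !is.na(y_ocm)
  if (sum(keep) < 5L) {
    stop("build_context: insufficient calibrants after intersection; ",
         "missing ids: ",
         paste(union(missing_ids, ids[!keep]), collapse = ", "),
         call. = FALSE)
  }
  if (sum(keep) < length(ids)) {
    message("build_context: using ", sum(keep), " of ", length(ids),
            " calibrants (incomplete coverage: ",
            paste(ids[!keep], collapse = ", "), ")")
  }
  ids_k <- ids[keep]
  x1 <- x_icm[keep]; x2 <- x_reicm[keep]; y <- y_ocm[keep]
  main_model <- fit_projection(x1, y, seed = seed, n_restarts = n_restarts,
                               source_cm = icm, target_cm = ocm)
  re_model <- fit_projection(x2, y, seed = seed, n_restarts = n_restarts,
                             source_cm = reicm, target_cm = ocm)
  r2_c <- r_squared(x1, x2)
  ctx <- structure(list(
    icm = icm, reicm = reicm, ocm = ocm,
    calibrant_set = calibrants, calibrant_ids_used = ids_k,
    main_model = main_model, re_model = re_model,
    r2_b = r_squared(x1, y), r2_c = r2_c,
    elution_time = elution_time(y),
    low_similarity = r2_c < 0.95
  ), class = "calibration_context")
  if (ctx$low_similarity) {
    warning("build_context: low ICM-ReICM similarity (r2_c = ",
            signif(r2_c, 3), " < 0.95); calibration accuracy may be poor")
  }
  ctx
}

#' Calibrate projected RTs against reference-projected RTs
#'
#' The heart of post-projection calibration. For each unknown molecule, the
#' main model projects its ICM RT (experimental or predicted) onto the OCM;
#' the ReProjection model projects its experimental ReICM RT onto the OCM,
#' giving the RePRT. Because ICM and ReICM share elution order, a molecule
#' that deviates from the calibrant trend does so in both projections, so
#' comparing projected RT to RePRT (instead of to the OCM experimental RT)
#' cancels the LC-setup-specific distortion.
#'
#' @param context A [build_context()] result.
#' @param rt_icm Named numeric vector: unknowns' RTs in the ICM (minutes).
#' @param rt_reicm Named numeric vector: unknowns' experimental RTs in the
#'   ReICM. Unknowns missing from either vector are skipped with a warning.
#' @param rt_ocm Optional named vector of experimental OCM RTs; when given,
#'   the pre-calibration error `err_before_pct` (projected vs experimental)
#'   is reported alongside `err_after_pct` (projected vs RePRT).
#' @return `data.frame` with `molecule_id`, `projected_rt`, `reprt`,
#'   `err_after_pct` and (if available) `err_before_pct`.
#' @export
calibrate <- function(context, rt_icm, rt_reicm, rt_ocm = NULL) {
  stopifnot(inherits(context, "calibration_context"))
  ids <- intersect(names(rt_icm), names(rt_reicm))
  skipped <- setdiff(union(names(rt_icm), names(rt_reicm)), ids)
  if (length(skipped)) {
    warning("calibrate: skipping ", length(skipped),
            " unknown(s) missing an ICM or ReICM RT: ",
            paste(utils::head(skipped, 5L), collapse = ", "))
  }
  ids <- sort(ids)
  projected <- project(context$main_model, unname(rt_icm[ids]))$mean
  reprt <- project(context$re_model, unname(rt_reicm[ids]))$mean
  out <- data.frame(
    molecule_id = ids,
    projected_rt = projected,
    reprt = reprt,
    err_after_pct = error_ret(projected, reprt, context$elution_time)
  )
  if (!is.null(rt_ocm)) {
    ref <- unname(rt_ocm[ids])
    out$err_before_pct <- error_ret(projected, ref, context$elution_time)
    out$rt_ocm <- ref
  }
  out
}

#' Advisory accuracy bands from r2_b / r2_c
#'
#' Maps the context diagnostics to expected-error bands calibrated on the
#' behavior-covering calibrant sets ("B"/"C"-style sets): when r2_c >= 0.992
#' the calibration RMSE relative to elution time is expected below 3%. The
#' estimate is advisory only and is flagged unreliable for sets that cover
#' few retention behaviors (set "E"-style), for which the r2 diagnostics
#' lose their predictive value.
#'
#' @param r2_b,r2_c Squared Pearson correlations in \[0, 1\].
#' @param calibrant_set_name Set name; `"E"` marks a limited-behavior set.
#' @param bands Override of the default band cutpoints, a list with
#'   `high = 0.992` and `moderate = 0.95`.
#' @return List with `band` (`"high"`, `"moderate"`, `"low"`), a
#'   human-readable `message`, `reliable` (FALSE for limited-behavior sets)
#'   and the inputs.
#' @export
quality_estimate <- function(r2_b, r2_c, calibrant_set_name = "B",
                             bands = list(high = 0.992, moderate = 0.95)) {
  stopifnot(r2_b >= 0, r2_b <= 1, r2_c >= 0, r2_c <= 1)
  band <- if (r2_c >= bands$high) "high"
          else if (r2_c >= bands$moderate) "moderate" else "low"
  msg <- switch(band,
    high = "calibration RMSE_Ret expected < 3.0%",
    moderate = "calibration expected usable; inspect residuals",
    low = "low ICM-ReICM similarity: calibration accuracy not assured")
  reliable <- !identical(calibrant_set_name, "E")
  if (!reliable) {
    msg <- paste0(msg, " [unreliable: calibrant set '", calibrant_set_name,
                  "' covers limited retention behaviors]")
  }
  list(band = band, message = msg, reliable = reliable,
       r2_b = r2_b, r2_c = r2_c, calibrant_set = calibrant_set_name)
}
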