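#' Construct a retention time table
#'
#' An `rt_table` is a long-format data frame with one aggregated retention
#' time per (molecule, method) pair: columns `molecule_id`, `cm_id`
#' (chromatographic method id, both opaque case-sensitive strings) and `rt`
#' (minutes, strictly positive).
#'
#' @param df Data frame with columns `molecule_id`, `cm_id`, `rt`.
#' @return A validated `rt_table` (rows ordered by molecule then method).
#' @export
rt_table <- function(df) {
  need <- c("molecule_id", "cm_id", "rt")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("rt_table: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df <- df[need]
  df$molecule_id <- as.character(df$molecule_id)
  df$cm_id <- as.character(df$cm_id)
  df$rt <- as.numeric(df$rt)
  bad <- which(!is.finite(df$rt) | df$rt <= 0)
  if (length(bad)) {
    stop("rt_table: non-positive or non-finite rt at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df[c("molecule_id", "cm_id")])) {
    stop("rt_table: duplicated (molecule_id, cm_id) after aggregation",
         call. = FALSE)
  }
  df <- df[order(df$molecule_id, df$cm_id), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("rt_table", "data.frame")
  df
}

#' Read a long-format RT table from CSV
#'
#' Expects columns `molecule_id,cm_id,rt_min[,replicate]` (comma-separated,
#' UTF-8, header required, "." decimal separator). Replicate measurements of
#' the same (molecule, method) pair are collapsed to a single value.
#'
#' @param path Path to the CSV file.
#' @param replicate_policy How replicates are aggregated: `"mean"`
#'   (default), `"median"`, or `"first"` (first occurrence in file order).
#' @return An [rt_table()].
#' @export
read_rt_table <- function(path, replicate_policy = c("mean", "median", "first")) {
  replicate_policy <- match.arg(replicate_policy)
  if (!file.exists(path)) stop("read_rt_table: file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = NA, check.names = FALSE)
  need <- c("molecule_id", "cm_id", "rt_min")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop("read_rt_table: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(raw) == 0L) {
    return(rt_table(data.frame(molecule_id = character(), cm_id = character(),
                               rt = numeric())))
  }
  rt <- as.numeric(raw$rt_min)
  bad <- which(!is.finite(rt) | rt <= 0)
  if (length(bad)) {
    stop("read_rt_table: non-positive rt_min at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  agg_fun <- switch(replicate_policy,
                    mean = mean, median = stats::median, first = function(v) v[[1L]])
  key <- paste(raw$molecule_id, raw$cm_id, sep = "\r")
  agg <- tapply(rt, key, agg_fun)
  ids <- strsplit(names(agg), "\r", fixed = TRUE)
  rt_table(data.frame(
    molecule_id = vapply(ids, `[[`, "", 1L),
    cm_id = vapply(ids, `[[`, "", 2L),
    rt = as.numeric(agg),
    stringsAsFactors = FALSE
  ))
}

#' Write an RT table to CSV
#'
#' @param table An [rt_table()].
#' @param path Output CSV path (columns `molecule_id,cm_id,rt_min`).
#' @export
write_rt_table <- function(table, path) {
  out <- data.frame(molecule_id = table$molecule_id, cm_id = table$cm_id,
                    rt_min = table$rt)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pivot an RT table to a molecules x methods matrix
#'
#' @param table An [rt_table()].
#' @return Numeric matrix with molecules as (sorted) rownames, method ids as
#'   (sorted) colnames, and `NA` where a pair was not measured.
#' @export
to_wide <- function(table) {
  mols <- sort(unique(table$molecule_id))
  cms <- sort(unique(table$cm_id))
  m <- matrix(NA_real_, nrow = length(mols), ncol = length(cms),
              dimnames = list(mols, cms))
  m[cbind(match(table$molecule_id, mols), match(table$cm_id, cms))] <- table$rt
  m
}

#' Flatten a wide RT matrix back to a long table
#'
#' Inverse of [to_wide()]: `NA` cells are dropped.
#'
#' @param wide Matrix as produced by [to_wide()].
#' @return An [rt_table()].
#' @export
to_long <- function(wide) {
  idx <- which(!is.na(wide), arr.ind = TRUE)
  rt_table(data.frame(
    molecule_id = rownames(wide)[idx[, 1L]],
    cm_id = colnames(wide)[idx[, 2L]],
    rt = wide[idx],
    stringsAsFactors = FALSE
  ))
}

#' Construct chromatographic method metadata
#'
#' Describes one LC method: column, mobile phases, additive family (one of
#' `A1B1`, `A2B2`, `A3B3`, `A4B4`, `A5B5`, labelling the mobile-phase
#' additive composition), the gradient program as a list of
#' `(t minutes, flow mL/min, %B)` breakpoints, total run time and column
#' temperature.
#'
#' @param cm_id,column,mobile_phase_a,mobile_phase_b Character scalars.
#' @param additive_family One of `"A1B1"`..`"A5B5"`.
#' @param gradient Numeric matrix (or list of length-3 vectors) with columns
#'   t, flow, percent_b; times strictly increasing, flow > 0, %B in \[0,100\].
#' @param run_time Run time in minutes; must be >= the last gradient time.
#' @param temperature Column temperature, degrees C.
#' @return A `chrom_method` object (a named list).
#' @export
chrom_method <- function(cm_id, column = "", mobile_phase_a = "",
                         mobile_phase_b = "", additive_family = "A1B1",
                         gradient, run_time, temperature = 30) {
  fams <- c("A1B1", "A2B2", "A3B3", "A4B4", "A5B5")
  if (!additive_family %in% fams) {
    stop("chrom_method: additive_family must be one of ",
         paste(fams, collapse = ", "), " (cm ", cm_id, ")", call. = FALSE)
  }
  if (is.list(gradient)) {
    if (any(vapply(gradient, length, 0L) != 3L)) {
      stop("chrom_method: malformed gradient tuple for cm ", cm_id, call. = FALSE)
    }
    gradient <- do.call(rbind, lapply(gradient, as.numeric))
  }
  gradient <- as.matrix(gradient)
  if (ncol(gradient) != 3L || !is.numeric(gradient) || anyNA(gradient)) {
    stop("chrom_method: malformed gradient for cm ", cm_id, call. = FALSE)
  }
  colnames(gradient) <- c("t", "flow", "percent_b")
  if (any(diff(gradient[, "t"]) <= 0)) {
    stop("chrom_method: gradient times must be strictly increasing (cm ",
         cm_id, ")", call. = FALSE)
  }
  if (any(gradient[, "flow"] <= 0)) {
    stop("chrom_method: flow must be > 0 (cm ", cm_id, ")", call. = FALSE)
  }
  if (any(gradient[, "percent_b"] < 0 | gradient[, "percent_b"] > 100)) {
    stop("chrom_method: percent_b must be in [0, 100] (cm ", cm_id, ")",
         call. = FALSE)
  }
  if (run_time < gradient[nrow(gradient), "t"]) {
    stop("chrom_method: run_time < last gradient time (cm ", cm_id, ")",
         call. = FALSE)
  }
  structure(list(cm_id = as.character(cm_id), column = column,
                 mobile_phase_a = mobile_phase_a,
                 mobile_phase_b = mobile_phase_b,
                 additive_family = additive_family, gradient = gradient,
                 run_time = as.numeric(run_time),
                 temperature = as.numeric(temperature)),
            class = "chrom_method")
}

#' Read chromatographic method metadata from JSON
#'
#' The file holds an array of objects mirroring [chrom_method()] fields,
#' with `gradient` an array of `[t, flow, percent_b]` triples.
#'
#' @param path Path to the JSON file.
#' @return Named list of `chrom_method` objects (names = cm ids).
#' @export
read_cm_metadata <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  out <- lapply(raw, function(x) {
    chrom_method(cm_id = x$cm_id, column = x$column %||% "",
                 mobile_phase_a = x$mobile_phase_a %||% "",
                 mobile_phase_b = x$mobile_phase_b %||% "",
                 additive_family = x$additive_family %||% "A1B1",
                 gradient = x$gradient, run_time = x$run_time,
                 temperature = x$temperature %||% 30)
  })
  names(out) <- vapply(out, `[[`, "", "cm_id")
  out
}

#' Write chromatographic method metadata to JSON
#'
#' @param cms Named list of [chrom_method()] objects.
#' @param path Output JSON path.
#' @export
write_cm_metadata <- function(cms, path) {
  payload <- lapply(unname(cms), function(x) {
    list(cm_id = x$cm_id, column = x$column,
         mobile_phase_a = x$mobile_phase_a, mobile_phase_b = x$mobile_phase_b,
         additive_family = x$additive_family,
         gradient = lapply(seq_len(nrow(x$gradient)),
                           function(i) unname(x$gradient[i, ])),
         run_time = x$run_time, temperature = x$temperature)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Construct a calibrant set
#'
#' A named, ordered list of calibrant molecule ids. Calibrants are molecules
#' with measured RT in every method involved in a projection; at least 5 are
#' required for a stable Gaussian-process fit.
#'
#' @param name Set name (e.g. `"B"`).
#' @param molecule_ids Character vector, no duplicates, length >= 5.
#' @return A `calibrant_set` object.
#' @export
calibrant_set <- function(name, molecule_ids) {
  molecule_ids <- as.character(molecule_ids)
  if (anyDuplicated(molecule_ids)) {
    stop("calibrant_set: duplicate molecule ids", call. = FALSE)
  }
  if (length(molecule_ids) < 5L) {
    stop("calibrant_set: need at least 5 calibrants", call. = FALSE)
  }
  structure(list(name = as.character(name), molecule_ids = molecule_ids),
            class = "calibrant_set")
}

#' Read / write a calibrant set (JSON `{name, molecule_ids}`)
#'
#' @param path JSON path.
#' @return [calibrant_set()] for the reader; the path, invisibly, for the
#'   writer.
#' @export
read_calibrant_set <- function(path) {
  x <- jsonlite::fromJSON(path)
  calibrant_set(x$name, x$molecule_ids)
}

#' @rdname read_calibrant_set
#' @param set A [calibrant_set()].
#' @export
write_calibrant_set <- function(set, path) {
  jsonlite::write_json(list(name = set$name,
                            molecule_ids = set$molecule_ids),
                       path, auto_unbox = TRUE)
  invisible(path)
}

#' Read a candidate table from CSV
#'
#' Columns `unknown_id,candidate_id,predicted_rt[,is_true]`; `is_true` (0/1
#' or logical) marks the true identity of the unknown feature, at most one
#' per unknown.
#'
#' @param path CSV path.
#' @return Data frame with columns `unknown_id`, `candidate_id`,
#'   `predicted_rt`, `is_true` (logical, `NA` when unlabeled).
#' @export
read_candidates <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("unknown_id", "candidate_id", "predicted_rt")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop("read_candidates: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  raw$is_true <- if ("is_true" %in% names(raw)) as.logical(raw$is_true) else NA
  per_true <- tapply(raw$is_true, raw$unknown_id,
                     function(v) sum(v, na.rm = TRUE))
  if (any(per_true > 1L)) {
    stop("read_candidates: more than one true identity for unknown(s): ",
         paste(names(per_true)[per_true > 1L], collapse = ", "), call. = FALSE)
  }
  raw[c("unknown_id", "candidate_id", "predicted_rt", "is_true")]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
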