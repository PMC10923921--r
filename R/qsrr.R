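#' Train/validation split with forced holdouts
#'
#' Splits molecule ids into a training and a validation set. Ids in
#' `holdout_ids` (e.g. molecules overlapping an evaluation database) are
#' never eligible for training and always end up in the validation set;
#' `fraction` applies to the remaining ids, with the training size floored.
#'
#' @param molecule_ids Character vector of ids.
#' @param holdout_ids Ids excluded from training eligibility.
#' @param fraction Training fraction of the eligible ids, in (0, 1).
#' @param seed Integer seed; the split is deterministic given the seed.
#' @return List with `train` and `validation` id vectors.
#' @export
split_train_validation <- function(molecule_ids, holdout_ids = character(),
                                   fraction = 0.75, seed = 1L) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1) {
    stop("split_train_validation: fraction must be in (0, 1)", call. = FALSE)
  }
  molecule_ids <- as.character(molecule_ids)
  eligible <- setdiff(molecule_ids, holdout_ids)
  n_train <- floor(fraction * length(eligible))
  train <- with_seed(seed, sort(sample(eligible, n_train)))
  list(train = train,
       validation = setdiff(molecule_ids, train))
}

#' Fit a QSRR retention model
#'
#' Quantitative structure-retention relationship: a single-hidden-layer
#' neural network (default 10 hidden units, linear output) regressing RT on
#' precomputed molecular descriptors, with L2 weight regularization.
#' Features and target are standardized to zero mean / unit variance;
#' zero-variance descriptor columns are dropped (their list is messaged).
#' With `reg_strength = "auto"` the L2 strength is chosen on an internal
#' seeded 75/25 holdout over a small grid, then the network is refit on all
#' rows.
#'
#' @param features Numeric matrix, molecules x named descriptors; rownames
#'   are molecule ids. No missing values allowed.
#' @param rts Numeric vector of RTs (minutes), aligned with rows.
#' @param hidden_units Hidden layer size (default 10).
#' @param reg_strength `"auto"` or a non-negative L2 decay value
#'   (standardized units).
#' @param seed Integer seed; training is reproducible given the seed.
#' @param maxit Maximum optimizer iterations per fit.
#' @return A `qsrr_model`.
#' @export
fit_qsrr <- function(features, rts, hidden_units = 10L, reg_strength = "auto",
                     seed = 1L, maxit = 500L) {
  X <- as.matrix(features)
  if (is.null(colnames(X))) {
    stop("fit_qsrr: features must have named columns", call. = FALSE)
  }
  if (nrow(X) != length(rts)) {
    stop("fit_qsrr: features rows and rts length differ", call. = FALSE)
  }
  if (anyNA(X) || any(!is.finite(X))) {
    stop("fit_qsrr: features contain NA/NaN/Inf; preprocess first",
         call. = FALSE)
  }
  sds <- apply(X, 2L, stats::sd)
  dropped <- colnames(X)[sds == 0]
  if (length(dropped)) {
    message("fit_qsrr: dropping ", length(dropped),
            " zero-variance descriptor(s): ",
            paste(utils::head(dropped, 10L), collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  centers <- colMeans(X)
  Xs <- scale(X, center = centers, scale = sds)
  y_mean <- mean(rts); y_sd <- stats::sd(rts)
  if (y_sd == 0) {
    # degenerate target: the constant is the model
    return(structure(list(net = NULL, feature_names = colnames(X),
                          dropped_features = dropped, centers = centers,
                          scales = sds, y_mean = y_mean, y_sd = 1,
                          hidden_units = hidden_units,
                          reg_strength = reg_strength, seed = seed),
                     class = "qsrr_model"))
  }
  ys <- (rts - y_mean) / y_sd

  fit_one <- function(x, y, decay, s) {
    with_seed(s, nnet::nnet(x, y, size = hidden_units, linout = TRUE,
                            decay = decay, maxit = maxit, trace = FALSE,
                            MaxNWts = 100000L))
  }
  if (identical(reg_strength, "auto")) {
    grid <- c(1e-3, 1e-2, 3e-2, 1e-1, 3e-1, 1)
    idx <- with_seed(seed + 1L,
                     sample.int(nrow(Xs), floor(0.75 * nrow(Xs))))
    rmse <- vapply(grid, function(d) {
      f <- fit_one(Xs[idx, , drop = FALSE], ys[idx], d, seed)
      p <- as.numeric(stats::predict(f, Xs[-idx, , drop = FALSE]))
      sqrt(mean((p - ys[-idx])^2))
    }, 0)
    reg_strength <- grid[which.min(rmse)]
  }
  net <- fit_one(Xs, ys, reg_strength, seed)
  structure(list(
    net = net, feature_names = colnames(X),
    dropped_features = dropped,
    centers = centers, scales = sds,
    y_mean = y_mean, y_sd = y_sd,
    hidden_units = hidden_units, reg_strength = reg_strength,
    seed = seed
  ), class = "qsrr_model")
}

#' Predict retention times from descriptors
#'
#' Features are aligned to the training schema by column name (extra columns
#' ignored, order irrelevant); a missing training descriptor is an error.
#'
#' @param model A [fit_qsrr()] model.
#' @param features Numeric matrix with named descriptor columns.
#' @return Numeric vector of predicted RTs, minutes.
#' @export
predict_qsrr <- function(model, features) {
  X <- as.matrix(features)
  missing_f <- setdiff(model$feature_names, colnames(X))
  if (length(missing_f)) {
    stop("predict_qsrr: missing descriptor(s): ",
         paste(utils::head(missing_f, 10L), collapse = ", "), call. = FALSE)
  }
  X <- X[, model$feature_names, drop = FALSE]
  if (is.null(model$net)) return(rep(model$y_mean, nrow(X)))
  Xs <- scale(X, center = model$centers, scale = model$scales)
  as.numeric(stats::predict(model$net, Xs)) * model$y_sd + model$y_mean
}

#' @export
predict.qsrr_model <- function(object, newdata, ...) {
  predict_qsrr(object, newdata)
}
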