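#' Rational quadratic covariance
#'
#' `k(x, x') = sf2 * (1 + (x - x')^2 / (2 * alpha * l^2))^(-alpha)` -- a
#' scale mixture of squared-exponential kernels. As `alpha -> Inf` it
#' converges to the squared exponential `sf2 * exp(-(x - x')^2 / (2 l^2))`.
#'
#' @param x,x2 Numeric vectors of inputs (minutes).
#' @param sf2 Signal variance (> 0), minutes^2.
#' @param l Length scale (> 0), minutes.
#' @param alpha Shape parameter (> 0), dimensionless.
#' @return `length(x) x length(x2)` covariance matrix.
#' @export
rq_kernel <- function(x, x2, sf2, l, alpha) {
  if (any(c(sf2, l, alpha) <= 0) || anyNA(c(sf2, l, alpha))) {
    stop("rq_kernel: hyperparameters must be positive", call. = FALSE)
  }
  d2 <- outer(x, x2, `-`)^2
  sf2 * (1 + d2 / (2 * alpha * l^2))^(-alpha)
}

# Negative log marginal likelihood of the constant-mean RQ GP, in
# standardized coordinates. par = (m, log sf2, log l, log alpha, log sn2).
gp_nll <- function(par, xs, ys) {
  m <- par[1L]
  sf2 <- exp(par[2L]); l <- exp(par[3L])
  alpha <- exp(par[4L]); sn2 <- exp(par[5L])
  n <- length(xs)
  K <- rq_kernel(xs, xs, sf2, l, alpha)
  diag(K) <- diag(K) + sn2
  L <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(L)) return(1e10)
  r <- ys - m
  a <- backsolve(L, forwardsolve(t(L), r))
  val <- 0.5 * sum(r * a) + sum(log(diag(L))) + 0.5 * n * log(2 * pi)
  if (!is.finite(val)) 1e10 else val
}

#' Fit a retention time projection model
#'
#' Fits a one-dimensional Gaussian-process regression mapping calibrant RTs
#' in a source chromatographic method to the same molecules' RTs in a target
#' method. The GP has a constant mean (fitted jointly), a rational quadratic
#' kernel and an additive noise variance (floored, never zero: calibrant RTs
#' are noisy measurements, so exact interpolation is deliberately avoided).
#' Inputs and outputs are standardized to zero mean / unit variance before
#' fitting; hyperparameters are maximized over the log marginal likelihood
#' with L-BFGS-B from `n_restarts` seeded initializations, keeping the best.
#'
#' @param x Calibrant RTs in the source method, minutes (length >= 5).
#' @param y Calibrant RTs in the target method, minutes (same length).
#' @param seed Integer seed controlling restart initializations.
#' @param n_restarts Number of optimizer starts (default 5; the first is a
#'   fixed unit-scale init, the rest are log-uniform draws).
#' @param noise_floor Lower bound for the noise variance in standardized
#'   units (default 1e-6).
#' @param source_cm,target_cm Optional method ids stored for bookkeeping.
#' @return A `projection_model` with the fitted hyperparameters (in
#'   standardized units), training data, standardization constants and the
#'   achieved log marginal likelihood.
#' @export
fit_projection <- function(x, y, seed = 1L, n_restarts = 5L,
                           noise_floor = 1e-6,
                           source_cm = NA_character_,
                           target_cm = NA_character_) {
  if (length(x) != length(y)) {
    stop("fit_projection: x and y must have equal length", call. = FALSE)
  }
  if (length(x) < 5L) {
    stop("fit_projection: need at least 5 calibrant pairs", call. = FALSE)
  }
  if (any(!is.finite(x)) || any(!is.finite(y)) || any(x <= 0) || any(y <= 0)) {
    stop("fit_projection: RTs must be finite and positive", call. = FALSE)
  }
  x_mean <- mean(x); x_sd <- stats::sd(x); if (x_sd == 0) x_sd <- 1
  y_mean <- mean(y); y_sd <- stats::sd(y); if (y_sd == 0) y_sd <- 1
  xs <- (x - x_mean) / x_sd
  ys <- (y - y_mean) / y_sd

  # alpha is bounded below at 0.5: smaller values make the RQ covariance
  # near-constant at long range with a spike at zero distance, turning the
  # posterior into an interpolator of calibrant noise rather than a smooth
  # warp (the marginal likelihood alone does not rule this out at n ~ 35)
  lower <- c(-5, log(1e-4), log(1e-3), log(0.5), log(noise_floor))
  upper <- c(5, log(1e4), log(1e3), log(1e6), log(10))
  inits <- with_seed(seed, {
    first <- c(0, 0, 0, 0, log(1e-2))
    more <- if (n_restarts > 1L) {
      lapply(seq_len(n_restarts - 1L), function(i) c(
        stats::runif(1, -0.5, 0.5),
        log(stats::runif(1, 0.5, 2)),
        stats::runif(1, log(0.1), log(2)),
        stats::runif(1, log(0.5), log(10)),
        stats::runif(1, log(1e-4), log(0.1))
      ))
    } else list()
    c(list(first), more)
  })

  fits <- lapply(inits, function(p0) {
    tryCatch(
      stats::optim(p0, gp_nll, xs = xs, ys = ys, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 200L)),
      error = function(e) NULL
    )
  })
  fits <- Filter(function(f) !is.null(f) && is.finite(f$value) &&
                   f$value < 1e9, fits)
  if (length(fits) == 0L) {
    stop("fit_projection: all optimizer restarts failed (n = ", length(x),
         ", x range ", min(x), "-", max(x), ")", call. = FALSE)
  }
  lmls <- -vapply(fits, `[[`, 0, "value")
  best <- fits[[which.max(lmls)]]
  p <- best$par
  structure(list(
    source_cm = source_cm, target_cm = target_cm,
    mean_const = p[1L],
    rq_signal_var = exp(p[2L]),
    rq_length_scale = exp(p[3L]),
    rq_alpha = exp(p[4L]),
    noise_var = max(exp(p[5L]), noise_floor),
    train_x = x, train_y = y,
    standardization = list(x_mean = x_mean, x_sd = x_sd,
                           y_mean = y_mean, y_sd = y_sd),
    log_marginal_likelihood = max(lmls),
    restart_lml = sort(lmls, decreasing = TRUE),
    seed = seed, n_restarts = n_restarts
  ), class = "projection_model")
}

#' Project retention times through a fitted model
#'
#' Standard GP posterior prediction, de-standardized back to minutes. The
#' reported `sd` is the predictive standard deviation of a new observation
#' (latent posterior plus measurement noise). Inputs outside the training RT
#' range are still projected but flagged as extrapolations.
#'
#' @param model A fitted [fit_projection()] model.
#' @param x_new Numeric vector of RTs in the source method, minutes.
#' @return `data.frame` with columns `mean`, `sd` (minutes) and
#'   `extrapolated` (logical).
#' @export
project <- function(model, x_new) {
  if (!inherits(model, "projection_model")) {
    stop("project: not a fitted projection model", call. = FALSE)
  }
  st <- model$standardization
  xs <- (model$train_x - st$x_mean) / st$x_sd
  ys <- (model$train_y - st$y_mean) / st$y_sd
  xn <- (x_new - st$x_mean) / st$x_sd
  K <- rq_kernel(xs, xs, model$rq_signal_var, model$rq_length_scale,
                 model$rq_alpha)
  diag(K) <- diag(K) + model$noise_var
  L <- chol(K)
  r <- ys - model$mean_const
  a <- backsolve(L, forwardsolve(t(L), r))
  ks <- rq_kernel(xs, xn, model$rq_signal_var, model$rq_length_scale,
                  model$rq_alpha)
  mu <- model$mean_const + drop(crossprod(ks, a))
  v <- forwardsolve(t(L), ks)
  var_pred <- pmax(model$rq_signal_var - colSums(v^2), 0) + model$noise_var
  data.frame(
    mean = mu * st$y_sd + st$y_mean,
    sd = sqrt(var_pred) * st$y_sd,
    extrapolated = x_new < min(model$train_x) | x_new > max(model$train_x)
  )
}

#' @export
predict.projection_model <- function(object, newdata, ...) {
  project(object, newdata)$mean
}

#' Serialize / deserialize a projection model (JSON)
#'
#' The JSON stores kernel hyperparameters, training vectors, standardization
#' constants and fit diagnostics at full precision, so a round trip
#' reproduces predictions exactly.
#'
#' @param model A `projection_model`.
#' @param path JSON path.
#' @return `read_model` returns the model; `write_model` the path, invisibly.
#' @export
write_model <- function(model, path) {
  payload <- list(
    kernel = "rational_quadratic",
    source_cm = model$source_cm, target_cm = model$target_cm,
    mean_const = model$mean_const,
    rq_signal_var = model$rq_signal_var,
    rq_length_scale = model$rq_length_scale,
    rq_alpha = model$rq_alpha,
    noise_var = model$noise_var,
    train_x = model$train_x, train_y = model$train_y,
    standardization = model$standardization,
    log_marginal_likelihood = model$log_marginal_likelihood,
    seed = model$seed, n_restarts = model$n_restarts
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  x <- jsonlite::fromJSON(path)
  m <- list(
    source_cm = x$source_cm, target_cm = x$target_cm,
    mean_const = x$mean_const,
    rq_signal_var = x$rq_signal_var,
    rq_length_scale = x$rq_length_scale,
    rq_alpha = x$rq_alpha,
    noise_var = x$noise_var,
    train_x = as.numeric(x$train_x), train_y = as.numeric(x$train_y),
    standardization = lapply(x$standardization, as.numeric),
    log_marginal_likelihood = x$log_marginal_likelihood,
    seed = x$seed, n_restarts = x$n_restarts
  )
  structure(m, class = "projection_model")
}
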