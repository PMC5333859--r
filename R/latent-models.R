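#' Fit a principal component regression model
#'
#' Columns of `X` are mean-centered (no unit-variance scaling: all features
#' share percent-mass units), the leading eigenvectors of the covariance of
#' `X` define the loadings, scores are the projections of the centered data,
#' and the centered response is regressed on the first `n_factors` scores by
#' ordinary least squares. Coefficients are folded back to feature space. The
#' sign of each loading is fixed so its largest-magnitude element is positive,
#' which makes results deterministic across runs.
#'
#' @param X A `feature_matrix` or numeric matrix (samples x features).
#' @param y Numeric response vector.
#' @param n_factors Number of principal components to retain.
#'
#' @return A `latent_model` with loadings, eigenvalues, scores, per-factor
#'   coefficient path and feature-space `coefficients`.
#' @export
fit_pcr <- function(X, y, n_factors) {
  X <- fm_matrix(X)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n, n >= 3)
  if (n_factors < 1 || n_factors > min(n - 1, p)) {
    stop("n_factors must be between 1 and min(n - 1, p)", call. = FALSE)
  }
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  Xc <- sweep(X, 2, x_mean)
  yc <- y - y_mean
  k_avail <- min(n - 1, p)
  sv <- svd(Xc, nu = 0, nv = k_avail)
  rank <- sum(sv$d > max(sv$d) * 1e-10)
  if (n_factors > rank) {
    stop("n_factors (", n_factors, ") exceeds the rank of X (", rank, ")",
         call. = FALSE)
  }
  V <- sv$v[, seq_len(n_factors), drop = FALSE]
  # deterministic sign: largest-magnitude loading element positive
  for (k in seq_len(n_factors)) {
    j <- which.max(abs(V[, k]))
    if (V[j, k] < 0) V[, k] <- -V[, k]
  }
  Z <- Xc %*% V
  b_z <- drop(crossprod(Z, yc)) / colSums(Z^2)
  coef_path <- sapply(seq_len(n_factors), function(k) {
    drop(V[, seq_len(k), drop = FALSE] %*% b_z[seq_len(k)])
  })
  coef_path <- matrix(coef_path, nrow = p)
  structure(
    list(
      method = "PCR",
      x_mean = x_mean,
      y_mean = y_mean,
      loadings = V,
      eigenvalues = (sv$d[seq_len(n_factors)]^2) / (n - 1),
      scores = Z,
      score_coefficients = b_z,
      coef_path = coef_path,
      coefficients = coef_path[, n_factors],
      n_factors = n_factors
    ),
    class = "latent_model"
  )
}

#' Fit a partial least squares model (NIPALS, single response)
#'
#' Per factor: the weight vector is proportional to `X'y` (unit norm, so the
#' first factor maximizes covariance between the score and the response), the
#' score is `Xw`, the X-loading and y-loading come from regressing `X` and `y`
#' on the score, and `X` is deflated. Coefficients are composed across factors
#' as `W (P'W)^{-1} q`. Centering only, as for PCR.
#'
#' @inheritParams fit_pcr
#' @return A `latent_model` with weights, loadings, y-loadings, per-factor
#'   coefficient path and feature-space `coefficients`.
#' @export
fit_pls <- function(X, y, n_factors) {
  X <- fm_matrix(X)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n, n >= 3)
  if (n_factors < 1 || n_factors > min(n - 1, p)) {
    stop("n_factors must be between 1 and min(n - 1, p)", call. = FALSE)
  }
  if (var(y) == 0) {
    stop("response has zero variance: degenerate response", call. = FALSE)
  }
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  Xd <- sweep(X, 2, x_mean)
  yc <- y - y_mean
  W <- matrix(0, p, n_factors)
  P <- matrix(0, p, n_factors)
  Tm <- matrix(0, n, n_factors)
  q <- numeric(n_factors)
  for (k in seq_len(n_factors)) {
    w <- drop(crossprod(Xd, yc))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {
      stop("all-zero weight vector at factor ", k,
           ": X carries no further covariance with y", call. = FALSE)
    }
    w <- w / nw
    j <- which.max(abs(w))
    if (w[j] < 0) w <- -w
    t_k <- drop(Xd %*% w)
    tt <- sum(t_k^2)
    p_k <- drop(crossprod(Xd, t_k)) / tt
    q[k] <- sum(yc * t_k) / tt
    Xd <- Xd - tcrossprod(t_k, p_k)
    W[, k] <- w
    P[, k] <- p_k
    Tm[, k] <- t_k
  }
  coef_path <- sapply(seq_len(n_factors), function(k) {
    Wk <- W[, seq_len(k), drop = FALSE]
    Pk <- P[, seq_len(k), drop = FALSE]
    drop(Wk %*% solve(crossprod(Pk, Wk), q[seq_len(k)]))
  })
  coef_path <- matrix(coef_path, nrow = p)
  structure(
    list(
      method = "PLS",
      x_mean = x_mean,
      y_mean = y_mean,
      weights = W,
      loadings = P,
      y_loadings = q,
      scores = Tm,
      coef_path = coef_path,
      coefficients = coef_path[, n_factors],
      n_factors = n_factors
    ),
    class = "latent_model"
  )
}

#' Predict from a fitted latent model
#'
#' @param object A `latent_model` from [fit_pcr()] or [fit_pls()].
#' @param newdata A `feature_matrix` or numeric matrix with matching columns.
#' @param n_factors Use the coefficient path truncated at this many factors
#'   (default all fitted factors); 0 gives the mean-only prediction.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.latent_model <- function(object, newdata, n_factors = object$n_factors, ...) {
  X <- fm_matrix(newdata)
  if (ncol(X) != length(object$x_mean)) {
    stop("newdata has ", ncol(X), " features but the model expects ",
         length(object$x_mean), call. = FALSE)
  }
  if (n_factors < 0 || n_factors > object$n_factors) {
    stop("n_factors must be between 0 and the fitted factor count", call. = FALSE)
  }
  Xc <- sweep(X, 2, object$x_mean)
  if (n_factors == 0) {
    return(rep(object$y_mean, nrow(X)))
  }
  drop(Xc %*% object$coef_path[, n_factors]) + object$y_mean
}

#' @export
print.latent_model <- function(x, ...) {
  cat("<latent_model>", x$method, "with", x$n_factors, "factor(s),",
      length(x$x_mean), "features\n")
  invisible(x)
}

#' Align model coefficients with the feature grid
#'
#' Returns the feature-space regression coefficients labelled with the grid's
#' time and temperature, for interpreting which temperatures drive the
#' prediction of a property.
#'
#' @param model A fitted `latent_model`.
#' @param grid The `grid` tibble of the `feature_matrix` the model was trained
#'   on (or the `feature_matrix` itself).
#' @return A tibble: `time`, `temperature` (degC; meaningful on ramp points),
#'   `is_ramp`, `coefficient`.
#' @export
coefficient_profile <- function(model, grid) {
  stopifnot(inherits(model, "latent_model"))
  if (inherits(grid, "feature_matrix")) grid <- grid$grid
  if (nrow(grid) != length(model$coefficients)) {
    stop("grid has ", nrow(grid), " points but the model has ",
         length(model$coefficients), " coefficients", call. = FALSE)
  }
  tibble(
    time = grid$time,
    temperature = grid$temperature,
    is_ramp = grid$is_ramp,
    coefficient = model$coefficients
  )
}

#' Locate the dominant coefficient peak within a temperature window
#'
#' @param profile Result of [coefficient_profile()].
#' @param window Temperature window `c(lo, hi)` in degC (ramp points only).
#' @param zero_tol Coefficients with absolute value at or below this are
#'   treated as absent.
#' @return A one-row tibble (`time`, `temperature`, `coefficient`) at the
#'   maximum absolute coefficient, or a zero-row tibble if all coefficients in
#'   the window are (numerically) zero.
#' @export
profile_peak <- function(profile, window = c(-Inf, Inf), zero_tol = 1e-12) {
  cand <- profile[profile$is_ramp &
                    profile$temperature >= window[1] &
                    profile$temperature <= window[2], ]
  if (nrow(cand) == 0 || all(abs(cand$coefficient) <= zero_tol)) {
    return(cand[0, c("time", "temperature", "coefficient")])
  }
  cand[which.max(abs(cand$coefficient)), c("time", "temperature", "coefficient")]
}

#' Save / load a latent model as JSON
#'
#' @param model A `latent_model`.
#' @param path JSON file path.
#' @return `path` (write) or the restored `latent_model` (read).
#' @export
write_latent_model <- function(model, path) {
  stopifnot(inherits(model, "latent_model"))
  payload <- list(
    method = model$method,
    n_factors = model$n_factors,
    x_mean = model$x_mean,
    y_mean = model$y_mean,
    loadings = model$loadings,
    coefficients = model$coefficients,
    coef_path = model$coef_path
  )
  if (model$method == "PLS") {
    payload$weights <- model$weights
    payload$y_loadings <- model$y_loadings
  } else {
    payload$eigenvalues <- model$eigenvalues
    payload$score_coefficients <- model$score_coefficients
  }
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_latent_model
#' @export
read_latent_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  payload$loadings <- as.matrix(payload$loadings)
  payload$coef_path <- as.matrix(payload$coef_path)
  if (!is.null(payload$weights)) payload$weights <- as.matrix(payload$weights)
  structure(payload, class = "latent_model")
}
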