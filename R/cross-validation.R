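#' Leave-one-out cross-validation over a range of factor counts
#'
#' For every factor count 0..`k_max` and every sample, the model is refit on
#' the remaining samples (re-centering inside the fold) and used to predict
#' the held-out sample. Factor count 0 is the mean-only model. PRESS(k) is the
#' sum of squared held-out residuals.
#'
#' @param X A `feature_matrix` or numeric matrix.
#' @param y Numeric response.
#' @param method `"PLS"` or `"PCR"`.
#' @param k_max Largest factor count to evaluate (default 10); must not exceed
#'   `min(n - 2, p)`.
#'
#' @return A `cv_result`: `press_by_factors` (named vector, "0".."k_max"),
#'   `predictions` (n x (k_max + 1) matrix of held-out predictions),
#'   `residuals`, `minimizing_factors`, `method`, `y`.
#' @export
loo_cross_validate <- function(X, y, method = c("PLS", "PCR"), k_max = 10) {
  method <- match.arg(method)
  X <- fm_matrix(X)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n)
  if (n < 4) stop("leave-one-out cross-validation needs at least 4 samples", call. = FALSE)
  if (k_max < 1 || k_max > min(n - 2, p)) {
    stop("k_max must be between 1 and min(n - 2, p)", call. = FALSE)
  }
  fit_fun <- if (method == "PLS") fit_pls else fit_pcr
  preds <- matrix(NA_real_, n, k_max + 1)
  for (i in seq_len(n)) {
    Xi <- X[-i, , drop = FALSE]
    yi <- y[-i]
    if (all(abs(sweep(Xi, 2, colMeans(Xi))) < 1e-14)) {
      stop("fold ", i, " has zero variance in X: degenerate fold", call. = FALSE)
    }
    model <- fit_fun(Xi, yi, n_factors = k_max)
    for (k in 0:k_max) {
      preds[i, k + 1] <- predict(model, X[i, , drop = FALSE], n_factors = k)
    }
  }
  residuals <- y - preds
  press <- colSums(residuals^2)
  names(press) <- as.character(0:k_max)
  colnames(preds) <- colnames(residuals) <- as.character(0:k_max)
  structure(
    list(
      method = method,
      k_max = k_max,
      y = y,
      predictions = preds,
      residuals = residuals,
      press_by_factors = press,
      minimizing_factors = as.integer(which.min(press) - 1)
    ),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result>", x$method, "LOO over k = 0..", x$k_max,
      "; PRESS minimized at k =", x$minimizing_factors, "\n")
  print(round(x$press_by_factors, 4))
  invisible(x)
}

#' Choose a parsimonious factor count from a PRESS table
#'
#' Randomized paired test (van der Voet style) of each candidate factor count
#' against the PRESS-minimizing count: the statistic is the mean difference of
#' squared held-out residuals, its null distribution is generated by random
#' sign flips of the paired differences, and the chosen count is the smallest
#' candidate whose two-sided p-value exceeds `alpha` -- i.e. the simplest
#' model whose cross-validated error is statistically indistinguishable from
#' the best one.
#'
#' @param cv A `cv_result` from [loo_cross_validate()].
#' @param alpha Significance threshold (default 0.1).
#' @param n_randomizations Number of sign-flip draws (default 2000; at least
#'   100).
#' @param seed Seed for the sign flips, making the choice deterministic.
#'
#' @return The chosen factor count (integer) with attributes `p_values`
#'   (named, one per candidate 0..minimizer) and `minimizing_factors`.
#' @export
select_factors <- function(cv, alpha = 0.1, n_randomizations = 2000, seed = 1) {
  stopifnot(inherits(cv, "cv_result"))
  if (n_randomizations < 100) {
    stop("n_randomizations must be at least 100", call. = FALSE)
  }
  k_min <- cv$minimizing_factors
  n <- length(cv$y)
  r_min2 <- cv$residuals[, as.character(k_min)]^2
  candidates <- 0:k_min
  set.seed(seed)
  flips <- matrix(sample(c(-1, 1), n_randomizations * n, replace = TRUE),
                  nrow = n_randomizations)
  p_values <- vapply(candidates, function(k) {
    if (k == k_min) return(1)
    d <- cv$residuals[, as.character(k)]^2 - r_min2
    if (all(d == 0)) return(1)
    obs <- mean(d)
    null <- drop(flips %*% d) / n
    (1 + sum(abs(null) >= abs(obs) - 1e-15)) / (n_randomizations + 1)
  }, numeric(1))
  names(p_values) <- as.character(candidates)
  chosen <- candidates[which(p_values > alpha)[1]]
  structure(as.integer(chosen),
            p_values = p_values,
            minimizing_factors = k_min)
}

#' Calibration and cross-validation performance metrics
#'
#' `SECV = sqrt(PRESS / n)`, `SEC = sqrt(RSS / (n - n_factors - 1))`,
#' R-squared is the squared Pearson correlation between the reference values
#' and the held-out predictions, and `RPD = sd(y) / SECV` (sample SD, n - 1
#' denominator). `r2_press = 1 - PRESS/SST` is carried along as a secondary
#' diagnostic.
#'
#' @param y Reference values.
#' @param y_cv Held-out (leave-one-out) predictions.
#' @param y_fit In-sample predictions (optional; `SEC` is `NA` without them).
#' @param n_factors Factor count used, for the SEC degrees of freedom.
#'
#' @return A one-row `model_metrics` tibble: `SEC`, `SECV`, `R2`, `RPD`,
#'   `r2_press`, `n_factors`, `n`.
#' @export
compute_metrics <- function(y, y_cv, y_fit = NULL, n_factors = 0) {
  n <- length(y)
  stopifnot(length(y_cv) == n, n >= 3)
  press <- sum((y - y_cv)^2)
  secv <- sqrt(press / n)
  sec <- NA_real_
  if (!is.null(y_fit)) {
    stopifnot(length(y_fit) == n)
    rss <- sum((y - y_fit)^2)
    df <- n - n_factors - 1
    if (df < 1) stop("no residual degrees of freedom for SEC", call. = FALSE)
    sec <- sqrt(rss / df)
  }
  # squared Pearson correlation of measured vs held-out predictions, floored
  # at zero for negative association: leave-one-out predictions of an
  # uninformative model are anti-correlated with the held-out values (each
  # fold's fit excludes them), and that artifact must not count as skill
  r2 <- if (sd(y_cv) == 0 || sd(y) == 0) {
    if (isTRUE(all.equal(y, y_cv))) 1 else 0
  } else {
    r <- cor(y, y_cv)
    if (r > 0) r^2 else 0
  }
  sst <- sum((y - mean(y))^2)
  rpd <- if (secv == 0) {
    warning("SECV is zero: RPD undefined, reported as Inf", call. = FALSE)
    Inf
  } else {
    sd(y) / secv
  }
  out <- tibble(
    SEC = sec,
    SECV = secv,
    R2 = r2,
    RPD = rpd,
    r2_press = 1 - press / sst,
    n_factors = as.integer(n_factors),
    n = as.integer(n)
  )
  class(out) <- c("model_metrics", class(out))
  out
}

#' Calibrate one property end to end
#'
#' Runs leave-one-out cross-validation, chooses the parsimonious factor count,
#' fits the final model on all samples, and computes the metrics at the chosen
#' count. If the selection lands on 0 factors (no usable signal) the final
#' model is fitted with 1 factor for interpretability while metrics keep the
#' chosen count.
#'
#' @inheritParams loo_cross_validate
#' @inheritParams select_factors
#' @return A `tg_calibration`: list with `model`, `cv`, `chosen_factors`,
#'   `minimizing_factors`, `p_values`, `metrics`.
#' @export
calibrate_property <- function(X, y, method = c("PLS", "PCR"), k_max = 10,
                               alpha = 0.1, n_randomizations = 2000, seed = 1) {
  method <- match.arg(method)
  cv <- loo_cross_validate(X, y, method = method, k_max = k_max)
  chosen <- select_factors(cv, alpha = alpha,
                           n_randomizations = n_randomizations, seed = seed)
  k_fit <- max(chosen, 1L)
  fit_fun <- if (method == "PLS") fit_pls else fit_pcr
  model <- fit_fun(X, y, n_factors = k_fit)
  y_fit <- if (chosen == 0) rep(mean(y), length(y)) else predict(model, X, n_factors = chosen)
  metrics <- compute_metrics(
    y,
    y_cv = cv$predictions[, as.character(chosen)],
    y_fit = y_fit,
    n_factors = chosen
  )
  structure(
    list(
      method = method,
      model = model,
      cv = cv,
      chosen_factors = as.integer(chosen),
      minimizing_factors = attr(chosen, "minimizing_factors"),
      p_values = attr(chosen, "p_values"),
      metrics = metrics
    ),
    class = "tg_calibration"
  )
}

#' @export
print.tg_calibration <- function(x, ...) {
  cat("<tg_calibration>", x$method, "- chosen", x$chosen_factors,
      "factor(s) (PRESS minimum at", paste0(x$minimizing_factors, ")"), "\n")
  print(x$metrics)
  invisible(x)
}
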