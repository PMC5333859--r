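#' Kinetic deconvolution regimes
#'
#' A regime names the fixed boundary temperatures at which masses are read off
#' a normalized TG curve to split it into constituent losses:
#'
#' * `KIN1` (chemical): boundaries 130 / 250 / 350 / 500 degC giving masses
#'   A, B, C, D; hemicellulose = (B - C)/A, cellulose = (C - D)/A,
#'   lignin = D/A (all x 100).
#' * `KIN2` (chemical): boundaries 180 / 360 / 440 degC giving masses A, B, C;
#'   hemicellulose = (A - B)/A (loss 180--360), cellulose = (B - C)/A (loss
#'   360--440), lignin = C/A.
#' * `KIN3` (proximate): A = dry mass (100 on a normalized curve), B = mass at
#'   the end of the nitrogen isothermal hold, C = final residue after
#'   oxidation; volatile matter = (A - B)/A, ash = C/A, fixed carbon by
#'   difference.
#'
#' @param name `"KIN1"`, `"KIN2"` or `"KIN3"`.
#' @param boundaries Optional override of the boundary temperatures (degC) for
#'   the chemical regimes.
#'
#' @return A `kinetic_regime` object.
#' @export
kinetic_regime <- function(name = c("KIN1", "KIN2", "KIN3"), boundaries = NULL) {
  name <- match.arg(name)
  if (is.null(boundaries)) {
    boundaries <- switch(name,
      KIN1 = c(A = 130, B = 250, C = 350, D = 500),
      KIN2 = c(A = 180, B = 360, C = 440),
      KIN3 = NULL
    )
  }
  if (!is.null(boundaries) && any(diff(boundaries) <= 0)) {
    stop("boundary temperatures must be strictly increasing", call. = FALSE)
  }
  structure(list(name = name, boundaries = boundaries), class = "kinetic_regime")
}

#' Estimate chemical composition by kinetic deconvolution
#'
#' Reads the normalized masses at the regime's boundary temperatures (linear
#' interpolation on the heating ramp) and converts mass differences into
#' hemicellulose, cellulose and lignin percentages.
#'
#' @param tg A normalized [thermogram()].
#' @param regime A `KIN1` or `KIN2` [kinetic_regime()].
#' @return A one-row tibble: `sample_id`, `regime`, `hemicellulose`,
#'   `cellulose`, `lignin`.
#' @export
estimate_chemical <- function(tg, regime = kinetic_regime("KIN1")) {
  stopifnot(inherits(tg, "thermogram"), inherits(regime, "kinetic_regime"))
  if (regime$name == "KIN3") {
    stop("KIN3 is a proximate regime; use estimate_proximate()", call. = FALSE)
  }
  m <- mass_after_temperature(tg, regime$boundaries)
  names(m) <- names(regime$boundaries)
  if (regime$name == "KIN1") {
    hemi <- (m[["B"]] - m[["C"]]) / m[["A"]] * 100
    cell <- (m[["C"]] - m[["D"]]) / m[["A"]] * 100
    lignin <- m[["D"]] / m[["A"]] * 100
  } else {
    hemi <- (m[["A"]] - m[["B"]]) / m[["A"]] * 100
    cell <- (m[["B"]] - m[["C"]]) / m[["A"]] * 100
    lignin <- m[["C"]] / m[["A"]] * 100
  }
  tibble(
    sample_id = tg$sample_id,
    regime = regime$name,
    hemicellulose = hemi,
    cellulose = cell,
    lignin = lignin
  )
}

#' Estimate proximate composition from a nitrogen-plus-air thermogram
#'
#' Volatile matter is the dry-basis mass lost over the nitrogen stage (down to
#' the mass B at the end of the nitrogen isothermal hold), ash is the final
#' residue after oxidation in air, and fixed carbon is obtained by difference,
#' so the three always sum to exactly 100.
#'
#' @param tg A normalized [thermogram()] whose program ends with an air stage.
#' @return A one-row tibble: `sample_id`, `regime`, `volatile_matter`, `ash`,
#'   `fixed_carbon`.
#' @export
estimate_proximate <- function(tg) {
  stopifnot(inherits(tg, "thermogram"))
  if (!tg$normalized) {
    stop("estimate_proximate expects a normalized thermogram", call. = FALSE)
  }
  if (!has_air_segment(tg$program)) {
    stop("heating program has no air stage: cannot measure ash", call. = FALSE)
  }
  t_n2 <- nitrogen_end_time(tg$program)
  A <- tg$mass[1]
  B <- approx(tg$time, tg$mass, xout = t_n2, rule = 2)$y
  C <- tg$mass[length(tg$mass)]
  vm <- (A - B) / A * 100
  ash <- C / A * 100
  tibble(
    sample_id = tg$sample_id,
    regime = "KIN3",
    volatile_matter = vm,
    ash = ash,
    fixed_carbon = 100 - vm - ash
  )
}

#' Apply a kinetic regime to a set of thermograms
#'
#' @param tgs List of normalized [thermogram()]s.
#' @param regime A [kinetic_regime()] (or its name).
#' @return A tibble of per-sample estimates.
#' @export
estimate_kinetics <- function(tgs, regime = kinetic_regime("KIN1")) {
  if (is.character(regime)) regime <- kinetic_regime(regime)
  if (regime$name == "KIN3") {
    purrr::list_rbind(purrr::map(tgs, estimate_proximate))
  } else {
    purrr::list_rbind(purrr::map(tgs, estimate_chemical, regime = regime))
  }
}

#' Evaluate kinetic estimates against reference values
#'
#' Fits the simple linear recalibration `measured = a + b * estimate` by least
#' squares and reports the same metrics used for the chemometric models: SEC
#' from the in-sample residuals, and SECV / R-squared / RPD from leave-one-out
#' refits of the univariate regression.
#'
#' @param estimates Tibble of kinetic estimates (from [estimate_kinetics()]).
#' @param truth Tibble of reference compositions with matching `sample_id`s.
#' @param property Name of the property column present in both tables.
#' @return A one-row `model_metrics` tibble.
#' @export
evaluate_kinetic <- function(estimates, truth, property) {
  stopifnot(property %in% names(estimates), property %in% names(truth))
  merged <- dplyr::inner_join(
    estimates[, c("sample_id", property)] |> stats::setNames(c("sample_id", "estimate")),
    truth[, c("sample_id", property)] |> stats::setNames(c("sample_id", "measured")),
    by = "sample_id"
  )
  n <- nrow(merged)
  if (n < 3) stop("need at least 3 matched samples", call. = FALSE)
  x <- merged$estimate
  y <- merged$measured
  if (var(x) == 0) {
    stop("kinetic estimates have zero variance: degenerate regressor", call. = FALSE)
  }
  fit <- lm(y ~ x)
  y_fit <- fitted(fit)
  y_cv <- vapply(seq_len(n), function(i) {
    f <- lm(y[-i] ~ x[-i])
    unname(coef(f)[1] + coef(f)[2] * x[i])
  }, numeric(1))
  metrics <- compute_metrics(y, y_cv, y_fit = y_fit, n_factors = 1)
  metrics$property <- property
  metrics$method <- if ("regime" %in% names(estimates)) estimates$regime[1] else "kinetic"
  metrics[, c("property", "method", setdiff(names(metrics), c("property", "method")))]
}
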