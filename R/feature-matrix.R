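#' Resample normalized thermograms onto a shared time grid
#'
#' Builds the predictor matrix for chemometric calibration: each normalized
#' thermogram is linearly interpolated onto a uniform grid of `n_points` time
#' points spanning the post-drying part of the shared heating program. The
#' grid carries the program temperature at each point plus ramp/atmosphere
#' flags for interpretation; the feature axis is time (not temperature)
#' because the program contains isothermal holds where temperature is not
#' injective.
#'
#' @param tgs List of normalized [thermogram()] objects sharing one heating
#'   program.
#' @param n_points Number of grid points (default 500, which resolves the
#'   105--800 degC ramp at roughly 1.4 degC).
#'
#' @return A `feature_matrix` object: list with `X` (samples x grid matrix of
#'   mass percent), `grid` (tibble: time, temperature, is_ramp, atmosphere),
#'   `sample_ids`, and the shared `program`.
#' @export
build_feature_matrix <- function(tgs, n_points = 500) {
  stopifnot(is.list(tgs), length(tgs) >= 1)
  if (!all(vapply(tgs, inherits, logical(1), what = "thermogram"))) {
    stop("tgs must be a list of thermogram objects", call. = FALSE)
  }
  if (!is.numeric(n_points) || n_points < 2) {
    stop("n_points must be at least 2", call. = FALSE)
  }
  if (!all(vapply(tgs, function(tg) tg$normalized, logical(1)))) {
    stop("all thermograms must be normalized before building a feature matrix",
         call. = FALSE)
  }
  program <- tgs[[1]]$program
  same <- vapply(tgs, function(tg) programs_identical(tg$program, program), logical(1))
  if (!all(same)) {
    stop("thermograms were acquired under different heating programs", call. = FALSE)
  }
  t0 <- max(vapply(tgs, function(tg) tg$time[1], numeric(1)))
  t1 <- min(vapply(tgs, function(tg) tg$time[length(tg$time)], numeric(1)))
  if (t1 <= t0) stop("thermograms share no common time span", call. = FALSE)
  grid_time <- seq(t0, t1, length.out = n_points)
  X <- t(vapply(tgs, function(tg) {
    approx(tg$time, tg$mass, xout = grid_time, rule = 1)$y
  }, numeric(n_points)))
  if (anyNA(X)) stop("resampling produced missing values", call. = FALSE)
  sample_ids <- unname(vapply(tgs, function(tg) tg$sample_id, character(1)))
  rownames(X) <- sample_ids
  grid <- tibble(
    time = grid_time,
    temperature = program_temperature(program, grid_time),
    is_ramp = program_is_ramp(program, grid_time),
    atmosphere = program_atmosphere(program, grid_time)
  )
  structure(
    list(X = X, grid = grid, sample_ids = sample_ids, program = program),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("<feature_matrix>", nrow(x$X), "samples x", ncol(x$X), "grid points,",
      "time", round(min(x$grid$time), 2), "-", round(max(x$grid$time), 2), "min\n")
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$X)

# extract the plain numeric matrix from a feature_matrix or pass a matrix through
fm_matrix <- function(X) {
  if (inherits(X, "feature_matrix")) return(X$X)
  if (is.matrix(X)) return(X)
  stop("X must be a feature_matrix or a numeric matrix", call. = FALSE)
}

#' Export a feature matrix as wide CSV
#'
#' First column `sample_id`, remaining columns named `t<minutes>` for each grid
#' time point.
#'
#' @param fm A `feature_matrix`.
#' @param path Destination path.
#' @return The path, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  wide <- as_tibble(fm$X, .name_repair = "minimal")
  names(wide) <- sprintf("t%.4f", fm$grid$time)
  wide <- dplyr::bind_cols(tibble(sample_id = fm$sample_ids), wide)
  readr::write_csv(wide, path, progress = FALSE)
  invisible(path)
}
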