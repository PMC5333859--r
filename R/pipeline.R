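#' Configure the generate / calibrate / compare pipeline
#'
#' @param generator A [generator_config()] (its seed drives the whole run).
#' @param responses Property names to model. Chemical responses are evaluated
#'   against KIN1/KIN2, proximate responses against KIN3; hemicellulose and
#'   sugars get chemometric models only.
#' @param methods Subset of `"PLS"`, `"PCR"`, `"KIN1"`, `"KIN2"`, `"KIN3"`.
#' @param alpha Parsimony threshold for PRESS-based factor selection.
#' @param k_max Largest candidate factor count.
#' @param n_randomizations Sign-flip draws for factor selection.
#' @param n_points Feature-grid size for the chemometric matrix.
#' @param seed Pipeline seed (defaults to the generator seed).
#' @param output_dir Optional directory; when given, all tables, models and
#'   thermograms are written there.
#'
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(generator = generator_config(),
                            responses = c("lignin", "cellulose", "hemicellulose",
                                          "volatile_matter", "fixed_carbon", "ash"),
                            methods = c("PLS", "PCR", "KIN1", "KIN2", "KIN3"),
                            alpha = 0.1,
                            k_max = 10,
                            n_randomizations = 2000,
                            n_points = 500,
                            seed = generator$seed,
                            output_dir = NULL) {
  stopifnot(inherits(generator, "generator_config"))
  if (length(responses) == 0) stop("responses must be non-empty", call. = FALSE)
  methods <- match.arg(methods, c("PLS", "PCR", "KIN1", "KIN2", "KIN3"),
                       several.ok = TRUE)
  structure(
    list(
      generator = generator,
      responses = responses,
      methods = methods,
      alpha = alpha,
      k_max = as.integer(k_max),
      n_randomizations = as.integer(n_randomizations),
      n_points = as.integer(n_points),
      seed = as.integer(seed),
      output_dir = output_dir
    ),
    class = "pipeline_config"
  )
}

chemical_responses <- function() c("lignin", "cellulose", "hemicellulose")
proximate_responses <- function() c("volatile_matter", "fixed_carbon", "ash")
kinetic_chemical_responses <- function() c("lignin", "cellulose")

pipeline_log <- function(quiet, stage, ...) {
  if (!quiet) message(sprintf("[tgchemo] %-10s %s", stage, paste0(...)))
}

#' Run the full comparison pipeline
#'
#' Generates the paired synthetic dataset (the same compositions simulated
#' under both the nitrogen-plus-air proximate program and the nitrogen-only
#' pyrolysis program), normalizes all curves, builds the chemometric feature
#' matrix from the proximate-program curves, calibrates PLS/PCR models for
#' every requested response, applies the kinetic regimes (KIN1/KIN2 to the
#' nitrogen-only curves for lignin and cellulose, KIN3 to the air curves for
#' the proximate triple), and assembles the comparison report. Fully
#' deterministic from the config seed.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage log messages.
#'
#' @return A `comparison_report`: list with `metrics` (property x method
#'   table), `report` (SECV deltas chemometric minus kinetic), `calibrations`,
#'   `kinetic_estimates`, `truth`, `feature_matrix`, `group_stats`, `config`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  gen <- config$generator

  t0 <- Sys.time()
  data_air <- generate_dataset(gen)
  truth <- data_air$compositions
  # same samples re-run under the nitrogen-only program (fresh noise stream)
  gen_n2 <- gen
  gen_n2$program <- program_pyrolysis()
  gen_n2$seed <- (gen$seed %% 2000000000L) + 1L
  data_n2 <- generate_dataset(gen_n2, compositions = truth)
  pipeline_log(quiet, "generate",
               nrow(truth), " samples x 2 programs (",
               round(difftime(Sys.time(), t0, units = "secs"), 1), "s)")

  t0 <- Sys.time()
  tgs_air <- purrr::map(data_air$thermograms, normalize_to_dry_mass)
  tgs_n2 <- purrr::map(data_n2$thermograms, normalize_to_dry_mass)
  fm <- build_feature_matrix(tgs_air, n_points = config$n_points)
  pipeline_log(quiet, "normalize",
               "feature matrix ", nrow(fm$X), " x ", ncol(fm$X), " (",
               round(difftime(Sys.time(), t0, units = "secs"), 1), "s)")

  latent_methods <- intersect(config$methods, c("PLS", "PCR"))
  set.seed(config$seed)
  selection_seeds <- matrix(
    sample.int(.Machine$integer.max, length(config$responses) * max(length(latent_methods), 1)),
    nrow = length(config$responses)
  )

  metrics <- list()
  calibrations <- list()
  t0 <- Sys.time()
  for (ri in seq_along(config$responses)) {
    response <- config$responses[ri]
    if (!response %in% names(truth)) {
      stop("response '", response, "' is not a column of the truth table",
           call. = FALSE)
    }
    y <- truth[[response]]
    for (mi in seq_along(latent_methods)) {
      method <- latent_methods[mi]
      cal <- calibrate_property(
        fm, y, method = method, k_max = config$k_max, alpha = config$alpha,
        n_randomizations = config$n_randomizations,
        seed = selection_seeds[ri, mi]
      )
      calibrations[[response]][[method]] <- cal
      m <- cal$metrics
      m$property <- response
      m$method <- method
      metrics[[length(metrics) + 1]] <- m
      if (m$RPD < 1.5 && !quiet) {
        pipeline_log(quiet, "warn", response, " / ", method,
                     ": RPD ", round(m$RPD, 2), " below the 1.5 screening bar")
      }
    }
  }
  pipeline_log(quiet, "calibrate",
               length(config$responses), " responses x ",
               length(latent_methods), " latent methods (",
               round(difftime(Sys.time(), t0, units = "secs"), 1), "s)")

  t0 <- Sys.time()
  kinetic_estimates <- list()
  for (regime_name in intersect(config$methods, c("KIN1", "KIN2"))) {
    est <- estimate_kinetics(tgs_n2, kinetic_regime(regime_name))
    kinetic_estimates[[regime_name]] <- est
    for (response in intersect(config$responses, kinetic_chemical_responses())) {
      metrics[[length(metrics) + 1]] <- evaluate_kinetic(est, truth, response)
    }
  }
  if ("KIN3" %in% config$methods) {
    est <- estimate_kinetics(tgs_air, kinetic_regime("KIN3"))
    kinetic_estimates[["KIN3"]] <- est
    for (response in intersect(config$responses, proximate_responses())) {
      metrics[[length(metrics) + 1]] <- evaluate_kinetic(est, truth, response)
    }
  }
  pipeline_log(quiet, "kinetics",
               length(kinetic_estimates), " regimes (",
               round(difftime(Sys.time(), t0, units = "secs"), 1), "s)")

  metrics <- purrr::list_rbind(metrics)
  metrics <- metrics[, c("property", "method", "SEC", "SECV", "R2", "RPD",
                         "r2_press", "n_factors", "n")]

  report <- compare_methods(metrics)
  group_stats <- summarize_group_stats(truth)

  out <- structure(
    list(
      config = config,
      truth = truth,
      feature_matrix = fm,
      thermograms = list(proximate = tgs_air, pyrolysis = tgs_n2),
      calibrations = calibrations,
      kinetic_estimates = kinetic_estimates,
      metrics = metrics,
      report = report,
      group_stats = group_stats
    ),
    class = "comparison_report"
  )
  if (!is.null(config$output_dir)) {
    write_pipeline_outputs(out, config$output_dir)
    pipeline_log(quiet, "write", "outputs under ", config$output_dir)
  }
  out
}

#' SECV deltas between chemometric and kinetic methods
#'
#' @param metrics The pipeline metrics table.
#' @return A tibble with one row per property x chemometric x kinetic pairing
#'   present in `metrics`, with `delta_secv` = chemometric SECV minus kinetic
#'   SECV (negative when the chemometric model is better).
#' @export
compare_methods <- function(metrics) {
  chemo <- metrics[metrics$method %in% c("PLS", "PCR"), ]
  kin <- metrics[grepl("^KIN", metrics$method), ]
  if (nrow(chemo) == 0 || nrow(kin) == 0) {
    return(tibble(property = character(), chemometric_method = character(),
                  kinetic_method = character(), chemometric_secv = numeric(),
                  kinetic_secv = numeric(), delta_secv = numeric()))
  }
  pairs <- dplyr::inner_join(
    chemo[, c("property", "method", "SECV")] |>
      stats::setNames(c("property", "chemometric_method", "chemometric_secv")),
    kin[, c("property", "method", "SECV")] |>
      stats::setNames(c("property", "kinetic_method", "kinetic_secv")),
    by = "property",
    relationship = "many-to-many"
  )
  pairs$delta_secv <- pairs$chemometric_secv - pairs$kinetic_secv
  dplyr::arrange(pairs, property, chemometric_method, kinetic_method)
}

#' Per-group composition summary
#'
#' @param truth Composition table with a `biomass_type` column.
#' @return A tibble with one row per biomass type and, per property, the mean,
#'   SD and a formatted `"mean (SD)"` string in long layout.
#' @export
summarize_group_stats <- function(truth) {
  stopifnot("biomass_type" %in% names(truth))
  counts <- table(truth$biomass_type)
  if (any(counts < 2)) {
    stop("every biomass group needs at least 2 samples to summarize", call. = FALSE)
  }
  numeric_cols <- names(truth)[vapply(truth, is.numeric, logical(1))]
  long <- truth |>
    tidyr_pivot(numeric_cols)
  long |>
    dplyr::group_by(biomass_type, property) |>
    dplyr::summarise(
      mean_value = mean(value),
      sd_value = sd(value),
      formatted = sprintf("%.1f (%.1f)", mean(value), sd(value)),
      .groups = "drop"
    )
}

# minimal long-pivot so the package does not need tidyr for one reshape
tidyr_pivot <- function(truth, cols) {
  purrr::list_rbind(purrr::map(cols, function(col) {
    tibble(
      biomass_type = truth$biomass_type,
      property = col,
      value = truth[[col]]
    )
  }))
}

write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(result$truth, file.path(dir, "truth.csv"), progress = FALSE)
  readr::write_csv(result$metrics, file.path(dir, "metrics.csv"), progress = FALSE)
  readr::write_csv(result$report, file.path(dir, "report.csv"), progress = FALSE)
  readr::write_csv(result$group_stats, file.path(dir, "group_stats.csv"), progress = FALSE)
  write_feature_matrix(result$feature_matrix, file.path(dir, "feature_matrix.csv"))
  models_dir <- file.path(dir, "models")
  dir.create(models_dir, showWarnings = FALSE)
  for (response in names(result$calibrations)) {
    for (method in names(result$calibrations[[response]])) {
      write_latent_model(
        result$calibrations[[response]][[method]]$model,
        file.path(models_dir, paste0(response, "_", method, ".json"))
      )
    }
  }
  tg_dir <- file.path(dir, "thermograms")
  dir.create(tg_dir, showWarnings = FALSE)
  for (label in names(result$thermograms)) {
    for (tg in result$thermograms[[label]]) {
      write_thermogram(tg, file.path(tg_dir, paste0(tg$sample_id, "_", label, ".csv")))
    }
  }
  txt <- file.path(dir, "report.txt")
  con <- file(txt, open = "wt")
  on.exit(close(con))
  writeLines(utils::capture.output({
    cat("tgchemo comparison report\n\n")
    cat("Per-method metrics:\n")
    print(as.data.frame(result$metrics), digits = 4, row.names = FALSE)
    cat("\nSECV deltas (chemometric - kinetic):\n")
    print(as.data.frame(result$report), digits = 4, row.names = FALSE)
  }), con)
  invisible(dir)
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report>", nrow(x$truth), "samples,",
      length(unique(x$metrics$property)), "properties,",
      length(unique(x$metrics$method)), "methods\n")
  print(x$metrics, n = nrow(x$metrics))
  invisible(x)
}
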