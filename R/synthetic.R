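#' Default pseudo-component degradation kernels
#'
#' Each organic constituent devolatilizes along a smooth logistic survival
#' curve in temperature, centred at `peak` with scale `width / 6`, and leaves
#' behind `char_fraction` of its mass as char at the end of the nitrogen
#' stage. Defaults place the hemicellulose peak inside its 150--360 degC
#' window, the cellulose peak at 355 degC (the maximum mass-loss temperature
#' of pure cellulose), and give lignin a broad, slow decay with a high char
#' yield so that it dominates fixed carbon. Hemicellulose and cellulose
#' kernels deliberately overlap over 250--360 degC.
#'
#' @return A tibble with columns `component`, `onset`, `peak`, `width`
#'   (degC) and `char_fraction`.
#' @export
default_kernels <- function() {
  kernels <- tibble(
    component = c("extractives", "hemicellulose", "cellulose", "lignin"),
    onset = c(120, 150, 250, 180),
    peak = c(220, 300, 355, 400),
    width = c(150, 130, 90, 500),
    char_fraction = c(0, 0.15, 0.06, 0.45)
  )
  validate_kernels(kernels)
  kernels
}

validate_kernels <- function(kernels) {
  stopifnot(is.data.frame(kernels))
  required <- c("component", "onset", "peak", "width", "char_fraction")
  missing <- setdiff(required, names(kernels))
  if (length(missing) > 0) {
    stop("kernel table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(kernels$onset >= kernels$peak)) {
    stop("kernel onset must be below its peak", call. = FALSE)
  }
  if (any(kernels$width <= 0)) stop("kernel width must be positive", call. = FALSE)
  if (any(kernels$char_fraction < 0 | kernels$char_fraction >= 1)) {
    stop("char_fraction must lie in [0, 1)", call. = FALSE)
  }
  invisible(kernels)
}

#' Default composition means and SDs for the four biomass groups
#'
#' Group means and standard deviations (percent of oven-dry mass) of lignin,
#' cellulose, hemicellulose, extractives and ash for whole-tree, wood-and-bark,
#' slash and clean-wood loblolly pine fractions, as used to drive the
#' composition sampler.
#'
#' @return A long tibble: `biomass_type`, `constituent`, `mean`, `sd`.
#' @export
default_group_parameters <- function() {
  tibble(
    biomass_type = rep(biomass_types(), each = 5),
    constituent = rep(c("lignin", "cellulose", "hemicellulose", "extractives", "ash"), 4),
    mean = c(
      37.3, 31.0, 24.1, 4.0, 1.8,   # whole
      35.9, 38.9, 22.8, 2.0, 1.5,   # wood_and_bark
      43.7, 25.2, 22.1, 10.0, 1.9,  # slash
      33.5, 42.7, 20.3, 3.0, 0.4    # wood
    ),
    sd = c(
      1.6, 2.4, 2.2, 1.0, 0.7,
      2.0, 3.8, 2.8, 0.5, 1.6,
      1.7, 2.4, 4.2, 2.5, 0.2,
      1.6, 2.4, 0.9, 0.75, 0.1
    )
  )
}

#' Configuration for the synthetic thermogram generator
#'
#' @param group_parameters Long tibble of composition means/SDs per biomass
#'   type (see [default_group_parameters()]).
#' @param kernels Pseudo-component kernel table (see [default_kernels()]).
#' @param moisture Moisture content of the as-loaded sample, percent of wet
#'   mass.
#' @param noise_sd Pointwise Gaussian mass noise, in percent-of-dry-mass
#'   units (default 0.5, the low end of typical run-to-run TGA variation).
#' @param n_per_group Samples per biomass group (default 10, for a 40-sample
#'   dataset).
#' @param seed Integer seed; together with the config it fully determines the
#'   generated dataset.
#' @param program Heating program to simulate (default [program_proximate()]).
#' @param initial_mass_mg Loaded sample mass in mg (nominal 7 mg).
#' @param sample_interval Recording interval in minutes (default 0.05, i.e.
#'   2.5 degC at 50 degC/min).
#' @param sugars Whether to derive monomeric-sugar reference columns.
#'
#' @return A `generator_config` object.
#' @export
generator_config <- function(group_parameters = default_group_parameters(),
                             kernels = default_kernels(),
                             moisture = 5,
                             noise_sd = 0.5,
                             n_per_group = 10,
                             seed = 1,
                             program = program_proximate(),
                             initial_mass_mg = 7,
                             sample_interval = 0.05,
                             sugars = TRUE) {
  validate_kernels(kernels)
  stopifnot(inherits(program, "heating_program"))
  if (any(group_parameters$sd < 0)) {
    stop("composition SDs must be non-negative", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  if (n_per_group < 1) stop("n_per_group must be at least 1", call. = FALSE)
  if (moisture < 0 || moisture >= 100) stop("moisture must be in [0, 100)", call. = FALSE)
  structure(
    list(
      group_parameters = group_parameters,
      kernels = kernels,
      moisture = moisture,
      noise_sd = noise_sd,
      n_per_group = as.integer(n_per_group),
      seed = as.integer(seed),
      program = program,
      initial_mass_mg = initial_mass_mg,
      sample_interval = sample_interval,
      sugars = isTRUE(sugars)
    ),
    class = "generator_config"
  )
}

# one truncated-at-zero normal draw per (mean, sd) pair, by rejection
rtruncnorm0 <- function(mean, sd) {
  out <- numeric(length(mean))
  for (i in seq_along(mean)) {
    if (sd[i] == 0) {
      out[i] <- mean[i]
      next
    }
    repeat {
      x <- rnorm(1, mean[i], sd[i])
      if (x >= 0) break
    }
    out[i] <- x
  }
  out
}

# internal sampler: does not touch the RNG seed, draws from the current stream
draw_compositions <- function(config) {
  gp <- config$group_parameters
  groups <- unique(gp$biomass_type)
  char <- setNames(config$kernels$char_fraction, config$kernels$component)
  organics <- c("lignin", "cellulose", "hemicellulose", "extractives")
  records <- list()
  for (g in groups) {
    pars <- gp[gp$biomass_type == g, ]
    means <- setNames(pars$mean, pars$constituent)
    sds <- setNames(pars$sd, pars$constituent)
    missing <- setdiff(c(organics, "ash"), names(means))
    if (length(missing) > 0) {
      stop("group ", g, " lacks mean/SD for: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    for (i in seq_len(config$n_per_group)) {
      draw <- rtruncnorm0(means[c(organics, "ash")], sds[c(organics, "ash")])
      names(draw) <- c(organics, "ash")
      ash <- draw[["ash"]]
      w <- draw[organics]
      # rescale organics so constituents + ash close to exactly 100 (dry basis)
      w <- w * (100 - ash) / sum(w)
      vm <- sum(w * (1 - char[organics]))
      rec <- tibble(
        sample_id = sprintf("%s_%02d", g, i),
        biomass_type = g,
        lignin = w[["lignin"]],
        cellulose = w[["cellulose"]],
        hemicellulose = w[["hemicellulose"]],
        extractives = w[["extractives"]],
        ash = ash,
        volatile_matter = vm,
        fixed_carbon = 100 - vm - ash
      )
      if (config$sugars) {
        rec <- add_sugar_references(rec)
      }
      records[[length(records) + 1]] <- rec
    }
  }
  purrr::list_rbind(records)
}

# Sugar reference values as stoichiometric shares of the polysaccharides:
# softwood hemicellulose is mostly galactoglucomannan plus arabinoxylan, so
# hemicellulose splits into mannose/xylose/galactose/arabinose/glucose shares
# and cellulose hydrolyses to glucose. A small independent error emulates the
# wet-chemistry reference measurement.
add_sugar_references <- function(rec) {
  hemi <- rec$hemicellulose
  cell <- rec$cellulose
  wet_err <- function(x, sd = 0.3) pmax(0, x + rnorm(length(x), 0, sd))
  rec$glucose <- wet_err(0.95 * cell + 0.10 * hemi)
  rec$mannose <- wet_err(0.45 * hemi, sd = 0.2)
  rec$galactose <- wet_err(0.10 * hemi, sd = 0.15)
  rec$xylose <- wet_err(0.30 * hemi, sd = 0.2)
  rec$arabinose <- wet_err(0.05 * hemi, sd = 0.1)
  rec$holocellulose <- wet_err(cell + hemi, sd = 0.4)
  rec
}

#' Draw per-sample reference compositions
#'
#' Draws each constituent from a truncated-at-zero normal with its group mean
#' and SD, rescales the organic constituents so constituents plus ash sum to
#' exactly 100 (dry basis), and derives volatile matter as the char-weighted
#' volatile share of the organics with fixed carbon by difference.
#'
#' @param config A [generator_config()].
#' @return A tibble of composition records (one row per sample).
#' @export
sample_compositions <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  draw_compositions(config)
}

# normalized logistic survival: exactly 1 at the dry point, exactly 0 at the
# program's top temperature, monotone non-increasing in T
kernel_survival <- function(temperature, peak, width, t_lo = 105, t_hi) {
  scale <- width / 6
  s <- function(T) 1 / (1 + exp((T - peak) / scale))
  raw <- s(temperature)
  lo <- s(t_lo)
  hi <- s(t_hi)
  pmin(1, pmax(0, (raw - hi) / (lo - hi)))
}

# moisture release: smooth cosine decay reaching exactly zero at the dry point
drying_decay <- function(time, t_dry) {
  frac <- pmin(time / t_dry, 1)
  0.5 * (1 + cos(pi * frac))
}

# char burn-off under air: cosine decay over the first 70% of the air stage,
# exactly zero afterwards so the final residue is ash alone
char_decay <- function(time, program) {
  tab <- program_segment_table(program)
  air <- which(tab$atmosphere == "air")
  if (length(air) == 0) return(rep(1, length(time)))
  t_a <- tab$start_time[min(air)]
  d_a <- max(tab$end_time[air]) - t_a
  frac <- pmin(pmax((time - t_a) / (0.7 * d_a), 0), 1)
  0.5 * (1 + cos(pi * frac))
}

#' Simulate one thermogram from a known composition
#'
#' The noise-free mass trace is
#' `moisture * drying_decay(t) + sum_c w_c * (char_c * g(t) + (1 - char_c) * S_c(T(t))) + ash`,
#' where `S_c` is the constituent's normalized logistic survival curve and
#' `g(t)` burns the char off during the air stage. Gaussian noise with SD
#' `noise_sd` (percent of dry mass) is added pointwise and clipped at zero.
#' The noise-free residue after the air stage equals the ash fraction exactly.
#'
#' @param comp One composition record (single row of [sample_compositions()]).
#' @param config A [generator_config()].
#' @param seed Seed for the noise draw (default the config seed); the result
#'   is bit-reproducible given `comp`, `config` and `seed`.
#' @return A raw (mg-scale) [thermogram()].
#' @export
simulate_thermogram <- function(comp, config, seed = config$seed) {
  stopifnot(inherits(config, "generator_config"))
  comp <- as.list(comp)
  kernels <- config$kernels
  organics <- c("lignin", "cellulose", "hemicellulose", "extractives")
  present <- organics[vapply(organics, function(nm)
    !is.null(comp[[nm]]) && comp[[nm]] > 0, logical(1))]
  without_kernel <- setdiff(present, kernels$component)
  if (length(without_kernel) > 0) {
    stop("no degradation kernel for constituent(s): ",
         paste(without_kernel, collapse = ", "), call. = FALSE)
  }
  program <- config$program
  total <- program_duration(program)
  # include segment boundaries so the dry point and stage ends are sampled
  # exactly whatever the recording interval
  time <- sort(unique(round(
    c(seq(0, total, by = config$sample_interval),
      program_segment_table(program)$end_time, total),
    10
  )))
  temperature <- program_temperature(program, time)
  t_dry <- dry_point_time(program)
  t_hi <- max_program_temperature(program)

  moisture_mg <- config$initial_mass_mg * config$moisture / 100
  dry_mg <- config$initial_mass_mg - moisture_mg
  ash_pct <- if (is.null(comp$ash)) 0 else comp$ash

  g <- char_decay(time, program)
  organic_frac <- rep(0, length(time))
  for (k in seq_len(nrow(kernels))) {
    nm <- kernels$component[k]
    w <- comp[[nm]]
    if (is.null(w) || w == 0) next
    s <- kernel_survival(temperature, kernels$peak[k], kernels$width[k],
                         t_lo = 105, t_hi = t_hi)
    char <- kernels$char_fraction[k]
    organic_frac <- organic_frac + (w / 100) * (char * g + (1 - char) * s)
  }
  mass <- dry_mg * (organic_frac + ash_pct / 100) +
    moisture_mg * drying_decay(time, t_dry)
  if (config$noise_sd > 0) {
    set.seed(seed)
    mass <- mass + rnorm(length(mass), 0, config$noise_sd / 100 * dry_mg)
    mass <- pmax(mass, 0)
  }
  thermogram(
    sample_id = if (is.null(comp$sample_id)) "synthetic" else comp$sample_id,
    time = time,
    temperature = temperature,
    mass = mass,
    program = program,
    biomass_type = if (is.null(comp$biomass_type)) NA_character_ else comp$biomass_type,
    normalized = FALSE
  )
}

#' Generate a full synthetic dataset with known truth
#'
#' Draws `n_per_group` compositions per biomass group and simulates one
#' thermogram per sample under the config's heating program. Fully
#' reproducible from the config seed.
#'
#' @param config A [generator_config()].
#' @param compositions Optional pre-drawn composition table (to simulate the
#'   same samples under a second heating program).
#' @return A list with `thermograms` (list of raw [thermogram()]s) and
#'   `compositions` (the truth tibble).
#' @export
generate_dataset <- function(config, compositions = NULL) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  if (is.null(compositions)) {
    compositions <- draw_compositions(config)
  } else {
    # keep the per-sample noise stream aligned with a fresh draw
    invisible(draw_compositions(config))
  }
  n <- nrow(compositions)
  sample_seeds <- sample.int(.Machine$integer.max, n)
  tgs <- purrr::map(seq_len(n), function(i) {
    simulate_thermogram(compositions[i, ], config, seed = sample_seeds[i])
  })
  names(tgs) <- compositions$sample_id
  list(thermograms = tgs, compositions = compositions)
}

#' Write a generated dataset to disk
#'
#' Emits one thermogram CSV per sample plus `truth.csv` and a `manifest.csv`
#' mapping sample ids to files and biomass types.
#'
#' @param dataset Result of [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- vapply(dataset$thermograms, function(tg) {
    f <- paste0(tg$sample_id, ".csv")
    write_thermogram(tg, file.path(dir, f))
    f
  }, character(1))
  manifest <- tibble(
    sample_id = dataset$compositions$sample_id,
    file = unname(files[dataset$compositions$sample_id]),
    biomass_type = dataset$compositions$biomass_type
  )
  readr::write_csv(manifest, file.path(dir, "manifest.csv"), progress = FALSE)
  readr::write_csv(dataset$compositions, file.path(dir, "truth.csv"), progress = FALSE)
  invisible(dir)
}
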