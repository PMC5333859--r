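#' Construct a thermogram
#'
#' A thermogram is the mass-versus-time/temperature trace recorded by a
#' thermogravimetric analyzer for one sample under a known heating program.
#' Raw traces carry mass in mg; normalized traces carry mass as percent of the
#' dry mass with the wet (30--105 degC) portion removed.
#'
#' @param sample_id Sample label.
#' @param time Time in minutes, strictly increasing.
#' @param temperature Temperature in degrees Celsius.
#' @param mass Mass in mg (raw) or percent of dry mass (normalized);
#'   non-negative.
#' @param program The [heating_program()] the trace was acquired under.
#' @param biomass_type One of `"whole"`, `"wood_and_bark"`, `"slash"`,
#'   `"wood"`, or `NA`.
#' @param normalized Logical; `TRUE` once [normalize_to_dry_mass()] has been
#'   applied.
#'
#' @return A `thermogram` object.
#' @export
thermogram <- function(sample_id, time, temperature, mass, program,
                       biomass_type = NA_character_, normalized = FALSE) {
  stopifnot(inherits(program, "heating_program"))
  n <- length(time)
  if (n < 2) stop("a thermogram needs at least 2 points", call. = FALSE)
  if (length(temperature) != n || length(mass) != n) {
    stop("time, temperature and mass must have equal length", call. = FALSE)
  }
  if (anyNA(time) || anyNA(temperature) || anyNA(mass)) {
    stop("thermogram series must not contain missing values", call. = FALSE)
  }
  if (any(diff(time) <= 0)) {
    stop("time must be strictly increasing", call. = FALSE)
  }
  if (any(mass < 0)) {
    stop("mass must be non-negative everywhere", call. = FALSE)
  }
  if (!is.na(biomass_type)) {
    biomass_type <- match.arg(biomass_type, biomass_types())
  }
  if (isTRUE(normalized) && abs(mass[1] - 100) > 1e-8) {
    stop("a normalized thermogram must have mass 100 at its dry point", call. = FALSE)
  }
  structure(
    list(
      sample_id = as.character(sample_id),
      biomass_type = biomass_type,
      time = as.numeric(time),
      temperature = as.numeric(temperature),
      mass = as.numeric(mass),
      program = program,
      normalized = isTRUE(normalized)
    ),
    class = "thermogram"
  )
}

#' The four biomass type labels
#'
#' @return Character vector of the recognised forest-biomass fractions.
#' @export
biomass_types <- function() c("whole", "wood_and_bark", "slash", "wood")

#' @export
print.thermogram <- function(x, ...) {
  cat("<thermogram>", x$sample_id,
      if (!is.na(x$biomass_type)) paste0("(", x$biomass_type, ")") else "",
      "\n  points:", length(x$time),
      " time:", round(min(x$time), 3), "-", round(max(x$time), 3), "min",
      " mass:", if (x$normalized) "% of dry mass" else "mg",
      " program:", x$program$name, "\n")
  invisible(x)
}

#' @export
as_tibble.thermogram <- function(x, ...) {
  tibble(time_min = x$time, temperature_C = x$temperature, mass = x$mass)
}

#' Read a thermogram from CSV
#'
#' Expects the exchange dialect used throughout the package: a comma-separated
#' UTF-8 file with header `time_min,temperature_C,mass` and `.` as the decimal
#' mark.
#'
#' @param path Path to the CSV file.
#' @param program The [heating_program()] the trace belongs to.
#' @param sample_id Sample label; defaults to the file name.
#' @param biomass_type Optional biomass type label.
#' @param normalized Whether the stored mass is already percent of dry mass.
#'
#' @return A [thermogram()].
#' @export
read_thermogram <- function(path, program, sample_id = NULL,
                            biomass_type = NA_character_, normalized = FALSE) {
  dat <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_double()),
                         progress = FALSE)
  required <- c("time_min", "temperature_C", "mass")
  missing <- setdiff(required, names(dat))
  if (length(missing) > 0) {
    stop("thermogram CSV is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(dat) < 2) stop("thermogram CSV needs at least 2 rows", call. = FALSE)
  if (is.null(sample_id)) {
    sample_id <- sub("\\.csv$", "", basename(path))
  }
  thermogram(
    sample_id = sample_id,
    time = dat$time_min,
    temperature = dat$temperature_C,
    mass = dat$mass,
    program = program,
    biomass_type = biomass_type,
    normalized = normalized
  )
}

#' Write a thermogram to CSV
#'
#' @param tg A [thermogram()].
#' @param path Destination path.
#' @return The path, invisibly.
#' @export
write_thermogram <- function(tg, path) {
  stopifnot(inherits(tg, "thermogram"))
  readr::write_csv(as_tibble(tg), path, progress = FALSE)
  invisible(path)
}

#' Read a set of thermograms described by a manifest
#'
#' The manifest is a CSV with columns `sample_id`, `file` (path relative to the
#' manifest unless absolute) and optionally `biomass_type`.
#'
#' @param manifest_path Path to the manifest CSV.
#' @param program The shared [heating_program()].
#' @param normalized Whether stored traces are already normalized.
#' @return A list of [thermogram()] objects.
#' @export
read_thermogram_set <- function(manifest_path, program, normalized = FALSE) {
  manifest <- readr::read_csv(manifest_path, col_types = readr::cols(), progress = FALSE)
  required <- c("sample_id", "file")
  missing <- setdiff(required, names(manifest))
  if (length(missing) > 0) {
    stop("manifest is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  base <- dirname(manifest_path)
  purrr::map(seq_len(nrow(manifest)), function(i) {
    file <- manifest$file[i]
    if (!grepl("^(/|[A-Za-z]:)", file)) file <- file.path(base, file)
    read_thermogram(
      file, program,
      sample_id = manifest$sample_id[i],
      biomass_type = if ("biomass_type" %in% names(manifest))
        manifest$biomass_type[i] else NA_character_,
      normalized = normalized
    )
  })
}

#' Normalize a thermogram to its dry mass
#'
#' Removes the drying stage (everything before the dry point, see
#' [dry_point_time()]) and rescales mass to percent of the mass remaining at
#' the dry point, so the first retained value is exactly 100. This discards
#' moisture differences between runs before any modeling.
#'
#' @param tg A raw [thermogram()].
#' @return A normalized [thermogram()].
#' @export
normalize_to_dry_mass <- function(tg) {
  stopifnot(inherits(tg, "thermogram"))
  if (tg$normalized) {
    stop("thermogram is already normalized to dry mass", call. = FALSE)
  }
  t_dry <- dry_point_time(tg$program)
  idx <- which(tg$time >= t_dry - 1e-9)
  if (length(idx) < 2) {
    stop("thermogram has fewer than 2 points after the dry point", call. = FALSE)
  }
  first <- idx[1]
  dry_mass <- tg$mass[first]
  if (dry_mass <= 0) {
    stop("dry mass is zero: cannot normalize", call. = FALSE)
  }
  keep <- seq(first, length(tg$time))
  thermogram(
    sample_id = tg$sample_id,
    time = tg$time[keep],
    temperature = tg$temperature[keep],
    mass = tg$mass[keep] / dry_mass * 100,
    program = tg$program,
    biomass_type = tg$biomass_type,
    normalized = TRUE
  )
}

#' Mass remaining after a given temperature
#'
#' Looks up the normalized mass at the first time the heating ramp reaches
#' temperature `T`, linearly interpolating between the bracketing grid points.
#' Temperatures revisited during isothermal holds resolve to the first
#' crossing.
#'
#' @param tg A normalized [thermogram()].
#' @param temperature Temperature(s) in degrees Celsius, inside the observed
#'   ramp range.
#' @return Mass in percent of dry mass, one value per requested temperature.
#' @export
mass_after_temperature <- function(tg, temperature) {
  stopifnot(inherits(tg, "thermogram"))
  if (!tg$normalized) {
    stop("mass_after_temperature expects a normalized thermogram", call. = FALSE)
  }
  # take the ramp portion up to the first time the top temperature is reached
  top <- which.max(tg$temperature)
  ramp_temp <- tg$temperature[seq_len(top)]
  ramp_mass <- tg$mass[seq_len(top)]
  lo <- ramp_temp[1]
  hi <- ramp_temp[top]
  vapply(temperature, function(Tq) {
    if (Tq < lo - 1e-9 || Tq > hi + 1e-9) {
      stop("temperature ", Tq, " outside the observed ramp range [",
           lo, ", ", hi, "]", call. = FALSE)
    }
    j <- which(ramp_temp >= Tq - 1e-12)[1]
    if (ramp_temp[j] <= Tq + 1e-12 || j == 1) {
      return(ramp_mass[j])
    }
    frac <- (Tq - ramp_temp[j - 1]) / (ramp_temp[j] - ramp_temp[j - 1])
    ramp_mass[j - 1] + frac * (ramp_mass[j] - ramp_mass[j - 1])
  }, numeric(1))
}
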