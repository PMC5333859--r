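#' Define one segment of a TGA heating program
#'
#' A segment is either a linear temperature ramp (`rate` > 0, `hold_time` = 0)
#' or an isothermal hold (`rate` = 0, `hold_time` > 0), run under a nitrogen
#' or air atmosphere.
#'
#' @param start_temperature,end_temperature Segment temperatures in degrees
#'   Celsius. Equal for isothermal holds.
#' @param rate Heating rate in degrees Celsius per minute; 0 for holds.
#' @param hold_time Hold duration in minutes; 0 for ramps.
#' @param atmosphere `"nitrogen"` or `"air"`.
#'
#' @return A `heating_segment` object.
#' @export
#'
#' @examples
#' heating_segment(30, 105, rate = 20)
#' heating_segment(105, 105, rate = 0, hold_time = 5)
heating_segment <- function(start_temperature, end_temperature, rate,
                            hold_time = 0, atmosphere = c("nitrogen", "air")) {
  atmosphere <- match.arg(atmosphere)
  stopifnot(
    is.numeric(start_temperature), length(start_temperature) == 1,
    is.numeric(end_temperature), length(end_temperature) == 1,
    is.numeric(rate), length(rate) == 1, rate >= 0,
    is.numeric(hold_time), length(hold_time) == 1, hold_time >= 0
  )
  if ((rate == 0) != (start_temperature == end_temperature)) {
    stop("a segment is isothermal (rate = 0) exactly when start and end temperatures agree",
         call. = FALSE)
  }
  if ((hold_time > 0) != (rate == 0)) {
    stop("hold_time must be positive for isothermal segments and zero for ramps",
         call. = FALSE)
  }
  if (rate > 0 && end_temperature < start_temperature) {
    stop("cooling ramps are not supported", call. = FALSE)
  }
  structure(
    list(
      start_temperature = start_temperature,
      end_temperature = end_temperature,
      rate = rate,
      hold_time = hold_time,
      atmosphere = atmosphere
    ),
    class = "heating_segment"
  )
}

segment_duration <- function(segment) {
  if (segment$rate == 0) {
    segment$hold_time
  } else {
    (segment$end_temperature - segment$start_temperature) / segment$rate
  }
}

#' Assemble a heating program from temperature-continuous segments
#'
#' @param segments List of [heating_segment()] objects; each segment must start
#'   at the temperature where the previous one ends.
#' @param name Label for the program.
#'
#' @return A `heating_program` object.
#' @export
heating_program <- function(segments, name = "program") {
  stopifnot(is.list(segments), length(segments) >= 1)
  ok <- vapply(segments, inherits, logical(1), what = "heating_segment")
  if (!all(ok)) stop("all segments must be heating_segment objects", call. = FALSE)
  if (length(segments) > 1) {
    for (i in seq_len(length(segments) - 1)) {
      if (segments[[i]]$end_temperature != segments[[i + 1]]$start_temperature) {
        stop("segments must be temperature-continuous: segment ", i,
             " ends at ", segments[[i]]$end_temperature,
             " but segment ", i + 1, " starts at ",
             segments[[i + 1]]$start_temperature, call. = FALSE)
      }
    }
  }
  total <- sum(vapply(segments, segment_duration, numeric(1)))
  if (!is.finite(total)) stop("program duration must be finite", call. = FALSE)
  structure(list(segments = segments, name = name), class = "heating_program")
}

#' The proximate-analysis heating program (nitrogen then air)
#'
#' 30--105 degC at 20 degC/min, 5 min hold at 105 degC, 105--800 degC at
#' 50 degC/min, 7 min isothermal hold at 800 degC under nitrogen, then 10 min
#' at 800 degC under air to burn off the char. Roughly a 40-minute run.
#'
#' @return A `heating_program`.
#' @export
program_proximate <- function() {
  heating_program(
    list(
      heating_segment(30, 105, rate = 20),
      heating_segment(105, 105, rate = 0, hold_time = 5),
      heating_segment(105, 800, rate = 50),
      heating_segment(800, 800, rate = 0, hold_time = 7),
      heating_segment(800, 800, rate = 0, hold_time = 10, atmosphere = "air")
    ),
    name = "proximate_n2_air"
  )
}

#' The pyrolysis heating program (nitrogen only)
#'
#' A single 30--800 degC ramp at 20 degC/min under nitrogen (38.5 min).
#'
#' @return A `heating_program`.
#' @export
program_pyrolysis <- function() {
  heating_program(
    list(heating_segment(30, 800, rate = 20)),
    name = "pyrolysis_n2"
  )
}

#' Tabulate the segments of a heating program
#'
#' @param program A [heating_program()].
#'
#' @return A tibble with one row per segment: start/end times (min), start/end
#'   temperatures (degC), rate, hold time, atmosphere and a ramp flag.
#' @export
program_segment_table <- function(program) {
  stopifnot(inherits(program, "heating_program"))
  durations <- vapply(program$segments, segment_duration, numeric(1))
  end_time <- cumsum(durations)
  tibble(
    segment = seq_along(program$segments),
    start_time = c(0, head(end_time, -1)),
    end_time = end_time,
    start_temperature = vapply(program$segments, `[[`, numeric(1), "start_temperature"),
    end_temperature = vapply(program$segments, `[[`, numeric(1), "end_temperature"),
    rate = vapply(program$segments, `[[`, numeric(1), "rate"),
    hold_time = vapply(program$segments, `[[`, numeric(1), "hold_time"),
    atmosphere = vapply(program$segments, `[[`, character(1), "atmosphere"),
    is_ramp = vapply(program$segments, function(s) s$rate > 0, logical(1))
  )
}

#' Total duration of a heating program in minutes
#'
#' @param program A [heating_program()].
#' @return Duration in minutes.
#' @export
program_duration <- function(program) {
  sum(vapply(program$segments, segment_duration, numeric(1)))
}

segment_index_at <- function(program, time) {
  tab <- program_segment_table(program)
  total <- max(tab$end_time)
  if (any(time < -1e-9 | time > total + 1e-9)) {
    stop("time outside the heating program (0 to ", total, " min)", call. = FALSE)
  }
  idx <- findInterval(pmin(pmax(time, 0), total), tab$start_time)
  pmin(idx, nrow(tab))
}

#' Program temperature at given times
#'
#' @param program A [heating_program()].
#' @param time Times in minutes from the start of the run.
#' @return Temperatures in degrees Celsius.
#' @export
program_temperature <- function(program, time) {
  tab <- program_segment_table(program)
  idx <- segment_index_at(program, time)
  temp <- tab$start_temperature[idx] + tab$rate[idx] * (time - tab$start_time[idx])
  pmin(temp, tab$end_temperature[idx])
}

#' Program atmosphere at given times
#'
#' @param program A [heating_program()].
#' @param time Times in minutes from the start of the run.
#' @return Character vector, `"nitrogen"` or `"air"`.
#' @export
program_atmosphere <- function(program, time) {
  tab <- program_segment_table(program)
  tab$atmosphere[segment_index_at(program, time)]
}

program_is_ramp <- function(program, time) {
  tab <- program_segment_table(program)
  tab$is_ramp[segment_index_at(program, time)]
}

#' Time at which the sample is dry
#'
#' The dry point is the end of the last 105 degC isothermal hold if the program
#' has one, otherwise the time at which the first ramp crosses 105 degC.
#' Normalization to dry mass and the generator's moisture decay are anchored
#' here.
#'
#' @param program A [heating_program()].
#' @return Time in minutes.
#' @export
dry_point_time <- function(program) {
  tab <- program_segment_table(program)
  holds <- which(!tab$is_ramp & tab$start_temperature == 105)
  if (length(holds) > 0) {
    return(tab$end_time[max(holds)])
  }
  crossing <- which(tab$is_ramp & tab$start_temperature < 105 & tab$end_temperature >= 105)
  if (length(crossing) == 0) {
    stop("heating program has no drying stage: it never reaches 105 degC", call. = FALSE)
  }
  i <- crossing[1]
  tab$start_time[i] + (105 - tab$start_temperature[i]) / tab$rate[i]
}

has_air_segment <- function(program) {
  any(vapply(program$segments, function(s) s$atmosphere == "air", logical(1)))
}

#' End time of the nitrogen stage
#'
#' The time at which the first air segment begins, or the full program duration
#' for nitrogen-only programs. This is the boundary used for the volatile-matter
#' mass in proximate estimation.
#'
#' @param program A [heating_program()].
#' @return Time in minutes.
#' @export
nitrogen_end_time <- function(program) {
  tab <- program_segment_table(program)
  air <- which(tab$atmosphere == "air")
  if (length(air) == 0) max(tab$end_time) else tab$start_time[min(air)]
}

max_program_temperature <- function(program) {
  max(vapply(program$segments, `[[`, numeric(1), "end_temperature"))
}

programs_identical <- function(a, b) {
  identical(program_segment_table(a)[, -1], program_segment_table(b)[, -1])
}

#' @export
print.heating_program <- function(x, ...) {
  cat("<heating_program>", x$name, "\n")
  print(program_segment_table(x), ...)
  invisible(x)
}
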