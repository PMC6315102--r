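#' Parse a diel time-point label
#'
#' Diel sampling schemes label each sample by the photic phase it falls in and
#' the number of hours since that phase began: `"L6"` is 6 h into the light
#' period, `"D3"` is 3 h into the dark period, and a `"2"` prefix (`"2L12"`,
#' `"2D12"`) marks the second light/dark cycle of a multi-day time course.
#'
#' The absolute hour is placed on a contiguous timeline whose origin is the
#' first sunrise (first dark onset when `dark_first = TRUE`): with the default
#' 12 h/12 h regime, cycle-1 light occupies \[0, 12), cycle-1 dark \[12, 24),
#' and the second cycle adds 24 h. The nominal within-day hour is computed
#' modulo 24 so that an end-of-dark label such as `"D12"` maps to the sunrise
#' it coincides with (hour 0, or 24 with the `"2"` prefix), which is how
#' published diel series are ordered.
#'
#' @param label Character scalar matching `[2]?[LD][0-9]+`.
#' @param photoperiod_hours Length of the light phase in hours (default 12).
#' @param dark_first If `TRUE` the timeline starts at dark onset (organisms
#'   whose series begin in the dark), so dark precedes light in each cycle.
#' @return An object of class `diel_timepoint`: a list with `raw_label`,
#'   `cycle_index`, `phase` (`"light"`/`"dark"`), `hour_in_phase` and
#'   `absolute_hour`.
#' @seealso [parse_time_series()] for ordered label sequences,
#'   [format_time_label()] for the inverse.
#' @examples
#' parse_time_label("L6")$absolute_hour    # 6
#' parse_time_label("D3")$absolute_hour    # 15
#' parse_time_label("2L3")$absolute_hour   # 27
#' @export
parse_time_label <- function(label, photoperiod_hours = 12, dark_first = FALSE) {
  if (!is.character(label) || length(label) != 1L || is.na(label)) {
    stop("time label must be a single character string")
  }
  m <- regmatches(label, regexec("^(2?)([LD])([0-9]+)$", label))[[1]]
  if (length(m) == 0L) {
    stop("malformed time label: '", label, "'")
  }
  if (photoperiod_hours <= 0 || photoperiod_hours >= 24) {
    stop("photoperiod_hours must lie in (0, 24)")
  }
  cycle <- if (m[2] == "2") 2L else 1L
  phase <- if (m[3] == "L") "light" else "dark"
  hour_in_phase <- as.integer(m[4])
  phase_len <- if (phase == "light") photoperiod_hours else 24 - photoperiod_hours
  if (hour_in_phase < 1L || hour_in_phase > phase_len) {
    stop(
      "hour in label '", label, "' exceeds the ", phase, " phase length (",
      phase_len, " h)"
    )
  }
  phase_start <- if (dark_first) {
    if (phase == "dark") 0 else 24 - photoperiod_hours
  } else {
    if (phase == "light") 0 else photoperiod_hours
  }
  nominal <- (phase_start + hour_in_phase) %% 24
  structure(
    list(
      raw_label = label,
      cycle_index = cycle,
      phase = phase,
      hour_in_phase = hour_in_phase,
      absolute_hour = nominal + 24 * (cycle - 1L)
    ),
    class = "diel_timepoint"
  )
}

#' @export
format.diel_timepoint <- function(x, ...) format_time_label(x)

#' @export
print.diel_timepoint <- function(x, ...) {
  cat(
    sprintf(
      "<diel_timepoint> %s: cycle %d, %s+%dh, t = %g h\n",
      x$raw_label, x$cycle_index, x$phase, x$hour_in_phase, x$absolute_hour
    )
  )
  invisible(x)
}

#' Format a diel time point back into its label
#'
#' Inverse of [parse_time_label()]: `format_time_label(parse_time_label(l))`
#' returns `l` for every well-formed label.
#'
#' @param tp A `diel_timepoint`.
#' @return Character scalar label.
#' @export
format_time_label <- function(tp) {
  stopifnot(inherits(tp, "diel_timepoint"))
  paste0(
    if (tp$cycle_index == 2L) "2" else "",
    if (tp$phase == "light") "L" else "D",
    tp$hour_in_phase
  )
}

#' Parse an ordered sequence of diel labels onto a monotone time axis
#'
#' Published diel series are listed in sampling order, but the labels alone do
#' not always encode the day unambiguously (a series that starts in the dark
#' can revisit the same phase-hour combination on day two without a `"2"`
#' prefix). For a sequence declared ordered, each label is first parsed with
#' [parse_time_label()] and then unwrapped: whenever a later label would not
#' advance the clock, whole days (24 h) are added until it does. Repeated
#' identical labels (replicate samples) keep the same absolute hour.
#'
#' @param labels Character vector of diel labels in sampling order.
#' @inheritParams parse_time_label
#' @return A data frame with one row per label: `label`, `cycle_index`,
#'   `phase`, `hour_in_phase`, `absolute_hour` (strictly increasing across
#'   distinct consecutive labels).
#' @examples
#' # an 8-point series spanning 36 h
#' parse_time_series(c("L6", "L9", "D3", "D6", "2D12", "2L3", "2L9", "2L12"))
#' @export
parse_time_series <- function(labels, photoperiod_hours = 12, dark_first = FALSE) {
  stopifnot(is.character(labels), length(labels) >= 1L)
  tps <- lapply(labels, parse_time_label,
    photoperiod_hours = photoperiod_hours, dark_first = dark_first
  )
  hours <- vapply(tps, `[[`, numeric(1), "absolute_hour")
  if (length(hours) > 1L) {
    for (i in 2:length(hours)) {
      if (labels[i] == labels[i - 1L]) {
        hours[i] <- hours[i - 1L]
      } else {
        while (hours[i] <= hours[i - 1L]) hours[i] <- hours[i] + 24
      }
    }
  }
  data.frame(
    label = labels,
    cycle_index = vapply(tps, `[[`, integer(1), "cycle_index"),
    phase = vapply(tps, `[[`, character(1), "phase"),
    hour_in_phase = vapply(tps, `[[`, integer(1), "hour_in_phase"),
    absolute_hour = hours,
    stringsAsFactors = FALSE
  )
}
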