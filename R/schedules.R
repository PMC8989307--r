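#' Dosing schedules as explicit event lists
#'
#' A schedule is an ordered list of bolus dosing events, each with a time (days
#' since treatment start) and an amount (mg/kg). All schedule families used in
#' the dosing-comparison experiments are built from a handful of constructors;
#' the simulator consumes the event list and is agnostic to how it was built.
#'
#' Internally, week days are 0-based with treatment starting at t = 0, so the
#' conventional "day 1" of a weekly pattern corresponds to offset 0.
#'
#' @param times numeric vector of event times in days (non-negative).
#' @param amounts numeric vector of doses in mg/kg (positive), recycled to
#'   `length(times)`.
#' @param label short text label for the schedule.
#' @param horizon nominal schedule horizon in days (used for weekly totals).
#' @return An object of class `chemo_schedule`: a list with elements `label`,
#'   `events` (a data.frame with columns `time`, `amount`, sorted by time) and
#'   `horizon`.
#' @examples
#' schedule(c(0, 7, 14, 21), 168, label = "weekly MTD")
#' @export
schedule <- function(times, amounts, label = "custom", horizon = NULL) {
  times <- as.numeric(times)
  amounts <- rep_len(as.numeric(amounts), length(times))
  if (any(times < 0)) stop("event times must be non-negative")
  if (length(times) && any(amounts <= 0)) stop("dose amounts must be positive")
  o <- order(times)
  times <- times[o]
  amounts <- amounts[o]
  if (anyDuplicated(times)) stop("no two events may share an identical time")
  if (is.null(horizon)) horizon <- if (length(times)) floor(max(times)) + 1 else 0
  structure(
    list(label = as.character(label),
         events = data.frame(time = times, amount = amounts),
         horizon = horizon),
    class = "chemo_schedule"
  )
}

#' @export
print.chemo_schedule <- function(x, ...) {
  cat(sprintf("<schedule '%s': %d events over %g days, total %g mg/kg>\n",
              x$label, nrow(x$events), x$horizon, sum(x$events$amount)))
  invisible(x)
}

#' @export
length.chemo_schedule <- function(x) nrow(x$events)

#' Daily dosing schedule
#'
#' One dose on each of days `0 ... n_days - 1`, the standard daily regimen
#' (28 doses by default).
#'
#' @param dose dose per administration, mg/kg (> 0).
#' @param n_days number of dosed days (>= 0).
#' @return A [schedule()].
#' @examples
#' schedule_daily(24)            # 168 mg/kg per week
#' @export
schedule_daily <- function(dose, n_days = 28) {
  stopifnot(dose > 0, n_days >= 0)
  times <- if (n_days > 0) seq.int(0, n_days - 1) else numeric(0)
  schedule(times, dose, label = sprintf("daily-%g", dose), horizon = n_days)
}

#' Cyclic on/off dosing schedule
#'
#' Repeating blocks of `on_days` dosed days followed by `off_days` drug-holiday
#' days, truncated at `horizon`. The 5-on/2-off week-day regimen is
#' `schedule_cycle(5, 2, dose)`.
#'
#' @param on_days dosed days per cycle (>= 1).
#' @param off_days holiday days per cycle (>= 0).
#' @param dose dose per administration, mg/kg.
#' @param horizon days; events strictly before this are kept.
#' @return A [schedule()].
#' @examples
#' schedule_cycle(5, 2, 35)      # 20 doses over 28 days
#' schedule_cycle(1, 6, 168)     # weekly maximum-tolerated-dose
#' @export
schedule_cycle <- function(on_days, off_days, dose, horizon = 28) {
  stopifnot(on_days >= 1, off_days >= 0, dose > 0, horizon >= 1)
  period <- on_days + off_days
  days <- seq.int(0, horizon - 1)
  days <- days[(days %% period) < on_days]
  schedule(days, dose,
           label = sprintf("%gon%goff-%g", on_days, off_days, dose),
           horizon = horizon)
}

#' Weekly on/off pattern schedule
#'
#' `pattern` gives alternating on/off block lengths within one week, starting
#' with an on-block; e.g. `c(4, 1, 1, 1)` doses on week-day offsets
#' 0, 1, 2, 3 and 5 (the pattern "4-on, 1-off, 1-on, 1-off"). Days not covered
#' by the pattern are holidays.
#'
#' @param pattern integer vector of block lengths, `sum(pattern) <= 7`.
#' @param dose dose per administration, mg/kg.
#' @param n_weeks number of weeks the pattern repeats.
#' @return A [schedule()].
#' @examples
#' schedule_weekly_pattern(c(4, 1, 1, 1), 42)
#' @export
schedule_weekly_pattern <- function(pattern, dose, n_weeks = 4) {
  pattern <- as.integer(pattern)
  stopifnot(length(pattern) >= 1, all(pattern >= 1), dose > 0, n_weeks >= 1)
  if (sum(pattern) > 7) stop("pattern block lengths must sum to at most 7")
  on <- logical(7)
  at <- 0L
  for (i in seq_along(pattern)) {
    if (i %% 2 == 1) on[at + seq_len(pattern[i])] <- TRUE
    at <- at + pattern[i]
  }
  offsets <- which(on) - 1L
  days <- as.vector(outer(offsets, 7 * (seq_len(n_weeks) - 1L), `+`))
  schedule(sort(days), dose,
           label = sprintf("pat(%s)-%g", paste(pattern, collapse = ","), dose),
           horizon = 7 * n_weeks)
}

#' Every-other-day schedule
#'
#' Doses on days 0, 2, 4, ... strictly before `horizon`.
#'
#' @param dose dose per administration, mg/kg.
#' @param horizon days.
#' @return A [schedule()].
#' @examples
#' schedule_every_other_day(48)  # 168 mg/kg per week on average
#' @export
schedule_every_other_day <- function(dose, horizon = 28) {
  stopifnot(dose > 0, horizon >= 1)
  schedule(seq.int(0, horizon - 1, by = 2), dose,
           label = sprintf("eod-%g", dose), horizon = horizon)
}

#' Metronomic (multiple doses per day) schedule
#'
#' A fixed weekly total is split into `doses_per_day` equal administrations at
#' equally spaced intraday times `k / doses_per_day` (k = 0, ...,
#' `doses_per_day` - 1) on every day of the treatment window, so the per-dose
#' amount is `weekly_total / (7 * doses_per_day)`.
#'
#' @param doses_per_day integer in 1..6.
#' @param weekly_total mg/kg delivered per 7-day week.
#' @param n_days number of treated days.
#' @return A [schedule()].
#' @examples
#' schedule_metronomic(3, 168)   # 8 mg/kg three times a day
#' @export
schedule_metronomic <- function(doses_per_day, weekly_total, n_days = 28) {
  stopifnot(doses_per_day %in% 1:6, weekly_total > 0, n_days >= 0)
  per_dose <- weekly_total / (7 * doses_per_day)
  days <- if (n_days > 0) seq.int(0, n_days - 1) else numeric(0)
  intraday <- (seq_len(doses_per_day) - 1) / doses_per_day
  times <- as.vector(outer(intraday, days, `+`))
  schedule(sort(times), per_dose,
           label = sprintf("metronomic-%gx-%gwk", doses_per_day, weekly_total),
           horizon = n_days)
}

#' Weekly dose totals of a schedule
#'
#' Sums event amounts in each consecutive `[7k, 7k + 7)` window up to the
#' schedule horizon.
#'
#' @param sch a [schedule()].
#' @return Numeric vector of mg/kg per week (possibly length 0).
#' @examples
#' weekly_totals(schedule_cycle(5, 2, 35))   # 175 175 175 175
#' @export
weekly_totals <- function(sch) {
  stopifnot(inherits(sch, "chemo_schedule"))
  n_weeks <- ceiling(max(sch$horizon,
                         if (length(sch)) max(sch$events$time) + 1e-9 else 0) / 7)
  if (n_weeks == 0) return(numeric(0))
  wk <- findInterval(sch$events$time, 7 * seq_len(n_weeks))
  out <- numeric(n_weeks)
  if (length(sch)) {
    agg <- tapply(sch$events$amount, factor(wk, levels = 0:(n_weeks - 1)), sum)
    out <- as.numeric(ifelse(is.na(agg), 0, agg))
  }
  out
}

#' Parse a schedule from its text shorthand
#'
#' Mini-language used in configuration files:
#' * `"daily:24"` — 24 mg/kg daily;
#' * `"5on2off:35"` — cyclic on/off blocks;
#' * `"pattern:4,1,1,1@42"` — weekly on/off pattern at 42 mg/kg;
#' * `"eod:48"` — every other day;
#' * `"metronomic:3x@168wk"` — 3 doses/day totalling 168 mg/kg/week.
#'
#' @param text schedule shorthand string.
#' @param horizon days (daily/cycle/eod families); weeks are `horizon / 7`.
#' @return A [schedule()].
#' @examples
#' parse_schedule("pattern:4,1,1,1@42")
#' @export
parse_schedule <- function(text, horizon = 28) {
  stopifnot(is.character(text), length(text) == 1)
  m <- regmatches(text, regexec("^([a-z0-9]+):(.+)$", text))[[1]]
  if (length(m) != 3) stop("unrecognized schedule shorthand: ", text)
  kind <- m[2]; rest <- m[3]
  if (kind == "daily") {
    return(schedule_daily(as.numeric(rest), n_days = horizon))
  }
  if (grepl("^([0-9]+)on([0-9]+)off$", kind)) {
    b <- as.numeric(regmatches(kind, regexec("^([0-9]+)on([0-9]+)off$", kind))[[1]][2:3])
    return(schedule_cycle(b[1], b[2], as.numeric(rest), horizon = horizon))
  }
  if (kind == "eod") {
    return(schedule_every_other_day(as.numeric(rest), horizon = horizon))
  }
  if (kind == "pattern") {
    p <- strsplit(rest, "@", fixed = TRUE)[[1]]
    if (length(p) != 2) stop("pattern shorthand needs 'blocks@dose': ", text)
    return(schedule_weekly_pattern(as.integer(strsplit(p[1], ",")[[1]]),
                                   as.numeric(p[2]), n_weeks = horizon / 7))
  }
  if (kind == "metronomic") {
    p <- regmatches(rest, regexec("^([0-9]+)x@([0-9.]+)wk$", rest))[[1]]
    if (length(p) != 3) stop("metronomic shorthand needs 'Nx@TOTALwk': ", text)
    return(schedule_metronomic(as.integer(p[2]), as.numeric(p[3]), n_days = horizon))
  }
  stop("unrecognized schedule family: ", kind)
}

#' Write / read a schedule as CSV
#'
#' Columns `time_days`, `dose_mg_per_kg`; the label and horizon are carried in
#' `#`-prefixed header comments and restored on read.
#'
#' @param sch a [schedule()].
#' @param path file path.
#' @return `write_schedule_csv` returns `path` invisibly; `read_schedule_csv`
#'   returns a [schedule()].
#' @export
write_schedule_csv <- function(sch, path) {
  stopifnot(inherits(sch, "chemo_schedule"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# label: %s", sch$label),
               sprintf("# horizon: %g", sch$horizon)), con)
  utils::write.csv(
    data.frame(time_days = sch$events$time, dose_mg_per_kg = sch$events$amount),
    con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule_csv
#' @export
read_schedule_csv <- function(path) {
  hdr <- readLines(path, n = 2)
  lab <- sub("^# label: ", "", hdr[1])
  hor <- as.numeric(sub("^# horizon: ", "", hdr[2]))
  df <- utils::read.csv(path, comment.char = "#")
  schedule(df$time_days, df$dose_mg_per_kg, label = lab, horizon = hor)
}
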