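#' Experiment suites
#'
#' A suite is a named list of [scenario()]s plus a reference schedule label;
#' [run_suite()] simulates every member and scores it against the reference
#' with [efficacy_scores()]. Scenarios sharing a condition (e.g. aged hosts,
#' morphine comedication) are scored against the matching-condition daily
#' reference via `reference_map`.
#'
#' @param name suite name.
#' @param scenarios named list of [scenario()] objects.
#' @param reference label (name) of the reference scenario.
#' @param reference_map optional named character vector mapping scenario
#'   names to their reference's name; unmapped members use `reference`.
#' @return An `experiment_suite` list.
#' @export
experiment_suite <- function(name, scenarios, reference,
                             reference_map = NULL) {
  stopifnot(is.list(scenarios), length(scenarios) >= 1,
            !is.null(names(scenarios)), reference %in% names(scenarios))
  if (!is.null(reference_map)) {
    stopifnot(all(reference_map %in% names(scenarios)))
  }
  structure(list(name = name, scenarios = scenarios, reference = reference,
                 reference_map = reference_map),
            class = "experiment_suite")
}

#' @export
print.experiment_suite <- function(x, ...) {
  cat(sprintf("<experiment_suite '%s': %d scenarios, reference '%s'>\n",
              x$name, length(x$scenarios), x$reference))
  invisible(x)
}

#' Simulate and score an experiment suite
#'
#' Runs every scenario, computes AUC efficacy scores against the suite's
#' reference, and (optionally) writes one trajectory CSV per scenario, the
#' score table, and a YAML sidecar with run metadata to `out_dir`. Fully
#' deterministic given the suite.
#'
#' @param suite an [experiment_suite()].
#' @param window AUC window in days.
#' @param out_dir optional output directory (created if missing).
#' @return List with `scores` (tibble, reference rows flagged) and
#'   `trajectories` (named list of `host_trajectory`).
#' @export
run_suite <- function(suite, window = c(0, 56), out_dir = NULL) {
  stopifnot(inherits(suite, "experiment_suite"))
  trajs <- lapply(suite$scenarios, simulate_host)
  ref_for <- function(nm) {
    if (!is.null(suite$reference_map) && nm %in% names(suite$reference_map)) {
      suite$reference_map[[nm]]
    } else {
      suite$reference
    }
  }
  rows <- lapply(names(trajs), function(nm) {
    sc <- efficacy_scores(trajs[[nm]], trajs[[ref_for(nm)]], window = window)
    sc$name <- nm
    sc$is_reference <- nm == ref_for(nm)
    sc
  })
  scores <- do.call(rbind, rows)
  scores <- scores[, c("name", "schedule", "reference", "lean_auc_ratio",
                       "tumour_auc_ratio", "total_te", "is_reference",
                       "window_start", "window_end")]
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(as.data.frame(scores),
                     file.path(out_dir, paste0(suite$name, "_scores.csv")),
                     row.names = FALSE)
    for (nm in names(trajs)) {
      write_trajectory_csv(trajs[[nm]],
                           file.path(out_dir, paste0(suite$name, "_", nm, ".csv")))
    }
    meta <- lapply(suite$scenarios, function(sc) {
      list(schedule = sc$sch$label, n_events = length(sc$sch),
           total_dose = sum(sc$sch$events$amount),
           tau = sc$ce$tau, Rd = sc$ce$Rd,
           morphine = sc$morphine, aged = sc$aged,
           t_end = sc$t_end, resolution = sc$resolution,
           rtol = sc$rtol, atol = sc$atol)
    })
    yaml::write_yaml(list(suite = suite$name, window = window,
                          scenarios = meta),
                     file.path(out_dir, paste0(suite$name, "_meta.yaml")))
  }
  list(scores = scores, trajectories = trajs)
}

# shared scaffolding for the built-in suites
.suite_scenario <- function(sch, ...) {
  scenario(sch, tp = tumour_params(), t_end = 56, ...)
}

.named_scenarios <- function(schedules, ...) {
  out <- lapply(schedules, .suite_scenario, ...)
  names(out) <- vapply(schedules, function(s) s$label, character(1))
  out
}

#' Built-in suites: weekly dose-equivalent schedule comparisons
#'
#' `suite_table2()`: the ten equal-dose weekly regimens delivering 168-175
#' mg/kg/week (daily 24; 6-on/1-off 28, 29; 5-on/2-off 34, 35; 4-on/3-off
#' 42, 43; 3-on/4-off 56, 57, 58), referenced to 24 mg/kg daily.
#'
#' `suite_table3()`: the within-week on/off patterns at the same weekly
#' totals (five 5-day patterns at 34 and 35 mg/kg, five 4-day patterns at 42
#' and 43 mg/kg, every-other-day 48 and 50 mg/kg) plus the daily reference.
#'
#' `suite_metronomic()`: 1-6 equal doses per day at 168 mg/kg/week, with the
#' daily 24 and 5-on/2-off 35 standards.
#'
#' `suite_aging()`: the 168 mg/kg/week schedule family (daily, 5-on/2-off 35,
#' 4-on/3-off 42, 3-on/4-off 56, 2-on/5-off 84, 1-on/6-off 168,
#' every-other-day 48, 3-a-day metronomic), each in a young and an aged host;
#' each age group is referenced to its own daily run.
#'
#' `suite_morphine()`: the same schedule family with and without the morphine
#' pharmacokinetic adjustment; each comedication group is referenced to its
#' own daily run.
#'
#' `suite_mtd()`: maximum-tolerated-dose regimens delivering the weekly
#' standard in concentrated form — 168 mg/kg weekly, 336 mg/kg biweekly
#' (days 0 and 14), 672 mg/kg once (day 0) — against the two standards.
#'
#' @return An [experiment_suite()].
#' @export
suite_table2 <- function() {
  specs <- list(c(0, 0, 24), c(6, 1, 28), c(6, 1, 29), c(5, 2, 34),
                c(5, 2, 35), c(4, 3, 42), c(4, 3, 43), c(3, 4, 56),
                c(3, 4, 57), c(3, 4, 58))
  schedules <- lapply(specs, function(s) {
    if (s[1] == 0) schedule_daily(s[3]) else schedule_cycle(s[1], s[2], s[3])
  })
  experiment_suite("table2", .named_scenarios(schedules), "daily-24")
}

#' @rdname suite_table2
#' @export
suite_table3 <- function() {
  pat5 <- list(c(5, 2), c(4, 1, 1, 1), c(3, 1, 2, 1), c(2, 1, 3, 1),
               c(1, 1, 4, 1))
  pat4 <- list(c(4, 3), c(3, 2, 1, 1), c(2, 2, 2, 1), c(1, 2, 3, 1),
               c(1, 1, 1, 1, 1, 1, 1))
  schedules <- c(
    list(schedule_daily(24)),
    unlist(lapply(c(34, 35), function(d)
      lapply(pat5, schedule_weekly_pattern, dose = d)), recursive = FALSE),
    unlist(lapply(c(42, 43), function(d)
      lapply(pat4, schedule_weekly_pattern, dose = d)), recursive = FALSE),
    list(schedule_every_other_day(48), schedule_every_other_day(50)))
  experiment_suite("table3", .named_scenarios(schedules), "daily-24")
}

#' @rdname suite_table2
#' @export
suite_metronomic <- function() {
  schedules <- c(list(schedule_daily(24)),
                 lapply(2:6, schedule_metronomic, weekly_total = 168),
                 list(schedule_cycle(5, 2, 35)))
  experiment_suite("metronomic", .named_scenarios(schedules), "daily-24")
}

.weekly168_schedules <- function() {
  list(schedule_daily(24), schedule_cycle(5, 2, 35), schedule_cycle(4, 3, 42),
       schedule_cycle(3, 4, 56), schedule_cycle(2, 5, 84),
       schedule_cycle(1, 6, 168), schedule_every_other_day(48),
       schedule_metronomic(3, 168))
}

#' @rdname suite_table2
#' @export
suite_aging <- function() {
  schedules <- .weekly168_schedules()
  young <- .named_scenarios(schedules)
  aged <- .named_scenarios(schedules, aged = TRUE)
  names(aged) <- paste0(names(aged), "-aged")
  refs <- c(stats::setNames(rep("daily-24", length(young)), names(young)),
            stats::setNames(rep("daily-24-aged", length(aged)), names(aged)))
  experiment_suite("aging", c(young, aged), "daily-24", reference_map = refs)
}

#' @rdname suite_table2
#' @export
suite_morphine <- function() {
  schedules <- .weekly168_schedules()
  plain <- .named_scenarios(schedules)
  mor <- .named_scenarios(schedules, morphine = TRUE)
  names(mor) <- paste0(names(mor), "-morphine")
  refs <- c(stats::setNames(rep("daily-24", length(plain)), names(plain)),
            stats::setNames(rep("daily-24-morphine", length(mor)), names(mor)))
  experiment_suite("morphine", c(plain, mor), "daily-24", reference_map = refs)
}

#' @rdname suite_table2
#' @export
suite_mtd <- function() {
  schedules <- list(
    schedule_daily(24),
    schedule_cycle(5, 2, 35),
    schedule_cycle(1, 6, 168),
    schedule(c(0, 14), 336, label = "biweekly-336", horizon = 28),
    schedule(0, 672, label = "monthly-672", horizon = 28))
  experiment_suite("mtd", .named_scenarios(schedules), "daily-24")
}
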