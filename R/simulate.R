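#' Treatment scenario
#'
#' Bundles everything one simulation needs: pharmacokinetics, dosing schedule,
#' muscle and chemotherapy-effect parameters, optional tumour parameters,
#' initial host state, horizon and solver settings. The `morphine` flag
#' applies [morphine_adjust()] to the rates at run time; the `aged` flag
#' applies [aged_params()] and, unless `host0` is given explicitly, the aged
#' initial conditions [aged_state()].
#'
#' @param sch a [schedule()].
#' @param pk a [pk_params()] object.
#' @param mp a [muscle_params()] object.
#' @param ce a [chemo_effect()] object (carries `Rd` and `tau`).
#' @param tp a [tumour_params()] object, or `NULL` for no tumour.
#' @param host0 initial [host_state()]; defaults to [young_state()] (or
#'   [aged_state()] when `aged = TRUE`).
#' @param t_end simulation horizon, days (28 treatment + 28 observation by
#'   default); must cover the schedule.
#' @param resolution pharmacokinetic output grid step, days.
#' @param out_step tissue-stage output step, days (a multiple of
#'   `resolution`, so output times sit on the PK grid).
#' @param morphine,aged logical flags, independently toggleable.
#' @param rtol,atol tissue-stage solver tolerances.
#' @return An object of class `chemo_scenario`.
#' @examples
#' sc <- scenario(schedule_daily(24), tp = tumour_params())
#' @export
scenario <- function(sch, pk = pk_params(), mp = muscle_params(),
                     ce = chemo_effect(), tp = NULL, host0 = NULL,
                     t_end = 56, resolution = 0.005, out_step = 0.05,
                     morphine = FALSE, aged = FALSE,
                     rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(sch, "chemo_schedule"), inherits(pk, "pk_params"),
            inherits(mp, "muscle_params"), inherits(ce, "chemo_effect"))
  if (!is.null(tp)) stopifnot(inherits(tp, "tumour_params"))
  if (length(sch) && max(sch$events$time) > t_end) {
    stop("t_end must be at or after the last dose")
  }
  if (abs(out_step / resolution - round(out_step / resolution)) > 1e-8) {
    stop("out_step must be a multiple of resolution")
  }
  if (is.null(host0)) host0 <- if (aged) aged_state() else young_state()
  structure(list(sch = sch, pk = pk, mp = mp, ce = ce, tp = tp,
                 host0 = host0, t_end = t_end, resolution = resolution,
                 out_step = out_step, morphine = isTRUE(morphine),
                 aged = isTRUE(aged), rtol = rtol, atol = atol),
            class = "chemo_scenario")
}

#' @export
print.chemo_scenario <- function(x, ...) {
  cat(sprintf(
    "<scenario: %s | tau=%g Rd=%g | %s%s%s| %g days>\n",
    x$sch$label, x$ce$tau, x$ce$Rd,
    if (x$morphine) "morphine " else "", if (x$aged) "aged " else "",
    if (is.null(x$tp)) "no tumour " else "tumour ", x$t_end))
  invisible(x)
}

# effective parameters after resolving the morphine / aged flags
.effective <- function(sc) {
  list(pk = if (sc$morphine) morphine_adjust(sc$pk) else sc$pk,
       mp = if (sc$aged) aged_params(sc$mp) else sc$mp)
}

#' Run the full coupled simulation for a scenario
#'
#' Staged solve: (i) exact pharmacokinetics with bolus events
#' ([simulate_pk()], with the morphine adjustment when flagged); (ii) the
#' `tau`-day moving-average exposure ([average_exposure()]); (iii) the muscle
#' lineage ODEs driven by the interpolated exposure, and the tumour equation
#' driven by the tissue concentration, each solved adaptively (lsoda,
#' `rtol`/`atol` from the scenario). The exposure is precomputed exactly
#' because the pharmacokinetics are autonomous — the distributed delay never
#' needs a delay solver, and each stage is separately testable.
#'
#' @param sc a [scenario()].
#' @return A `host_trajectory`: a [tibble::tibble()] with columns `time`,
#'   `C1`, `C2`, `y` (micrograms/ml), `S`, `M` (mm^3), `lean_mass` (g),
#'   `stem_ratio`, and `tumour` (mm^3, if configured), one row per output
#'   time; the scenario is attached as attribute `"scenario"`.
#' @examples
#' traj <- simulate_host(scenario(schedule_daily(24), t_end = 56))
#' @export
simulate_host <- function(sc) {
  stopifnot(inherits(sc, "chemo_scenario"))
  eff <- .effective(sc)
  pktraj <- simulate_pk(eff$pk, sc$sch, t_end = sc$t_end,
                        resolution = sc$resolution)
  exps <- average_exposure(pktraj, sc$ce$tau)
  tout <- round(seq(0, sc$t_end, by = sc$out_step), 9)
  sol <- .solve_muscle(tout, cbind(exps$times, exps$y), sc$host0, eff$mp,
                       sc$ce$Rd, rtol = sc$rtol, atol = sc$atol)
  S <- sol$S[, 1]; M <- sol$M[, 1]
  if (any(S < -1e-6) || any(M < -1e-6)) stop("negative state: integration fault")
  ix <- match(tout, round(pktraj$times, 9))
  out <- tibble::tibble(
    time = tout,
    C1 = pktraj$C1[ix], C2 = pktraj$C2[ix], y = exps$y[ix],
    S = S, M = M,
    lean_mass = lean_mass(S, M, eff$mp),
    stem_ratio = ifelse(M > 0, S / M, NA_real_))
  if (!is.null(sc$tp)) {
    out$tumour <- .solve_tumour(tout, cbind(pktraj$times, pktraj$C2), sc$tp,
                                rtol = sc$rtol, atol = sc$atol)
  }
  attr(out, "scenario") <- sc
  class(out) <- c("host_trajectory", class(out))
  out
}

#' Untreated control run
#'
#' Identical to [simulate_host()] with the schedule emptied — the time-matched
#' untreated comparator.
#'
#' @param sc a [scenario()].
#' @return A `host_trajectory`.
#' @export
simulate_control <- function(sc) {
  stopifnot(inherits(sc, "chemo_scenario"))
  sc$sch <- schedule(numeric(0), numeric(0),
                     label = paste0(sc$sch$label, "-control"),
                     horizon = sc$sch$horizon)
  simulate_host(sc)
}

#' Write a host trajectory as CSV
#'
#' One row per output time, one column per series.
#'
#' @param traj a `host_trajectory`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}
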