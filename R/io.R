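#' Write / read a scenario as YAML
#'
#' Parameters are keyed by their conventional symbols (k10, k12, k21, V1, V2,
#' p0, p1, nu0, nu1, d0, m, density, Rd, tau, mu0, mu1, eta, kappa, T0); the
#' schedule is stored either as its text shorthand (when it parses back) or
#' as an explicit event list.
#'
#' @param sc a [scenario()].
#' @param path file path.
#' @return `write_scenario_yaml` returns `path` invisibly;
#'   `read_scenario_yaml` returns a [scenario()].
#' @export
write_scenario_yaml <- function(sc, path) {
  stopifnot(inherits(sc, "chemo_scenario"))
  x <- list(
    schedule = list(label = sc$sch$label,
                    time_days = sc$sch$events$time,
                    dose_mg_per_kg = sc$sch$events$amount,
                    horizon = sc$sch$horizon),
    pk = unclass(sc$pk),
    muscle = unclass(sc$mp),
    chemo = list(Rd = sc$ce$Rd, tau = sc$ce$tau),
    tumour = if (!is.null(sc$tp)) unclass(sc$tp),
    host0 = list(S = sc$host0[["S"]], M = sc$host0[["M"]]),
    t_end = sc$t_end, resolution = sc$resolution, out_step = sc$out_step,
    morphine = sc$morphine, aged = sc$aged, rtol = sc$rtol, atol = sc$atol)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_scenario_yaml
#' @export
read_scenario_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  sch <- schedule(unlist(x$schedule$time_days %||% numeric(0)),
                  unlist(x$schedule$dose_mg_per_kg %||% numeric(0)),
                  label = x$schedule$label, horizon = x$schedule$horizon)
  scenario(sch,
           pk = do.call(pk_params, x$pk),
           mp = do.call(muscle_params, x$muscle),
           ce = chemo_effect(Rd = x$chemo$Rd, tau = x$chemo$tau),
           tp = if (!is.null(x$tumour)) do.call(tumour_params, x$tumour),
           host0 = host_state(x$host0$S, x$host0$M),
           t_end = x$t_end, resolution = x$resolution,
           out_step = x$out_step, morphine = x$morphine, aged = x$aged,
           rtol = x$rtol, atol = x$atol)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
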