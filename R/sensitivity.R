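# Parameters addressable by name in a scenario, and where they live.
.PARAM_SLOTS <- list(
  pk = c("k10", "k12", "k21", "V1", "V2"),
  mp = c("p0", "p1", "nu0", "nu1", "d0", "m"),
  ce = c("Rd", "tau"),
  tp = c("mu0", "mu1", "eta", "kappa"))

.param_value <- function(sc, name) {
  for (slot in names(.PARAM_SLOTS)) {
    if (name %in% .PARAM_SLOTS[[slot]]) {
      if (slot == "tp" && is.null(sc$tp)) stop("scenario has no tumour stage")
      return(sc[[slot]][[name]])
    }
  }
  stop("unknown parameter name: ", name)
}

# Return the scenario with `name` multiplied by `factor`; re-validates
# through the parameter constructors.
.perturb_scenario <- function(sc, name, factor) {
  slot <- names(.PARAM_SLOTS)[vapply(.PARAM_SLOTS, function(p) name %in% p,
                                     logical(1))]
  if (!length(slot)) stop("unknown parameter name: ", name)
  obj <- sc[[slot]]
  vals <- unclass(obj)
  vals[[name]] <- vals[[name]] * factor
  sc[[slot]] <- switch(slot,
    pk = do.call(pk_params, vals),
    mp = do.call(muscle_params, vals),
    ce = do.call(chemo_effect, vals[c("Rd", "tau")]),
    tp = do.call(tumour_params, vals))
  sc
}

#' Dynamic sensitivity coefficients of lean mass
#'
#' One-sided finite-difference sensitivity of the lean-mass trajectory to a
#' relative perturbation of one parameter:
#' `S(t) = (LM(t; (1 + e) rho) - LM(t; rho)) / (e rho)` with `e = +/-eps`
#' (sign from `direction`), and the dimensionless relative coefficient
#' `S_rel(t) = S(t) rho / LM(t)`. The default `eps = 1e-5` is small enough
#' that the coefficients are stable; `tau` is perturbed continuously
#' (non-integer windows are well defined in the exposure average).
#'
#' @param sc a [scenario()].
#' @param parameter one of k10, k12, k21, V1, V2, p0, p1, nu0, nu1, d0, m,
#'   Rd, tau (or a tumour parameter, whose lean-mass sensitivity is zero by
#'   model structure).
#' @param eps relative perturbation (> 0).
#' @param direction `"plus"` or `"minus"` one-sided difference.
#' @param out_step output grid step, days (daily by default).
#' @param rtol,atol tissue-stage tolerances for the paired runs. Defaults are
#'   much tighter than for plain simulation: the epsilon-level lean-mass
#'   difference is of order `1e-6` g, so the integration error must sit well
#'   below that for the quotient to be meaningful.
#' @return A `sensitivity_series` tibble with columns `parameter`, `time`,
#'   `S` (g per parameter unit) and `S_rel` (dimensionless).
#' @export
sensitivity_series <- function(sc, parameter, eps = 1e-5,
                               direction = c("plus", "minus"), out_step = 1,
                               rtol = 1e-11, atol = 1e-13) {
  stopifnot(inherits(sc, "chemo_scenario"), eps > 0)
  direction <- match.arg(direction)
  rho <- .param_value(sc, parameter)
  if (rho == 0) stop("relative perturbation undefined: nominal value is zero")
  e <- if (direction == "plus") eps else -eps
  sc1 <- .perturb_scenario(sc, parameter, 1 + e)
  eff0 <- .effective(sc)
  eff1 <- .effective(sc1)
  tout <- round(seq(0, sc$t_end, by = out_step), 9)
  # nominal and perturbed blocks are integrated jointly (shared solver steps)
  # so truncation error cancels in the epsilon-level lean-mass difference
  pk0 <- simulate_pk(eff0$pk, sc$sch, t_end = sc$t_end,
                     resolution = sc$resolution)
  pk1 <- if (parameter %in% .PARAM_SLOTS$pk) {
    simulate_pk(eff1$pk, sc$sch, t_end = sc$t_end, resolution = sc$resolution)
  } else {
    pk0
  }
  ex0 <- average_exposure(pk0, sc$ce$tau)
  ex1 <- if (parameter %in% c(.PARAM_SLOTS$pk, "tau")) {
    average_exposure(pk1, sc1$ce$tau)
  } else {
    ex0
  }
  sol <- .solve_muscle_pair(tout, cbind(ex0$times, ex0$y),
                            cbind(ex1$times, ex1$y), sc$host0,
                            eff0$mp, sc$ce$Rd, eff1$mp, sc1$ce$Rd,
                            rtol = rtol, atol = atol)
  lm0 <- eff0$mp$density * (sol$S[, 1] + sol$M[, 1])
  lm1 <- eff1$mp$density * (sol$S[, 2] + sol$M[, 2])
  S <- (lm1 - lm0) / (e * rho)
  out <- tibble::tibble(
    parameter = parameter,
    time = tout,
    S = S,
    S_rel = S * rho / lm0)
  class(out) <- c("sensitivity_series", class(out))
  out
}

#' Paired +/- perturbation trajectories
#'
#' Full simulations at the nominal parameter value and at `(1 +/- fraction)`
#' times it (10% by default), aligned on one output grid — the display
#' companion to the epsilon-level coefficients of [sensitivity_series()].
#'
#' @param sc a [scenario()].
#' @param parameter addressable parameter name.
#' @param fraction relative displacement (>= 0).
#' @return List with elements `nominal`, `plus`, `minus` (each a
#'   `host_trajectory`) and `parameter`, `fraction`.
#' @export
perturbation_run <- function(sc, parameter, fraction = 0.10) {
  stopifnot(inherits(sc, "chemo_scenario"), fraction >= 0)
  .param_value(sc, parameter)  # validates the name
  list(nominal = simulate_host(sc),
       plus = simulate_host(.perturb_scenario(sc, parameter, 1 + fraction)),
       minus = simulate_host(.perturb_scenario(sc, parameter, 1 - fraction)),
       parameter = parameter, fraction = fraction)
}

#' Sensitivity of lean mass to every addressable parameter
#'
#' Runs [sensitivity_series()] for each parameter that can affect the lean
#' mass (pharmacokinetic rates and volumes, lineage parameters, `Rd`, `tau`);
#' tumour-only parameters are excluded by contract since the tumour equation
#' does not feed back on the muscle.
#'
#' @param sc a [scenario()].
#' @param parameters character vector of parameter names.
#' @param ... passed to [sensitivity_series()].
#' @return A tibble of stacked sensitivity series.
#' @export
all_param_sensitivity <- function(sc,
                                  parameters = c("k10", "k12", "k21", "V1",
                                                 "V2", "p0", "p1", "nu0",
                                                 "nu1", "d0", "m", "Rd",
                                                 "tau"),
                                  ...) {
  stopifnot(length(parameters) >= 1)
  bad <- setdiff(parameters, unlist(.PARAM_SLOTS[c("pk", "mp", "ce")]))
  if (length(bad)) stop("unknown or tumour-only parameter: ",
                        paste(bad, collapse = ", "))
  do.call(rbind, lapply(parameters, function(p) sensitivity_series(sc, p, ...)))
}

#' Write sensitivity series as CSV
#'
#' Columns `parameter, time, S, S_rel`.
#'
#' @param sens a sensitivity tibble.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_sensitivity_csv <- function(sens, path) {
  utils::write.csv(as.data.frame(sens), path, row.names = FALSE)
  invisible(path)
}
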