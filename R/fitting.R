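#' Multi-arm dose-response dataset
#'
#' Tidy container for lean-mass time courses under a family of dosing
#' schedules: one row per observation with columns `family` ("daily" or
#' "5on2off"), `dose_mg_per_kg` (0 = untreated control arm), `day`,
#' `lean_mass_g` and `replicate`.
#'
#' @param df data frame with the columns above (`replicate` optional,
#'   defaults to 1).
#' @return A `dose_response_dataset` (a tibble subclass).
#' @export
dose_response_dataset <- function(df) {
  df <- tibble::as_tibble(df)
  need <- c("family", "dose_mg_per_kg", "day", "lean_mass_g")
  if (!all(need %in% names(df))) {
    stop("dataset needs columns: ", paste(need, collapse = ", "))
  }
  if (!"replicate" %in% names(df)) df$replicate <- 1L
  if (nrow(df) == 0) stop("empty dataset")
  if (any(df$day < 0 | df$day > 56)) stop("observation days must lie in [0, 56]")
  if (any(df$lean_mass_g <= 0)) stop("lean masses must be positive")
  if (!any(df$dose_mg_per_kg > 0)) stop("need at least one non-zero dose arm")
  class(df) <- c("dose_response_dataset", class(df))
  df
}

#' Write / read the dataset CSV schema
#'
#' Long format: `family, dose_mg_per_kg, day, lean_mass_g, replicate`.
#'
#' @param ds a [dose_response_dataset()].
#' @param path file path.
#' @return `write_dataset_csv` returns `path` invisibly; `read_dataset_csv`
#'   returns a [dose_response_dataset()].
#' @export
write_dataset_csv <- function(ds, path) {
  utils::write.csv(as.data.frame(ds), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset_csv
#' @export
read_dataset_csv <- function(path) {
  dose_response_dataset(utils::read.csv(path))
}

#' Scenario template for fitting
#'
#' Fixes everything about the simulation except the schedule (constructed per
#' arm from the dataset's family and dose) and the `(tau, Rd)` pair under
#' evaluation.
#'
#' @param pk a [pk_params()] object.
#' @param mp a [muscle_params()] object.
#' @param host0 initial [host_state()].
#' @param t_end horizon, days.
#' @param resolution PK grid step, days.
#' @param rtol,atol tissue-stage tolerances.
#' @return A list of class `fit_template`.
#' @export
scenario_template <- function(pk = pk_params(), mp = muscle_params(),
                              host0 = young_state(), t_end = 56,
                              resolution = 0.005, rtol = 1e-8, atol = 1e-10) {
  structure(list(pk = pk, mp = mp, host0 = host0, t_end = t_end,
                 resolution = resolution, rtol = rtol, atol = atol),
            class = "fit_template")
}

# Schedule for a (family, dose) arm.
.family_schedule <- function(family, dose) {
  switch(family,
         daily = schedule_daily(dose, n_days = 28),
         `5on2off` = schedule_cycle(5, 2, dose, horizon = 28),
         stop("unknown schedule family: ", family))
}

# Non-control arms as a list of (family, dose, days, obs) with observations
# averaged over replicates left as-is (each row is a residual).
.arms <- function(ds) {
  key <- interaction(ds$family, ds$dose_mg_per_kg, drop = TRUE)
  lapply(split(seq_len(nrow(ds)), key), function(ix) {
    list(family = ds$family[ix[1]], dose = ds$dose_mg_per_kg[ix[1]],
         day = ds$day[ix], obs = ds$lean_mass_g[ix])
  })
}

# PK trajectories per non-zero-dose arm (independent of tau and Rd).
.arm_pk <- function(arms, tmpl) {
  lapply(arms, function(a) {
    if (a$dose == 0) return(NULL)
    simulate_pk(tmpl$pk, .family_schedule(a$family, a$dose),
                t_end = tmpl$t_end, resolution = tmpl$resolution)
  })
}

# Vector of SSE values, one per Rd, for fixed tau. `pks` as from .arm_pk.
.sse_vector <- function(arms, pks, tau, Rd, tmpl) {
  total <- numeric(length(Rd))
  for (i in seq_along(arms)) {
    a <- arms[[i]]
    if (a$dose == 0) next  # control arm excluded from the cost
    exps <- average_exposure(pks[[i]], tau)
    tout <- sort(unique(c(0, a$day)))
    sol <- .solve_muscle(tout, cbind(exps$times, exps$y), tmpl$host0,
                         tmpl$mp, Rd, rtol = tmpl$rtol, atol = tmpl$atol)
    lean <- tmpl$mp$density * (sol$S + sol$M)  # times x Rd
    rowix <- match(a$day, tout)
    resid <- lean[rowix, , drop = FALSE] - a$obs
    total <- total + colSums(resid^2)
  }
  total
}

#' Total sum of squared errors at a (tau, Rd) pair
#'
#' Simulates every non-zero-dose arm of the dataset under the template at the
#' given `(tau, Rd)`, reads the model lean mass at the observation days, and
#' accumulates squared residuals (grams^2) across all arms at once. The
#' control arm is excluded from the cost.
#'
#' @param ds a [dose_response_dataset()].
#' @param tau exposure window, days (> 0).
#' @param Rd threshold, micrograms/ml (> 0).
#' @param template a [scenario_template()].
#' @return SSE in g^2.
#' @export
fit_sse <- function(ds, tau, Rd, template = scenario_template()) {
  stopifnot(inherits(ds, "dose_response_dataset"), tau > 0, Rd > 0)
  arms <- .arms(ds)
  .sse_vector(arms, .arm_pk(arms, template), tau, Rd, template)
}

#' Grid-search fit of Rd at fixed tau
#'
#' Two-stage grid search: a coarse sweep (step `coarse`, default 0.05
#' micrograms/ml over `[1, 20]`) followed by a fine sweep (step `fine`,
#' default 0.01) around the coarse minimum. Ties break toward smaller `Rd`.
#' If the coarse minimum sits on a search boundary the result is flagged
#' (`boundary = TRUE`) with a warning.
#'
#' @param ds a [dose_response_dataset()].
#' @param tau exposure window, days.
#' @param rd_bounds length-2 search bounds, micrograms/ml.
#' @param coarse,fine grid steps, micrograms/ml (`coarse > fine`).
#' @param template a [scenario_template()].
#' @return List with `Rd`, `sse`, `boundary`.
#' @export
fit_rd_given_tau <- function(ds, tau, rd_bounds = c(1, 20), coarse = 0.05,
                             fine = 0.01, template = scenario_template()) {
  stopifnot(inherits(ds, "dose_response_dataset"),
            tau > 0, all(rd_bounds > 0), coarse > fine, fine > 0)
  arms <- .arms(ds)
  pks <- .arm_pk(arms, template)
  .fit_rd(arms, pks, tau, rd_bounds, coarse, fine, template)
}

.fit_rd <- function(arms, pks, tau, rd_bounds, coarse, fine, tmpl) {
  grid <- seq(rd_bounds[1], rd_bounds[2], by = coarse)
  if (!length(grid)) stop("bounds exclude the entire coarse grid")
  sse_c <- .sse_vector(arms, pks, tau, grid, tmpl)
  i <- which.min(sse_c)            # first minimum = smallest Rd on ties
  boundary <- i == 1L || i == length(grid)
  if (boundary) {
    warning("coarse-grid minimum on the search boundary (Rd = ", grid[i], ")")
  }
  fgrid <- seq(max(rd_bounds[1], grid[i] - coarse),
               min(rd_bounds[2], grid[i] + coarse), by = fine)
  sse_f <- .sse_vector(arms, pks, tau, fgrid, tmpl)
  j <- which.min(sse_f)
  list(Rd = fgrid[j], sse = sse_f[j], boundary = boundary)
}

#' Sweep integer tau values, fitting Rd at each
#'
#' Runs [fit_rd_given_tau()] for every `tau` in `tau_range` (integers 1..15
#' by default), recording the SSE profile. Pharmacokinetic trajectories are
#' cached per arm across the sweep (they do not depend on `tau` or `Rd`).
#'
#' @param ds a [dose_response_dataset()].
#' @param tau_range integer vector of windows, days.
#' @inheritParams fit_rd_given_tau
#' @return A `fit_grid` tibble with columns `tau`, `Rd`, `sse`, `boundary`.
#' @export
fit_grid <- function(ds, tau_range = 1:15, rd_bounds = c(1, 20),
                     coarse = 0.05, fine = 0.01,
                     template = scenario_template()) {
  stopifnot(inherits(ds, "dose_response_dataset"), length(tau_range) >= 1)
  arms <- .arms(ds)
  pks <- .arm_pk(arms, template)
  rows <- lapply(tau_range, function(tau) {
    f <- .fit_rd(arms, pks, tau, rd_bounds, coarse, fine, template)
    tibble::tibble(tau = tau, Rd = f$Rd, sse = f$sse, boundary = f$boundary)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("fit_grid", class(out))
  out
}

#' Global parameter selection across the two schedule families
#'
#' The global window is the midpoint of the two per-family argmin `tau`
#' values; a half-integer midpoint is rounded toward the daily family's
#' argmin (and flagged). The global `Rd` is the mean of the two families'
#' best-fit `Rd` at that window.
#'
#' @param fit_daily,fit_52 `fit_grid` results for the daily and 5-on/2-off
#'   families (sharing the `tau` range).
#' @return List of class `global_fit` with `tau`, `Rd`, `tau_daily`,
#'   `tau_52`, `half_integer`.
#' @export
select_global <- function(fit_daily, fit_52) {
  stopifnot(inherits(fit_daily, "fit_grid"), inherits(fit_52, "fit_grid"),
            setequal(fit_daily$tau, fit_52$tau))
  a <- fit_daily$tau[which.min(fit_daily$sse)]
  b <- fit_52$tau[which.min(fit_52$sse)]
  mid <- (a + b) / 2
  half <- abs(mid - round(mid)) > 1e-9
  tau_g <- if (!half) mid else floor(mid) + (a > b)  # round toward daily argmin
  rd_g <- mean(c(fit_daily$Rd[fit_daily$tau == tau_g],
                 fit_52$Rd[fit_52$tau == tau_g]))
  structure(list(tau = tau_g, Rd = rd_g, tau_daily = a, tau_52 = b,
                 half_integer = half),
            class = "global_fit")
}

#' @export
print.global_fit <- function(x, ...) {
  cat(sprintf("<global_fit: tau = %g days, Rd = %g ug/ml (family argmins %g, %g%s)>\n",
              x$tau, x$Rd, x$tau_daily, x$tau_52,
              if (x$half_integer) "; half-integer midpoint rounded" else ""))
  invisible(x)
}
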