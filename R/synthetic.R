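#' Synthetic dose-response configuration
#'
#' Describes a simulated dose-response experiment with the structure of the
#' digitized mouse data: several dose arms (including a zero-dose control)
#' of one schedule family, lean mass sampled every `cadence` days over
#' `horizon` days, generated from the coupled model at a known
#' `(true_tau, true_Rd)` plus additive Gaussian measurement noise. With
#' `body_weight_emulation` the initial state encodes a 25 g mouse at 40%
#' lean mass (10 g lean) — the young-host initial volumes.
#'
#' @param family `"daily"` or `"5on2off"`.
#' @param dose_arms doses in mg/kg; 0 is the control arm.
#' @param true_tau generating exposure window, days.
#' @param true_Rd generating threshold, micrograms/ml.
#' @param noise_sd measurement noise standard deviation, g (>= 0). The source
#'   curves are digitized means with no stated error model, so this is a
#'   free knob; 0.2 g is the package default for realistic scatter.
#' @param cadence days between observations (> 0).
#' @param horizon days (28 treatment + 28 observation by default).
#' @param seed integer RNG seed; identical seeds give identical datasets.
#' @param replicates series per arm (1 = arm means, the default).
#' @param body_weight_emulation use the 25 g / 40%-lean initial state.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(family = "daily",
                             dose_arms = c(0, 14, 17, 20, 24, 29, 35),
                             true_tau = 8, true_Rd = 6.8, noise_sd = 0.2,
                             cadence = 2, horizon = 56, seed = 1L,
                             replicates = 1L, body_weight_emulation = TRUE) {
  stopifnot(family %in% c("daily", "5on2off"), noise_sd >= 0, cadence > 0,
            true_tau > 0, true_Rd > 0, replicates >= 1)
  if (anyDuplicated(dose_arms)) stop("dose arms must be distinct")
  structure(list(family = family, dose_arms = sort(dose_arms),
                 true_tau = true_tau, true_Rd = true_Rd,
                 noise_sd = noise_sd, cadence = cadence, horizon = horizon,
                 seed = as.integer(seed), replicates = as.integer(replicates),
                 body_weight_emulation = isTRUE(body_weight_emulation)),
            class = "synthetic_config")
}

#' Default daily and 5-on/2-off experiment configurations
#'
#' The dose arms mirror the source experiment: 14-35 mg/kg for the daily
#' family and 24-60 mg/kg for the 5-on/2-off family, each with a zero-dose
#' control, 2-day cadence, 56-day horizon.
#'
#' @param ... overrides passed to both [synthetic_config()] calls.
#' @return Named list with elements `daily` and `5on2off`.
#' @export
default_configs <- function(...) {
  list(daily = synthetic_config(family = "daily",
                                dose_arms = c(0, 14, 17, 20, 24, 29, 35), ...),
       `5on2off` = synthetic_config(family = "5on2off",
                                    dose_arms = c(0, 24, 35, 42, 50, 60), ...))
}

#' Generate a synthetic dose-response dataset
#'
#' Simulates each arm with the coupled model at the configuration's
#' `(true_tau, true_Rd)`, samples lean mass at the cadence, and adds
#' independent Gaussian noise. The RNG state is scoped to the call, so the
#' same configuration always yields the same dataset and the caller's RNG
#' stream is untouched.
#'
#' @param config a [synthetic_config()].
#' @param template a [scenario_template()] carrying the fixed parameters.
#' @return A [dose_response_dataset()].
#' @export
generate_dataset <- function(config, template = scenario_template()) {
  stopifnot(inherits(config, "synthetic_config"))
  host0 <- if (config$body_weight_emulation) young_state() else template$host0
  days <- seq(0, config$horizon, by = config$cadence)
  arms <- lapply(config$dose_arms, function(dose) {
    sch <- if (dose == 0) {
      schedule(numeric(0), numeric(0), label = "control", horizon = 28)
    } else {
      .family_schedule(config$family, dose)
    }
    sc <- scenario(sch, pk = template$pk, mp = template$mp,
                   ce = chemo_effect(Rd = config$true_Rd, tau = config$true_tau),
                   host0 = host0, t_end = config$horizon,
                   resolution = template$resolution,
                   rtol = template$rtol, atol = template$atol)
    traj <- simulate_host(sc)
    truth <- stats::approx(traj$time, traj$lean_mass, xout = days)$y
    tibble::tibble(family = config$family,
                   dose_mg_per_kg = rep(dose, length(days) * config$replicates),
                   day = rep(days, config$replicates),
                   lean_mass_g = rep(truth, config$replicates),
                   replicate = rep(seq_len(config$replicates), each = length(days)))
  })
  out <- do.call(rbind, arms)
  out$lean_mass_g <- withr::with_seed(
    config$seed,
    out$lean_mass_g + stats::rnorm(nrow(out), sd = config$noise_sd))
  if (any(out$lean_mass_g <= 0)) {
    stop("noise produced non-positive lean mass; lower noise_sd")
  }
  dose_response_dataset(out)
}
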