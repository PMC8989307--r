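#' Muscle stem-cell lineage parameters
#'
#' Parameters of the two-compartment stem-cell lineage model of skeletal
#' muscle: satellite (stem) cells `S` divide symmetrically at rate `nu(M)`,
#' self-renewing with probability `p(M)`, and differentiated fibres `M` die at
#' rate `d0`. Both `p` and `nu` decrease with muscle volume through a shared
#' half-saturation feedback `1 / (1 + M/m)`, which shuts growth off as the
#' tissue approaches homeostasis. Volumes (mm^3) convert to lean mass via
#' `density` g/mm^3.
#'
#' Defaults are the literature fit to CDF1 mouse growth curves.
#'
#' @param p0 base self-renewal probability (homeostatic).
#' @param p1 perturbation probability active in early growth / after damage.
#' @param nu0 base proliferation rate, /day.
#' @param nu1 perturbation proliferation rate, /day.
#' @param d0 muscle fibre death rate, /day.
#' @param m half-saturation volume of the feedback, mm^3.
#' @param density lean-mass conversion factor, g/mm^3.
#' @return An object of class `muscle_params`.
#' @export
muscle_params <- function(p0 = 0.479, p1 = 0.133, nu0 = 0.087, nu1 = 5.591,
                          d0 = 0.05, m = 1000, density = 0.002) {
  if (!(p0 > 0 && p0 < 0.5)) stop("need 0 < p0 < 0.5")
  if (!(p0 + p1 > 0.5 && p0 + p1 <= 1)) stop("need 0.5 < p0 + p1 <= 1")
  if (any(c(nu0, nu1, d0, m, density) <= 0)) {
    stop("nu0, nu1, d0, m and density must be positive")
  }
  structure(list(p0 = p0, p1 = p1, nu0 = nu0, nu1 = nu1, d0 = d0, m = m,
                 density = density),
            class = "muscle_params")
}

#' @export
print.muscle_params <- function(x, ...) {
  cat(sprintf(
    "<muscle_params: p0=%g p1=%g nu0=%g nu1=%g /day d0=%g /day m=%g mm^3>\n",
    x$p0, x$p1, x$nu0, x$nu1, x$d0, x$m))
  invisible(x)
}

#' Chemotherapy effect parameters
#'
#' The chemotherapy pharmacodynamic effect multiplies both lineage fluxes by
#' `1 - (y/Rd)^3`, where `y` is the `tau`-day moving-average tissue exposure.
#' `Rd` is the thresholding concentration at which net proliferation is
#' nullified; the cubic exponent encodes the observed strongly nonlinear dose
#' response. Defaults are the global fitted values `tau = 8` days,
#' `Rd = 6.8` micrograms/ml.
#'
#' @param Rd thresholding constant, micrograms/ml.
#' @param tau exposure-averaging window, days.
#' @return An object of class `chemo_effect` (exponent fixed at 3).
#' @export
chemo_effect <- function(Rd = 6.8, tau = 8) {
  if (Rd <= 0) stop("Rd must be positive")
  if (tau <= 0) stop("tau must be positive")
  structure(list(Rd = Rd, tau = tau, exponent = 3), class = "chemo_effect")
}

#' @export
print.chemo_effect <- function(x, ...) {
  cat(sprintf("<chemo_effect: Rd = %g ug/ml, tau = %g days, cubic>\n",
              x$Rd, x$tau))
  invisible(x)
}

#' Exponential-linear tumour growth parameters
#'
#' Tumour volume grows exponentially at rate `mu0` while small, transitioning
#' (sharpness `eta`) to linear growth at rate `mu1`; chemotherapy kills in
#' proportion to the tissue drug concentration with efficacy `kappa`.
#' Defaults are the C26 murine carcinoma fit with `kappa = 0.13` ml/ug/day
#' and `T0 = 10` mm^3.
#'
#' @param mu0 exponential growth rate, /day.
#' @param mu1 linear growth rate, mm^3/day.
#' @param eta transition sharpness (dimensionless, >= 4).
#' @param kappa kill efficacy, ml/ug/day.
#' @param T0 initial tumour volume, mm^3.
#' @return An object of class `tumour_params`.
#' @export
tumour_params <- function(mu0 = 0.446, mu1 = 116.0, eta = 20, kappa = 0.13,
                          T0 = 10) {
  if (any(c(mu0, mu1, eta, kappa, T0) <= 0)) stop("all tumour parameters must be positive")
  if (eta < 4) stop("eta below 4 distorts the exponential-linear transition")
  structure(list(mu0 = mu0, mu1 = mu1, eta = eta, kappa = kappa, T0 = T0),
            class = "tumour_params")
}

#' @export
print.tumour_params <- function(x, ...) {
  cat(sprintf(
    "<tumour_params: mu0=%g /day mu1=%g mm^3/day eta=%g kappa=%g ml/ug/day T0=%g mm^3>\n",
    x$mu0, x$mu1, x$eta, x$kappa, x$T0))
  invisible(x)
}

#' Host state (satellite and muscle volumes)
#'
#' @param S satellite-cell volume, mm^3 (>= 0).
#' @param M muscle-fibre volume, mm^3 (>= 0).
#' @return Named numeric vector `c(S, M)`.
#' @export
host_state <- function(S, M) {
  if (S < 0 || M < 0) stop("volumes must be non-negative")
  c(S = unname(S), M = unname(M))
}

#' Self-renewal probability feedback
#'
#' `p(M) = p0 + p1 / (1 + M/m)`; strictly decreasing in muscle volume.
#'
#' @param M muscle volume, mm^3 (vectorized, >= 0).
#' @param mp a [muscle_params()] object.
#' @return Probability (same length as `M`).
#' @examples
#' renewal_probability(1000, muscle_params())   # 0.5455
#' @export
renewal_probability <- function(M, mp = muscle_params()) {
  if (any(M < 0)) stop("M must be non-negative")
  mp$p0 + mp$p1 / (1 + M / mp$m)
}

#' Proliferation-rate feedback
#'
#' `nu(M) = nu0 + nu1 / (1 + M/m)`; strictly decreasing in muscle volume.
#'
#' @inheritParams renewal_probability
#' @return Rate in /day (same length as `M`).
#' @examples
#' proliferation_rate(0, muscle_params())   # 5.678
#' @export
proliferation_rate <- function(M, mp = muscle_params()) {
  if (any(M < 0)) stop("M must be non-negative")
  mp$nu0 + mp$nu1 / (1 + M / mp$m)
}

#' Cubic chemotherapy suppression factor
#'
#' `1 - (y/Rd)^3`. Deliberately not clamped below zero: exposures above `Rd`
#' drive net loss of both compartments, which is what produces the severe
#' response at high doses.
#'
#' @param y moving-average exposure, micrograms/ml (vectorized, >= 0).
#' @param Rd thresholding constant, micrograms/ml.
#' @return Dimensionless multiplier (<= 1).
#' @examples
#' chemo_factor(c(0, 6.8, 13.6), Rd = 6.8)   # 1 0 -7
#' @export
chemo_factor <- function(y, Rd) {
  if (Rd <= 0) stop("Rd must be positive")
  1 - (y / Rd)^3
}

#' Lineage derivatives under chemotherapy
#'
#' Right-hand side of the chemotherapy-coupled lineage model:
#' `dS/dt = f(y) (2p - 1) nu S`, `dM/dt = f(y) 2 (1 - p) nu S - d0 M`, with
#' `f` the [chemo_factor()] and `p`, `nu` evaluated at `M`. With `y = 0` this
#' is the healthy model.
#'
#' @param state [host_state()] vector `c(S, M)`.
#' @param y moving-average exposure, micrograms/ml.
#' @param mp a [muscle_params()] object.
#' @param ce a [chemo_effect()] object.
#' @return Named numeric vector `c(dS, dM)` in mm^3/day.
#' @export
muscle_derivatives <- function(state, y = 0, mp = muscle_params(),
                               ce = chemo_effect()) {
  S <- state[["S"]]; M <- state[["M"]]
  p <- renewal_probability(M, mp)
  nu <- proliferation_rate(M, mp)
  f <- chemo_factor(y, ce$Rd)
  c(dS = f * (2 * p - 1) * nu * S,
    dM = f * 2 * (1 - p) * nu * S - mp$d0 * M)
}

#' Lean mass from compartment volumes
#'
#' `density * (S + M)` grams.
#'
#' @param S,M volumes in mm^3 (vectorized), or `S` may be a [host_state()].
#' @param mp a [muscle_params()] object (supplies `density`).
#' @return Grams.
#' @examples
#' lean_mass(267.5, 4732.5)   # 10 g
#' @export
lean_mass <- function(S, M = NULL, mp = muscle_params()) {
  if (is.null(M)) { M <- S[["M"]]; S <- S[["S"]] }
  mp$density * (S + M)
}

#' Healthy homeostatic equilibrium (closed form)
#'
#' At equilibrium the self-renewal probability equals 1/2, giving
#' `M* = m (p1 / (1/2 - p0) - 1)`, and the fibre balance gives
#' `S* = d0 M* / nu(M*)`. Exists (positive) iff `p0 < 1/2 < p0 + p1`.
#'
#' @param mp a [muscle_params()] object.
#' @return [host_state()] vector `c(S, M)` in mm^3.
#' @examples
#' healthy_equilibrium()   # (274.97, 5333.33): lean mass 11.22 g, ratio 0.0516
#' @export
healthy_equilibrium <- function(mp = muscle_params()) {
  if (!(mp$p0 < 0.5 && mp$p0 + mp$p1 > 0.5)) {
    stop("no positive equilibrium: need p0 < 1/2 < p0 + p1")
  }
  Mstar <- mp$m * (mp$p1 / (0.5 - mp$p0) - 1)
  Sstar <- mp$d0 * Mstar / proliferation_rate(Mstar, mp)
  host_state(S = Sstar, M = Mstar)
}

#' Tumour growth derivative
#'
#' `dT/dt = mu0 T (1 + (mu0 T / mu1)^eta)^(-1/eta) - kappa C2 T`: exponential
#' growth for small volumes, linear for large, with kill proportional to the
#' tissue drug concentration.
#'
#' @param T_vol tumour volume, mm^3 (vectorized, >= 0).
#' @param C2 tissue drug concentration, micrograms/ml.
#' @param tp a [tumour_params()] object.
#' @return mm^3/day.
#' @export
tumour_derivative <- function(T_vol, C2 = 0, tp = tumour_params()) {
  if (any(T_vol < 0)) stop("tumour volume must be non-negative")
  g <- tp$mu0 * T_vol / tp$mu1
  tp$mu0 * T_vol * (1 + g^tp$eta)^(-1 / tp$eta) - tp$kappa * C2 * T_vol
}

#' Initial host state from lean mass and stem-cell ratio
#'
#' Inverts the lean-mass conversion so that
#' `lean_mass(initial_state(x, r)) == x` exactly:
#' `M = x / (density (1 + r))`, `S = r M`.
#'
#' @param lean_mass_g initial lean mass, g (> 0).
#' @param stem_ratio S/M ratio (> 0); about 0.0565 for a 6-week-old mouse.
#' @param mp a [muscle_params()] object.
#' @return [host_state()] vector.
#' @examples
#' initial_state(10, 0.0565)   # (267.4, 4732.6) mm^3
#' @export
initial_state <- function(lean_mass_g, stem_ratio, mp = muscle_params()) {
  if (lean_mass_g <= 0 || stem_ratio <= 0) stop("inputs must be positive")
  M <- lean_mass_g / (mp$density * (1 + stem_ratio))
  host_state(S = stem_ratio * M, M = M)
}

#' Conventional young- and aged-host initial conditions
#'
#' `young_state()` returns the 6-week-old mouse initial volumes used for
#' fitting, (S, M) = (267.5, 4732.5) mm^3 (10 g lean mass). The aging
#' analyses quote a slight variant (268.5, 4732.5) with stem ratio 0.0567;
#' select it with `variant = "aging"` (the source values differ by 1 mm^3 in
#' S and both are supported). `aged_state()` returns the 2-year-old values
#' (275, 5333) mm^3, the rounded healthy equilibrium, stem ratio 0.0516.
#'
#' @param variant `"fitting"` (default) or `"aging"`.
#' @return [host_state()] vector.
#' @export
young_state <- function(variant = c("fitting", "aging")) {
  variant <- match.arg(variant)
  if (variant == "fitting") host_state(267.5, 4732.5) else host_state(268.5, 4732.5)
}

#' @rdname young_state
#' @export
aged_state <- function() host_state(275, 5333)

#' Age-related decay of stem-cell viability
#'
#' Simulates aging by scaling the self-renewal perturbation probability `p1`
#' to a fraction of its nominal value (98% by default), which lowers the
#' homeostatic equilibrium and produces a gradual (about 2.5%) loss of lean
#' mass in the untreated aged host.
#'
#' @param mp a [muscle_params()] object.
#' @param scale fraction in `(0, 1]` applied to `p1`.
#' @return A [muscle_params()] object.
#' @export
aged_params <- function(mp = muscle_params(), scale = 0.98) {
  if (scale <= 0 || scale > 1) stop("scale must be in (0, 1]")
  muscle_params(p0 = mp$p0, p1 = scale * mp$p1, nu0 = mp$nu0, nu1 = mp$nu1,
                d0 = mp$d0, m = mp$m, density = mp$density)
}
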