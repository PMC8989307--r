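# Internal solver wrappers around the compiled right-hand sides.

.MAXRD <- 512L

# Integrate n lineage blocks sharing the exposure forcing, one block per Rd.
# forc: 2-column matrix (time, y). Returns list(times, S, M) where S and M are
# length(times) x length(Rd) matrices.
.solve_muscle <- function(times, forc, host0, mp, Rd,
                          rtol = 1e-8, atol = 1e-10) {
  nR <- length(Rd)
  stopifnot(nR >= 1)
  Sout <- matrix(NA_real_, length(times), nR)
  Mout <- matrix(NA_real_, length(times), nR)
  for (start in seq(1, nR, by = .MAXRD)) {
    idx <- start:min(start + .MAXRD - 1L, nR)
    n <- length(idx)
    parms <- c(mp$p0, mp$p1, mp$nu0, mp$nu1, mp$d0, mp$m, n,
               Rd[idx], rep(1, .MAXRD - n))
    y0 <- rep(c(host0[["S"]], host0[["M"]]), n)
    sol <- deSolve::lsoda(
      y = y0, times = times, func = "derivs_muscle", parms = parms,
      dllname = "chemocachexia", initfunc = "initmod_muscle",
      initforc = "initforc_muscle", forcings = forc,
      fcontrol = list(method = "linear", rule = 2),
      jactype = "bandint", bandup = 1L, banddown = 1L,
      rtol = rtol, atol = atol, maxsteps = 50000)
    if (attr(sol, "istate")[1] < 0) stop("muscle stage integration failed")
    Sout[, idx] <- sol[, 1 + 2 * seq_len(n) - 1, drop = FALSE]
    Mout[, idx] <- sol[, 1 + 2 * seq_len(n), drop = FALSE]
  }
  if (any(!is.finite(Sout)) || any(!is.finite(Mout))) {
    stop("muscle stage integration produced non-finite state")
  }
  list(times = times, S = Sout, M = Mout)
}

# Jointly integrate a nominal and a perturbed lineage block (shared step
# sequence; see src/tissue.c). forc0/forc1: 2-column (time, y) matrices.
# Returns list(times, S, M) with 2-column S and M (nominal, perturbed).
.solve_muscle_pair <- function(times, forc0, forc1, host0, mp0, Rd0,
                               mp1, Rd1, rtol = 1e-11, atol = 1e-13) {
  pset <- function(mp, Rd) c(mp$p0, mp$p1, mp$nu0, mp$nu1, mp$d0, mp$m, Rd)
  sol <- deSolve::lsoda(
    y = rep(c(host0[["S"]], host0[["M"]]), 2), times = times,
    func = "derivs_muscle_pair", parms = c(pset(mp0, Rd0), pset(mp1, Rd1)),
    dllname = "chemocachexia", initfunc = "initmod_muscle_pair",
    initforc = "initforc_muscle_pair", forcings = list(forc0, forc1),
    fcontrol = list(method = "linear", rule = 2),
    jactype = "bandint", bandup = 1L, banddown = 1L,
    rtol = rtol, atol = atol, maxsteps = 100000)
  if (attr(sol, "istate")[1] < 0) stop("paired muscle integration failed")
  list(times = times, S = sol[, c(2, 4)], M = sol[, c(3, 5)])
}

# Integrate the tumour equation driven by the C2 forcing (2-column matrix).
.solve_tumour <- function(times, forc, tp, rtol = 1e-8, atol = 1e-10) {
  parms <- c(tp$mu0, tp$mu1, tp$eta, tp$kappa)
  sol <- deSolve::lsoda(
    y = tp$T0, times = times, func = "derivs_tumour", parms = parms,
    dllname = "chemocachexia", initfunc = "initmod_tumour",
    initforc = "initforc_tumour", forcings = forc,
    fcontrol = list(method = "linear", rule = 2),
    rtol = rtol, atol = atol, maxsteps = 50000)
  if (attr(sol, "istate")[1] < 0) stop("tumour stage integration failed")
  sol[, 2]
}
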