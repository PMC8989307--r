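# Independent oracles and small shared fixtures, built in code.

# Healthy lineage right-hand side, written independently of the package
# internals, for use with deSolve's R interface as a convergence oracle.
healthy_rhs <- function(t, state, parms) {
  S <- state[1]; M <- state[2]
  fb <- 1 / (1 + M / parms$m)
  p <- parms$p0 + parms$p1 * fb
  nu <- parms$nu0 + parms$nu1 * fb
  list(c((2 * p - 1) * nu * S,
         2 * (1 - p) * nu * S - parms$d0 * M))
}

integrate_healthy <- function(state0, t_end, mp = muscle_params(),
                              rtol = 1e-12, atol = 1e-12, by = 1) {
  deSolve::lsoda(y = unname(state0), times = seq(0, t_end, by = by),
                 func = healthy_rhs, parms = unclass(mp),
                 rtol = rtol, atol = atol)
}

# Composite Simpson quadrature of a sampled curve (interpolated linearly onto
# an even refinement), as an independent check of the trapezoid AUC.
simpson_auc <- function(times, values, window, n = 20000) {
  if (n %% 2 == 1) n <- n + 1
  x <- seq(window[1], window[2], length.out = n + 1)
  y <- stats::approx(times, values, xout = x, rule = 2)$y
  h <- (window[2] - window[1]) / n
  h / 3 * (y[1] + y[n + 1] + 4 * sum(y[seq(2, n, 2)]) + 2 * sum(y[seq(3, n - 1, 2)]))
}

# Direct per-point window quadrature of the piecewise-linear interpolant of a
# gridded concentration series (zero history before t = 0).
window_quadrature <- function(times, C2, t, tau) {
  cum <- c(0, cumsum(diff(times) * (C2[-length(C2)] + C2[-1]) / 2))
  at <- function(s) {
    if (s <= 0) return(0)
    j <- findInterval(s, times)
    h <- s - times[j]
    cs <- C2[j] + (C2[j + 1] - C2[j]) * h / (times[j + 1] - times[j])
    cum[j] + h * (C2[j] + cs) / 2
  }
  vapply(t, function(ti) (at(ti) - at(ti - tau)) / tau, numeric(1))
}

# lean mass at a given day, linearly interpolated from a host trajectory
lean_at <- function(traj, day) {
  stats::approx(traj$time, traj$lean_mass, xout = day)$y
}

# memoised shared simulations (several test files reuse the same runs)
.cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

table2_schedules <- function() {
  specs <- list(c(0, 0, 24), c(6, 1, 28), c(6, 1, 29), c(5, 2, 34),
                c(5, 2, 35), c(4, 3, 42), c(4, 3, 43), c(3, 4, 56),
                c(3, 4, 57), c(3, 4, 58))
  lapply(specs, function(s) {
    if (s[1] == 0) schedule_daily(s[3]) else schedule_cycle(s[1], s[2], s[3])
  })
}

table2_run <- function() {
  cached("table2_run", run_suite(suite_table2()))
}
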