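mp <- muscle_params()

test_that("self-renewal and proliferation feedbacks take their worked values", {
  expect_equal(renewal_probability(mp$m, mp), 0.5455)
  expect_equal(renewal_probability(1e9, mp), mp$p0, tolerance = 1e-4)
  expect_equal(renewal_probability(5333.33, mp), 0.5, tolerance = 1e-6)
  expect_equal(proliferation_rate(0, mp), 5.678)
  expect_equal(proliferation_rate(1e9, mp), mp$nu0, tolerance = 1e-4)
  expect_equal(proliferation_rate(5333.33, mp), 0.9698, tolerance = 1e-4)
  expect_error(renewal_probability(-1, mp), "non-negative")
  # strict monotonicity and range
  Ms <- seq(0, 2e4, by = 100)
  expect_true(all(diff(renewal_probability(Ms, mp)) < 0))
  expect_true(all(diff(proliferation_rate(Ms, mp)) < 0))
  expect_true(all(renewal_probability(Ms, mp) > mp$p0))
  expect_true(all(proliferation_rate(Ms, mp) <= mp$nu0 + mp$nu1))
})

test_that("the cubic suppression factor is unclamped", {
  expect_equal(chemo_factor(0, 6.8), 1)
  expect_equal(chemo_factor(6.8, 6.8), 0)
  expect_equal(chemo_factor(13.6, 6.8), -7)
})

test_that("lineage derivatives reduce to the healthy field and vanish at equilibrium", {
  st <- host_state(200, 3000)
  d0 <- muscle_derivatives(st, y = 0, mp)
  p <- renewal_probability(3000, mp); nu <- proliferation_rate(3000, mp)
  expect_equal(unname(d0["dS"]), (2 * p - 1) * nu * 200)
  expect_equal(unname(d0["dM"]), 2 * (1 - p) * nu * 200 - mp$d0 * 3000)
  # exposure at the threshold nullifies proliferation entirely
  dR <- muscle_derivatives(st, y = 6.8, mp, chemo_effect(Rd = 6.8))
  expect_equal(unname(dR["dS"]), 0)
  expect_equal(unname(dR["dM"]), -mp$d0 * 3000)
  # the healthy equilibrium is a zero of the field
  expect_equal(unname(muscle_derivatives(healthy_equilibrium(mp), 0, mp)),
               c(0, 0), tolerance = 1e-10)
})

test_that("lean-mass conversion and worked initial conditions agree", {
  expect_equal(lean_mass(267.5, 4732.5), 10)
  expect_equal(lean_mass(0, 0), 0)
  expect_equal(lean_mass(275, 5333), 11.216)
  expect_equal(lean_mass(host_state(267.5, 4732.5)), 10)
})

test_that("the closed-form equilibrium matches its long-run ODE oracle", {
  eq <- healthy_equilibrium(mp)
  expect_equal(unname(eq), c(274.97, 5333.33), tolerance = 1e-4)
  aged <- healthy_equilibrium(aged_params(mp))
  expect_equal(unname(aged), c(263.55, 5206.67), tolerance = 1e-4)
  sol <- integrate_healthy(c(100, 1000), 500, mp)
  expect_equal(unname(tail(sol, 1)[, 2:3]), unname(eq), tolerance = 1e-4)
  expect_error(healthy_equilibrium(muscle_params(p0 = 0.3, p1 = 0.15)),
               "p0 \\+ p1")
})

test_that("healthy trajectories from positive states converge to equilibrium", {
  eq <- healthy_equilibrium(mp)
  for (s0 in list(c(10, 10), c(10, 1e4), c(1e4, 10), c(1e4, 1e4), c(300, 5000))) {
    sol <- integrate_healthy(s0, 1000, mp, by = 10)
    expect_true(all(sol[, 2:3] > 0), info = paste(s0, collapse = ","))
    expect_equal(unname(tail(sol, 1)[, 2:3]), unname(eq), tolerance = 1e-3,
                 info = paste(s0, collapse = ","))
  }
})

test_that("sustained exposure above the threshold forces muscle decline", {
  # any exposure above the threshold makes the suppression factor negative,
  # so replenishment stops entirely and the muscle declines monotonically
  # until it collapses to the numerical floor
  forc <- cbind(c(0, 200), c(7.0, 7.0))   # constant y > Rd = 6.8
  sol <- chemocachexia:::.solve_muscle(seq(0, 200, by = 1), forc,
                                       young_state(), mp, 6.8)
  M <- sol$M[, 1]
  alive <- which(M > 1)                   # above the floor
  expect_true(all(diff(M[alive]) < 0))
  expect_lt(max(alive), 100)              # collapse well inside the horizon
})

test_that("tumour growth interpolates between exponential and linear regimes", {
  tp <- tumour_params()
  expect_equal(tumour_derivative(0.1, 0, tp), tp$mu0 * 0.1, tolerance = 1e-6)
  expect_equal(tumour_derivative(1e5, 0, tp), tp$mu1, tolerance = 1e-3)
  expect_equal(tumour_derivative(10, 0, tp), 4.46, tolerance = 1e-6)
})

test_that("tumour curves are insensitive to the transition sharpness above 4", {
  sols <- lapply(c(4, 20, 100), function(eta) {
    tp <- tumour_params(eta = eta)
    deSolve::lsoda(y = tp$T0, times = seq(0, 56, by = 1),
                   func = function(t, y, p) list(tumour_derivative(y, 0, tp)),
                   parms = NULL, rtol = 1e-10, atol = 1e-10)[, 2]
  })
  # eta >= 20 curves are pointwise interchangeable; eta = 4 deviates by a few
  # percent around the exponential-to-linear transition (days ~7-20 for an
  # untreated 10 mm^3 tumour) and agrees with both limbs outside it
  expect_lt(max(abs(sols[[3]] / sols[[2]] - 1)), 0.02)
  t <- 0:56
  limb <- t <= 4 | t >= 25
  expect_lt(max(abs(sols[[1]][limb] / sols[[2]][limb] - 1)), 0.02)
  expect_lt(max(abs(sols[[1]] / sols[[2]] - 1)), 0.07)
})

test_that("initial-state construction inverts the lean-mass conversion", {
  st <- initial_state(10, 0.0565)
  expect_equal(unname(st), c(267.4, 4732.6), tolerance = 1e-3)
  expect_equal(unname(initial_state(11.216, 0.0516)), c(275.2, 5332.8),
               tolerance = 2e-4)
  for (x in c(5, 10, 11.2)) {
    for (r in c(0.03, 0.0565, 0.1)) {
      expect_equal(lean_mass(initial_state(x, r, mp)), x)
    }
  }
  expect_error(initial_state(-1, 0.05), "positive")
})

test_that("aging scales the renewal perturbation and shifts the equilibrium", {
  am <- aged_params(mp)
  expect_equal(am$p1, 0.13034)
  expect_equal(unclass(aged_params(mp, 1)), unclass(mp))
  drop <- 100 * (1 - lean_mass(healthy_equilibrium(am)) /
                   lean_mass(healthy_equilibrium(mp)))
  expect_equal(drop, 2.46, tolerance = 0.01)
})

test_that("host state conventions match the printed values", {
  expect_equal(unname(young_state()), c(267.5, 4732.5))
  expect_equal(unname(young_state("aging")), c(268.5, 4732.5))
  expect_equal(unname(aged_state()), c(275, 5333))
  expect_error(host_state(-1, 5), "non-negative")
})
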