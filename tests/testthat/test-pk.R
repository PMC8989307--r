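pk <- pk_params()

test_that("an empty schedule yields identically zero concentrations", {
  tr <- simulate_pk(pk, schedule(numeric(0), numeric(0)), t_end = 5)
  expect_true(all(tr$C1 == 0) && all(tr$C2 == 0))
})

test_that("a bolus jumps plasma concentration by 1000 d / V1", {
  tr <- simulate_pk(pk, schedule(0, 35, horizon = 1), t_end = 10)
  expect_equal(tr$C1[1], 35000 / 710, tolerance = 1e-12)
})

test_that("single-dose tissue exposure matches the mass-balance closed form", {
  d <- 35
  expect_equal(dose_tissue_auc(pk, d), 5.6317, tolerance = 1e-4)
  tr <- simulate_pk(pk, schedule(0, d, horizon = 1), t_end = 10)
  # exact running integral vs closed form (tail truncated at e^{-lambda t})
  expect_equal(tail(tr$cumI2, 1), dose_tissue_auc(pk, d), tolerance = 1e-6)
  # and against straightforward fine-grid quadrature
  fine <- simulate_pk(pk, schedule(0, d, horizon = 1), t_end = 10,
                      resolution = 2e-4)
  quad <- sum(diff(fine$times) * (fine$C2[-length(fine$C2)] + fine$C2[-1]) / 2)
  expect_equal(quad, dose_tissue_auc(pk, d), tolerance = 1e-4)
})

test_that("mass balance holds exactly for a multi-dose schedule", {
  sch <- schedule_cycle(5, 2, 35, 28)
  tr <- simulate_pk(pk, sch, t_end = 56)
  n <- length(tr$times)
  lhs <- pk$V1 * pk$k10 * tr$cumI1[n] + pk$V1 * tr$C1[n] + pk$V2 * tr$C2[n]
  expect_equal(lhs, 1000 * sum(sch$events$amount), tolerance = 1e-9)
})

test_that("the trajectory is linear and superposable in the doses", {
  sch <- schedule(c(0, 1.5, 4), c(20, 35, 10), horizon = 5)
  tr <- simulate_pk(pk, sch, t_end = 8)
  # linearity: alpha-scaled doses scale the whole solution
  tr2 <- simulate_pk(pk, schedule(c(0, 1.5, 4), c(20, 35, 10) * 2.5, horizon = 5),
                     t_end = 8)
  expect_equal(tr2$C1, 2.5 * tr$C1, tolerance = 1e-10)
  expect_equal(tr2$C2, 2.5 * tr$C2, tolerance = 1e-10)
  # superposition of time-shifted single-dose solutions
  sum1 <- Reduce(`+`, lapply(1:3, function(i) {
    s <- simulate_pk(pk, schedule(sch$events$time[i], sch$events$amount[i],
                                  horizon = 5), t_end = 8)
    s$C2
  }))
  expect_equal(sum1, tr$C2, tolerance = 1e-10)
  # exposure inherits the scaling
  y1 <- average_exposure(tr, 3)$y
  y2 <- average_exposure(tr2, 3)$y
  expect_equal(y2, 2.5 * y1, tolerance = 1e-10)
})

test_that("morphine adjustment scales the three rates only", {
  adj <- morphine_adjust(pk)
  expect_equal(adj$k10, 98.28)
  expect_equal(adj$k12, 3.653)
  expect_equal(adj$k21, 1.5015)
  expect_equal(adj$V1, pk$V1)
  expect_equal(adj$V2, pk$V2)
  expect_equal(unclass(morphine_adjust(pk, 0)), unclass(pk))
  expect_error(morphine_adjust(pk, 1), "reduction")
  # slower clearance raises the per-dose tissue exposure
  expect_gt(dose_tissue_auc(adj, 35), dose_tissue_auc(pk, 35))
})

test_that("moving-average exposure has the constant-history closed form", {
  t <- seq(0, 10, by = 0.01)
  const <- list(times = t, C2 = rep(2.5, length(t)))
  y <- average_exposure(const, tau = 4, method = "trapezoid")$y
  expect_equal(y, ifelse(t >= 4, 2.5, 2.5 * t / 4), tolerance = 1e-12)
  zero <- list(times = t, C2 = rep(0, length(t)))
  expect_true(all(average_exposure(zero, 4, method = "trapezoid")$y == 0))
  expect_error(average_exposure(const, -1), "tau")
})

test_that("exposure agrees with direct per-point window quadrature", {
  tr <- simulate_pk(pk, schedule_daily(35, 12), t_end = 12)
  fine <- simulate_pk(pk, schedule_daily(35, 12), t_end = 12,
                      resolution = 1e-5)
  probe <- c(0.5, 2, 5.5, 7, 9.25, 11.8)
  for (tau in c(5, 11)) {
    y <- average_exposure(tr, tau)
    impl <- stats::approx(y$times, y$y, xout = probe)$y
    oracle <- window_quadrature(fine$times, fine$C2, probe, tau)
    expect_equal(impl, oracle, tolerance = 1e-8, info = paste("tau", tau))
    # the trapezoid cumulative-difference path matches its own per-point form
    ytz <- average_exposure(tr, tau, method = "trapezoid")
    direct <- window_quadrature(tr$times, tr$C2, tr$times[c(100, 1500, 2000)], tau)
    expect_equal(ytz$y[c(100, 1500, 2000)], direct, tolerance = 1e-10)
  }
  # larger windows smooth and lag the exposure
  y5 <- average_exposure(tr, 5)$y
  y11 <- average_exposure(tr, 11)$y
  expect_gt(max(y5), max(y11))
})

test_that("the averaged exposure lags the tissue concentration", {
  tr <- simulate_pk(pk, schedule(0, 35, horizon = 1), t_end = 6)
  y <- average_exposure(tr, 2)
  expect_gte(y$times[which.max(y$y)], tr$times[which.max(tr$C2)])
})

test_that("pk trajectories round-trip through CSV (trapezoid fallback)", {
  tr <- simulate_pk(pk, schedule_daily(35, 3), t_end = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_pk_csv(tr, path)
  tr2 <- read_pk_csv(path)
  expect_equal(tr2$C2, tr$C2, tolerance = 1e-12)
  y2 <- average_exposure(tr2, 3)         # falls back to trapezoid
  y1 <- average_exposure(tr, 3, method = "trapezoid")
  expect_equal(y2$y, y1$y, tolerance = 1e-12)
})

test_that("schedules beyond the horizon and bad parameters are rejected", {
  expect_error(simulate_pk(pk, schedule_daily(24, 28), t_end = 20), "beyond")
  expect_error(pk_params(k10 = -1), "positive")
})
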