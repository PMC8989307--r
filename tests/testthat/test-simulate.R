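test_that("an untreated young host grows monotonically to its equilibrium mass", {
  sc <- scenario(schedule(numeric(0), numeric(0)), t_end = 200, out_step = 1)
  tr <- simulate_host(sc)
  # monotone through the growth phase; the approach overshoots the
  # equilibrium by well under 1% (peak near day 55) before settling
  expect_true(all(diff(tr$lean_mass[tr$time <= 50]) > 0))
  expect_lt(max(tr$lean_mass) / 11.2166, 1.01)
  expect_equal(tail(tr$lean_mass, 1), 11.217, tolerance = 1e-3)
  # stem ratio declines monotonically toward the equilibrium ratio
  expect_true(all(diff(tr$stem_ratio) < 1e-9))
  expect_equal(tail(tr$stem_ratio, 1), 274.97 / 5333.33, tolerance = 1e-3)
})

test_that("control runs equal zero-dose runs exactly", {
  sc <- scenario(schedule(numeric(0), numeric(0)), t_end = 30)
  a <- simulate_host(sc)
  b <- simulate_control(scenario(schedule_daily(24), t_end = 30))
  expect_identical(a$lean_mass, b$lean_mass)
  expect_identical(a$S, b$S)
})

test_that("the aged control declines toward its reduced equilibrium", {
  sc <- scenario(schedule_daily(24), aged = TRUE, t_end = 250, out_step = 1)
  tr <- simulate_control(sc)
  expect_lt(tail(tr$lean_mass, 1), tr$lean_mass[1])
  expect_equal(tail(tr$lean_mass, 1), 10.94, tolerance = 1e-3)
})

test_that("standard schedules separate tumour control: 5-day succeeds, daily fails", {
  tp <- tumour_params()
  t52 <- simulate_host(scenario(schedule_cycle(5, 2, 35), tp = tp))
  td <- simulate_host(scenario(schedule_daily(24), tp = tp))
  expect_lt(min(t52$tumour), 1)
  expect_gte(min(td$tumour), 1)
})

test_that("the coupled run reuses the standalone pharmacokinetics unchanged", {
  sc <- scenario(schedule_cycle(5, 2, 35), tp = tumour_params())
  tr <- simulate_host(sc)
  pk <- simulate_pk(pk_params(), sc$sch, t_end = sc$t_end,
                    resolution = sc$resolution)
  y <- average_exposure(pk, sc$ce$tau)
  ix <- match(tr$time, round(pk$times, 9))
  expect_identical(tr$C1, pk$C1[ix])
  expect_identical(tr$C2, pk$C2[ix])
  expect_identical(tr$y, y$y[ix])
})

test_that("with no dosing the coupled solver reproduces the healthy model", {
  sc <- scenario(schedule(numeric(0), numeric(0)), t_end = 56, out_step = 1,
                 rtol = 1e-11, atol = 1e-13)
  tr <- simulate_host(sc)
  oracle <- integrate_healthy(young_state(), 56, rtol = 1e-12, atol = 1e-12)
  expect_equal(tr$S, unname(oracle[, 2]), tolerance = 1e-9)
  expect_equal(tr$M, unname(oracle[, 3]), tolerance = 1e-9)
})

test_that("treatment disruption of the stem ratio is transient", {
  sc <- scenario(schedule_daily(35), t_end = 190, out_step = 1)
  tr <- simulate_host(sc)
  ct <- simulate_control(sc)
  i <- tr$time >= 187   # 160 days after the last dose (day 27)
  rel <- abs(tr$stem_ratio[i] - ct$stem_ratio[i]) / ct$stem_ratio[i]
  expect_lt(max(rel), 1e-3)
})

test_that("the lean-mass nadir is non-increasing in dose", {
  nadir <- vapply(c(14, 24, 35, 45, 60), function(d) {
    min(simulate_host(scenario(schedule_daily(d)))$lean_mass)
  }, numeric(1))
  # low doses never dip below the starting mass, so ties at the initial value
  # are expected; beyond that the nadir falls strictly with dose
  expect_true(all(diff(nadir) <= 1e-12))
  expect_lt(nadir[5], nadir[1])
})

test_that("the averaging window delays the onset of mass loss", {
  onset <- function(tau) {
    sc <- scenario(schedule_daily(35), ce = chemo_effect(Rd = 6.18, tau = tau))
    tr <- simulate_host(sc)
    ct <- simulate_control(sc)
    tr$time[which(tr$lean_mass < 0.98 * ct$lean_mass)[1]]
  }
  expect_gt(onset(11), onset(1))
})

test_that("halving the pharmacokinetic grid leaves day-28 lean mass unchanged", {
  l28 <- function(res) {
    tr <- simulate_host(scenario(schedule_daily(35), resolution = res))
    tr$lean_mass[tr$time == 28]
  }
  expect_lt(abs(l28(0.005) - l28(0.0025)), 1e-4)
})

test_that("morphine and aged flags reroute through the adjusted parameters", {
  scm <- scenario(schedule_daily(24), morphine = TRUE)
  trm <- simulate_host(scm)
  pkm <- simulate_pk(morphine_adjust(pk_params()), scm$sch, t_end = 56,
                     resolution = scm$resolution)
  ix <- match(trm$time, round(pkm$times, 9))
  expect_identical(trm$C2, pkm$C2[ix])
  # morphine deepens the loss at equal dose
  tr <- simulate_host(scenario(schedule_daily(24)))
  expect_lt(min(trm$lean_mass), min(tr$lean_mass))
  # aged default initial conditions
  sca <- scenario(schedule_daily(24), aged = TRUE)
  expect_equal(unname(sca$host0), c(275, 5333))
})

test_that("scenarios round-trip through YAML and trajectories through CSV", {
  sc <- scenario(schedule_cycle(5, 2, 35), tp = tumour_params(),
                 morphine = TRUE, t_end = 40)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scenario_yaml(sc, path)
  sc2 <- read_scenario_yaml(path)
  expect_equal(sc2$sch$events, sc$sch$events)
  expect_equal(unclass(sc2$pk), unclass(sc$pk))
  expect_equal(unclass(sc2$tp), unclass(sc$tp))
  expect_true(sc2$morphine)
  tr <- simulate_host(scenario(schedule_daily(24, 3), t_end = 4))
  csv <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(tr, csv)
  back <- utils::read.csv(csv)
  expect_equal(back$lean_mass, tr$lean_mass, tolerance = 1e-10)
})

test_that("invalid scenarios are rejected", {
  expect_error(scenario(schedule_daily(24, 28), t_end = 20), "last dose")
  expect_error(scenario(schedule_daily(24), out_step = 0.007), "multiple")
})
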