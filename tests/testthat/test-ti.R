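test_that("trapezoidal integration is exact for linear profiles", {
  lam <- seq(0, 1, length.out = 11)
  expect_equal(ti_integrate(lam, rep(5, 11)), 5)
  expect_equal(ti_integrate(lam, 10 * lam), 5)
  ## quadratic profile: trapezoid error has the known sign and size
  exact <- 1 / 3
  est <- ti_integrate(lam, lam^2)
  expect_equal(est, exact, tolerance = 0.01)
  expect_gt(est, exact) # convex integrand is overestimated
  expect_error(ti_integrate(c(0, 0.5, 0.5, 1), rep(1, 4)),
               class = "aedskit_parameter_error")
  expect_error(ti_integrate(c(0, 1), 1), class = "aedskit_size_error")
})

test_that("lambda protocols are validated", {
  p <- lambda_protocol(n_windows = 5)
  expect_equal(p$lambdas, seq(0, 1, 0.25))
  expect_error(lambda_protocol(n_windows = 1))
  expect_error(lambda_protocol(direction = "sideways"))
})

test_that("offset schedules reproduce the searched endpoint offsets", {
  sch <- build_offset_schedule(c(coupled = 0, dummy = 12.9),
                               c(coupled = 0, dummy = 1.4))
  expect_equal(offset_at(sch[[2]], 0), 12.9)
  expect_equal(offset_at(sch[[2]], 1), 1.4)
  expect_equal(offset_at(sch[[2]], 0.5), (12.9 + 1.4) / 2)
  ## name matching guards against state-order mixups
  sch2 <- build_offset_schedule(c(a = 1, b = 2), c(b = 20, a = 10))
  expect_equal(offset_at(sch2[[1]], 1), 10)
})

test_that("per-frame dH/dlambda is the lambda-derivative of the Hamiltonian", {
  ## including the offset-schedule compensation and the boost slope
  p <- make_pocket_probe_system(15, 2)
  ref <- toy_reference(p$system,
                       offsets = list(offset_schedule(0, 0),
                                      offset_schedule(-11, 12.9)),
                       accel = accel_params(-14, -2))
  RT <- ref$RT
  total_e <- function(x, lam) {
    phi <- exp(-x^2 / (2 * 0.12^2))
    g <- (1 - lam) * 15 + lam * 2
    H <- c(-g * phi, 0)
    off <- c(0, -11 * lam + 12.9)
    er <- reference_energy(H, off, RT)
    aeds_boost(er, ref$accel)$energy + 0.5 * 200 * x^2
  }
  h <- 1e-6
  for (x in c(-0.3, 0.05, 0.2)) {
    for (lam in c(0.1, 0.5, 0.9)) {
      fd <- (total_e(x, lam + h) - total_e(x, lam - h)) / (2 * h)
      expect_equal(dhdl_frame(c(x, 0), lam, NULL, ref), fd, tolerance = 1e-5)
    }
  }
})

test_that("plain TI over a pure energy shift is exact in expectation", {
  ## single state whose energy constant morphs 0 -> 6: dH/dlambda == 6
  states <- tibble::tibble(label = "s", role = "physical", k = 500, x0 = 0,
                           c0 = 0, c1 = 6, g0 = 0, g1 = 0)
  sys <- toy_system(states)
  ti <- run_ti_aeds(sys, toy_reference(sys),
                    lambda_protocol(n_windows = 5, n_steps = 2000,
                                    n_equil = 500, direction = "both"),
                    seed = 31)
  expect_equal(ti$dg, 6, tolerance = 1e-9)
  expect_equal(ti$dg_backward, 6, tolerance = 1e-9)
  expect_equal(ti$hysteresis, 0, tolerance = 1e-9)
  expect_equal(nrow(ti$table), 5)
})

test_that("forward and backward sweeps report hysteresis", {
  pair <- make_displaced_harmonic_pair(400, 0.2, 2)
  sys <- pair$system
  ti <- run_ti_aeds(sys, toy_reference(sys, offsets = list(0, 2)),
                    lambda_protocol(n_windows = 7, n_steps = 3000,
                                    n_equil = 500, direction = "both"),
                    seed = 32)
  expect_true(is.finite(ti$hysteresis))
  expect_equal(ti$hysteresis, abs(ti$dg - ti$dg_backward))
  expect_s3_class(ti$backward_table, "tbl_df")
})

test_that("reweighting a single-state run onto itself changes nothing", {
  states <- tibble::tibble(label = "s", role = "physical", k = 500, x0 = 0,
                           c0 = 0, c1 = 6, g0 = 0, g1 = 0)
  sys <- toy_system(states)
  ti <- run_ti_aeds(sys, toy_reference(sys),
                    lambda_protocol(n_windows = 3, n_steps = 2000,
                                    n_equil = 200, direction = "forward"),
                    seed = 33)
  rw <- reweighted_profile(ti, "s")
  expect_equal(rw$table$dhdl_mean, ti$table$dhdl_mean, tolerance = 1e-9)
  expect_equal(rw$table$ess, vapply(ti$series, nrow, numeric(1)))
  expect_equal(rw$dg, ti$dg, tolerance = 1e-9)
})

test_that("reweighting withholds the estimate when weights degenerate", {
  ## dummy state without offsets is never sampled in a deep pocket
  p <- make_pocket_probe_system(40, 40)
  ti <- run_ti_aeds(p$system, p$reference,
                    lambda_protocol(n_windows = 3, n_steps = 2000,
                                    n_equil = 200, direction = "forward"),
                    seed = 34)
  rw <- reweighted_profile(ti, "dummy", min_ess = 20)
  expect_true(any(rw$table$degenerate))
  expect_true(is.na(rw$dg))
})

test_that("endpoint legs carry both states at both endpoints", {
  p <- make_pocket_probe_system(15, 2, offsets = list(0, 12),
                                accel = accel_params(-14, -2))
  cfg <- simulation_config(n_steps = 2e4, seed = 35)
  ts0 <- run_sampler(p$system, p$reference, cfg, lambda = 0)
  ts1 <- run_sampler(p$system, p$reference, cfg, lambda = 1)
  legs <- endpoint_legs(ts0, ts1)
  expect_equal(nrow(legs), 4)
  expect_setequal(legs$state, c("coupled", "dummy"))
  expect_setequal(legs$lambda, c(0, 1))
  expect_true(all(is.finite(legs$dg)))
})
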