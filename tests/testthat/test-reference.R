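test_that("reference energy matches the analytic two-state envelope", {
  RT <- RT300
  expect_equal(reference_energy(c(10, 10), c(0, 0), RT), 10 - RT * log(2))
  ## offsets shift the effective energies
  expect_equal(reference_energy(c(10, 14), c(0, 4), RT), 10 - RT * log(2))
})

test_that("reference energy is bounded by the lowest effective state", {
  RT <- RT300
  for (i in 1:20) {
    H <- runif(4, -50, 50)
    off <- runif(4, -10, 10)
    er <- reference_energy(H, off, RT)
    expect_lte(er, min(H - off) + 1e-12)
    expect_gte(er, min(H - off) - RT * log(4) - 1e-12)
  }
})

test_that("reference energy is overflow-safe for extreme energies", {
  RT <- RT300
  expect_equal(reference_energy(c(1e6, 0), c(0, 0), RT), -RT * log(1 + exp(-1e6 / RT)))
  expect_true(is.finite(reference_energy(c(-1e6, 1e6), c(0, 0), RT)))
})

test_that("state weights are a proper distribution and gauge-invariant", {
  RT <- RT300
  H <- c(3, 3, 8)
  w <- state_weights(H, c(0, 0, 0), RT)
  expect_equal(sum(w), 1)
  expect_equal(w[1], w[2])
  ## a uniform shift of all offsets changes nothing
  expect_equal(state_weights(H, c(5, 5, 5), RT), w)
  ## the lowest effective state dominates when well separated
  expect_gt(state_weights(c(0, 50), c(0, 0), RT)[1], 0.999)
})

test_that("the boost is identity below E_min and flat above E_max", {
  acc <- accel_params(0, 100)
  below <- aeds_boost(c(-20, -1, 0), acc)
  expect_equal(below$energy, c(-20, -1, 0))
  expect_equal(below$slope, c(1, 1, 1))
  above <- aeds_boost(c(100, 150, 1e4), acc)
  expect_equal(above$energy, rep(50, 3))
  expect_equal(above$slope, rep(0, 3))
  ## interior midpoint of the published example
  mid <- aeds_boost(100, accel_params(0, 200))
  expect_equal(mid$energy, 100 - 100^2 / 400)
  expect_equal(mid$slope, 0.5)
})

test_that("the boost is continuous and once-differentiable at the joins", {
  acc <- accel_params(5, 35)
  h <- 1e-6
  for (e0 in c(5, 35)) {
    lo <- aeds_boost(e0 - h, acc)
    hi <- aeds_boost(e0 + h, acc)
    expect_lt(abs(lo$energy - hi$energy), 1e-5)
    expect_lt(abs(lo$slope - hi$slope), 1e-4)
  }
  ## slope equals the finite-difference derivative in the interior
  e <- seq(6, 34, length.out = 11)
  fd <- (aeds_boost(e + h, acc)$energy - aeds_boost(e - h, acc)$energy) / (2 * h)
  expect_equal(aeds_boost(e, acc)$slope, fd, tolerance = 1e-6)
})

test_that("the boost slope lies in [0, 1] and the map is non-decreasing", {
  acc <- accel_params(-12.3, 41.7)
  e <- seq(-60, 100, length.out = 400)
  b <- aeds_boost(e, acc)
  expect_true(all(b$slope >= 0 & b$slope <= 1))
  expect_true(all(diff(b$energy) >= -1e-12))
})

test_that("degenerate and absent acceleration are the identity map", {
  e <- c(-5, 0, 17.2)
  deg <- aeds_boost(e, accel_params(10, 10))
  expect_equal(deg$energy, e)
  expect_equal(deg$slope, rep(1, 3))
  none <- aeds_boost(e, NULL)
  expect_equal(none$energy, e)
})

test_that("acceleration parameters reject an inverted range", {
  expect_error(accel_params(10, 5), class = "aedskit_parameter_error")
})

test_that("offset schedules interpolate linearly and numbers are constants", {
  sch <- offset_schedule(S = -60, b = 35)
  expect_equal(offset_at(sch, 0), 35)
  expect_equal(offset_at(sch, 1), -25)
  expect_equal(offset_at(sch, 0.5), 5)
  expect_equal(offset_at(7.5, 0.3), 7.5)
})

test_that("reference definitions validate labels and offsets", {
  s <- end_state("a", function(x, lambda) list(energy = 0, gradient = 0, dhdl = 0))
  s2 <- end_state("a", function(x, lambda) list(energy = 1, gradient = 0, dhdl = 0))
  expect_error(reference_definition(list(s, s2)),
               class = "aedskit_parameter_error")
  ref <- reference_definition(list(s), offsets = list(3))
  expect_equal(ref$offsets[[1]]$b, 3)
  expect_error(reference_definition(list(s), offsets = list(1, 2)),
               class = "aedskit_parameter_error")
})

test_that("the reference force matches the numerical gradient of E_R*", {
  p <- make_pocket_probe_system(15, 2, accel = accel_params(-14, -2))
  ref <- p$reference
  RT <- ref$RT
  er_star <- function(x, lam) {
    phi <- exp(-x^2 / (2 * 0.12^2))
    g <- (1 - lam) * 15 + lam * 2
    H <- c(-g * phi, 0)
    aeds_boost(reference_energy(H, c(0, 0), RT), ref$accel)$energy
  }
  h <- 1e-6
  for (x in c(-0.25, 0.03, 0.4)) {
    for (lam in c(0, 0.4, 1)) {
      fd <- (er_star(x + h, lam) - er_star(x - h, lam)) / (2 * h)
      f <- reference_force(c(x, 0), ref, lambda = lam)
      expect_equal(f[1], fd, tolerance = 1e-5)
    }
  }
})

test_that("combinatorial references enumerate coupled/dummy assignments", {
  base <- list(probed_terms = list(
    function(x, lambda) list(energy = 0.5 * x[1]^2, gradient = c(x[1], 0), dhdl = 0),
    function(x, lambda) list(energy = 0.5 * (x[1] - 1)^2, gradient = c(x[1] - 1, 0), dhdl = 0)))
  ref <- combinatorial_reference(2, base)
  expect_length(ref$end_states, 4)
  expect_equal(ref$labels, c("cc", "dc", "cd", "dd"))
  expect_equal(ref$end_states[[1]]$role, "physical")
  expect_equal(ref$end_states[[4]]$role, "dummy")
  expect_equal(ref$end_states[[2]]$role, "composite")
  ## the all-dummy state carries no probe energy
  expect_equal(ref$end_states[[4]]$energy(c(1, 0), 0)$energy, 0)
  ## the all-coupled state sums both terms
  expect_equal(ref$end_states[[1]]$energy(c(1, 0), 0)$energy, 0.5)
  expect_error(combinatorial_reference(5, base),
               class = "aedskit_parameter_error")
})
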