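make_test_series <- function(n = 2000, seed = 1, g = 15, off = list(0, 12)) {
  p <- make_pocket_probe_system(g, 2, offsets = off,
                                accel = accel_params(-14, -2))
  run_sampler(p$system, p$reference,
              simulation_config(n_steps = n * 10L, seed = seed))
}

test_that("occupancy fractions form a distribution and track the weights", {
  ts <- make_test_series()
  occ <- occupancy_fractions(ts)
  expect_s3_class(occ, "aeds_occupancy")
  expect_equal(sum(occ$fraction), 1, tolerance = 1e-12)
  expect_equal(occ$state, c("coupled", "dummy"))
  ## the running series converges to the reported fractions
  running <- attr(occ, "running")
  expect_equal(unname(unlist(running[nrow(running), ])),
               occ$fraction, tolerance = 1e-12)
  ## the argmin method is a coarser estimator but lands in the same ballpark
  occ_a <- occupancy_fractions(ts, method = "argmin")
  expect_equal(sum(occ_a$fraction), 1, tolerance = 1e-12)
  expect_lt(max(abs(occ_a$fraction - occ$fraction)), 0.25)
})

test_that("occupancy matches the quadrature oracle of the fixture", {
  p <- make_pocket_probe_system(15, 2, offsets = list(0, 12),
                                accel = accel_params(-14, -2))
  ts <- run_sampler(p$system, p$reference,
                    simulation_config(n_steps = 2e5, seed = 8))
  occ <- occupancy_fractions(ts)
  exact <- toy_occupancy_quadrature(p$reference, 0)
  expect_equal(occ$fraction[1], exact, tolerance = 0.05)
})

test_that("state lifetimes censor the first and last dwell", {
  lt <- state_lifetimes(c(1, 1, 2, 2, 2, 1, 1), frame_dt = 0.5, n_states = 2)
  expect_equal(lt$n_dwells, c(0L, 1L))
  expect_true(is.na(lt$mean_lifetime_ps[1]))
  expect_equal(lt$mean_lifetime_ps[2], 3 * 0.5)
  ## a single uninterrupted run has no completed dwell at all
  lt2 <- state_lifetimes(rep(1L, 10), n_states = 1)
  expect_equal(lt2$n_dwells, 0L)
})

test_that("one-step perturbation recovers the quadrature free-energy leg", {
  p <- make_pocket_probe_system(15, 2, offsets = list(0, 12),
                                accel = accel_params(-14, -2))
  ts <- run_sampler(p$system, p$reference,
                    simulation_config(n_steps = 2e5, seed = 12))
  o <- osp_free_energy(ts, "coupled")
  exact <- toy_state_free_energy(p$reference, 0, state = "coupled") -
    toy_state_free_energy(p$reference, 0, state = NULL)
  expect_true(o$reliable)
  expect_equal(o$dg, exact, tolerance = 0.15)
  expect_true(is.finite(o$err))
})

test_that("one-step perturbation flags a never-sampled state unreliable", {
  ## without offsets the deep attraction leaves the dummy state unvisited
  p <- make_pocket_probe_system(40, 40)
  ts <- run_sampler(p$system, p$reference,
                    simulation_config(n_steps = 2e4, seed = 13))
  o <- osp_free_energy(ts, "dummy")
  expect_false(o$reliable)
  expect_lt(o$fraction, 0.01)
})

test_that("reweighting to the same ensemble is the plain average", {
  x <- rnorm(500)
  v <- runif(500)
  rw <- reweight_expectation(x, v, v, RT300)
  expect_equal(rw$mean, mean(x))
  expect_equal(rw$ess, 500)
})

test_that("reweighting reports weight degeneracy", {
  ## one frame dominates: effective sample size collapses towards 1
  v_y <- c(0, rep(1e3, 99))
  rw <- reweight_expectation(rnorm(100), v_y, rep(0, 100), RT300)
  expect_lt(rw$ess, 1.5)
  ## non-overlapping ensembles abort
  expect_error(reweight_expectation(1:3, rep(Inf, 3), rep(0, 3), RT300),
               class = "aedskit_degeneracy_error")
  expect_error(reweight_expectation(1:3, 1:2, 1:3, RT300),
               class = "aedskit_size_error")
})

test_that("block errors shrink like one over the square root of n", {
  set.seed(99)
  e1 <- block_error(rnorm(2000))
  e2 <- block_error(rnorm(32000))
  expect_lt(e2, e1) # 16x more data must not be noisier
  expect_equal(block_error(rep(3.2, 100)), 0)
  expect_error(block_error(rnorm(5)), class = "aedskit_size_error")
})
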