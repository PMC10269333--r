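test_that("visited-state assignment picks the lowest effective energy", {
  expect_equal(assign_visited_state(c(5, 3), c(0, 0)), 2L)
  ## offsets can flip the assignment
  expect_equal(assign_visited_state(c(5, 3), c(4, 0)), 1L)
  ## ties break to the lowest index
  expect_equal(assign_visited_state(c(3, 3), c(0, 0)), 1L)
  H <- rbind(c(1, 2), c(4, 0), c(2, 2))
  expect_equal(assign_visited_state(H, c(0, 0)), c(1L, 2L, 1L))
  expect_error(assign_visited_state(c(1, 2, 3), c(0, 0)),
               class = "aedskit_size_error")
})

test_that("the memory window grows linearly from 500 to 500,000 steps", {
  expect_equal(memory_length(0, 1e6), 500)
  expect_equal(memory_length(1e6, 1e6), 500000)
  expect_equal(memory_length(5e5, 1e6), 250250)
  expect_error(memory_length(-1, 100), class = "aedskit_parameter_error")
  expect_error(memory_length(101, 100), class = "aedskit_parameter_error")
})

test_that("offset updates recover a constant energy gap and fix the gauge", {
  RT <- RT300
  p <- make_pocket_probe_system(15, 2, offsets = list(0, 12),
                                accel = accel_params(-14, -2))
  ts <- run_sampler(p$system, p$reference,
                    simulation_config(n_steps = 2e4, seed = 3))
  off <- update_offsets(ts)
  expect_equal(min(off), 0)
  expect_named(off, c("coupled", "dummy"))
  ## on a synthetic series with exactly constant H_i - E_R* the exponential
  ## average is exact: here states differ by a configuration-independent shift
  pair <- make_displaced_harmonic_pair(500, 0, 6) # same well, pure energy shift
  ref <- toy_reference(pair$system)
  ts2 <- run_sampler(pair$system, ref, simulation_config(n_steps = 5000, seed = 4))
  off2 <- update_offsets(ts2)
  expect_equal(unname(off2[2]), 6, tolerance = 1e-9)
})

test_that("acceleration estimates come from crossings and basin widths", {
  visited <- c(1, 1, 1, 2, 2, 2, 1, 1, 1, 2, 2, 2)
  e_r <- c(0, 1, 0, 5, 1, 0, 6, 1, 0, 4, 1, 0)
  acc <- update_acceleration(visited, e_r, min_frames_per_state = 2)
  ## E_max is the highest reference energy at a state-change frame (6)
  expect_equal(acc$e_max, 6)
  ## E_min is the largest per-state mean + 1 sd
  s1 <- e_r[visited == 1]; s2 <- e_r[visited == 2]
  expect_equal(acc$e_min, max(mean(s1) + sd(s1), mean(s2) + sd(s2)))
  expect_lte(acc$e_min, acc$e_max)
})

test_that("acceleration estimation clamps and warns on an inverted range", {
  visited <- c(1, 1, 1, 1, 1, 1, 2, 1, 1, 1)
  e_r <- c(10, -10, 10, -10, 10, -10, -30, 10, -10, 10)
  expect_warning(acc <- update_acceleration(visited, e_r),
                 class = "aedskit_accel_clamp_warning")
  expect_equal(acc$e_min, acc$e_max)
})

test_that("acceleration estimation refuses a series with no crossing", {
  expect_error(update_acceleration(rep(1L, 50), rnorm(50)),
               class = "aedskit_no_crossing_error")
})

test_that("a short search run yields named offsets and a convergence trail", {
  pair <- make_displaced_harmonic_pair(400, 0.3, 3)
  res <- suppressWarnings(search_run(
    pair$system, toy_reference(pair$system),
    simulation_config(n_steps = 3e4, seed = 21, save_interval = 10)))
  expect_named(res$offsets, c("state0", "state1"))
  expect_equal(min(res$offsets), 0)
  expect_s3_class(res$accel, "aeds_accel")
  expect_true(all(c("step", "n_mem", "e_min", "e_max",
                    "offset_state0", "offset_state1")
                  %in% names(res$diagnostics)))
  expect_equal(max(res$diagnostics$step), 3e4)
  ## the recorded series is thinned to the configured save interval
  expect_equal(nrow(res$series), 3e3)
  ## determinism of the full search loop
  res2 <- suppressWarnings(search_run(
    pair$system, toy_reference(pair$system),
    simulation_config(n_steps = 3e4, seed = 21, save_interval = 10)))
  expect_identical(res$offsets, res2$offsets)
  expect_identical(res$accel$e_max, res2$accel$e_max)
})
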