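test_that("the restraint-release correction matches its closed form", {
  RT <- RT300
  K <- 1500; v_site <- 3.0777e-2
  expect_equal(restraint_release_correction(K),
               -RT * log((2 * pi * RT / K)^1.5 / v_site))
  ## stiffer restraints cost more to release
  ks <- c(100, 500, 1500, 5000)
  vals <- vapply(ks, restraint_release_correction, numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_error(restraint_release_correction(-5),
               class = "aedskit_parameter_error")
})

test_that("the restraint correction agrees with the radial integral", {
  RT <- RT300
  for (K in c(200, 1500, 4000)) {
    vol <- stats::integrate(function(r) 4 * pi * r^2 * exp(-K * r^2 / (2 * RT)),
                            0, Inf, rel.tol = 1e-12)$value
    oracle <- -RT * log(vol / 3.0777e-2)
    expect_equal(restraint_release_correction(K), oracle, tolerance = 1e-9)
  }
})

test_that("the bulk transfer term scales with the number of waters", {
  expect_equal(bulk_transfer_term(0), 0)
  expect_equal(bulk_transfer_term(2), 53.6)
  expect_equal(bulk_transfer_term(1, dg_hyd_water = 25), 25)
  expect_error(bulk_transfer_term(-1))
})

test_that("relative binding assembly itemizes every term", {
  ddg <- assemble_relative_binding(
    dg_bound = list(dg = 60.2, err = 1.4),
    dg_free = list(dg = 30.0, err = 0.5),
    corrections = c(restraint_release = 8.38, bulk_transfer = 26.8))
  expect_equal(ddg$ddg, 60.2 - 30.0 + 8.38 + 26.8)
  expect_equal(ddg$err, sqrt(1.4^2 + 0.5^2))
  expect_equal(nrow(ddg$terms), 4)
  expect_true("restraint_release" %in% ddg$terms$term)
  ## bare numbers carry zero error
  ddg2 <- assemble_relative_binding(10, 4)
  expect_equal(ddg2$ddg, 6)
  expect_equal(ddg2$err, 0)
  expect_error(assemble_relative_binding(NULL, 4),
               class = "aedskit_state_error")
})

test_that("thermodynamically consistent graphs close at zero", {
  ## edges built from node potentials are exact by construction
  pot <- c(AW = 0, AR = -3.2, AD = 5.1, BW = 31.0, BR = 28.4, BD = 33.3)
  edges <- tibble::tibble(
    from = c("AR", "AW", "AD", "AW", "AR", "BW", "BR"),
    to   = c("BR", "BW", "BD", "AR", "AD", "BR", "BD"))
  edges$dg <- pot[edges$to] - pot[edges$from]
  cl <- cycle_closure(cycle_report(edges))
  expect_equal(nrow(cl), 2) # 7 edges, 6 nodes -> 2 independent cycles
  expect_lt(max(abs(cl$closure)), 1e-12)
})

test_that("a perturbed edge shows up as a nonzero closure", {
  pot <- c(A = 0, B = 2, C = 5)
  edges <- tibble::tibble(from = c("A", "B", "A"), to = c("B", "C", "C"))
  edges$dg <- pot[edges$to] - pot[edges$from]
  edges$dg[3] <- edges$dg[3] + 1.7
  cl <- cycle_closure(cycle_report(edges))
  expect_equal(max(abs(cl$closure)), 1.7, tolerance = 1e-12)
})

test_that("closure errors combine edge errors in quadrature", {
  edges <- tibble::tibble(from = c("A", "B", "A"), to = c("B", "C", "C"),
                          dg = c(1, 1, 2), err = c(0.3, 0.4, 0.5))
  cl <- cycle_closure(cycle_report(edges))
  expect_equal(cl$err, sqrt(0.3^2 + 0.4^2 + 0.5^2))
})

test_that("unreliable edges are excluded unless requested", {
  edges <- tibble::tibble(from = c("A", "B", "A", "A"),
                          to = c("B", "C", "C", "C"),
                          dg = c(1, 1, 2, 9),
                          reliable = c(TRUE, TRUE, TRUE, FALSE))
  cl <- cycle_closure(cycle_report(edges))
  expect_equal(nrow(cl), 1)
  cl_all <- cycle_closure(cycle_report(edges), include_unreliable = TRUE)
  expect_equal(nrow(cl_all), 2)
})

test_that("degenerate graphs are rejected with clear errors", {
  expect_error(cycle_closure(cycle_report(
    tibble::tibble(from = c("A", "C"), to = c("B", "D"), dg = c(1, 2)))),
    class = "aedskit_graph_error")
  expect_error(cycle_closure(cycle_report(
    tibble::tibble(from = "A", to = "B", dg = 1))),
    class = "aedskit_graph_error")
  expect_error(cycle_closure(cycle_report(
    tibble::tibble(from = "A", to = "B", dg = 1, reliable = FALSE))),
    class = "aedskit_graph_error")
})
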