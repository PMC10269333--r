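#' One-dimensional toy potential
#'
#' @param energy Function `U(x)` in kJ/mol (vectorized over x).
#' @param gradient Function `dU/dx(x)` in kJ/mol/nm, or `NULL`.
#' @param x_lo,x_hi Integration domain, nm.
#' @return An `aeds_potential_1d` object.
#' @export
toy_potential_1d <- function(energy, gradient = NULL, x_lo = -2, x_hi = 2) {
  stopifnot(is.function(energy), x_lo < x_hi)
  structure(list(energy = energy, gradient = gradient,
                 x_lo = x_lo, x_hi = x_hi),
            class = "aeds_potential_1d")
}

#' Configurational free energy by composite quadrature
#'
#' Brute-force oracle: `F = -RT log( integral exp(-U(x)/RT) dx )` over the
#' potential's domain, by composite Simpson quadrature. Fixtures publish their
#' free energies through this so that downstream estimators can be tested
#' against them.
#'
#' @param potential An [toy_potential_1d()], or a plain vectorized function
#'   (then `x_lo`/`x_hi` must be supplied).
#' @param RT Thermal energy, kJ/mol.
#' @param n Number of grid points (>= 1000; forced odd for Simpson).
#' @param x_lo,x_hi Domain override.
#' @return Free energy in kJ/mol.
#' @export
quadrature_free_energy <- function(potential, RT, n = 4097,
                                   x_lo = NULL, x_hi = NULL) {
  if (inherits(potential, "aeds_potential_1d")) {
    u <- potential$energy
    x_lo <- x_lo %||% potential$x_lo
    x_hi <- x_hi %||% potential$x_hi
  } else {
    u <- potential
    if (is.null(x_lo) || is.null(x_hi)) {
      abort("Supply `x_lo` and `x_hi` for a bare function.",
            class = "aedskit_parameter_error")
    }
  }
  stopifnot(n >= 1000, RT > 0)
  if (n %% 2L == 0L) n <- n + 1L
  x <- seq(x_lo, x_hi, length.out = n)
  h <- x[2L] - x[1L]
  lw <- -u(x) / RT
  if (!all(is.finite(lw) | lw == -Inf)) {
    abort("Potential is not integrable on the domain (non-finite weights).",
          class = "aedskit_domain_error")
  }
  coef <- c(1, rep(c(4, 2), length.out = n - 2L), 1)
  m <- max(lw)
  z <- sum(coef * exp(lw - m)) * h / 3
  -RT * (m + log(z))
}

#' Displaced harmonic pair with exact free-energy difference
#'
#' Two harmonic end states `U_0 = k/2 x^2` and
#' `U_1 = k2/2 (x - d)^2 + delta_e`. For equal curvature the exact free-energy
#' difference is `delta_e`; for unequal curvature it is
#' `delta_e + (RT/2) log(k2 / k)`.
#'
#' @param k Force constant of state 0, kJ/mol/nm^2 (> 0).
#' @param d Displacement of state 1, nm.
#' @param delta_e Energy offset of state 1, kJ/mol.
#' @param k2 Force constant of state 1 (defaults to `k`).
#' @return A list with the two [end_state()]s, the matching
#'   [toy_system()] for sampling, and `exact_df(RT)` giving the analytic
#'   free-energy difference F_1 - F_0.
#' @export
make_displaced_harmonic_pair <- function(k, d, delta_e, k2 = k) {
  if (k <= 0 || k2 <= 0) {
    abort("Force constants must be positive.", class = "aedskit_parameter_error")
  }
  s0 <- end_state("state0", function(x, lambda) {
    list(energy = 0.5 * k * x[1]^2, gradient = k * x[1], dhdl = 0)
  })
  s1 <- end_state("state1", function(x, lambda) {
    list(energy = 0.5 * k2 * (x[1] - d)^2 + delta_e,
         gradient = k2 * (x[1] - d), dhdl = 0)
  })
  sys <- toy_system(
    states = tibble::tibble(
      label = c("state0", "state1"), role = "physical",
      k = c(k, k2), x0 = c(0, d), c0 = c(0, delta_e), c1 = c(0, delta_e),
      g0 = 0, g1 = 0),
    well_width = 0.1, domain = c(min(0, d) - 1, max(0, d) + 1))
  list(states = list(s0, s1), system = sys,
       exact_df = function(RT) delta_e + RT / 2 * log(k2 / k))
}

#' Parametric toy system for the compiled sampler
#'
#' A toy system has one probed coordinate `x` (the switchable molecule), an
#' optional ligand coordinate `y`, an optional harmonic restraint on `x`, and
#' a set of parametric end states. Each end state contributes
#' `0.5 k (x - x0)^2 + c(lambda) - g(lambda) exp(-x^2 / (2 w^2))` with
#' `c(lambda)` and `g(lambda)` interpolated linearly between their endpoint
#' values. The restraint `0.5 K(lambda) x^2` and the ligand term
#' `0.5 kL (y - lambda dL)^2 + lambda dEL` are common to all end states (they
#' form the non-enveloped system Hamiltonian).
#'
#' @param states Tibble with columns `label`, `role`, `k`, `x0`, `c0`, `c1`,
#'   `g0`, `g1`.
#' @param well_width Width `w` of the Gaussian attraction well, nm.
#' @param restraint `c(K0, K1)` endpoint force constants of the harmonic
#'   restraint on `x` (kJ/mol/nm^2), or `NULL`.
#' @param ligand `c(kL, dL, dEL)` ligand-morph parameters, or `NULL`.
#' @param domain Quadrature domain for `x`, nm.
#' @return An `aeds_toy_system` object.
#' @export
toy_system <- function(states, well_width = 0.1, restraint = NULL,
                       ligand = NULL, domain = c(-1.5, 1.5)) {
  need <- c("label", "role", "k", "x0", "c0", "c1", "g0", "g1")
  stopifnot(all(need %in% names(states)))
  if (!is.null(restraint)) stopifnot(length(restraint) == 2L, all(restraint >= 0))
  if (!is.null(ligand)) stopifnot(length(ligand) == 3L, ligand[1] > 0)
  structure(list(states = tibble::as_tibble(states), well_width = well_width,
                 restraint = restraint, ligand = ligand, domain = domain),
            class = "aeds_toy_system")
}

## Per-state parametric energy at (x, lambda); vectorized over x.
toy_state_energy <- function(system, i, x, lambda) {
  s <- system$states[i, ]
  g <- (1 - lambda) * s$g0 + lambda * s$g1
  cc <- (1 - lambda) * s$c0 + lambda * s$c1
  phi <- exp(-x^2 / (2 * system$well_width^2))
  0.5 * s$k * (x - s$x0)^2 + cc - g * phi
}

toy_state_dhdl <- function(system, i, x, lambda) {
  s <- system$states[i, ]
  phi <- exp(-x^2 / (2 * system$well_width^2))
  (s$c1 - s$c0) - (s$g1 - s$g0) * phi
}

## Restraint energy on x at lambda (0 if none).
toy_restraint_energy <- function(system, x, lambda) {
  if (is.null(system$restraint)) return(0 * x)
  k <- (1 - lambda) * system$restraint[1] + lambda * system$restraint[2]
  0.5 * k * x^2
}

## Closure-based end states mirroring the parametric family (for the pure-R
## operations: reference_force, dhdl_frame, finite-difference oracles).
toy_end_states <- function(system) {
  lapply(seq_len(nrow(system$states)), function(i) {
    s <- system$states[i, ]
    w <- system$well_width
    force(i)
    end_state(s$label, function(x, lambda) {
      xx <- x[1]
      g <- (1 - lambda) * s$g0 + lambda * s$g1
      cc <- (1 - lambda) * s$c0 + lambda * s$c1
      phi <- exp(-xx^2 / (2 * w^2))
      grad_x <- s$k * (xx - s$x0) + g * xx / w^2 * phi
      grad <- c(grad_x, rep(0, length(x) - 1L))
      list(energy = 0.5 * s$k * (xx - s$x0)^2 + cc - g * phi,
           gradient = grad,
           dhdl = (s$c1 - s$c0) - (s$g1 - s$g0) * phi)
    }, role = if (s$role %in% c("physical", "dummy", "composite")) s$role else "physical")
  })
}

#' Reference definition for a toy system
#'
#' @param system An [toy_system()].
#' @param offsets Offset schedules (see [reference_definition()]).
#' @param temperature Temperature, K.
#' @param accel Optional [accel_params()].
#' @return An `aeds_reference` whose end states are the system's parametric
#'   states.
#' @export
toy_reference <- function(system, offsets = NULL, temperature = 300,
                          accel = NULL) {
  ref <- reference_definition(toy_end_states(system), offsets = offsets,
                              temperature = temperature, accel = accel)
  ref$system <- system
  ref
}

#' Pocket model with a probed (switchable) particle
#'
#' Emulates a protein hydration site: a probed particle confined by a
#' harmonic restraint, with a Gaussian site attraction whose depth morphs from
#' `g_A` (ligand A, lambda = 0) to `g_B` (ligand B, lambda = 1). The coupled
#' end state feels the attraction; the dummy end state feels only the
#' confining restraint. The exact coupled-state occupancy at any lambda is
#' available by quadrature over the two one-dimensional partition functions.
#'
#' @param g_A,g_B Site attraction depths (kJ/mol) at lambda 0 and 1; positive
#'   values attract.
#' @param well_width Width of the attraction well, nm.
#' @param restraint_k Confining force constant, kJ/mol/nm^2.
#' @param ligand `c(kL, dL, dEL)` parameters of the ligand-morph coordinate,
#'   or `NULL` for a probe-only system.
#' @param temperature Temperature, K.
#' @param accel Optional [accel_params()] for the returned reference.
#' @param offsets Optional offsets for the returned reference.
#' @return List with elements `system` ([toy_system()]) and `reference`
#'   (coupled + dummy end states, in that order).
#' @export
make_pocket_probe_system <- function(g_A, g_B, well_width = 0.12,
                                     restraint_k = 200,
                                     ligand = c(400, 0.3, 25),
                                     temperature = 300, accel = NULL,
                                     offsets = NULL) {
  stopifnot(is.finite(g_A), is.finite(g_B))
  states <- tibble::tibble(
    label = c("coupled", "dummy"),
    role = c("physical", "dummy"),
    k = 0, x0 = 0, c0 = 0, c1 = 0,
    g0 = c(g_A, 0), g1 = c(g_B, 0))
  sys <- toy_system(states, well_width = well_width,
                    restraint = c(restraint_k, restraint_k),
                    ligand = ligand, domain = c(-1.2, 1.2))
  list(system = sys,
       reference = toy_reference(sys, offsets = offsets,
                                 temperature = temperature, accel = accel))
}

#' Bulk-like probe system
#'
#' The pocket model with no site attraction in either end state: the probed
#' particle behaves identically in both ligand environments, standing in for
#' a bulk-water search system. Used to obtain transferable acceleration
#' parameters.
#'
#' @inheritParams make_pocket_probe_system
#' @return As [make_pocket_probe_system()].
#' @export
make_bulk_probe_system <- function(well_width = 0.12, restraint_k = 200,
                                   temperature = 300, accel = NULL) {
  make_pocket_probe_system(0, 0, well_width = well_width,
                           restraint_k = restraint_k, ligand = NULL,
                           temperature = temperature, accel = accel)
}

#' Exact occupancy of a toy reference by quadrature
#'
#' Computes the mean coupled-state weight under the boosted reference ensemble
#' by one-dimensional quadrature over the probed coordinate:
#' `<w_i>_{R*} = int w_i(x) exp(-(V_r(x) + E_R*(x))/RT) dx / Z`.
#'
#' @param reference A [toy_reference()] (must carry its system).
#' @param lambda Coupling parameter.
#' @param state Index or label of the state whose occupancy is wanted
#'   (default 1, the coupled state).
#' @param n Quadrature grid size.
#' @return Occupancy in [0, 1].
#' @export
toy_occupancy_quadrature <- function(reference, lambda = 0, state = 1L,
                                     n = 4001) {
  sys <- reference$system
  stopifnot(!is.null(sys))
  if (is.character(state)) state <- match(state, reference$labels)
  off <- reference_offsets_at(reference, lambda)
  RT <- reference$RT
  x <- seq(sys$domain[1], sys$domain[2], length.out = n)
  Hm <- vapply(seq_len(nrow(sys$states)),
               function(i) toy_state_energy(sys, i, x, lambda),
               numeric(length(x)))
  lse <- apply(-(sweep(Hm, 2, off)) / RT, 1, logsumexp)
  e_r <- -RT * lse
  w_i <- exp(-(Hm[, state] - off[state]) / RT - lse)
  vr <- toy_restraint_energy(sys, x, lambda)
  btot <- aeds_boost(e_r, reference$accel)$energy + vr
  dens <- exp(-(btot - min(btot)) / RT)
  sum(w_i * dens) / sum(dens)
}

## Total free energy (x part) of a fixed end state, or of the boosted
## reference, at lambda -- quadrature oracle for cycle legs.
toy_state_free_energy <- function(reference, lambda, state = NULL, n = 8193) {
  sys <- reference$system
  RT <- reference$RT
  if (!is.null(state) && is.character(state)) state <- match(state, reference$labels)
  u <- function(x) {
    vr <- toy_restraint_energy(sys, x, lambda)
    if (!is.null(state)) {
      vr + toy_state_energy(sys, state, x, lambda)
    } else {
      off <- reference_offsets_at(reference, lambda)
      Hm <- vapply(seq_len(nrow(sys$states)),
                   function(i) toy_state_energy(sys, i, x, lambda),
                   numeric(length(x)))
      e_r <- -RT * apply(-(sweep(Hm, 2, off)) / RT, 1, logsumexp)
      vr + aeds_boost(e_r, reference$accel)$energy
    }
  }
  quadrature_free_energy(u, RT, n = n, x_lo = sys$domain[1], x_hi = sys$domain[2])
}

#' Soft-core pair interaction
#'
#' Lennard-Jones plus Coulomb pair interaction with soft-core regularization
#' for alchemical decoupling (coupled at lambda = 0, fully decoupled at
#' lambda = 1, finite at r = 0 for intermediate lambda):
#' \deqn{U = (1-\lambda)\left[\frac{C_{12}}{(\alpha_{LJ}\lambda^2\sigma^6 + r^6)^2}
#'   - \frac{C_6}{\alpha_{LJ}\lambda^2\sigma^6 + r^6}
#'   + \frac{f\, q_1 q_2}{\sqrt{\alpha_{CRF}\lambda^2 + r^2}}\right]}
#' with `sigma^6 = C12/C6` and `f = 138.9354` kJ mol^-1 nm e^-2. The
#' lambda-derivative is analytic.
#'
#' @param r Distance, nm (vectorized).
#' @param lambda Coupling parameter in [0, 1].
#' @param alpha_lj Soft-core parameter for the Lennard-Jones term
#'   (dimensionless, default 0.5).
#' @param alpha_crf Soft-core parameter for the electrostatic term
#'   (nm^2, default 0.5).
#' @param c12 LJ repulsion coefficient, kJ/mol nm^12.
#' @param c6 LJ dispersion coefficient, kJ/mol nm^6.
#' @param q_prod Product of the partial charges, e^2.
#' @return Tibble with columns `r`, `lambda`, `energy`, `dhdl` (kJ/mol).
#' @export
soft_core_pair_energy <- function(r, lambda, alpha_lj = 0.5, alpha_crf = 0.5,
                                  c12 = 2.634129e-6, c6 = 2.617346e-3,
                                  q_prod = -0.1) {
  if (any(lambda < 0 | lambda > 1)) {
    abort("`lambda` must lie in [0, 1].", class = "aedskit_parameter_error")
  }
  stopifnot(all(r >= 0), alpha_lj >= 0, alpha_crf >= 0, c6 > 0)
  f_elec <- 138.9354
  sig6 <- c12 / c6
  den_lj <- alpha_lj * lambda^2 * sig6 + r^6
  den_c <- sqrt(alpha_crf * lambda^2 + r^2)
  lj <- c12 / den_lj^2 - c6 / den_lj
  coul <- f_elec * q_prod / den_c
  energy <- (1 - lambda) * (lj + coul)
  dlj <- (-2 * c12 / den_lj^3 + c6 / den_lj^2) * (2 * alpha_lj * lambda * sig6)
  dcoul <- -f_elec * q_prod * alpha_crf * lambda / den_c^3
  dhdl <- -(lj + coul) + (1 - lambda) * (dlj + dcoul)
  tibble::tibble(r = r, lambda = lambda, energy = energy, dhdl = dhdl)
}
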