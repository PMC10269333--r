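#' Sampler configuration
#'
#' @param mode `"metropolis"` (exact stationarity via detailed balance, the
#'   recommended correctness path) or `"langevin"` (overdamped
#'   Euler--Maruyama; carries a discretization bias of order `dt`, provided
#'   for time-series realism such as state lifetimes).
#' @param n_steps Number of production steps (> 0).
#' @param step_size Proposal width (nm) for Metropolis, or time step (ps) for
#'   Langevin.
#' @param temperature Temperature, K.
#' @param seed Integer seed; a fixed seed gives a bit-identical trajectory.
#' @param save_interval Record every this many steps.
#' @param burn_in Equilibration steps, discarded. For Metropolis the proposal
#'   width is auto-tuned during burn-in towards a 30--50% acceptance rate
#'   unless `tune = FALSE`.
#' @param tune Auto-tune the Metropolis proposal width during burn-in.
#' @param friction Langevin friction coefficient gamma, kJ ps mol^-1 nm^-2.
#' @param time_per_step Nominal time per Metropolis step, ps (used only to
#'   express the time axis; default 0.002).
#' @return An `aeds_sim_config` object.
#' @export
simulation_config <- function(mode = c("metropolis", "langevin"),
                              n_steps = 1e5, step_size = 0.1,
                              temperature = 300, seed = NULL,
                              save_interval = 10L, burn_in = 2000L,
                              tune = TRUE, friction = 1,
                              time_per_step = 0.002) {
  mode <- match.arg(mode)
  stopifnot(n_steps > 0, step_size > 0, save_interval >= 1, burn_in >= 0)
  structure(list(mode = mode, n_steps = as.integer(n_steps),
                 step_size = step_size, temperature = temperature,
                 seed = seed, save_interval = as.integer(save_interval),
                 burn_in = as.integer(burn_in), tune = tune,
                 friction = friction, time_per_step = time_per_step),
            class = "aeds_sim_config")
}

## Assemble the C++ spec list from a toy system + reference at given lambda.
toy_sampler_spec <- function(system, reference, RT) {
  st <- system$states
  sp <- cbind(st$k, st$x0, st$c0, st$c1, st$g0, st$g1)
  off <- do.call(rbind, lapply(reference$offsets, function(o) c(o$S, o$b)))
  accel <- if (is.null(reference$accel)) numeric(0) else
    c(reference$accel$e_min, reference$accel$e_max, 1)
  list(state_params = sp, well_width = system$well_width,
       restraint = if (is.null(system$restraint)) numeric(0) else system$restraint,
       ligand = if (is.null(system$ligand)) numeric(0) else system$ligand,
       offsets = off, accel = accel, RT = RT)
}

#' Sample the boosted reference ensemble of a toy system
#'
#' Runs Metropolis Monte Carlo (or overdamped Langevin dynamics) on the total
#' Hamiltonian `H_S + V_restraint + E_R*` at a fixed lambda, recording all
#' end-state energies, the reference energy before and after the boost, the
#' restraint energy and the lambda-derivative components every save interval.
#'
#' @param system An [toy_system()].
#' @param reference An `aeds_reference` over the same end states (offsets may
#'   be schedules; they are evaluated at `lambda` internally by the sampler).
#' @param config An [simulation_config()].
#' @param lambda Coupling parameter in [0, 1].
#' @param init Initial configuration `c(x, y)`; default `c(0, 0)`.
#' @return An `aeds_energy_series` tibble with columns `time_ps`, `lambda`,
#'   `H_<label>` per end state, `E_R`, `E_R_star`, `V_restraint`, `dHs_dl`
#'   (system + restraint lambda-derivative), `dH_<label>_dl` per end state,
#'   `dHdl` (total), `x`, `y`. Attributes carry the state labels, offsets at
#'   `lambda`, RT, acceleration parameters and acceptance rate.
#' @export
run_sampler <- function(system, reference, config, lambda = 0,
                        init = c(0, 0)) {
  stopifnot(inherits(system, "aeds_toy_system"),
            inherits(reference, "aeds_reference"),
            inherits(config, "aeds_sim_config"),
            lambda >= 0, lambda <= 1)
  if (nrow(system$states) != length(reference$end_states)) {
    abort("System and reference disagree on the number of end states.",
          class = "aedskit_parameter_error")
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  spec <- toy_sampler_spec(system, reference, reference$RT)
  out <- cpp_run_sampler(spec, lambda, config$n_steps, config$save_interval,
                         config$burn_in, config$step_size, config$tune,
                         config$mode,
                         dt = if (config$mode == "langevin") config$step_size else 0,
                         gamma = config$friction, init = as.numeric(init),
                         time_per_step = if (config$mode == "langevin")
                           config$step_size else config$time_per_step)
  labels <- reference$labels
  cn <- c("time_ps", "lambda", paste0("H_", labels), "E_R", "E_R_star",
          "V_restraint", "dHs_dl", paste0("dH_", labels, "_dl"), "dHdl",
          "x", "y")
  frames <- out$frames
  colnames(frames) <- cn
  ts <- tibble::as_tibble(as.data.frame(frames))
  new_energy_series(ts, labels = labels,
                    offsets = reference_offsets_at(reference, lambda),
                    RT = reference$RT, accel = reference$accel,
                    lambda = lambda,
                    accept_rate = out$accept_rate, sigma = out$sigma,
                    final = c(out$x, out$y))
}

new_energy_series <- function(ts, labels, offsets, RT, accel = NULL,
                              lambda = NA_real_, ...) {
  structure(ts, class = c("aeds_energy_series", class(tibble::tibble())),
            labels = labels, offsets = offsets, RT = RT, accel = accel,
            lambda = lambda, ...)
}

#' State labels of an energy series
#' @param ts An `aeds_energy_series`.
#' @return Character vector of end-state labels.
#' @export
series_labels <- function(ts) attr(ts, "labels")

## H matrix (frames x states) of an energy series.
series_H <- function(ts) {
  as.matrix(ts[paste0("H_", series_labels(ts))])
}

#' Verify the internal consistency of an energy series
#'
#' Recomputes `E_R` from the stored per-state energies and the offsets and
#' compares with the stored column; recomputes the boosted energy likewise.
#'
#' @param ts An `aeds_energy_series`.
#' @param tol Maximum allowed absolute deviation, kJ/mol.
#' @return `ts`, invisibly. Errors if the bookkeeping is inconsistent.
#' @export
validate_energy_series <- function(ts, tol = 1e-9) {
  H <- series_H(ts)
  off <- attr(ts, "offsets"); RT <- attr(ts, "RT")
  e_r <- apply(H, 1, reference_energy, offsets = off, RT = RT)
  if (max(abs(e_r - ts$E_R)) > tol) {
    abort("Stored E_R is inconsistent with the stored end-state energies.",
          class = "aedskit_state_error")
  }
  b <- aeds_boost(ts$E_R, attr(ts, "accel"))
  if (max(abs(b$energy - ts$E_R_star)) > tol) {
    abort("Stored E_R_star is inconsistent with the stored E_R.",
          class = "aedskit_state_error")
  }
  invisible(ts)
}

#' Harmonic distance restraint
#'
#' Restraint to a fixed anchor with optional lambda-ramped force constant
#' `K(lambda) = (1 - lambda) K0 + lambda K1` (reference distance 0).
#'
#' @param anchor Anchor point, nm (any dimension).
#' @param K0 Force constant at lambda = 0, kJ/mol/nm^2.
#' @param K1 Force constant at lambda = 1 (defaults to `K0`, i.e. constant).
#' @return An `aeds_restraint` object.
#' @export
harmonic_restraint <- function(anchor = 0, K0 = 1500, K1 = K0) {
  stopifnot(K0 >= 0, K1 >= 0)
  structure(list(anchor = anchor, K0 = K0, K1 = K1), class = "aeds_restraint")
}

#' Restraint energy and gradient
#'
#' @param configuration Position, nm (same dimension as the anchor).
#' @param restraint An [harmonic_restraint()].
#' @param lambda Coupling parameter.
#' @return List with `energy` (kJ/mol), `gradient` (kJ/mol/nm) and `dhdl`.
#' @export
restraint_energy <- function(configuration, restraint, lambda = 0) {
  d <- configuration - restraint$anchor
  K <- (1 - lambda) * restraint$K0 + lambda * restraint$K1
  list(energy = 0.5 * K * sum(d^2), gradient = K * d,
       dhdl = 0.5 * (restraint$K1 - restraint$K0) * sum(d^2))
}

#' Metropolis transition matrix for a discrete chain
#'
#' Diagnostic for the acceptance rule: nearest-neighbour proposals with
#' probability 1/2 each (reflecting at the ends by rejection) and Metropolis
#' acceptance `min(1, exp(-dU/RT))`. The stationary distribution of the
#' resulting kernel is the Boltzmann distribution of `U`, which is what the
#' detailed-balance unit tests assert.
#'
#' @param U Site energies, kJ/mol.
#' @param RT Thermal energy, kJ/mol.
#' @return Row-stochastic transition matrix.
#' @export
metropolis_kernel_matrix <- function(U, RT) {
  n <- length(U)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in c(i - 1L, i + 1L)) {
      if (j >= 1L && j <= n) {
        P[i, j] <- 0.5 * min(1, exp(-(U[j] - U[i]) / RT))
      }
    }
    P[i, i] <- 1 - sum(P[i, ])
  }
  P
}
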