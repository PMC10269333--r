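#' End state of an enveloping-distribution reference
#'
#' An end state is one physical (or dummy) Hamiltonian that the reference
#' state envelopes. Its `energy` contract maps a configuration and a coupling
#' parameter lambda to the state energy, its configurational gradient, and its
#' lambda-derivative. A dummy-role state carries none of the probed molecule's
#' nonbonded terms: its energy is the rest-of-system contribution (typically a
#' constant at the level of the per-state decomposition used here).
#'
#' @param label Unique state label.
#' @param energy Function `(configuration, lambda)` returning a list with
#'   elements `energy` (kJ/mol), `gradient` (kJ/mol/nm, same length as the
#'   configuration) and `dhdl` (kJ/mol, derivative with respect to lambda).
#' @param role One of `"physical"`, `"dummy"`, `"composite"`.
#' @return An `aeds_end_state` object.
#' @export
end_state <- function(label, energy, role = c("physical", "dummy", "composite")) {
  role <- match.arg(role)
  stopifnot(is.character(label), length(label) == 1L, nzchar(label),
            is.function(energy))
  structure(list(label = label, energy = energy, role = role),
            class = "aeds_end_state")
}

#' Linear energy-offset schedule
#'
#' Per-state energy offsets pull the end-state minima to comparable depth so
#' that every state is sampled. Along an alchemical path the offsets may be
#' interpolated linearly in lambda: `offset(lambda) = S * lambda + b`.
#'
#' @param S Slope, kJ/mol per unit lambda.
#' @param b Intercept, kJ/mol; the offset at lambda = 0.
#' @return An `aeds_offset_schedule` object.
#' @export
offset_schedule <- function(S = 0, b = 0) {
  stopifnot(is.numeric(S), is.numeric(b), length(S) == 1L, length(b) == 1L,
            is.finite(S), is.finite(b))
  structure(list(S = S, b = b), class = "aeds_offset_schedule")
}

#' Evaluate an offset schedule at lambda
#'
#' @param schedule An [offset_schedule()], or a bare number treated as a
#'   constant offset.
#' @param lambda Coupling parameter.
#' @return Offset in kJ/mol.
#' @export
offset_at <- function(schedule, lambda) {
  if (is.numeric(schedule)) return(schedule)
  schedule$S * lambda + schedule$b
}

#' Acceleration (boost) parameters
#'
#' `e_min` and `e_max` bound the acceleration range of the harmonic boosting
#' potential: below `e_min` the reference energy is untouched, between the two
#' bounds barriers are progressively damped, and above `e_max` the boosted
#' energy surface is flat.
#'
#' @param e_min,e_max Bounds of the acceleration range, kJ/mol
#'   (`e_min <= e_max`).
#' @return An `aeds_accel` object.
#' @export
accel_params <- function(e_min, e_max) {
  stopifnot(is.numeric(e_min), is.numeric(e_max),
            length(e_min) == 1L, length(e_max) == 1L,
            is.finite(e_min), is.finite(e_max))
  if (e_min > e_max) {
    abort("`e_min` must not exceed `e_max`.", class = "aedskit_parameter_error")
  }
  structure(list(e_min = e_min, e_max = e_max), class = "aeds_accel")
}

#' Reference-state definition
#'
#' Bundles the end states, their offset schedules, the temperature and the
#' acceleration parameters that together define an (accelerated) enveloping
#' reference Hamiltonian.
#'
#' @param end_states List of [end_state()] objects (>= 1, unique labels).
#' @param offsets List of [offset_schedule()] objects (or bare numbers,
#'   treated as constant offsets), one per end state. Default: all zero.
#' @param temperature Temperature in K (default 300).
#' @param accel An [accel_params()] object, or `NULL` for no boost.
#' @return An `aeds_reference` object with derived field `RT` (kJ/mol).
#' @export
reference_definition <- function(end_states, offsets = NULL, temperature = 300,
                                 accel = NULL) {
  if (inherits(end_states, "aeds_end_state")) end_states <- list(end_states)
  stopifnot(length(end_states) >= 1L,
            all(vapply(end_states, inherits, logical(1), "aeds_end_state")))
  labels <- vapply(end_states, `[[`, character(1), "label")
  if (anyDuplicated(labels)) {
    abort("End-state labels must be unique.", class = "aedskit_parameter_error")
  }
  if (is.null(offsets)) offsets <- rep(list(offset_schedule(0, 0)), length(end_states))
  offsets <- lapply(offsets, function(o) {
    if (is.numeric(o)) offset_schedule(0, o) else o
  })
  if (length(offsets) != length(end_states)) {
    abort("Need exactly one offset schedule per end state.",
          class = "aedskit_parameter_error")
  }
  if (!is.null(accel)) stopifnot(inherits(accel, "aeds_accel"))
  structure(list(end_states = end_states, labels = labels, offsets = offsets,
                 temperature = temperature, RT = rt_kj(temperature),
                 accel = accel),
            class = "aeds_reference")
}

#' @export
print.aeds_reference <- function(x, ...) {
  cat(sprintf("<aeds_reference> %d end state(s): %s\n",
              length(x$end_states), paste(x$labels, collapse = ", ")))
  cat(sprintf("  T = %g K (RT = %.4f kJ/mol)\n", x$temperature, x$RT))
  if (is.null(x$accel)) cat("  no acceleration\n")
  else cat(sprintf("  acceleration: E_min = %g, E_max = %g kJ/mol\n",
                   x$accel$e_min, x$accel$e_max))
  invisible(x)
}

## Offsets of a reference evaluated at lambda, as a numeric vector.
reference_offsets_at <- function(reference, lambda) {
  vapply(reference$offsets, offset_at, numeric(1), lambda = lambda)
}

#' Enveloping reference energy
#'
#' The reference energy combines the end-state Hamiltonians into a single
#' smooth envelope,
#' \deqn{E_R = -RT \ln \sum_i \exp(-(H_i - \Delta F_i)/RT),}
#' evaluated with an overflow-safe log-sum-exp. It is bounded by
#' `min(H - dF) - RT log(N) <= E_R <= min(H - dF)`.
#'
#' @param H Numeric vector of end-state energies, kJ/mol.
#' @param offsets Numeric vector of energy offsets (Delta F_i), kJ/mol.
#' @param RT Thermal energy, kJ/mol.
#' @return Reference energy E_R in kJ/mol.
#' @examples
#' reference_energy(c(10, 10), c(0, 0), RT = 2.494) # 10 - 2.494 * log(2)
#' @export
reference_energy <- function(H, offsets, RT) {
  assert_finite(H, "H"); assert_finite(offsets, "offsets")
  if (length(H) != length(offsets)) {
    abort("`H` and `offsets` must have equal length.", class = "aedskit_size_error")
  }
  stopifnot(is.finite(RT), RT > 0)
  -RT * logsumexp(-(H - offsets) / RT)
}

#' Boltzmann state weights of the reference ensemble
#'
#' @inheritParams reference_energy
#' @return Numeric vector of probabilities summing to 1. Invariant under a
#'   uniform shift of all offsets.
#' @examples
#' state_weights(c(3, 3), c(0, 0), RT = 2.494) # c(0.5, 0.5)
#' @export
state_weights <- function(H, offsets, RT) {
  assert_finite(H, "H"); assert_finite(offsets, "offsets")
  if (length(H) != length(offsets)) {
    abort("`H` and `offsets` must have equal length.", class = "aedskit_size_error")
  }
  z <- -(H - offsets) / RT
  z <- z - max(z)
  w <- exp(z)
  w / sum(w)
}

#' Harmonic boosting potential
#'
#' Applies the acceleration transform to the reference energy. The boost
#' leaves energies below `e_min` untouched (preserving the end-state minima),
#' damps the region between `e_min` and `e_max` harmonically,
#' \deqn{E_R^* = E_R - (E_R - E_{min})^2 / (2 (E_{max} - E_{min})),}
#' and flattens everything above `e_max` to the constant
#' `(e_min + e_max) / 2`. The transform is continuous, once-differentiable,
#' non-decreasing, and its slope `dE_R*/dE_R` lies in [0, 1]. The degenerate
#' case `e_min == e_max` is the identity map (no acceleration).
#'
#' @param e_r Reference energy (or vector of energies), kJ/mol.
#' @param accel An [accel_params()] object, or `NULL` for the identity.
#' @return A list with numeric vectors `energy` (boosted energy, kJ/mol) and
#'   `slope` (dimensionless derivative of the boosted energy with respect to
#'   the input energy).
#' @examples
#' aeds_boost(100, accel_params(0, 100)) # energy 50, slope 0
#' @export
aeds_boost <- function(e_r, accel) {
  if (is.null(accel)) return(list(energy = e_r, slope = rep(1, length(e_r))))
  stopifnot(inherits(accel, "aeds_accel"))
  e_min <- accel$e_min; e_max <- accel$e_max
  if (e_min == e_max) return(list(energy = e_r, slope = rep(1, length(e_r))))
  span <- e_max - e_min
  energy <- ifelse(e_r <= e_min, e_r,
            ifelse(e_r >= e_max, (e_min + e_max) / 2,
                   e_r - (e_r - e_min)^2 / (2 * span)))
  slope <- ifelse(e_r <= e_min, 1,
           ifelse(e_r >= e_max, 0, 1 - (e_r - e_min) / span))
  list(energy = energy, slope = slope)
}

## Evaluate every end state of a reference at (configuration, lambda).
## Returns list(H, grad [matrix n_states x dim], dhdl).
eval_end_states <- function(reference, configuration, lambda) {
  res <- lapply(reference$end_states, function(s) s$energy(configuration, lambda))
  H <- vapply(res, `[[`, numeric(1), "energy")
  grads <- do.call(rbind, lapply(res, function(r) as.numeric(r$gradient)))
  dhdl <- vapply(res, function(r) r$dhdl %||% 0, numeric(1))
  list(H = H, grad = grads, dhdl = dhdl)
}

#' Force of the boosted reference state
#'
#' Chain rule through the envelope and the boost:
#' `grad E_R* = slope(E_R) * sum_i w_i * grad H_i`.
#'
#' @param configuration Numeric configuration vector (nm).
#' @param reference An [reference_definition()] whose end states expose
#'   gradients.
#' @param lambda Coupling parameter (default 0).
#' @return Gradient vector, kJ/mol/nm.
#' @export
reference_force <- function(configuration, reference, lambda = 0) {
  ev <- eval_end_states(reference, configuration, lambda)
  if (is.null(ev$grad) || anyNA(ev$grad)) {
    abort("End states must supply gradients at this configuration.",
          class = "aedskit_capability_error")
  }
  off <- reference_offsets_at(reference, lambda)
  w <- state_weights(ev$H, off, reference$RT)
  e_r <- reference_energy(ev$H, off, reference$RT)
  slope <- aeds_boost(e_r, reference$accel)$slope
  slope * drop(w %*% ev$grad)
}

#' Combinatorial reference over probed molecules
#'
#' Enumerates every coupled/dummy assignment of `n_probed` switchable
#' molecules into `2^n_probed` end states. State labels encode the assignment
#' ("c" coupled, "d" dummy, one letter per molecule); ordering is binary
#' counting with the all-coupled state first.
#'
#' @param n_probed Number of probed molecules (>= 1).
#' @param base_system A system exposing `probed_terms`: a list of `n_probed`
#'   energy contracts (as in [end_state()]) for the coupled interaction of
#'   each probed molecule. The dummy assignment contributes zero energy.
#' @param temperature Temperature, K.
#' @param accel Optional [accel_params()].
#' @param cap Refuse more probed molecules than this (exponential growth).
#' @return An [reference_definition()] with `2^n_probed` end states.
#' @export
combinatorial_reference <- function(n_probed, base_system, temperature = 300,
                                    accel = NULL, cap = 4L) {
  stopifnot(n_probed >= 1L)
  if (n_probed > cap) {
    abort(sprintf(paste("Refusing %d probed molecules: 2^n end states grow",
                        "exponentially (cap %d). Raise `cap` explicitly if",
                        "you mean it."), n_probed, cap),
          class = "aedskit_parameter_error")
  }
  terms <- base_system$probed_terms
  stopifnot(length(terms) >= n_probed)
  states <- lapply(seq_len(2^n_probed) - 1L, function(code) {
    bits <- as.integer(intToBits(code))[seq_len(n_probed)] # 0 = coupled
    label <- paste(ifelse(bits == 0L, "c", "d"), collapse = "")
    coupled <- which(bits == 0L)
    fns <- terms[coupled]
    energy <- function(configuration, lambda) {
      if (length(fns) == 0L) {
        return(list(energy = 0, gradient = 0 * configuration, dhdl = 0))
      }
      parts <- lapply(fns, function(f) f(configuration, lambda))
      list(energy = sum(vapply(parts, `[[`, numeric(1), "energy")),
           gradient = Reduce(`+`, lapply(parts, function(p) as.numeric(p$gradient))),
           dhdl = sum(vapply(parts, function(p) p$dhdl %||% 0, numeric(1))))
    }
    role <- if (length(coupled) == 0L) "dummy"
            else if (length(coupled) == n_probed) "physical" else "composite"
    end_state(label, energy, role)
  })
  reference_definition(states, temperature = temperature, accel = accel)
}
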