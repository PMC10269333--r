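#' Lambda protocol for thermodynamic integration
#'
#' @param n_windows Number of equally spaced lambda points including 0 and 1
#'   (default 41, the coupled TI--AEDS protocol; plain TI commonly uses 11).
#' @param n_steps Production steps per window.
#' @param n_equil Equilibration steps per window (discarded).
#' @param direction `"forward"`, `"backward"` or `"both"`. Backward runs
#'   traverse the grid from lambda 1 to 0, starting from the final
#'   configuration of the forward lambda = 1 window.
#' @return An `aeds_lambda_protocol` object.
#' @export
lambda_protocol <- function(n_windows = 41L, n_steps = 2e4, n_equil = 2000L,
                            direction = c("both", "forward", "backward")) {
  direction <- match.arg(direction)
  stopifnot(n_windows >= 2L, n_steps > 0, n_equil >= 0)
  structure(list(lambdas = seq(0, 1, length.out = n_windows),
                 n_steps = as.integer(n_steps), n_equil = as.integer(n_equil),
                 direction = direction),
            class = "aeds_lambda_protocol")
}

#' Per-frame dH/dlambda of the coupled TI--AEDS Hamiltonian
#'
#' The derivative of the total Hamiltonian `H_S + E_R*` with respect to
#' lambda:
#' \deqn{\partial H/\partial\lambda = \partial H_S/\partial\lambda +
#'   \frac{dE_R^*}{dE_R} \sum_i w_i \left(\partial H_i/\partial\lambda -
#'   S_i\right),}
#' where the `-S_i` term is the lambda-derivative of the linearly interpolated
#' energy offsets and the outer factor is the boost slope.
#'
#' @param configuration Configuration vector.
#' @param lambda Coupling parameter.
#' @param system_dhdl Function `(configuration, lambda)` returning the
#'   lambda-derivative of the non-enveloped system Hamiltonian H_S (kJ/mol),
#'   or `NULL` for 0.
#' @param reference An `aeds_reference` whose end states expose `dhdl` and
#'   whose offsets are [offset_schedule()]s.
#' @return dH/dlambda in kJ/mol.
#' @export
dhdl_frame <- function(configuration, lambda, system_dhdl = NULL, reference) {
  ev <- eval_end_states(reference, configuration, lambda)
  if (anyNA(ev$dhdl)) {
    abort("End states must expose dH/dlambda.", class = "aedskit_capability_error")
  }
  off <- reference_offsets_at(reference, lambda)
  S <- vapply(reference$offsets, function(o) if (is.numeric(o)) 0 else o$S,
              numeric(1))
  w <- state_weights(ev$H, off, reference$RT)
  e_r <- reference_energy(ev$H, off, reference$RT)
  slope <- aeds_boost(e_r, reference$accel)$slope
  ds <- if (is.null(system_dhdl)) 0 else system_dhdl(configuration, lambda)
  ds + slope * sum(w * (ev$dhdl - S))
}

#' Trapezoidal thermodynamic integration
#'
#' @param lambdas Sorted lambda grid over [0, 1].
#' @param dhdl Mean dH/dlambda per window, kJ/mol.
#' @return Integrated free-energy difference, kJ/mol.
#' @export
ti_integrate <- function(lambdas, dhdl) {
  if (length(lambdas) < 2L || length(dhdl) != length(lambdas)) {
    abort("Need >= 2 matching lambda points.", class = "aedskit_size_error")
  }
  if (is.unsorted(lambdas, strictly = TRUE)) {
    abort("`lambdas` must be strictly increasing.",
          class = "aedskit_parameter_error")
  }
  assert_finite(dhdl, "dhdl")
  sum(diff(lambdas) * (head(dhdl, -1) + tail(dhdl, -1)) / 2)
}

## One direction of a windowed TI run. Returns per-window summary + series.
run_ti_direction <- function(system, reference, protocol, config, lambdas,
                             init) {
  state <- init
  sigma <- config$step_size
  rows <- vector("list", length(lambdas))
  series <- vector("list", length(lambdas))
  for (i in seq_along(lambdas)) {
    lam <- lambdas[i]
    ts <- run_sampler(system, reference, simulation_config(
      mode = config$mode, n_steps = protocol$n_steps, step_size = sigma,
      temperature = config$temperature, seed = NULL,
      save_interval = config$save_interval, burn_in = protocol$n_equil,
      tune = config$tune, friction = config$friction,
      time_per_step = config$time_per_step),
      lambda = lam, init = state)
    state <- attr(ts, "final")
    sigma <- attr(ts, "sigma")
    occ <- occupancy_fractions(ts)
    rows[[i]] <- tibble::tibble(
      lambda = lam, dhdl_mean = mean(ts$dHdl),
      dhdl_err = tryCatch(block_error(ts$dHdl),
                          aedskit_size_error = function(e) NA_real_),
      occupancy_coupled = occ$fraction[1])
    series[[i]] <- ts
  }
  list(table = dplyr::bind_rows(rows), series = series, final = state)
}

#' Run a TI (or TI--AEDS) calculation on a toy system
#'
#' Samples every lambda window of the protocol with the boosted reference
#' Hamiltonian coupled to the lambda-perturbed system, records per-frame
#' dH/dlambda (including the offset-schedule derivative term) and the
#' coupled-state occupancy per window, and integrates the profile by the
#' trapezoidal rule. With a single-end-state reference and no boost this is
#' plain thermodynamic integration. For `direction = "both"` the backward
#' sweep starts from the final forward configuration at lambda = 1 and the
#' hysteresis `|dG_forward - dG_backward|` is reported.
#'
#' @param system An [toy_system()].
#' @param reference An `aeds_reference` (offsets may be schedules).
#' @param protocol An [lambda_protocol()].
#' @param seed Integer seed for the whole run.
#' @param config Base [simulation_config()] (its `n_steps`/`burn_in` are
#'   overridden per window by the protocol).
#' @param init Initial configuration.
#' @return An `aeds_ti_result`: list with `table` (per-lambda tibble: lambda,
#'   `dhdl_mean`, `dhdl_err`, `occupancy_coupled`), `dg` (forward estimate),
#'   `dg_err` (quadrature-combined window errors), `dg_backward`,
#'   `hysteresis`, `series` (per-window `aeds_energy_series`, forward) and
#'   `protocol`.
#' @export
run_ti_aeds <- function(system, reference, protocol, seed = NULL,
                        config = simulation_config(), init = c(0, 0)) {
  stopifnot(inherits(protocol, "aeds_lambda_protocol"))
  if (!is.null(seed)) set.seed(seed)
  lambdas <- protocol$lambdas
  fwd <- bwd <- NULL
  if (protocol$direction %in% c("forward", "both")) {
    fwd <- run_ti_direction(system, reference, protocol, config, lambdas, init)
  }
  if (protocol$direction %in% c("backward", "both")) {
    binit <- if (is.null(fwd)) init else fwd$final
    bwd <- run_ti_direction(system, reference, protocol, config, rev(lambdas),
                            binit)
    bwd$table <- dplyr::arrange(bwd$table, .data$lambda)
  }
  main <- fwd %||% bwd
  dg <- ti_integrate(main$table$lambda, main$table$dhdl_mean)
  dg_err <- ti_error(main$table$lambda, main$table$dhdl_err)
  dg_b <- if (!is.null(bwd) && !is.null(fwd))
    ti_integrate(bwd$table$lambda, bwd$table$dhdl_mean) else NA_real_
  structure(list(table = main$table, backward_table = if (!is.null(fwd)) bwd$table,
                 dg = dg, dg_err = dg_err, dg_backward = dg_b,
                 hysteresis = if (is.na(dg_b)) NA_real_ else abs(dg - dg_b),
                 series = main$series, protocol = protocol,
                 reference = reference),
            class = "aeds_ti_result")
}

## Propagate per-window standard errors through the trapezoid weights.
ti_error <- function(lambdas, errs) {
  if (anyNA(errs)) return(NA_real_)
  n <- length(lambdas)
  w <- numeric(n)
  dl <- diff(lambdas)
  w[1] <- dl[1] / 2; w[n] <- dl[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (dl[-length(dl)] + dl[-1]) / 2
  sqrt(sum((w * errs)^2))
}

#' @export
print.aeds_ti_result <- function(x, ...) {
  cat(sprintf("<aeds_ti_result> %d windows, dG = %.3f +/- %.3f kJ/mol",
              nrow(x$table), x$dg, x$dg_err))
  if (!is.na(x$hysteresis)) {
    cat(sprintf(" (backward %.3f, hysteresis %.3f)", x$dg_backward, x$hysteresis))
  }
  cat("\n")
  invisible(x)
}

#' One-step-perturbation legs at the TI endpoints
#'
#' From the lambda = 0 and lambda = 1 reference-ensemble series, computes the
#' four free-energy legs from the AEDS reference state to each end state
#' (`R -> state` at each endpoint) by exponential averaging, with reliability
#' flags for legs whose target state was essentially never sampled.
#'
#' @param ts0,ts1 `aeds_energy_series` at lambda = 0 and lambda = 1.
#' @param reliable_min Reliability threshold on the target-state occupancy.
#' @return Tibble with columns `lambda`, `state`, `dg`, `err`, `reliable`,
#'   `fraction`; `dg` is the free energy of R -> state, kJ/mol.
#' @export
endpoint_legs <- function(ts0, ts1, reliable_min = 0.01) {
  one <- function(ts, lam) {
    labels <- series_labels(ts)
    purrr::map_dfr(labels, function(s) {
      o <- osp_free_energy(ts, s, reliable_min = reliable_min)
      tibble::tibble(lambda = lam, state = s, dg = o$dg, err = o$err,
                     reliable = o$reliable, fraction = o$fraction)
    })
  }
  dplyr::bind_rows(one(ts0, 0), one(ts1, 1))
}

#' Reweighted dH/dlambda profile for a fixed-state path
#'
#' Predicts the TI profile of a path that was not directly simulated — the
#' probed molecule held in one fixed end state — from the TI--AEDS windows, by
#' reweighting the fixed-state lambda-derivative with
#' `exp(-(H_state - E_R*)/RT)` (the common system terms cancel in the weight).
#' Windows whose Kish effective sample size falls below `min_ess` are flagged
#' degenerate; if any window is degenerate the integrated dG is withheld
#' (`NA`).
#'
#' @param ti An `aeds_ti_result` with stored per-window series.
#' @param state Target end state (label or index).
#' @param min_ess Minimum effective sample size per window.
#' @return List with `table` (lambda, `dhdl_mean`, `dhdl_err`, `ess`,
#'   `degenerate`), `dg` and `err` (kJ/mol, NA when any window is degenerate)
#'   and `state`.
#' @export
reweighted_profile <- function(ti, state, min_ess = 20) {
  stopifnot(inherits(ti, "aeds_ti_result"))
  rows <- purrr::map_dfr(ti$series, function(ts) {
    labels <- series_labels(ts)
    s <- if (is.character(state)) match(state, labels) else state
    RT <- attr(ts, "RT")
    h_s <- ts[[paste0("H_", labels[s])]]
    x <- ts$dHs_dl + ts[[paste0("dH_", labels[s], "_dl")]]
    rw <- tryCatch(reweight_expectation(x, h_s, ts$E_R_star, RT),
                   aedskit_degeneracy_error = function(e)
                     list(mean = NA_real_, ess = 0, n = nrow(ts)))
    ## block error of the reweighted window mean
    n <- nrow(ts); nb <- 10L
    err <- NA_real_
    if (is.finite(rw$mean) && n >= 2L * nb) {
      grp <- cut(seq_len(n), nb, labels = FALSE)
      bm <- vapply(seq_len(nb), function(b) {
        i <- grp == b
        tryCatch(reweight_expectation(x[i], h_s[i], ts$E_R_star[i], RT)$mean,
                 aedskit_degeneracy_error = function(e) NA_real_)
      }, numeric(1))
      if (!anyNA(bm)) err <- sd(bm) / sqrt(nb)
    }
    tibble::tibble(lambda = attr(ts, "lambda"), dhdl_mean = rw$mean,
                   dhdl_err = err, ess = rw$ess)
  })
  rows$degenerate <- !is.finite(rows$dhdl_mean) | rows$ess < min_ess
  degen <- any(rows$degenerate)
  dg <- if (degen) NA_real_ else ti_integrate(rows$lambda, rows$dhdl_mean)
  err <- if (degen) NA_real_ else ti_error(rows$lambda, rows$dhdl_err)
  list(table = rows, dg = dg, err = err,
       state = if (is.character(state)) state else
         series_labels(ti$series[[1]])[state])
}

#' Linear offset schedules from endpoint offsets
#'
#' When the offsets that enforce sampling of both probed states differ between
#' the two endpoint environments, the offset must change across the lambda
#' windows. This builds, per state, the linear interpolation
#' `offset(lambda) = S lambda + b` with `b = offset(0)` and
#' `S = offset(1) - offset(0)`.
#'
#' @param offsets0 Named offsets searched at lambda = 0, kJ/mol.
#' @param offsets1 Offsets searched at lambda = 1 (same states).
#' @return List of [offset_schedule()]s in the order of `offsets0`.
#' @export
build_offset_schedule <- function(offsets0, offsets1) {
  stopifnot(length(offsets0) == length(offsets1))
  if (!is.null(names(offsets0)) && !is.null(names(offsets1))) {
    offsets1 <- offsets1[names(offsets0)]
  }
  purrr::map2(as.numeric(offsets0), as.numeric(offsets1),
              function(b, o1) offset_schedule(S = o1 - b, b = b))
}
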