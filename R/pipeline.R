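#' Single-state variant of a toy system
#'
#' Collapses a multi-end-state toy system to one fixed end state (for plain-TI
#' comparison runs in which the probed molecule is held coupled or dummy).
#'
#' @param system An [toy_system()].
#' @param state State label or index to keep.
#' @return An [toy_system()] with a single end state.
#' @export
fixed_state_system <- function(system, state) {
  if (is.character(state)) state <- match(state, system$states$label)
  stopifnot(!is.na(state))
  toy_system(system$states[state, , drop = FALSE],
             well_width = system$well_width, restraint = system$restraint,
             ligand = system$ligand, domain = system$domain)
}

#' Plain TI run with the probed molecule in a fixed state
#'
#' Thermodynamic integration over the system morph with the probed molecule
#' held in one end state throughout (single-state reference, no boost).
#'
#' @inheritParams run_ti_aeds
#' @param state State label or index to hold fixed.
#' @return An `aeds_ti_result`.
#' @export
run_fixed_state_ti <- function(system, state, protocol, seed = NULL,
                               config = simulation_config(),
                               temperature = 300) {
  sub <- fixed_state_system(system, state)
  ref <- toy_reference(sub, temperature = temperature)
  run_ti_aeds(sub, ref, protocol, seed = seed, config = config)
}

#' Full TI--AEDS cycle study on a pocket fixture
#'
#' Runs the complete coupled workflow on a pocket system with one switchable
#' probed particle and a ligand morph A -> B:
#' \enumerate{
#'   \item search energy offsets (and acceleration parameters) at the two
#'     endpoints lambda = 0 and lambda = 1;
#'   \item build linear offset schedules from the endpoint offsets and take
#'     the widest acceleration range seen, so both probed states stay sampled
#'     at every lambda window;
#'   \item run TI--AEDS over the lambda protocol (the direct reference-state
#'     path A,R -> B,R);
#'   \item compute the four one-step-perturbation endpoint legs
#'     (R -> coupled and R -> dummy at each endpoint);
#'   \item predict the two fixed-state paths (always-coupled, always-dummy)
#'     by exponential reweighting of the TI--AEDS windows;
#'   \item assemble the six-node free-energy graph (ligand A/B x water
#'     coupled/reference/dummy) and evaluate the three thermodynamic cycle
#'     closures.
#' }
#'
#' @param pocket A list with `system` and `reference` as returned by
#'   [make_pocket_probe_system()].
#' @param seed Integer seed governing the whole study.
#' @param protocol [lambda_protocol()] for the TI--AEDS run.
#' @param search_steps Steps per endpoint search run.
#' @param config Base [simulation_config()].
#' @return An `aeds_cycle_study` list: `offsets0`, `offsets1`, `accel`,
#'   `schedules`, `ti` (the TI--AEDS `aeds_ti_result`), `legs` (endpoint OSP
#'   legs), `reweighted` (fixed-state path predictions), `edges`
#'   (`aeds_cycle_report`), `closures` (tibble of the three named cycles) and
#'   `max_closure` (kJ/mol).
#' @export
run_cycle_study <- function(pocket, seed = 1L,
                            protocol = lambda_protocol(n_windows = 41L,
                                                       n_steps = 2e4,
                                                       n_equil = 2000L,
                                                       direction = "forward"),
                            search_steps = 2e5,
                            config = simulation_config()) {
  system <- pocket$system
  temperature <- pocket$reference$temperature

  ## 1. endpoint searches
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, 4L)
  base_ref <- toy_reference(system, temperature = temperature)
  sc <- simulation_config(mode = config$mode, n_steps = search_steps,
                          step_size = config$step_size,
                          temperature = temperature, seed = seeds[1],
                          save_interval = config$save_interval,
                          burn_in = config$burn_in)
  s0 <- search_run(system, base_ref, sc, lambda = 0)
  sc$seed <- seeds[2]
  s1 <- search_run(system, base_ref, sc, lambda = 1)

  ## 2. schedules + widened acceleration range
  schedules <- build_offset_schedule(s0$offsets, s1$offsets)
  accel <- accel_params(min(s0$accel$e_min, s1$accel$e_min),
                        max(s0$accel$e_max, s1$accel$e_max))
  ref <- toy_reference(system, offsets = schedules,
                       temperature = temperature, accel = accel)

  ## 3. TI--AEDS over the protocol
  ti <- run_ti_aeds(system, ref, protocol, seed = seeds[3], config = config)

  ## 4. endpoint OSP legs
  n_win <- length(ti$series)
  legs <- endpoint_legs(ti$series[[1]], ti$series[[n_win]])

  ## 5. reweighted fixed-state paths
  rw_c <- reweighted_profile(ti, "coupled")
  rw_d <- reweighted_profile(ti, "dummy")

  ## 6. cycle graph and closures
  leg <- function(lam, st) legs[legs$lambda == lam & legs$state == st, ]
  edges <- tibble::tibble(
    from = c("AR", "AW", "AD", "AW", "AR", "BW", "BR"),
    to = c("BR", "BW", "BD", "AR", "AD", "BR", "BD"),
    dg = c(ti$dg, rw_c$dg, rw_d$dg,
           -leg(0, "coupled")$dg, leg(0, "dummy")$dg,
           -leg(1, "coupled")$dg, leg(1, "dummy")$dg),
    err = c(ti$dg_err, rw_c$err, rw_d$err,
            leg(0, "coupled")$err, leg(0, "dummy")$err,
            leg(1, "coupled")$err, leg(1, "dummy")$err),
    source = c("simulated", "reweighted", "reweighted",
               "osp", "osp", "osp", "osp"),
    reliable = c(TRUE, !any(rw_c$table$degenerate), !any(rw_d$table$degenerate),
                 leg(0, "coupled")$reliable, leg(0, "dummy")$reliable,
                 leg(1, "coupled")$reliable, leg(1, "dummy")$reliable))
  report <- cycle_report(edges)
  gv <- function(from, to) {
    i <- which(edges$from == from & edges$to == to)[1]
    edges$dg[i]
  }
  closures <- tibble::tibble(
    cycle = c("W-R (upper)", "full (outer)", "R-D (lower)"),
    closure = c(
      gv("AW", "BW") + gv("BW", "BR") - gv("AR", "BR") - gv("AW", "AR"),
      gv("AW", "BW") + gv("BW", "BR") + gv("BR", "BD") -
        gv("AD", "BD") - gv("AR", "AD") - gv("AW", "AR"),
      gv("AR", "BR") + gv("BR", "BD") - gv("AD", "BD") - gv("AR", "AD")))
  structure(list(offsets0 = s0$offsets, offsets1 = s1$offsets, accel = accel,
                 schedules = schedules, ti = ti, legs = legs,
                 reweighted = list(coupled = rw_c, dummy = rw_d),
                 edges = report, closures = closures,
                 max_closure = max(abs(closures$closure))),
            class = "aeds_cycle_study")
}

#' @export
print.aeds_cycle_study <- function(x, ...) {
  cat("<aeds_cycle_study>\n")
  cat(sprintf("  endpoint offsets (coupled, dummy): lambda 0: %s; lambda 1: %s\n",
              paste(sprintf("%.2f", x$offsets0), collapse = ", "),
              paste(sprintf("%.2f", x$offsets1), collapse = ", ")))
  cat(sprintf("  acceleration: E_min = %.2f, E_max = %.2f kJ/mol\n",
              x$accel$e_min, x$accel$e_max))
  cat(sprintf("  direct A,R -> B,R: %.3f +/- %.3f kJ/mol\n",
              x$ti$dg, x$ti$dg_err))
  print(x$closures)
  cat(sprintf("  max |closure| = %.3f kJ/mol\n", x$max_closure))
  invisible(x)
}
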