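#' Analytic restraint-release correction
#'
#' Free energy of releasing a decoupled molecule held by a harmonic distance
#' restraint (reference distance 0, force constant K) into a site volume at
#' bulk density:
#' \deqn{\Delta G = -RT \ln\left[\frac{(2\pi RT/K)^{3/2}}{V_{site}}\right],}
#' where `(2 pi RT / K)^{3/2}` is the configurational volume of the restraint
#' (the radial integral `int_0^inf 4 pi r^2 exp(-K r^2 / 2RT) dr`). The value
#' is positive for restraints stiffer than the site volume, and its magnitude
#' grows with K. Sign convention: this is the contribution *added* to a
#' removal-direction leg in which the restrained, decoupled molecule is
#' transferred to the bulk standard state.
#'
#' @param K Restraint force constant, kJ/mol/nm^2 (> 0).
#' @param temperature Temperature, K (> 0).
#' @param v_site Standard-state site volume, nm^3 (> 0); default the volume of
#'   one SPC water molecule at bulk density, 3.0777e-2 nm^3.
#' @return Correction in kJ/mol.
#' @export
restraint_release_correction <- function(K, temperature = 300,
                                         v_site = 3.0777e-2) {
  if (any(c(K, temperature, v_site) <= 0)) {
    abort("`K`, `temperature` and `v_site` must be positive.",
          class = "aedskit_parameter_error")
  }
  RT <- rt_kj(temperature)
  -RT * (1.5 * log(2 * pi * RT / K) - log(v_site))
}

#' Bulk-water transfer term
#'
#' For each probed water molecule removed from the binding site by the
#' alchemical perturbation, the free energy of removing one such molecule from
#' bulk water is added to the relative binding free energy, closing the cycle
#' through the bulk reservoir.
#'
#' @param n_waters Number of perturbed water molecules (>= 0).
#' @param dg_hyd_water Free energy of removing one water molecule from bulk,
#'   kJ/mol (default 26.8, the SPC value; sign is the removal direction).
#' @return `n_waters * dg_hyd_water`, kJ/mol.
#' @export
bulk_transfer_term <- function(n_waters, dg_hyd_water = 26.8) {
  stopifnot(n_waters >= 0)
  n_waters * dg_hyd_water
}

#' Assemble a relative binding free energy
#'
#' `ddG = dG_bound - dG_free + sum(corrections)`, with every term itemized and
#' the errors of the two legs and of any correction errors combined in
#' quadrature (legs assumed independent).
#'
#' @param dg_bound,dg_free The two alchemical legs: either numbers, or lists
#'   with elements `dg` and `err` (as returned by [run_ti_aeds()] fields or
#'   [osp_free_energy()]).
#' @param corrections Named numeric vector (or list) of analytic correction
#'   terms, kJ/mol.
#' @return An `aeds_ddg` list: `ddg`, `err`, and a `terms` tibble with the
#'   full provenance trail.
#' @export
assemble_relative_binding <- function(dg_bound, dg_free, corrections = NULL) {
  as_leg <- function(x, what) {
    if (is.null(x)) {
      abort(sprintf("Missing leg `%s`.", what), class = "aedskit_state_error")
    }
    if (is.numeric(x)) list(dg = x, err = 0)
    else list(dg = x$dg, err = x$err %||% 0)
  }
  b <- as_leg(dg_bound, "dg_bound"); f <- as_leg(dg_free, "dg_free")
  corr <- if (is.null(corrections)) numeric(0) else unlist(corrections)
  if (length(corr) && is.null(names(corr))) {
    names(corr) <- paste0("correction_", seq_along(corr))
  }
  terms <- tibble::tibble(
    term = c("dg_bound", "-dg_free", names(corr)),
    value = c(b$dg, -f$dg, as.numeric(corr)),
    err = c(b$err %||% 0, f$err %||% 0, rep(0, length(corr))))
  structure(list(ddg = sum(terms$value),
                 err = sqrt(sum(terms$err^2, na.rm = TRUE)),
                 terms = terms),
            class = "aeds_ddg")
}

#' @export
print.aeds_ddg <- function(x, ...) {
  cat(sprintf("<aeds_ddg> ddG = %.3f +/- %.3f kJ/mol\n", x$ddg, x$err))
  for (i in seq_len(nrow(x$terms))) {
    cat(sprintf("  %-14s %8.3f\n", x$terms$term[i], x$terms$value[i]))
  }
  invisible(x)
}

#' Build a thermodynamic-cycle report
#'
#' @param edges Tibble (or data frame) with columns `from`, `to`, `dg`, and
#'   optionally `err` (default 0), `source` (free tag: simulated, reweighted,
#'   osp, ...) and `reliable` (default `TRUE`).
#' @return An `aeds_cycle_report` holding the directed free-energy graph.
#' @export
cycle_report <- function(edges) {
  edges <- tibble::as_tibble(edges)
  stopifnot(all(c("from", "to", "dg") %in% names(edges)))
  if (!"err" %in% names(edges)) edges$err <- 0
  if (!"source" %in% names(edges)) edges$source <- "simulated"
  if (!"reliable" %in% names(edges)) edges$reliable <- TRUE
  structure(list(edges = edges), class = "aeds_cycle_report")
}

#' Cycle-closure errors of a free-energy graph
#'
#' Computes the signed sum of edge free energies around every independent
#' cycle of the graph (the fundamental cycles of a spanning tree), traversing
#' each edge with + in its stated direction and - against it. Exact,
#' thermodynamically consistent edges close at 0; the closure error of a
#' converged estimate is a convergence diagnostic. Edges flagged unreliable
#' are excluded unless `include_unreliable = TRUE`.
#'
#' @param report An [cycle_report()] (or a bare edge table).
#' @param include_unreliable Keep unreliable edges in the graph.
#' @return Tibble with one row per independent cycle: `cycle` (the node path),
#'   `closure` (kJ/mol) and `err` (quadrature-combined edge errors).
#' @export
cycle_closure <- function(report, include_unreliable = FALSE) {
  if (!inherits(report, "aeds_cycle_report")) report <- cycle_report(report)
  edges <- report$edges
  if (!include_unreliable) edges <- edges[edges$reliable, , drop = FALSE]
  if (nrow(edges) == 0L) {
    abort("No usable edges.", class = "aedskit_graph_error")
  }
  nodes <- unique(c(edges$from, edges$to))
  n <- length(nodes)
  fi <- match(edges$from, nodes); ti <- match(edges$to, nodes)

  ## BFS spanning tree from node 1; node potentials integrate tree-edge dGs
  pot <- rep(NA_real_, n); pot_var <- rep(NA_real_, n)
  pot[1] <- 0; pot_var[1] <- 0
  in_tree <- rep(FALSE, nrow(edges))
  queue <- 1L
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (e in seq_len(nrow(edges))) {
      if (in_tree[e]) next
      if (fi[e] == v && is.na(pot[ti[e]])) {
        pot[ti[e]] <- pot[v] + edges$dg[e]
        pot_var[ti[e]] <- pot_var[v] + edges$err[e]^2
        in_tree[e] <- TRUE; queue <- c(queue, ti[e])
      } else if (ti[e] == v && is.na(pot[fi[e]])) {
        pot[fi[e]] <- pot[v] - edges$dg[e]
        pot_var[fi[e]] <- pot_var[v] + edges$err[e]^2
        in_tree[e] <- TRUE; queue <- c(queue, fi[e])
      }
    }
  }
  if (anyNA(pot)) {
    abort("The free-energy graph is disconnected.",
          class = "aedskit_graph_error")
  }
  chords <- which(!in_tree)
  if (length(chords) == 0L) {
    abort("The graph contains no cycle.", class = "aedskit_graph_error")
  }
  ## closure of the fundamental cycle of each chord: the chord dG minus the
  ## potential difference accumulated along the tree path
  purrr::map_dfr(chords, function(e) {
    tibble::tibble(
      cycle = sprintf("%s -> %s (via tree)", edges$from[e], edges$to[e]),
      closure = edges$dg[e] - (pot[ti[e]] - pot[fi[e]]),
      err = sqrt(edges$err[e]^2 + pot_var[ti[e]] + pot_var[fi[e]]))
  })
}
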