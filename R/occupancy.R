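#' Fractional occupancy of the end states
#'
#' Turns an energy time series into per-state occupancy fractions. The
#' `weights` method (the default) averages the Boltzmann state weights of the
#' reference ensemble over frames — i.e. the weight each end state carries in
#' the energy of every configuration. The `argmin` method counts the frames
#' whose offset-corrected energy `H_i - dF_i` is lowest for state i.
#'
#' @param ts An `aeds_energy_series`.
#' @param offsets Energy offsets, kJ/mol (default: the series attribute).
#' @param RT Thermal energy (default: the series attribute).
#' @param method `"weights"` or `"argmin"`.
#' @param frame_dt Frame spacing in ps for lifetimes (default: inferred from
#'   the time column).
#' @return An `aeds_occupancy` object: a tibble with one row per state
#'   (columns `state`, `fraction`, `mean_lifetime_ps`, `n_dwells`), with the
#'   running-fraction convergence series and the method in attributes.
#' @export
occupancy_fractions <- function(ts, offsets = attr(ts, "offsets"),
                                RT = attr(ts, "RT"),
                                method = c("weights", "argmin"),
                                frame_dt = NULL) {
  method <- match.arg(method)
  if (is.null(ts) || nrow(ts) == 0L) {
    abort("Occupancy requires a non-empty series.", class = "aedskit_state_error")
  }
  labels <- series_labels(ts)
  if (length(offsets) != length(labels)) {
    abort("`offsets` must match the number of end states.",
          class = "aedskit_size_error")
  }
  H <- series_H(ts)
  n <- nrow(H)
  if (method == "weights") {
    Z <- -(sweep(H, 2, offsets)) / RT
    Z <- Z - apply(Z, 1, max)
    W <- exp(Z)
    W <- W / rowSums(W)
    fractions <- colMeans(W)
    running <- apply(W, 2, cumsum) / seq_len(n)
  } else {
    visited <- assign_visited_state(H, offsets)
    W <- outer(visited, seq_along(labels), `==`) + 0
    fractions <- colMeans(W)
    running <- apply(W, 2, cumsum) / seq_len(n)
  }
  visited <- assign_visited_state(H, offsets)
  if (is.null(frame_dt)) {
    frame_dt <- if ("time_ps" %in% names(ts) && n > 1L)
      ts$time_ps[2L] - ts$time_ps[1L] else 1
  }
  lt <- state_lifetimes(visited, frame_dt, n_states = length(labels))
  out <- tibble::tibble(state = labels, fraction = as.numeric(fractions),
                        mean_lifetime_ps = lt$mean_lifetime_ps,
                        n_dwells = lt$n_dwells)
  colnames(running) <- labels
  structure(out, class = c("aeds_occupancy", class(out)),
            method = method, running = tibble::as_tibble(as.data.frame(running)),
            frame_dt = frame_dt, n_frames = n)
}

#' Mean state lifetimes from a visited-state series
#'
#' Mean length of the maximal constant runs of each state, in ps. The first
#' and last runs are censored (their true length is unknown) and excluded;
#' states without a single completed dwell get `NA` with `n_dwells = 0`.
#'
#' @param visited Integer series of visited-state indices.
#' @param frame_dt Frame spacing, ps.
#' @param n_states Number of states (default: `max(visited)`).
#' @return Tibble with columns `state_index`, `mean_lifetime_ps`, `n_dwells`.
#' @export
state_lifetimes <- function(visited, frame_dt = 1, n_states = max(visited)) {
  r <- rle(as.integer(visited))
  k <- length(r$lengths)
  if (k > 2L) {
    lens <- r$lengths[2:(k - 1L)]
    vals <- r$values[2:(k - 1L)]
  } else {
    lens <- integer(0); vals <- integer(0)
  }
  tibble::tibble(
    state_index = seq_len(n_states),
    mean_lifetime_ps = vapply(seq_len(n_states), function(s) {
      if (any(vals == s)) mean(lens[vals == s]) * frame_dt else NA_real_
    }, numeric(1)),
    n_dwells = vapply(seq_len(n_states), function(s) sum(vals == s), integer(1)))
}

#' One-step-perturbation free energy from the reference ensemble
#'
#' Exponential-averaging (Zwanzig) estimate of the free-energy difference
#' between the boosted reference state and end state i,
#' `dF(R* -> i) = -RT log < exp(-(H_i - E_R*)/RT) >`, over the frames of a
#' reference-ensemble series. The estimate is flagged unreliable when the
#' target state's weight-method occupancy falls below `reliable_min`
#' (default 1%): when a state is essentially never sampled its exponential
#' average is dominated by rare frames and cannot be trusted.
#'
#' @param ts An `aeds_energy_series` sampled from the boosted reference.
#' @param state State label or index.
#' @param offsets,RT As in [occupancy_fractions()].
#' @param reliable_min Minimum weight-method fraction for a reliable estimate.
#' @param n_blocks Blocks for the error estimate.
#' @return A list with `dg` (kJ/mol), `err` (block standard error), `reliable`
#'   (logical) and `fraction` (the target state's occupancy).
#' @export
osp_free_energy <- function(ts, state, offsets = attr(ts, "offsets"),
                            RT = attr(ts, "RT"), reliable_min = 0.01,
                            n_blocks = 10L) {
  if (is.null(ts) || nrow(ts) == 0L) {
    abort("OSP requires a non-empty series.", class = "aedskit_state_error")
  }
  labels <- series_labels(ts)
  if (is.character(state)) state <- match(state, labels)
  stopifnot(!is.na(state), state >= 1L, state <= length(labels))
  h_i <- ts[[paste0("H_", labels[state])]]
  du <- h_i - ts$E_R_star
  dg <- -RT * logmeanexp(-du / RT)
  frac <- occupancy_fractions(ts, offsets = offsets, RT = RT,
                              method = "weights")$fraction[state]
  ## block error propagated through the log of the exponential average
  n <- nrow(ts)
  err <- NA_real_
  if (n >= 2L * n_blocks) {
    blocks <- split(du, cut(seq_len(n), n_blocks, labels = FALSE))
    bvals <- vapply(blocks, function(d) -RT * logmeanexp(-d / RT), numeric(1))
    err <- sd(bvals) / sqrt(length(bvals))
  }
  list(dg = dg, err = err, reliable = frac >= reliable_min, fraction = frac)
}

#' Reweighted expectation over a non-simulated ensemble
#'
#' Predicts the expectation of a property X in target ensemble y from frames
#' of the reference ensemble R by exponential reweighting,
#' \deqn{\langle X \rangle_y = \frac{\langle X e^{-(V_y - V_R)/RT}\rangle_R}
#'   {\langle e^{-(V_y - V_R)/RT}\rangle_R},}
#' evaluated overflow-safely. The Kish effective sample size of the weights is
#' reported as a degeneracy diagnostic.
#'
#' @param x Property series.
#' @param v_y Target-ensemble energy series, kJ/mol.
#' @param v_r Reference-ensemble energy series, kJ/mol.
#' @param RT Thermal energy, kJ/mol.
#' @return List with `mean` (the reweighted expectation), `ess` (Kish
#'   effective sample size) and `n`.
#' @export
reweight_expectation <- function(x, v_y, v_r, RT) {
  n <- length(x)
  if (length(v_y) != n || length(v_r) != n || n == 0L) {
    abort("`x`, `v_y`, `v_r` must be non-empty and of equal length.",
          class = "aedskit_size_error")
  }
  lw <- -(v_y - v_r) / RT
  lw <- lw - max(lw)
  w <- exp(lw)
  sw <- sum(w)
  if (!is.finite(sw) || sw == 0) {
    abort("All reweighting weights underflow; the ensembles do not overlap.",
          class = "aedskit_degeneracy_error")
  }
  list(mean = sum(w * x) / sw, ess = sw^2 / sum(w^2), n = n)
}

#' Block-averaging standard error
#'
#' Standard error of the mean estimated from `n_blocks` contiguous block
#' means; robust to the short-range autocorrelation of Monte Carlo series.
#'
#' @param series Numeric series.
#' @param n_blocks Number of blocks (>= 2; series must be at least twice as
#'   long).
#' @return Standard error of the block means.
#' @export
block_error <- function(series, n_blocks = 10L) {
  n <- length(series)
  if (n_blocks < 2L || n < 2L * n_blocks) {
    abort("Series too short for the requested number of blocks.",
          class = "aedskit_size_error")
  }
  means <- vapply(split(series, cut(seq_len(n), n_blocks, labels = FALSE)),
                  mean, numeric(1))
  sd(means) / sqrt(length(means))
}
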