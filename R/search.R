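#' Currently sampled end state
#'
#' The state with the lowest offset-corrected energy `H_i - dF_i` is taken to
#' be the one currently sampled. Ties break to the lowest index.
#'
#' @param H End-state energies, kJ/mol (vector, or a frames-by-states matrix).
#' @param offsets Energy offsets, kJ/mol.
#' @return Integer state index (or vector of indices for a matrix input).
#' @export
assign_visited_state <- function(H, offsets) {
  if (is.matrix(H)) {
    if (ncol(H) != length(offsets)) {
      abort("`offsets` must match the number of states.",
            class = "aedskit_size_error")
    }
    return(max.col(-sweep(H, 2, offsets), ties.method = "first"))
  }
  assert_finite(H, "H")
  if (length(H) != length(offsets)) {
    abort("`H` and `offsets` must have equal length.", class = "aedskit_size_error")
  }
  which.min(H - offsets)
}

#' Memory-decay window length
#'
#' Length (in steps) of the window used to estimate the energy offsets during
#' a search run, growing linearly from 500 steps at the start to 500,000 steps
#' at the end of the search, rounded to the nearest integer.
#'
#' @param step Current step (0 <= step <= total_steps).
#' @param total_steps Total search length in steps.
#' @param n_start,n_end Window lengths (steps) at the start and end of the
#'   search; defaults 500 and 500,000 (1 ps and 1 ns at a 2 fs step).
#' @return Window length in steps.
#' @examples
#' memory_length(0, 1e6)     # 500
#' memory_length(5e5, 1e6)   # 250250
#' @export
memory_length <- function(step, total_steps,
                          n_start = 500, n_end = 500000) {
  if (any(step < 0 | step > total_steps)) {
    abort("`step` must lie in [0, total_steps].",
          class = "aedskit_parameter_error")
  }
  round(n_start + (n_end - n_start) * step / total_steps)
}

#' Energy offsets from a window of frames
#'
#' Exponential-averaging estimate of the free-energy difference between each
#' accelerated end state and the accelerated reference state,
#' `dF_i = -RT log < exp(-(H_i - E_R*)/RT) >`, over the supplied window,
#' gauge-fixed so that `min(dF) = 0` (only offset differences matter).
#'
#' @param window An `aeds_energy_series` (or any data frame with `H_<label>`
#'   columns and `E_R_star`).
#' @param RT Thermal energy, kJ/mol (default: the series attribute).
#' @return Named numeric vector of offsets, kJ/mol, min 0.
#' @export
update_offsets <- function(window, RT = attr(window, "RT")) {
  if (is.null(window) || nrow(window) == 0L) {
    abort("Offset update requires a non-empty window.",
          class = "aedskit_state_error")
  }
  labels <- series_labels(window)
  H <- as.matrix(window[paste0("H_", labels)])
  setNames(offsets_from_matrix(H, window$E_R_star, RT), labels)
}

## Vector-level core of update_offsets.
offsets_from_matrix <- function(H, e_r_star, RT) {
  df <- vapply(seq_len(ncol(H)), function(i) {
    -RT * logmeanexp(-(H[, i] - e_r_star) / RT)
  }, numeric(1))
  df - min(df)
}

#' Acceleration parameters from a search trajectory
#'
#' `E_max` is the highest reference energy observed at a frame where the
#' visited state changes (a barrier crossing). `E_min` is, per visited state,
#' the mean reference energy plus one standard deviation, maximized over
#' states (so that the boost acts only above typical minimum-basin energies).
#' The returned parameters satisfy `E_min <= E_max` (clamped with a warning
#' otherwise).
#'
#' @param visited Integer series of visited-state indices.
#' @param e_r Reference-energy series, kJ/mol (same length).
#' @param min_frames_per_state Minimum frames per visited state for the
#'   fluctuation estimate (default 10).
#' @return An [accel_params()] object.
#' @export
update_acceleration <- function(visited, e_r, min_frames_per_state = 10L) {
  stopifnot(length(visited) == length(e_r))
  changes <- which(diff(visited) != 0L) + 1L
  if (length(changes) == 0L) {
    abort(paste("No crossing between end states observed; acceleration (or a",
                "longer search) is needed before E_max can be estimated."),
          class = "aedskit_no_crossing_error")
  }
  e_max <- max(e_r[changes])
  counts <- table(visited)
  ok <- as.integer(names(counts))[counts >= min_frames_per_state]
  if (length(ok) == 0L) ok <- as.integer(names(counts))
  e_min <- max(vapply(ok, function(s) {
    v <- e_r[visited == s]
    mean(v) + if (length(v) >= 2L) sd(v) else 0
  }, numeric(1)))
  if (e_min > e_max) {
    warn("Estimated E_min exceeded E_max; clamping E_min to E_max.",
         class = "aedskit_accel_clamp_warning")
    e_min <- e_max
  }
  accel_params(e_min, e_max)
}

#' Search acceleration parameters and energy offsets
#'
#' Alternates sampling of the (initially unboosted) reference ensemble with
#' parameter updates every `update_interval` steps: offsets from the
#' memory-decayed
#' window via [update_offsets()], the acceleration range from barrier
#' crossings and per-state reference-energy fluctuations via
#' [update_acceleration()]. Before any crossing has been observed, a bootstrap
#' acceleration range (running mean to running maximum of the reference
#' energy) is applied to induce crossings. Deterministic under a fixed seed.
#'
#' @param system An [toy_system()].
#' @param reference An `aeds_reference` without (or with initial)
#'   acceleration parameters; its offsets are ignored and re-estimated.
#' @param config An [simulation_config()]; `n_steps` is the total search
#'   length, the recorded series is thinned to every `save_interval` steps.
#' @param lambda Coupling parameter of the search (default 0).
#' @param monitor_interval Steps between recorded monitoring frames during
#'   the search (default 1: every step is monitored, so barrier crossings are
#'   seen at full resolution).
#' @param update_interval Steps between parameter updates (default 100).
#' @return List with `accel` ([accel_params()]), `offsets` (named vector,
#'   gauge min = 0), `diagnostics` (tibble of the offset/parameter convergence
#'   series) and `series` (the recorded `aeds_energy_series` of the search).
#' @export
search_run <- function(system, reference, config, lambda = 0,
                       monitor_interval = 1L, update_interval = 100L) {
  stopifnot(inherits(config, "aeds_sim_config"),
            monitor_interval >= 1L, update_interval >= monitor_interval)
  if (!is.null(config$seed)) set.seed(config$seed)
  n_states <- length(reference$end_states)
  labels <- reference$labels
  RT <- reference$RT
  i_er <- 3L + n_states
  i_estar <- 4L + n_states

  block_steps <- as.integer(update_interval)
  n_blocks <- ceiling(config$n_steps / block_steps)

  offsets <- setNames(rep(0, n_states), labels)
  accel <- reference$accel # may be NULL
  crossings_seen <- FALSE
  clamp_count <- 0L
  state <- c(0, 0)
  diag_rows <- vector("list", n_blocks)

  ## initial burn-in with tuning, unrecorded
  spec <- toy_sampler_spec(
    system, toy_reference(system, offsets = as.list(offsets),
                          temperature = reference$temperature, accel = accel),
    RT)
  dt <- if (config$mode == "langevin") config$step_size else 0
  tps <- if (config$mode == "langevin") config$step_size else
    config$time_per_step
  warm <- cpp_run_sampler(spec, lambda, as.integer(monitor_interval),
                          as.integer(monitor_interval),
                          max(config$burn_in, 1000L), config$step_size,
                          isTRUE(config$tune), config$mode, dt = dt,
                          gamma = config$friction, init = state,
                          time_per_step = tps)
  sigma <- warm$sigma
  state <- c(warm$x, warm$y)

  ## flat monitoring accumulators at full resolution
  frames_per_block <- block_steps %/% as.integer(monitor_interval)
  n_cap <- n_blocks * frames_per_block
  H_acc <- matrix(NA_real_, n_cap, n_states)
  er_acc <- rep(NA_real_, n_cap)
  estar_acc <- rep(NA_real_, n_cap)
  frame_acc <- matrix(NA_real_, n_cap, 2L * n_states + 9L)
  n_acc <- 0L
  max_avg_frames <- 25000L  # subsample cap for the exponential averages

  ## incremental per-block statistics of the visited-state assignment (made
  ## with the offsets live while each block was sampled) so that every update
  ## costs O(new frames), not O(window)
  blk_count <- matrix(0, n_blocks, n_states)
  blk_sum <- matrix(0, n_blocks, n_states)
  blk_sumsq <- matrix(0, n_blocks, n_states)
  cross_idx <- integer(0)
  cross_er <- numeric(0)
  last_visited <- NA_integer_

  for (b in seq_len(n_blocks)) {
    spec$offsets <- cbind(rep(0, n_states), unname(offsets))
    spec$accel <- if (is.null(accel)) numeric(0) else
      c(accel$e_min, accel$e_max, 1)
    out <- cpp_run_sampler(spec, lambda, block_steps,
                           as.integer(monitor_interval), 0L, sigma, FALSE,
                           config$mode, dt = dt, gamma = config$friction,
                           init = state, time_per_step = tps)
    state <- c(out$x, out$y)
    blk <- out$frames

    nb <- nrow(blk)
    idx <- n_acc + seq_len(nb)
    H_blk <- blk[, 2L + seq_len(n_states), drop = FALSE]
    er_blk <- blk[, i_er]
    H_acc[idx, ] <- H_blk
    er_acc[idx] <- er_blk
    estar_acc[idx] <- blk[, i_estar]
    frame_acc[idx, ] <- blk

    visited_blk <- assign_visited_state(H_blk, offsets)
    prev <- c(last_visited, visited_blk[-nb])
    is_cross <- !is.na(prev) & visited_blk != prev
    if (any(is_cross)) {
      cross_idx <- c(cross_idx, idx[is_cross])
      cross_er <- c(cross_er, er_blk[is_cross])
    }
    last_visited <- visited_blk[nb]
    for (s in seq_len(n_states)) {
      v <- er_blk[visited_blk == s]
      blk_count[b, s] <- length(v)
      blk_sum[b, s] <- sum(v)
      blk_sumsq[b, s] <- sum(v * v)
    }
    n_acc <- n_acc + nb

    step_now <- min(b * block_steps, config$n_steps)
    n_mem_steps <- memory_length(step_now, config$n_steps)
    n_mem_frames <- max(1L, round(n_mem_steps / monitor_interval))
    w0 <- max(1L, n_acc - n_mem_frames + 1L)
    wi <- seq.int(w0, n_acc)
    ai <- if (length(wi) > max_avg_frames) {
      wi[unique(round(seq(1L, length(wi), length.out = max_avg_frames)))]
    } else wi
    offsets <- setNames(
      offsets_from_matrix(H_acc[ai, , drop = FALSE], estar_acc[ai], RT),
      labels)

    ## acceleration range from window-scoped crossing and basin statistics
    b0 <- max(1L, b - ceiling(n_mem_frames / frames_per_block) + 1L)
    in_win <- cross_idx >= w0
    if (any(in_win)) {
      e_max <- max(cross_er[in_win])
      brange <- seq.int(b0, b)
      cnt <- colSums(blk_count[brange, , drop = FALSE])
      ok <- which(cnt >= 10)
      if (length(ok) == 0L) ok <- which(cnt > 0)
      e_min <- max(vapply(ok, function(s) {
        n <- cnt[s]
        m <- sum(blk_sum[brange, s]) / n
        ssq <- sum(blk_sumsq[brange, s])
        v <- if (n >= 2) max(0, (ssq - n * m * m) / (n - 1)) else 0
        m + sqrt(v)
      }, numeric(1)))
      if (e_min > e_max) {
        clamp_count <- clamp_count + 1L
        e_min <- e_max
      }
      accel <- accel_params(e_min, e_max)
      crossings_seen <- TRUE
    } else if (!crossings_seen) {
      ## bootstrap: flatten everything above the typical energy to force
      ## crossings until the first one is seen
      win_er <- er_acc[wi]
      e_lo <- mean(win_er)
      e_hi <- max(win_er) + RT
      if (e_hi > e_lo) accel <- accel_params(e_lo, e_hi)
    }
    diag_rows[[b]] <- tibble::tibble(
      step = step_now, n_mem = n_mem_steps,
      e_min = if (is.null(accel)) NA_real_ else accel$e_min,
      e_max = if (is.null(accel)) NA_real_ else accel$e_max,
      !!!setNames(as.list(offsets), paste0("offset_", labels)))
  }
  if (clamp_count > 0L) {
    warn(sprintf(paste("Estimated E_min exceeded E_max in %d of %d updates;",
                       "E_min was clamped to E_max there."),
                 clamp_count, n_blocks))
  }

  ## thin the recorded series to the configured save interval
  keep <- seq.int(1L, n_acc,
                  by = max(1L, config$save_interval %/% monitor_interval))
  ts <- tibble::as_tibble(as.data.frame(frame_acc[keep, , drop = FALSE]))
  names(ts) <- c("time_ps", "lambda", paste0("H_", labels), "E_R", "E_R_star",
                 "V_restraint", "dHs_dl", paste0("dH_", labels, "_dl"),
                 "dHdl", "x", "y")
  series <- new_energy_series(ts, labels = labels,
                              offsets = offsets, RT = RT, accel = accel,
                              lambda = lambda)
  list(accel = accel, offsets = offsets,
       diagnostics = dplyr::bind_rows(diag_rows), series = series,
       sigma = sigma)
}
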