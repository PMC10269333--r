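#' Tidy a TI result
#'
#' @param x An `aeds_ti_result`.
#' @param ... Unused.
#' @return Tibble with one row per lambda window: `lambda`, `dhdl_mean`,
#'   `dhdl_err`, `occupancy_coupled`.
#' @export
tidy.aeds_ti_result <- function(x, ...) x$table

#' One-row summary of a TI result
#'
#' @param x An `aeds_ti_result`.
#' @param ... Unused.
#' @return Tibble with `dg`, `dg_err`, `dg_backward`, `hysteresis`,
#'   `n_windows`.
#' @export
glance.aeds_ti_result <- function(x, ...) {
  tibble::tibble(dg = x$dg, dg_err = x$dg_err, dg_backward = x$dg_backward,
                 hysteresis = x$hysteresis, n_windows = nrow(x$table))
}

#' Tidy an occupancy report
#'
#' @param x An `aeds_occupancy`.
#' @param ... Unused.
#' @return Tibble with `state`, `fraction`, `mean_lifetime_ps`, `n_dwells`.
#' @export
tidy.aeds_occupancy <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("state", "fraction", "mean_lifetime_ps",
                                 "n_dwells")])
}

#' One-row summary of an occupancy report
#'
#' @param x An `aeds_occupancy`.
#' @param ... Unused.
#' @return Tibble with `method`, `n_frames`, `n_states` and the fraction of
#'   the first (coupled) state.
#' @export
glance.aeds_occupancy <- function(x, ...) {
  tibble::tibble(method = attr(x, "method"), n_frames = attr(x, "n_frames"),
                 n_states = nrow(x), fraction_coupled = x$fraction[1])
}

#' Tidy a cycle study
#'
#' @param x An `aeds_cycle_study`.
#' @param ... Unused.
#' @return The edge table of the free-energy graph.
#' @export
tidy.aeds_cycle_study <- function(x, ...) x$edges$edges

#' One-row summary of a cycle study
#'
#' @param x An `aeds_cycle_study`.
#' @param ... Unused.
#' @return Tibble with the direct-path dG, its error and the maximum absolute
#'   cycle closure.
#' @export
glance.aeds_cycle_study <- function(x, ...) {
  tibble::tibble(dg_direct = x$ti$dg, dg_err = x$ti$dg_err,
                 max_closure = x$max_closure,
                 e_min = x$accel$e_min, e_max = x$accel$e_max)
}
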