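#' Plot a TI profile with per-window occupancy
#'
#' The mean dH/dlambda per lambda window with error bars, and the
#' coupled-state occupancy on a secondary panel-free scale (dashed, right
#' axis), mirroring the standard presentation of coupled TI--AEDS runs.
#'
#' @param object An `aeds_ti_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.aeds_ti_result <- function(object, ...) {
  tab <- object$table
  span <- max(abs(tab$dhdl_mean), 1)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$lambda)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$dhdl_mean), colour = "#d95f02") +
    ggplot2::geom_pointrange(ggplot2::aes(
      y = .data$dhdl_mean,
      ymin = .data$dhdl_mean - .data$dhdl_err,
      ymax = .data$dhdl_mean + .data$dhdl_err), size = 0.2,
      colour = "#d95f02") +
    ggplot2::geom_line(ggplot2::aes(y = .data$occupancy_coupled * span),
                       linetype = "dashed", colour = "#1f78b4") +
    ggplot2::scale_y_continuous(
      name = expression(paste(langle, partialdiff * H / partialdiff * lambda,
                              rangle, " (kJ/mol)")),
      sec.axis = ggplot2::sec_axis(~ . / span, name = "coupled occupancy")) +
    ggplot2::labs(x = expression(lambda)) +
    ggplot2::theme_minimal()
}

#' Plot occupancy convergence
#'
#' Running per-state occupancy fractions against frame index.
#'
#' @param object An `aeds_occupancy`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.aeds_occupancy <- function(object, ...) {
  running <- attr(object, "running")
  running$frame <- seq_len(nrow(running))
  long <- tidyr::pivot_longer(running, -"frame", names_to = "state",
                              values_to = "fraction")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$frame, y = .data$fraction,
                                     colour = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "frame", y = "running occupancy fraction") +
    ggplot2::theme_minimal()
}

#' Plot the boost transform
#'
#' The boosted reference energy and its slope over a range of input energies;
#' useful for inspecting searched acceleration parameters.
#'
#' @param accel An [accel_params()] object.
#' @param from,to Energy range to display, kJ/mol.
#' @return A ggplot object.
#' @export
plot_boost <- function(accel, from = NULL, to = NULL) {
  span <- max(accel$e_max - accel$e_min, 1)
  from <- from %||% (accel$e_min - span)
  to <- to %||% (accel$e_max + span)
  e <- seq(from, to, length.out = 400)
  b <- aeds_boost(e, accel)
  tab <- tibble::tibble(e_r = e, boosted = b$energy, identity = e)
  long <- tidyr::pivot_longer(tab, -"e_r", names_to = "curve",
                              values_to = "energy")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$e_r, y = .data$energy,
                                     linetype = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = c(accel$e_min, accel$e_max),
                        colour = "grey60", linetype = "dotted") +
    ggplot2::labs(x = expression(E[R] ~ "(kJ/mol)"),
                  y = expression(E[R]^"*" ~ "(kJ/mol)")) +
    ggplot2::theme_minimal()
}
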