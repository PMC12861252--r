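#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a drying simulation
#'
#' Moisture (wet basis) and center/surface temperature against time.
#'
#' @param object a `drying_result`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.drying_result <- function(object, ...) {
  s <- object$series
  long <- dplyr::bind_rows(
    tibble::tibble(time_h = s$time_h, value = s$yw_wb,
                   what = "moisture y_w (w.b.)"),
    tibble::tibble(time_h = s$time_h, value = s$T_center_C,
                   what = "T center (degC)"),
    tibble::tibble(time_h = s$time_h, value = s$T_surface_C,
                   what = "T surface (degC)")
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$time_h, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~what, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time (h)", y = NULL)
}

#' Plot radial profiles of a drying simulation
#'
#' Water-activity (or temperature / porosity) profiles at the stored
#' snapshot times, from the lamella face (r = 0) to the cap surface.
#'
#' @param result a `drying_result` run with `profile_times_h`.
#' @param var one of "aw", "T_C", "phi_air", "Xm_db".
#' @return a ggplot object.
#' @export
plot_profiles <- function(result, var = c("aw", "T_C", "phi_air", "Xm_db")) {
  var <- match.arg(var)
  p <- result$profiles
  if (nrow(p) == 0) stop("no stored profiles; rerun with profile_times_h")
  ggplot2::ggplot(p, ggplot2::aes(.data$r_m * 100, .data[[var]],
                                  colour = factor(.data$time_h))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "r (cm)", y = var, colour = "time (h)")
}

#' Plot a DVS run
#'
#' End-of-step moisture against relative humidity, one line per branch,
#' which makes sorption hysteresis directly visible.
#'
#' @param object a `dvs_result`.
#' @param ... unused.
#' @export
autoplot.dvs_result <- function(object, ...) {
  ggplot2::ggplot(object$steps,
                  ggplot2::aes(.data$RH, .data$Xm_end,
                               colour = .data$branch)) +
    ggplot2::geom_path() + ggplot2::geom_point() +
    ggplot2::labs(x = "relative humidity", y = "X_m at step end (d.b.)")
}

#' Plot a T2 spectrum
#'
#' @param object a `t2_spectrum`.
#' @param ... unused.
#' @export
autoplot.t2_spectrum <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$T2_ms, .data$amplitude)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "T2 (ms)", y = "amplitude")
}

#' Plot a membrane-state overlay
#'
#' Drying trajectory in the (moisture, temperature) plane with the
#' integrity classification of each sample point and the critical
#' thresholds marked.
#'
#' @param overlay tibble from [overlay_trajectory()].
#' @param T_crit,yw_crit thresholds to draw.
#' @export
plot_state_diagram <- function(overlay, T_crit = 40, yw_crit = 0.03) {
  ggplot2::ggplot(overlay,
                  ggplot2::aes(.data$yw, .data$Tp_C, colour = .data$state)) +
    ggplot2::geom_path(colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = T_crit, linetype = 2) +
    ggplot2::geom_vline(xintercept = yw_crit, linetype = 2) +
    ggplot2::labs(x = "moisture y_w (w.b.)", y = "T product (degC)")
}
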