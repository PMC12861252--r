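#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a calibration fit
#'
#' One row per fitted parameter, broom style.
#'
#' @param x a `mushdry_fit` from [sequential_search()], [fit_drying()]
#'   or [fit_sorption_factors()].
#' @param ... unused.
#' @return tibble with columns `term` and `estimate`.
#' @export
tidy.mushdry_fit <- function(x, ...) {
  tibble::tibble(term = names(x$par), estimate = unname(x$par))
}

#' @rdname tidy.mushdry_fit
#' @return `glance()`: one-row tibble with the objective value at the
#'   optimum, the evaluation count and (when available) the pooled
#'   moisture-curve fit statistics.
#' @export
glance.mushdry_fit <- function(x, ...) {
  out <- tibble::tibble(objective = x$value, n_eval = x$n_eval)
  if (!is.null(x$stats)) {
    out$R2_min <- min(x$stats$R2)
    out$RMSE_max <- max(x$stats$RMSE)
  }
  out
}

#' Tidy a drying simulation
#'
#' @param x a `drying_result`.
#' @param ... unused.
#' @return the `series` tibble.
#' @export
tidy.drying_result <- function(x, ...) x$series

#' @rdname tidy.drying_result
#' @export
glance.drying_result <- function(x, ...) {
  s <- x$series
  tibble::tibble(
    t_end_h = max(s$time_h),
    yw_final = s$yw_wb[nrow(s)],
    Xm_final = s$Xm_db[nrow(s)],
    T_center_final_C = s$T_center_C[nrow(s)],
    nsteps = x$nsteps,
    mass_closure_rel = x$balance$mass_closure_rel,
    energy_closure_rel = x$balance$energy_closure_rel
  )
}
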