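#' Read and write the tool's CSV interchange formats
#'
#' Plain-CSV schemas used by the command-line interface and for exchanging
#' results with other tools:
#' \itemize{
#'   \item experiment: `time_h, yw_wb, T_center_C` (optional
#'     `T_surface_C`)
#'   \item drying result series: `time_h, yw_wb, Xm_db, T_center_C,
#'     T_surface_C`
#'   \item DVS steps: `step, RH, Xm_end`
#'   \item CPMG decay: `t_ms, signal`
#'   \item T2 spectrum: `T2_ms, amplitude`
#'   \item conductivity contour (long format): `Tp_C, yw,
#'     conductivity_uS_cm`
#' }
#'
#' @param path CSV path.
#' @param ambient an [ambient_schedule()] to attach to the record.
#' @return `read_experiment()` an [experiment_record()]; the other
#'   readers a tibble.
#' @export
read_experiment <- function(path, ambient) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  experiment_record(df$time_h, df$yw_wb, df$T_center_C, ambient)
}

#' @rdname read_experiment
#' @param record an [experiment_record()].
#' @export
write_experiment <- function(record, path) {
  readr::write_csv(record$data, path)
  invisible(path)
}

#' @rdname read_experiment
#' @export
read_decay <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot(all(c("t_ms", "signal") %in% names(out)))
  class(out) <- c("cpmg_decay", class(out))
  out
}

#' @rdname read_experiment
#' @param result a `drying_result` (series written) or a tibble.
#' @export
write_series <- function(result, path) {
  ser <- if (inherits(result, "drying_result")) result$series else result
  readr::write_csv(ser, path)
  invisible(path)
}

#' @rdname read_experiment
#' @export
read_contour <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot(all(c("Tp_C", "yw", "conductivity_uS_cm") %in% names(out)))
  out
}
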