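#' Experiment record
#'
#' Measured drying curve used as a calibration target: sample times,
#' moisture (wet basis) and center temperature, together with the ambient
#' schedule under which it was collected.
#'
#' @param time_h sample times (h), strictly increasing.
#' @param yw_wb moisture content wet basis in (0, 1).
#' @param T_center_C product center temperature (degC); may contain NA.
#' @param ambient the matching [ambient_schedule()].
#' @param T_init_C initial product temperature; defaults to the first
#'   temperature sample.
#' @param T_air_C nominal air setpoint; defaults to the schedule maximum.
#' @return object of class `experiment_record`.
#' @export
experiment_record <- function(time_h, yw_wb, T_center_C, ambient,
                              T_init_C = T_center_C[1],
                              T_air_C = max(ambient$T_air_C)) {
  stopifnot(!is.unsorted(time_h, strictly = TRUE),
            all(yw_wb > 0), all(yw_wb < 1))
  if (abs(T_air_C - T_init_C) < 1e-9)
    stop("T_air equals T_init: temperature rescaling undefined")
  structure(
    list(data = tibble::tibble(time_h = time_h, yw_wb = yw_wb,
                               T_center_C = T_center_C),
         ambient = ambient, T_init_C = T_init_C, T_air_C = T_air_C),
    class = "experiment_record"
  )
}

#' Calibration objective: weighted least squares over experiments
#'
#' For each experiment sums the squared residuals of the rescaled
#' temperature Theta = (T_p - T_init)/(T_air - T_init) and of the
#' wet-basis moisture, each normalized by its number of data points, the
#' moisture term carrying a weight of 10:
#' \deqn{LSE_{sum} = \sum_i \Big[ \tfrac{1}{N_{T}}\sum_j
#'   (\Theta_{exp}-\Theta_{pred})^2 +
#'   \tfrac{10}{N_{y}}\sum_j (y_{exp}-y_{pred})^2 \Big]}
#' Simulated curves are interpolated linearly onto the experimental
#' sample times.
#'
#' @param experiments list of [experiment_record()]s.
#' @param simulations matching list of `drying_result`s (or their
#'   `series` tibbles).
#' @return scalar objective value, >= 0, zero iff a perfect match.
#' @export
objective_lse <- function(experiments, simulations) {
  stopifnot(length(experiments) == length(simulations))
  total <- 0
  for (i in seq_along(experiments)) {
    ex <- experiments[[i]]
    sim <- simulations[[i]]
    ser <- if (inherits(sim, "drying_result")) sim$series else sim
    y_pred <- stats::approx(ser$time_h, ser$yw_wb, xout = ex$data$time_h,
                            rule = 2)$y
    T_pred <- stats::approx(ser$time_h, ser$T_center_C,
                            xout = ex$data$time_h, rule = 2)$y
    den <- ex$T_air_C - ex$T_init_C
    keep <- !is.na(ex$data$T_center_C)
    theta_exp <- (ex$data$T_center_C[keep] - ex$T_init_C) / den
    theta_pred <- (T_pred[keep] - ex$T_init_C) / den
    n_T <- sum(keep)
    n_y <- nrow(ex$data)
    term_T <- if (n_T > 0) sum((theta_exp - theta_pred)^2) / n_T else 0
    term_y <- 10 * sum((ex$data$yw_wb - y_pred)^2) / n_y
    total <- total + term_T + term_y
  }
  total
}

#' Goodness-of-fit statistics
#'
#' @param observed,predicted numeric vectors of equal length >= 2.
#' @return tibble with `R2` (NA when the observations have zero
#'   variance), `RMSE` and `MAE`.
#' @export
#' @examples
#' fit_stats(c(0, 1), c(0.1, 0.9))
fit_stats <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 2)
  res <- observed - predicted
  ss_tot <- sum((observed - mean(observed))^2)
  tibble::tibble(
    R2 = if (ss_tot > 0) 1 - sum(res^2) / ss_tot else NA_real_,
    RMSE = sqrt(mean(res^2)),
    MAE = mean(abs(res))
  )
}

#' Sequential single-factor search
#'
#' Coordinate-descent grid search: cycles through the parameters, varying
#' one at a time over its candidate grid while holding the others at the
#' incumbent best, accepting the grid argmin, until a full cycle brings
#' no improvement. Repeated parameter vectors are cached so the
#' incumbent is never re-simulated.
#'
#' @param objective function taking a named numeric vector and returning
#'   a scalar; failures (errors/NaN) are skipped with a warning.
#' @param grids named list of candidate numeric grids.
#' @param start named start vector; defaults to the middle grid element
#'   of each parameter.
#' @param max_cycles cycle cap.
#' @param prescan if `TRUE`, evaluate the full factorial lattice of the
#'   grids first and start the cyclic refinement from its argmin. The
#'   single-factor cycle alone can stall in the curved valleys of
#'   strongly correlated parameters (e.g. a modulus-relaxation-time
#'   product); the pre-scan mechanizes the preliminary range study that
#'   seeds such fits. Only sensible when one evaluation is cheap.
#' @return object of class `mushdry_fit`: list with `par` (named best
#'   vector), `value`, `trace` (tibble of all evaluations) and
#'   `n_eval`.
#' @export
sequential_search <- function(objective, grids, start = NULL,
                              max_cycles = 25, prescan = FALSE) {
  stopifnot(length(grids) >= 1, !is.null(names(grids)))
  par <- if (is.null(start)) {
    vapply(grids, function(g) g[[ceiling(length(g) / 2)]], numeric(1))
  } else {
    start[names(grids)]
  }
  cache <- new.env(parent = emptyenv())
  n_eval <- 0L
  trace <- list()
  eval_pt <- function(p) {
    key <- paste(signif(p, 12), collapse = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- tryCatch(objective(p), error = function(e) {
      warning("objective failed at (", key, "): ", conditionMessage(e))
      NA_real_
    })
    if (is.nan(val)) val <- NA_real_
    n_eval <<- n_eval + 1L
    trace[[length(trace) + 1L]] <<-
      tibble::tibble(!!!as.list(p), value = val)
    cache[[key]] <- val
    val
  }
  best <- eval_pt(par)
  if (is.na(best)) best <- Inf
  if (isTRUE(prescan)) {
    lattice <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE)
    for (r in seq_len(nrow(lattice))) {
      p <- unlist(lattice[r, , drop = TRUE])
      v <- eval_pt(p)
      if (!is.na(v) && v < best) {
        best <- v
        par <- p
      }
    }
  }
  for (cycle in seq_len(max_cycles)) {
    improved <- FALSE
    for (nm in names(grids)) {
      vals <- vapply(grids[[nm]], function(g) {
        p <- par; p[nm] <- g
        v <- eval_pt(p)
        if (is.na(v)) Inf else v
      }, numeric(1))
      k <- which.min(vals)
      if (vals[k] < best - 1e-15) {
        best <- vals[k]
        par[nm] <- grids[[nm]][k]
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  structure(
    list(par = par, value = best, trace = dplyr::bind_rows(trace),
         n_eval = n_eval),
    class = "mushdry_fit"
  )
}

#' Refit the drying-model correction factors
#'
#' The calibration the drying experiments feed: sequential single-factor
#' search over the oven emissivity `e` and the convective and diffusive
#' correction factors `F_w_conv`, `F_w_diff`, minimizing
#' [objective_lse()] against the supplied experiment records.
#'
#' @param experiments list of [experiment_record()]s.
#' @param config base configuration (the searched parameters are
#'   overridden per evaluation).
#' @param grids candidate grids; the defaults span the physically
#'   expected ranges.
#' @param t_end_h simulated duration per experiment; defaults to each
#'   experiment's last sample time.
#' @param start optional named start vector.
#' @return `mushdry_fit` with elements `par` (e, F_w_conv, F_w_diff),
#'   `value`, `stats` (per-experiment R2/RMSE/MAE of moisture at the
#'   optimum) and the evaluation `trace`.
#' @export
fit_drying <- function(experiments, config = default_config(),
                       grids = list(
                         e = c(0.1, 0.3, 0.5, 0.7, 0.9),
                         F_w_conv = c(0.1, 0.2, 0.5, 1, 2, 5, 8, 10),
                         F_w_diff = c(0.1, 0.2, 0.5, 1, 2, 5, 8, 10)
                       ),
                       t_end_h = NULL, start = NULL) {
  ends <- if (is.null(t_end_h)) {
    vapply(experiments, function(e) max(e$data$time_h), numeric(1))
  } else {
    rep_len(t_end_h, length(experiments))
  }
  simulate_all <- function(p) {
    lapply(seq_along(experiments), function(i) {
      cfg <- config
      cfg$transport$emissivity <- p[["e"]]
      cfg$transport$F_w_conv <- p[["F_w_conv"]]
      cfg$transport$F_w_diff <- p[["F_w_diff"]]
      simulate_drying(cfg, experiments[[i]]$ambient, t_end_h = ends[i])
    })
  }
  obj <- function(p) objective_lse(experiments, simulate_all(p))
  fit <- sequential_search(obj, grids, start = start)
  sims <- simulate_all(fit$par)
  fit$stats <- dplyr::bind_rows(lapply(seq_along(experiments), function(i) {
    ex <- experiments[[i]]
    y_pred <- stats::approx(sims[[i]]$series$time_h, sims[[i]]$series$yw_wb,
                            xout = ex$data$time_h, rule = 2)$y
    dplyr::mutate(fit_stats(ex$data$yw_wb, y_pred), experiment = i,
                  .before = 1)
  }))
  fit$simulations <- sims
  fit
}

#' Stepped-RH dynamic vapor sorption protocol
#'
#' @param RH_steps ordered relative-humidity setpoints (descending =
#'   desorption, ascending = adsorption).
#' @param dwell_h dwell time per step (h).
#' @param T_C temperature (degC).
#' @param k_cond lumped mass-transfer conductance of the powder sample
#'   (m^3 kg^-1 s^-1), fixed from the approach rate of the first step.
#' @return list of class `dvs_protocol`.
#' @export
dvs_protocol <- function(RH_steps = c(seq(0.9, 0.1, by = -0.1),
                                      seq(0.2, 0.9, by = 0.1)),
                         dwell_h = 6, T_C = 25, k_cond = 2e-2) {
  stopifnot(all(RH_steps > 0), all(RH_steps < 1), dwell_h > 0, k_cond >= 0)
  structure(list(RH_steps = RH_steps, dwell_h = dwell_h, T_C = T_C,
                 k_cond = k_cond),
            class = "dvs_protocol")
}

#' Simulate a dynamic vapor sorption run
#'
#' Lumped (gradient-free) powder sample: moisture relaxes toward the
#' vapor concentration of each RH step through the protocol conductance
#' while the Maxwell matrix relaxes viscoelastically, so slow modes lock
#' in stress and produce sorption hysteresis between the descending and
#' ascending branches. The sample starts relaxed at equilibrium with the
#' first RH step.
#'
#' @param protocol a [dvs_protocol()].
#' @param config model configuration (the `viscoelastic$F_G`/`F_tau`
#'   scaling factors are what [fit_sorption_factors()] searches).
#' @param n_sub sub-steps per dwell.
#' @return object of class `dvs_result`: list with `steps` (tibble:
#'   step, RH, branch, Xm_end, aw_end) and `trajectory` (tibble: time_h,
#'   RH, Xm).
#' @export
simulate_dvs <- function(protocol = dvs_protocol(),
                         config = default_config(), n_sub = 60) {
  T_K <- protocol$T_C + 273.15
  cfg <- strip_config(config)
  X0 <- cpp_aw_to_Xm(cfg, protocol$RH_steps[1], T_K)
  raw <- cpp_dvs(cfg, protocol$RH_steps, protocol$dwell_h * 3600, T_K,
                 protocol$k_cond, X0, as.integer(n_sub))
  n <- length(protocol$RH_steps)
  branch <- c("start", ifelse(diff(protocol$RH_steps) < 0,
                              "desorption", "adsorption"))
  branch[1] <- branch[2]
  structure(
    list(
      steps = tibble::tibble(step = seq_len(n), RH = protocol$RH_steps,
                             branch = branch, Xm_end = raw$X_end,
                             aw_end = raw$aw_end),
      trajectory = tibble::tibble(time_h = raw$t_s / 3600, RH = raw$RH,
                                  Xm = raw$X_m),
      protocol = protocol, X0 = X0
    ),
    class = "dvs_result"
  )
}

#' Fit the viscoelastic scaling factors to DVS data
#'
#' Sequential single-factor search over the four scaling factors
#' (F_G0, F_G1, F_tau00, F_tau01) on a log-spaced grid, minimizing the
#' squared end-of-step moisture error against observed DVS data.
#'
#' @param observed tibble with columns `step` and `Xm_end` (as produced
#'   by `simulate_dvs()$steps`).
#' @param protocol the [dvs_protocol()] the data were collected under.
#' @param config base configuration.
#' @param grid candidate grid applied to each factor.
#' @param start optional named start vector.
#' @return `mushdry_fit` with `par` = (F_G0, F_G1, F_tau00, F_tau01).
#' @export
fit_sorption_factors <- function(observed, protocol = dvs_protocol(),
                                 config = default_config(),
                                 grid = c(0.1, 0.3, 1, 3, 10, 30, 100),
                                 start = NULL) {
  grids <- list(F_G0 = grid, F_G1 = grid, F_tau00 = grid, F_tau01 = grid)
  T_K <- protocol$T_C + 273.15
  cfg0 <- strip_config(config)
  # the relaxed-equilibrium start moisture is independent of the factors
  X0 <- cpp_aw_to_Xm(cfg0, protocol$RH_steps[1], T_K)
  obj <- function(p) {
    cfg <- cfg0
    cfg$viscoelastic$F_G <- c(p[["F_G0"]], p[["F_G1"]])
    cfg$viscoelastic$F_tau <- c(p[["F_tau00"]], p[["F_tau01"]])
    raw <- cpp_dvs(cfg, protocol$RH_steps, protocol$dwell_h * 3600, T_K,
                   protocol$k_cond, X0, 60L)
    sum((observed$Xm_end - raw$X_end[observed$step])^2)
  }
  sequential_search(obj, grids, start = start, prescan = TRUE)
}

#' @export
print.mushdry_fit <- function(x, ...) {
  cat("<mushdry_fit>\n  best parameters:\n")
  for (nm in names(x$par)) cat(sprintf("    %-10s %g\n", nm, x$par[[nm]]))
  cat(sprintf("  objective: %.6g  (%d evaluations)\n", x$value, x$n_eval))
  invisible(x)
}
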