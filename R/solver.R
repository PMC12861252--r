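#' Ambient drying schedule
#'
#' Air temperature, relative humidity and air velocity as a time series,
#' interpolated piecewise-linearly by the solver. A constant schedule is
#' built by passing scalars.
#'
#' @param time_h sample times (h), strictly increasing, starting at 0.
#' @param T_air_C air temperature (degC).
#' @param RH relative humidity in [0, 1].
#' @param u_air_m_s air velocity (m/s).
#' @return tibble of class `ambient_schedule`.
#' @export
#' @examples
#' ambient_schedule(0, T_air_C = 35, RH = 0.3, u_air_m_s = 0.3)
ambient_schedule <- function(time_h, T_air_C, RH, u_air_m_s) {
  n <- max(length(time_h), length(T_air_C), length(RH), length(u_air_m_s))
  out <- tibble::tibble(
    time_h = rep_len(time_h, n),
    T_air_C = rep_len(T_air_C, n),
    RH = rep_len(RH, n),
    u_air_m_s = rep_len(u_air_m_s, n)
  )
  stopifnot(!is.unsorted(out$time_h), all(out$RH >= 0), all(out$RH <= 1),
            all(out$u_air_m_s >= 0))
  class(out) <- c("ambient_schedule", class(out))
  out
}

#' Read / write an ambient schedule CSV
#'
#' Columns `time_h`, `T_air_C`, `RH`, `u_air_m_s` (header required).
#' @param path CSV file path.
#' @export
read_ambient <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  ambient_schedule(df$time_h, df$T_air_C, df$RH, df$u_air_m_s)
}

#' @rdname read_ambient
#' @param ambient an [ambient_schedule()].
#' @export
write_ambient <- function(ambient, path) {
  readr::write_csv(ambient, path)
  invisible(path)
}

ambient_to_list <- function(ambient) {
  list(t_s = ambient$time_h * 3600,
       T_air_K = ambient$T_air_C + 273.15,
       RH = ambient$RH,
       u_air = ambient$u_air_m_s)
}

#' Build the finite-volume drying grid
#'
#' Discretizes the fresh mushroom (hemispherical cap plus a dual-porosity
#' lamella layer at the base, represented as the innermost region of the
#' 1-D radial grid) into control volumes of equal solid mass per region.
#' Solid masses are constant in time (Lagrangian shrinkage); volumes,
#' radii and interface areas are recomputed each step from the local
#' moisture content through the shrinkage law.
#'
#' @param config model configuration, see [default_config()].
#' @return list of class `drying_grid` with per-CV solid masses `m_s`
#'   (kg), lamella tags, the gap exchange area density, and the initial
#'   outer radius `r0_m`.
#' @export
build_grid <- function(config = default_config()) {
  g <- config$geometry
  stopifnot(g$N >= 4, g$fresh_mass > 0, g$X_m0 > 0)
  m_dry <- g$fresh_mass / (1 + g$X_m0)
  # tissue volume split: lamella tissue occupies f_lamella of tissue volume,
  # and tissue is uniform, so dry mass splits in the same proportion
  m_dry_lam <- m_dry * g$f_lamella
  n_lam <- max(1L, round(g$N * g$f_lamella))
  n_cap <- g$N - n_lam
  m_s <- c(rep(m_dry_lam / n_lam, n_lam),
           rep((m_dry - m_dry_lam) / n_cap, n_cap))
  vol <- tissue_volumes(g$X_m0, config$structure)
  v_tissue <- m_dry / config$structure$rho_solid * vol$V_ratio
  v_total <- v_tissue * (1 - g$f_lamella) +
    v_tissue * g$f_lamella / g$phi_hypha_lam
  r0 <- (3 * v_total / (2 * pi))^(1 / 3)
  if (!all(m_s > 0)) stop("infeasible geometry: nonpositive CV solid mass")
  structure(
    list(m_s = m_s, is_lamella = seq_len(g$N) <= n_lam,
         a_gap = g$a_gap, phi_hypha_lam = g$phi_hypha_lam,
         n_lamella = n_lam, r0_m = r0, m_dry = m_dry),
    class = "drying_grid"
  )
}

#' Simulate a hot-air drying run
#'
#' Integrates the coupled moisture and energy balances on the shrinking
#' grid under an ambient schedule, with per-CV two-phase water activity,
#' Maxwell viscoelastic state and vapor-equilibrium pore humidity. The
#' integrator is a linearized backward-Euler method whose update is
#' applied in flux form, so the discrete balances are conservative to
#' round-off; the adaptive step is governed by local change targets
#' (`solver$target_dm_rel`, `solver$target_dT`).
#'
#' @param config model configuration ([default_config()]).
#' @param ambient an [ambient_schedule()]; defaults to the configured
#'   constant conditions 35 degC, RH 0.3, 0.3 m/s.
#' @param t_end_h simulated duration (h).
#' @param profile_times_h times at which full radial profiles are stored.
#' @param closed_box disable all boundary exchange (conservation testing).
#' @param state0 optional state list from a previous run (continuation).
#' @param max_steps safety cap on the number of internal steps.
#' @return object of class `drying_result`: list with tibbles `series`
#'   (time_h, yw_wb, Xm_db, T_center_C, T_surface_C, aw_center,
#'   aw_surface), `profiles` (time_h, cv, r_m, Xm_db, aw, T_C, phi_air),
#'   the balance diagnostics, step count and the final solver state.
#' @export
#' @examples
#' \donttest{
#' cfg <- default_config(geometry = list(N = 8, fresh_mass = 2e-3))
#' res <- simulate_drying(cfg, t_end_h = 2)
#' head(res$series)
#' }
simulate_drying <- function(config = default_config(),
                            ambient = NULL,
                            t_end_h = 48,
                            profile_times_h = numeric(0),
                            closed_box = FALSE,
                            state0 = NULL,
                            max_steps = 5e7) {
  if (is.null(ambient)) {
    ambient <- ambient_schedule(0, T_air_C = 35, RH = 0.3, u_air_m_s = 0.3)
  }
  grid <- build_grid(config)
  control <- list(
    t_end_s = t_end_h * 3600,
    save_dt_s = config$solver$save_interval_h * 3600,
    closed_box = closed_box,
    profile_times_s = sort(profile_times_h) * 3600,
    max_steps = max_steps,
    X_m0 = config$geometry$X_m0,
    T_init_K = config$geometry$T_init_C + 273.15,
    state0 = state0
  )
  raw <- cpp_simulate(strip_config(config), unclass(grid),
                      ambient_to_list(ambient), control)
  if (isTRUE(raw$aborted)) {
    stop("drying simulation aborted: ", raw$abort_msg)
  }
  ser <- tibble::as_tibble(as.data.frame(raw$series))
  series <- tibble::tibble(
    time_h = ser$t_s / 3600,
    yw_wb = ser$y_w,
    Xm_db = ser$X_m,
    T_center_C = ser$T_center_K - 273.15,
    T_surface_C = ser$T_surface_K - 273.15,
    aw_center = ser$aw_center,
    aw_surface = ser$aw_surface
  )
  series <- series[!is.na(series$yw_wb), ]
  prof <- tibble::as_tibble(as.data.frame(raw$profiles))
  profiles <- tibble::tibble(
    time_h = prof$t_s / 3600, cv = prof$cv, r_m = prof$r_m,
    Xm_db = prof$X_m, aw = prof$aw, T_C = prof$T_K - 273.15,
    phi_air = prof$phi_air
  )
  structure(
    list(series = series, profiles = profiles, balance = raw$balance,
         nsteps = raw$nsteps, t_final_h = raw$t_final_s / 3600,
         state = raw$state, grid = grid, config = config,
         ambient = ambient),
    class = "drying_result"
  )
}

# drop S3 classes so Rcpp sees plain lists
strip_config <- function(config) {
  cfg <- unclass(config)
  cfg$composition$components <- as.list(cfg$composition$components)
  cfg
}

#' Advance the drying state by one macro step
#'
#' Runs the solver for exactly `dt_s` seconds (internally sub-stepped at
#' the stability limit) from a given state, returning the updated state
#' and the balance diagnostics. Used for conservation and fixed-point
#' testing; [simulate_drying()] is the user-facing entry point.
#'
#' @inheritParams simulate_drying
#' @param state state list (`m_w`, `H`, `phi_ref1`, `phi_ref2`, `T`,
#'   `m_v`) or `NULL` to start from the configured fresh state.
#' @param dt_s macro step length (s).
#' @return list with `state`, `balance`, `nsteps`.
#' @export
drying_step <- function(config, state = NULL, ambient = NULL, dt_s = 60,
                        closed_box = FALSE) {
  res <- simulate_drying(config, ambient,
                         t_end_h = dt_s / 3600,
                         closed_box = closed_box, state0 = state)
  list(state = res$state, balance = res$balance, nsteps = res$nsteps)
}

#' Split conserved densities into primitive variables
#'
#' Given the conserved pair (total moisture mass, enthalpy) of one control
#' volume, recovers liquid water, vapor load, temperature and water
#' activity under the local vapor-equilibrium closure; the inverse of
#' [compose_state()]. Pure R reference implementation used for testing
#' the algebraic closure.
#'
#' @param m_w total water mass in the CV (kg).
#' @param H enthalpy of the CV relative to the reference temperature (J).
#' @param m_s solid mass (kg).
#' @param config model configuration.
#' @param state Maxwell state or `NULL` (relaxed).
#' @return list with `T` (K), `m_liq`, `m_v`, `a_w`, `c_w`, `c_v`.
#' @export
split_state <- function(m_w, H, m_s, config = default_config(),
                        state = NULL) {
  stopifnot(m_w > 0, is.finite(H))
  tr <- config$transport
  T0 <- config$solver$T0
  X <- m_w / m_s
  vol <- tissue_volumes(X, config$structure)
  V_t <- m_s / config$structure$rho_solid * vol$V_ratio
  m_v <- 0
  T <- T0 + H / (m_s * tr$c_p_s + m_w * tr$c_p_w)
  for (i in 1:60) {
    m_liq <- m_w - m_v
    a_w <- sorption_isotherm(m_liq / m_s, T, config, state)
    c_v <- a_w * c_sat(T, tr$M_v)
    m_v_new <- min(c_v * vol$phi_air * V_t, 0.9 * m_w)
    T_new <- T0 + (H - m_v_new * tr$h_evap) /
      (m_s * tr$c_p_s + (m_w - m_v_new) * tr$c_p_w + m_v_new * tr$c_p_v)
    conv <- abs(T_new - T) < 1e-10 && abs(m_v_new - m_v) < 1e-15 * (1 + m_w)
    T <- T_new; m_v <- m_v_new
    if (conv) break
  }
  m_liq <- m_w - m_v
  list(T = T, m_liq = m_liq, m_v = m_v,
       a_w = sorption_isotherm(m_liq / m_s, T, config, state),
       c_w = m_liq / ((1 - vol$phi_air) * V_t),
       c_v = m_v / (vol$phi_air * V_t))
}

#' @rdname split_state
#' @param T temperature (K).
#' @export
compose_state <- function(m_w, T, m_s, config = default_config(),
                          state = NULL) {
  tr <- config$transport
  T0 <- config$solver$T0
  X <- m_w / m_s
  vol <- tissue_volumes(X, config$structure)
  V_t <- m_s / config$structure$rho_solid * vol$V_ratio
  m_v <- 0
  for (i in 1:40) {
    a_w <- sorption_isotherm((m_w - m_v) / m_s, T, config, state)
    m_v_new <- min(a_w * c_sat(T, tr$M_v) * vol$phi_air * V_t, 0.9 * m_w)
    if (abs(m_v_new - m_v) < 1e-16 * (1 + m_w)) { m_v <- m_v_new; break }
    m_v <- m_v_new
  }
  H <- (m_s * tr$c_p_s + (m_w - m_v) * tr$c_p_w) * (T - T0) +
    m_v * (tr$c_p_v * (T - T0) + tr$h_evap)
  list(m_w = m_w, H = H, m_v = m_v)
}

#' @export
print.drying_result <- function(x, ...) {
  s <- x$series
  cat("<drying_result>\n")
  cat(sprintf("  duration: %.2f h in %d rows (%g internal steps)\n",
              max(s$time_h), nrow(s), x$nsteps))
  cat(sprintf("  moisture: y_w %.3f -> %.3f (X_m %.2f -> %.3f d.b.)\n",
              s$yw_wb[1], s$yw_wb[nrow(s)], s$Xm_db[1], s$Xm_db[nrow(s)]))
  cat(sprintf("  T_center: %.1f -> %.1f degC\n",
              s$T_center_C[1], s$T_center_C[nrow(s)]))
  cat(sprintf("  balance closure (rel): mass %.2e, energy %.2e\n",
              x$balance$mass_closure_rel, x$balance$energy_closure_rel))
  invisible(x)
}
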