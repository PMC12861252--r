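#' Default model configuration
#'
#' Builds the nested configuration list that drives every other component:
#' tissue composition (per-phase Flory-Huggins parameters), viscoelastic
#' base regressions and scaling factors, shrinkage-law coefficients,
#' transport constants and correction factors, geometry, and solver
#' controls. All values are SI unless the name says otherwise.
#'
#' The composition splits the hyphal dry matter into the two thermodynamic
#' phases: phase 1 is the vacuole (small solutes: mannitol, trehalose,
#' ions), phase 2 the cytoplasm-plus-cell-wall biopolymer network.
#' `N` is the molar-volume size ratio of a component relative to water
#' (`N_inv = 1/N`, with `N_inv = 0` for polymers) and `chi` the pairwise
#' water interaction parameter.
#'
#' @param ... named overrides merged (recursively for lists) into the
#'   defaults, e.g. `default_config(transport = list(F_w_conv = 5))`.
#' @return A nested named list with class `mushdry_config`.
#' @export
#' @examples
#' cfg <- default_config(geometry = list(N = 10))
#' cfg$geometry$N
default_config <- function(...) {
  cfg <- list(
    composition = list(
      # mass_dm: kg per kg total dry matter; phase 1 = vacuole solutes,
      # phase 2 = biopolymers (protein + cell-wall material)
      components = tibble::tibble(
        name    = c("mannitol", "trehalose", "ions", "protein", "cell_wall"),
        phase   = c(1L, 1L, 1L, 2L, 2L),
        mass_dm = c(0.15, 0.10, 0.05, 0.20, 0.50),
        density = c(1490, 1580, 2160, 1330, 1500),
        N_inv   = c(1 / 5, 1 / 9, 1, 0, 0),
        chi     = c(0.3, 0.4, 0.0, 0.8, 0.8)
      ),
      rho_water = 1000,
      v_w = 1.8e-5,           # molar volume of water, m^3/mol
      elastic_sign = 1        # sign flag for the phase-2 pressure term v_w*p = sign * v_w*sigma
    ),
    viscoelastic = list(
      # log10-linear base regressions in moisture (d.b.):
      # log10 G_i = G_a - G_b * X_m    [Pa]
      # log10 tau_i = tau_a - tau_b * X_m  [s], Arrhenius factor in T
      G_a    = c(7.5, 7.0),   # slow, fast (cell-wall scale)
      G_b    = c(0.3, 0.3),
      tau_a  = c(5.0, 3.0),
      tau_b  = c(2.0, 2.0),
      Ea_tau = 3e4,           # J/mol, Arrhenius activation of tau
      T_ref  = 298.15,
      F_G    = c(1, 1),       # scaling factors per mode (fitted by DVS)
      F_tau  = c(1, 1)
    ),
    structure = list(
      # gas/solid volume-ratio law, exponential branch below X_star,
      # linear branch above
      exp_a = 8.637, exp_b = 4.034, exp_c = 6.674,
      lin_m = 2.467, lin_k = 4.33,
      X_star = 0.95,
      blend = FALSE,          # opt-in linear blend over [0.90, 1.00]
      rho_solid = 1500,
      rho_water = 1000
    ),
    transport = list(
      F_w_diff = 1,
      F_w_conv = 1,
      emissivity = 0.9,
      sigma_SB = 5.70e-8,     # Stefan constant as used by the model, W/m^2/K^4
      M_v = 0.018,            # kg/mol
      R = 8.314,
      c_p_s = 1700, c_p_w = 4187, c_p_v = 1900, c_p_air = 1005,
      rho_air = 1.2,
      h_evap = 2.45e6,        # J/kg
      lambda_s = 0.2, lambda_w = 0.6, lambda_air = 0.026,
      P_atm = 101325,
      diffusivity = list(
        D_dil = 2.3e-9,       # dilute-limit water self-diffusivity at T_ref, m^2/s
        Ea = 2e4,             # J/mol Arrhenius activation
        T_ref = 298.15,
        A_fv = 4, B_fv = 0.4, # free-volume retardation vs dry-matter fraction
        solute_ratio = 0.1,   # D_s,self / D_w,self
        M_dm = 0.3            # effective molar mass of dry matter, kg/mol
      )
    ),
    geometry = list(
      fresh_mass = 25e-3,     # kg
      X_m0 = 9,               # initial moisture d.b.
      T_init_C = 25,
      N = 20,                 # control volumes
      f_lamella = 0.15,       # fraction of tissue volume in the lamella layer
      phi_hypha_lam = 0.5,    # hyphae fraction of the dual-porosity lamella region
      a_gap = 300             # specific ambient-exchange area of lamella gaps, m^2/m^3
    ),
    solver = list(
      safety = 0.4,
      dt_max = 300,           # s
      dt_min = 1e-7,
      target_dm_rel = 0.03,   # per-step local moisture change target
      target_dT = 0.7,        # per-step temperature change target, K
      T0 = 273.15,            # enthalpy reference, K
      save_interval_h = 0.25
    )
  )
  modifyList(cfg, rlang::list2(...), keep.null = TRUE) |>
    structure(class = c("mushdry_config", "list"))
}

#' Read / write a configuration as YAML
#'
#' Tabular composition is stored as a list of rows in the YAML file.
#' @param path file path.
#' @return `read_config()` returns a `mushdry_config`; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$composition$components)) {
    raw$composition$components <-
      purrr::map_dfr(raw$composition$components, tibble::as_tibble)
  }
  cfg <- default_config()
  structure(modifyList(cfg, raw, keep.null = TRUE),
            class = c("mushdry_config", "list"))
}

#' @rdname read_config
#' @param config a `mushdry_config` list.
#' @export
write_config <- function(config, path) {
  config <- unclass(config)
  config$composition$components <-
    purrr::transpose(as.list(config$composition$components)) |>
    purrr::map(~ purrr::map(.x, identity))
  yaml::write_yaml(config, path)
  invisible(path)
}
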