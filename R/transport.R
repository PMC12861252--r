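#' Saturation vapor pressure and concentration of water
#'
#' Antoine correlation for water (1-100 degC range constants), with the
#' saturated vapor concentration from the ideal-gas law,
#' `c_sat = M_v p_sat / (R T)`. Both are strictly increasing in T.
#'
#' @param T temperature (K), in (250, 400).
#' @return pressure (Pa) / concentration (kg/m^3).
#' @export
p_sat <- function(T) {
  stopifnot(all(is.finite(T)))
  if (any(T <= 250 | T >= 400)) stop("T outside correlation validity (250, 400) K")
  T_C <- T - 273.15
  133.322 * 10^(8.07131 - 1730.63 / (233.426 + T_C))
}

#' @rdname p_sat
#' @param M_v molar mass of water (kg/mol).
#' @export
c_sat <- function(T, M_v = 0.018) {
  M_v * p_sat(T) / (8.314 * T)
}

#' Equilibrium vapor concentration in the pores
#'
#' `c_v = a_w M_v p_sat(T) / (R T)`: linear in the water activity, equal
#' to the saturation concentration at `a_w = 1`.
#'
#' @param a_w water activity in [0, 1].
#' @inheritParams c_sat
#' @export
vapor_concentration <- function(a_w, T, M_v = 0.018) {
  stopifnot(all(a_w >= 0), all(a_w <= 1 + 1e-12))
  a_w * c_sat(T, M_v)
}

#' Mutual moisture diffusivity of the hyphal matrix
#'
#' Darken-type mutual diffusivity
#' \eqn{D = F_{w,diff}\,(x_w D_{s,self} + x_s D_{w,self})\,\Gamma} with
#' free-volume self-diffusivities that collapse by orders of magnitude as
#' the matrix densifies, and the thermodynamic factor
#' \eqn{\Gamma = \partial \ln a_w / \partial \ln \phi_w} evaluated from the
#' composition-based isotherm by finite differences. The correction factor
#' `F_w_diff` absorbs the level mismatch between theory and tissue.
#'
#' @param X_m moisture content d.b. (scalar or vector).
#' @param T temperature (K).
#' @param config model configuration.
#' @return diffusivity (m^2/s).
#' @export
moisture_diffusivity <- function(X_m, T = 298.15, config = default_config()) {
  stopifnot(all(X_m > 0))
  tr <- config$transport
  dp <- tr$diffusivity
  vapply(X_m, function(x) {
    Dw <- water_self_diffusivity(x, T, dp, config$structure)
    Ds <- dp$solute_ratio * Dw
    n_w <- x / tr$M_v
    n_s <- 1 / dp$M_dm
    x_w <- n_w / (n_w + n_s)
    G <- thermo_factor(x, T, config)
    tr$F_w_diff * (x_w * Ds + (1 - x_w) * Dw) * G
  }, numeric(1))
}

# free-volume self-diffusivity of water in the matrix
water_self_diffusivity <- function(X_m, T, dp, st) {
  phi_dm <- (1 / st$rho_solid) / (1 / st$rho_solid + X_m / st$rho_water)
  dp$D_dil * exp(-dp$Ea / 8.314 * (1 / T - 1 / dp$T_ref)) *
    10^(-dp$A_fv * phi_dm / (1 - dp$B_fv * phi_dm))
}

# thermodynamic factor d ln a_w / d ln phi_w on the relaxed isotherm,
# central finite difference in X_m
thermo_factor <- function(X_m, T, config, rel_h = 1e-3) {
  st <- config$structure
  h <- X_m * rel_h
  x2 <- X_m + h; x1 <- max(X_m - h, X_m * 0.5)
  aw <- sorption_isotherm(c(x1, x2), T, config)
  phiw <- tissue_phi_w_hyphae(c(x1, x2), st)
  G <- (log(aw[2]) - log(aw[1])) / (log(phiw[2]) - log(phiw[1]))
  max(G, 1e-3)
}

# water volume fraction within the hyphae (solid + water, no pores)
tissue_phi_w_hyphae <- function(X_m, st) {
  vw <- X_m / st$rho_water
  vs <- 1 / st$rho_solid
  vw / (vw + vs)
}

#' Binary water-vapor-in-air diffusivity
#'
#' Standard T^1.75 correlation anchored at 2.5e-5 m^2/s (298.15 K, 1 atm);
#' the porosity factor is applied in the flux, not here.
#'
#' @param T temperature (K).
#' @param P total pressure (Pa).
#' @export
vapor_diffusivity <- function(T, P = 101325) {
  2.5e-5 * (T / 298.15)^1.75 * (101325 / P)
}

#' Effective thermal conductivity of the tissue
#'
#' Volume-fraction-weighted parallel model over solid, water and air.
#'
#' @param phi_s,phi_w,phi_air volume fractions summing to 1 (+- 1e-6).
#' @param tr the `transport` section of [default_config()].
#' @export
thermal_conductivity <- function(phi_s, phi_w, phi_air,
                                 tr = default_config()$transport) {
  if (any(abs(phi_s + phi_w + phi_air - 1) > 1e-6))
    stop("volume fractions must sum to 1")
  phi_s * tr$lambda_s + phi_w * tr$lambda_w + phi_air * tr$lambda_air
}

#' External heat and mass exchange coefficients
#'
#' Radiative coefficient from the linearized Stefan law
#' `h_rad = e * 4 * sigma * T_wall^3`, convective coefficient from the
#' flat-surface rule of thumb `h_conv = 6 + 10 u_air`, and the external
#' mass-transfer coefficient from the Lewis relation applied to the
#' convective part, `beta_ext = F_w_conv * h_conv / (rho_air c_p_air)`.
#'
#' @param T_wall oven wall temperature (K), equal to the air temperature.
#' @param u_air air velocity at the product surface (m/s).
#' @param tr the `transport` section of [default_config()].
#' @return list with `h_rad`, `h_conv`, `h_ext` (W/m^2/K) and `beta_ext`
#'   (m/s).
#' @export
#' @examples
#' exchange_coefficients(308.15, u_air = 0.3)
exchange_coefficients <- function(T_wall, u_air,
                                  tr = default_config()$transport) {
  stopifnot(u_air >= 0)
  h_rad <- tr$emissivity * 4 * tr$sigma_SB * T_wall^3
  h_conv <- 6 + 10 * u_air
  list(h_rad = h_rad, h_conv = h_conv, h_ext = h_rad + h_conv,
       beta_ext = tr$F_w_conv * h_conv / (tr$rho_air * tr$c_p_air))
}
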