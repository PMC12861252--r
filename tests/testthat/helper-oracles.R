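# Shared fixtures and independent oracles for the test suite.

# small, fast solver configuration used wherever full fidelity is not the
# point of the test
fast_config <- function(...) {
  default_config(
    geometry = list(N = 10, fresh_mass = 5e-3),
    ...
  )
}

# the calibrated transport vector used as ground truth in the
# self-consistency studies
truth_config <- function(...) {
  default_config(
    transport = list(F_w_diff = 8, F_w_conv = 5, emissivity = 0.9),
    ...
  )
}

# Magnus saturation-pressure correlation: independent of the Antoine
# correlation used by the implementation (agreement ~0.1% over 0-60 degC)
p_sat_magnus <- function(T_C) 610.94 * exp(17.625 * T_C / (T_C + 243.04))
c_sat_magnus <- function(T_C) {
  0.018 * p_sat_magnus(T_C) / (8.314 * (T_C + 273.15))
}

# Psychrometric surface-balance oracle: steady temperature of an
# evaporating wet surface, solving
#   h_ext (T_air - T) = dH_evap * beta * (c_sat(T) - RH c_sat(T_air))
# with the model's exchange-coefficient formulas but the Magnus saturation
# curve. F_w_conv = 1 and e = 0 recovers the textbook psychrometric wet
# bulb.
wet_bulb_oracle <- function(T_air_C, RH, u_air, emissivity = 0,
                            F_w_conv = 1, h_evap = 2.45e6) {
  h_conv <- 6 + 10 * u_air
  h_rad <- emissivity * 4 * 5.70e-8 * (T_air_C + 273.15)^3
  beta <- F_w_conv * h_conv / (1.2 * 1005)
  f <- function(T_C) {
    (h_conv + h_rad) * (T_air_C - T_C) -
      h_evap * beta * (c_sat_magnus(T_C) - RH * c_sat_magnus(T_air_C))
  }
  stats::uniroot(f, c(-5, T_air_C))$root
}

# Closed-form multicomponent Flory-Huggins mixing free energy (units of
# RT, arbitrary scale): used as the brute-force minimization oracle for
# the water partitioning.  n_j ln phi_j summed over species plus the
# solvent-solute interaction term.
fh_free_energy <- function(water, components, rho_water = 1000,
                           v_w = 1.8e-5, M_w = 0.018) {
  V_w <- water / rho_water
  V_i <- components$mass_dm / components$density
  V <- V_w + sum(V_i)
  if (V_w <= 0) return(Inf)
  phi_w <- V_w / V
  phi_i <- V_i / V
  n_w <- V_w / v_w
  # moles of component j proportional to V_j / N_j (zero for polymers)
  n_i <- ifelse(components$N_inv > 0, V_i * components$N_inv / v_w, 0)
  sum_ni <- if (length(n_i)) sum(ifelse(n_i > 0, n_i * log(phi_i), 0)) else 0
  n_w * log(phi_w) + sum_ni + n_w * sum(components$chi * phi_i)
}

# fine-step explicit-Euler integration of the Maxwell internal-variable
# relaxation at constant phi_s, with one Richardson extrapolation (h, h/2)
# to push the oracle error below the 1e-8 comparison tolerance
euler_maxwell <- function(phi_ref, phi_s, tau, dt, n = 5e4) {
  run <- function(n) {
    h <- dt / n
    x <- phi_ref
    for (k in seq_len(n)) x <- x + h * (phi_s - x) / tau
    x
  }
  2 * run(2 * n) - run(n)
}
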