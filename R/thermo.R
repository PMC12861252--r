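#' Phase composition
#'
#' A phase is a mixture of water and non-water components (solutes or
#' biopolymers), each with a density, a molar-volume size ratio relative to
#' water (stored as its inverse `N_inv`, 0 for polymers) and a
#' water-interaction parameter `chi`. Masses are kg per kg of *total* dry
#' matter so that phases assembled from the same configuration share a
#' common basis.
#'
#' @param water water mass (kg per kg dry matter basis).
#' @param components tibble with columns `name`, `mass_dm`, `density`,
#'   `N_inv`, `chi` (non-water components; may have zero rows).
#' @param T temperature (K).
#' @param v_w molar volume of water (m^3/mol).
#' @param rho_water water density (kg/m^3).
#' @return An object of class `phase_composition`.
#' @export
phase_composition <- function(water, components, T = 298.15,
                              v_w = 1.8e-5, rho_water = 1000) {
  stopifnot(is.numeric(water), length(water) == 1, is.finite(water))
  if (water < 0) stop("negative water mass")
  if (nrow(components) > 0 && any(components$mass_dm < 0))
    stop("negative component mass")
  if (nrow(components) > 0 && any(components$N_inv > 1 + 1e-12))
    stop("size ratio N must be >= 1")
  structure(
    list(water = water, components = components, T = T,
         v_w = v_w, rho_water = rho_water, R = 8.314),
    class = "phase_composition"
  )
}

#' Volume fractions of a phase
#'
#' @param phase a [phase_composition()].
#' @return list with `phi_w` (water) and `phi_i` (vector over non-water
#'   components); fractions sum to 1.
#' @export
phase_volume_fractions <- function(phase) {
  v_w_vol <- phase$water / phase$rho_water
  v_i <- if (nrow(phase$components)) {
    phase$components$mass_dm / phase$components$density
  } else numeric(0)
  tot <- v_w_vol + sum(v_i)
  if (tot <= 0) stop("phase has no volume")
  list(phi_w = v_w_vol / tot, phi_i = v_i / tot)
}

#' Flory-Huggins chemical potential of mixing for water
#'
#' Multicomponent Flory-Huggins form
#' \deqn{\ln a_{w,mix} = \ln\phi_w + \sum_i (1 - 1/N_i)\,\phi_i +
#'       \Big(\sum_i \chi_{wi}\phi_i\Big)(1 - \phi_w)}
#' over the non-water components, returning \eqn{RT \ln a_{w,mix}} in
#' J/mol. For pure water the result is exactly zero.
#'
#' @inheritParams phase_volume_fractions
#' @return chemical potential of mixing (J/mol).
#' @export
#' @examples
#' ph <- phase_composition(1, dplyr::slice(default_config()$composition$components, 0))
#' mu_mix_water(ph)  # 0: pure solvent
mu_mix_water <- function(phase) {
  vf <- phase_volume_fractions(phase)
  if (vf$phi_w <= 0) stop("water volume fraction must be positive")
  phase$R * phase$T * ln_aw_mix(vf$phi_w, vf$phi_i,
                                phase$components$N_inv,
                                phase$components$chi)
}

# scalar core shared with the numeric solvers
ln_aw_mix <- function(phi_w, phi_i, N_inv, chi) {
  if (length(phi_i) == 0) return(log(phi_w))
  log(phi_w) + sum((1 - N_inv) * phi_i) + sum(chi * phi_i) * (1 - phi_w)
}

#' Water activity of one phase under a pressure term
#'
#' \eqn{a_w = \exp[(\Delta\mu_{mix} + v_w p)/(RT)]}. For the biopolymer
#' phase the caller passes the elastic pressure term; `p = 0` recovers the
#' pure mixing value.
#'
#' @inheritParams phase_volume_fractions
#' @param p pressure term (J/m^3).
#' @return water activity (dimensionless, > 0).
#' @export
water_activity_phase <- function(phase, p = 0) {
  stopifnot(is.finite(p))
  mu <- mu_mix_water(phase)
  exp((mu + phase$v_w * p) / (phase$R * phase$T))
}

#' Partition water between the vacuole and biopolymer phases
#'
#' Splits a prescribed total water mass over the two thermodynamic phases
#' so that their water activities are equal (the intact-membrane local
#' equilibrium), by monotone bisection on the phase-1 water fraction. The
#' elastic pressure term applies to phase 2 only.
#'
#' @param total_water total water mass (kg per kg dry matter).
#' @param phase1_dry,phase2_dry tibbles of non-water components for each
#'   phase (columns as in [phase_composition()]).
#' @param p2 pressure term applied to phase 2 (J/m^3), e.g. the
#'   viscoelastic stress routed through the configured sign flag.
#' @param T temperature (K).
#' @param v_w,rho_water water molar volume and density.
#' @param tol absolute tolerance on the activity residual.
#' @return list with `w1`, `w2` (kg water in each phase), `a_w` (common
#'   activity), `residual` (|a_w1 - a_w2|) and `converged`.
#' @export
partition_water <- function(total_water, phase1_dry, phase2_dry, p2 = 0,
                            T = 298.15, v_w = 1.8e-5, rho_water = 1000,
                            tol = 1e-9) {
  stopifnot(total_water > 0)
  dm1 <- sum(phase1_dry$mass_dm)
  dm2 <- sum(phase2_dry$mass_dm)
  if (dm1 <= 0 && dm2 <= 0) stop("both phases empty of dry matter")
  aw_of <- function(w, dry, p) {
    water_activity_phase(
      phase_composition(w, dry, T = T, v_w = v_w, rho_water = rho_water), p)
  }
  if (dm2 <= 0) {
    aw <- aw_of(total_water, phase1_dry, 0)
    return(list(w1 = total_water, w2 = 0, a_w = aw, residual = 0,
                converged = TRUE))
  }
  if (dm1 <= 0) {
    aw <- aw_of(total_water, phase2_dry, p2)
    return(list(w1 = 0, w2 = total_water, a_w = aw, residual = 0,
                converged = TRUE))
  }
  # residual a_w1(f) - a_w2(f) is monotone increasing in f = w1/total
  resid <- function(f) {
    aw_of(f * total_water, phase1_dry, 0) -
      aw_of((1 - f) * total_water, phase2_dry, p2)
  }
  lo <- 1e-12; hi <- 1 - 1e-12
  flo <- resid(lo); fhi <- resid(hi)
  if (is.nan(flo) || is.nan(fhi) || flo > 0 || fhi < 0) {
    # pathological parameters: report the better endpoint as non-equilibrium
    f <- if (!is.nan(flo) && abs(flo) < abs(fhi)) lo else hi
    return(list(w1 = f * total_water, w2 = (1 - f) * total_water,
                a_w = aw_of(f * total_water, phase1_dry, 0),
                residual = abs(resid(f)), converged = FALSE))
  }
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    fm <- resid(mid)
    if (fm > 0) hi <- mid else lo <- mid
    if (abs(fm) < tol && (hi - lo) < 1e-14) break
  }
  f <- (lo + hi) / 2
  list(w1 = f * total_water, w2 = (1 - f) * total_water,
       a_w = aw_of(f * total_water, phase1_dry, 0),
       residual = abs(resid(f)), converged = abs(resid(f)) <= max(tol, 1e-8))
}

# split the configured component table into per-phase tibbles
phase_tables <- function(config) {
  comps <- config$composition$components
  list(p1 = comps[comps$phase == 1L, , drop = FALSE],
       p2 = comps[comps$phase == 2L, , drop = FALSE])
}

# polymer volume fraction of phase 2 at a given phase-2 water load
phase2_polymer_fraction <- function(w2, phase2_dry, rho_water = 1000) {
  v_p <- sum(phase2_dry$mass_dm / phase2_dry$density)
  v_p / (v_p + w2 / rho_water)
}

#' Composition-based sorption isotherm
#'
#' Water activity of the whole tissue at moisture content `X_m` (d.b.),
#' obtained by partitioning the water over the two phases with the
#' viscoelastic stress of the cell-wall matrix coupled into the phase-2
#' chemical potential. With a fully relaxed state (the default) the elastic
#' term vanishes and the isotherm is the equilibrium sorption curve.
#'
#' @param X_m moisture content, kg water / kg dry matter (scalar or vector).
#' @param T temperature (K).
#' @param config model configuration, see [default_config()].
#' @param state Maxwell internal state as [maxwell_state()], or `NULL` for
#'   the fully relaxed equilibrium curve.
#' @return water activity (same length as `X_m`).
#' @export
#' @examples
#' sorption_isotherm(c(0.1, 1, 5), T = 308.15)
sorption_isotherm <- function(X_m, T = 298.15, config = default_config(),
                              state = NULL) {
  vapply(X_m, function(x) tissue_equilibrium(x, T, config, state)$a_w,
         numeric(1))
}

# Full tissue equilibrium at one X_m: iterate partition <-> elastic stress.
# Returns split, common a_w, phase-2 polymer fraction and stress.
tissue_equilibrium <- function(X_m, T, config, state = NULL) {
  stopifnot(X_m > 0)
  pt <- phase_tables(config)
  ve <- config$viscoelastic
  sgn <- config$composition$elastic_sign
  rho_w <- config$composition$rho_water
  v_w <- config$composition$v_w
  p2 <- 0; split <- NULL; phi_s <- NA_real_; sigma <- 0
  for (it in 1:30) {
    split <- partition_water(X_m, pt$p1, pt$p2, p2 = p2, T = T,
                             v_w = v_w, rho_water = rho_w)
    phi_s <- phase2_polymer_fraction(split$w2, pt$p2, rho_w)
    sigma <- if (is.null(state)) 0 else {
      mf <- material_functions(X_m, T, ve)
      maxwell_stress(state, phi_s, G = mf$G)
    }
    p2_new <- sgn * sigma
    if (abs(p2_new - p2) < 1e-6 * (1 + abs(p2))) { p2 <- p2_new; break }
    p2 <- p2_new
  }
  list(split = split, a_w = split$a_w, phi_s = phi_s, sigma = sigma, p2 = p2)
}

#' Invert the sorption isotherm
#'
#' Moisture content at a prescribed water activity, by bisection on `X_m`
#' (the forward curve is strictly increasing). Round-trips with
#' [sorption_isotherm()] to about 1e-6 relative.
#'
#' @param a_w target water activity in (0, 1).
#' @inheritParams sorption_isotherm
#' @param X_range bracketing interval for the moisture content.
#' @return moisture content d.b.
#' @export
aw_to_moisture <- function(a_w, T = 298.15, config = default_config(),
                           state = NULL, X_range = c(1e-8, 1e3)) {
  stopifnot(length(a_w) == 1)
  if (a_w >= 1) stop("a_w >= 1: equilibrium moisture content is unbounded")
  if (a_w <= 0) stop("a_w must be in (0, 1)")
  f <- function(x) sorption_isotherm(x, T, config, state) - a_w
  lo <- X_range[1]; hi <- X_range[2]
  if (f(hi) < 0) stop("a_w out of range of the isotherm on X_range")
  while (f(lo) > 0) lo <- lo / 10
  for (i in 1:100) {
    mid <- sqrt(lo * hi)    # bisect in log space: X_m spans decades
    if (f(mid) > 0) hi <- mid else lo <- mid
    if (abs(f(mid)) < 1e-8 || (hi / lo - 1) < 1e-12) break
  }
  sqrt(lo * hi)
}
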