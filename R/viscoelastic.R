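#' Maxwell internal state
#'
#' The two reference polymer volume fractions carrying the viscoelastic
#' memory of the cell-wall matrix, one per relaxation mode (slow, fast).
#' At full relaxation both equal the current polymer fraction and the
#' stress vanishes.
#'
#' @param phi_ref numeric length-2 vector in (0, 1].
#' @return object of class `maxwell_state`.
#' @export
maxwell_state <- function(phi_ref = c(1, 1)) {
  stopifnot(length(phi_ref) == 2, all(is.finite(phi_ref)),
            all(phi_ref > 0), all(phi_ref <= 1))
  structure(list(phi_ref = phi_ref), class = "maxwell_state")
}

#' Moisture-dependent moduli and relaxation times
#'
#' Evaluates the base log10-linear regressions for the per-mode elastic
#' modulus `G_i(X_m)` and relaxation time `tau_i(X_m, T)` (Arrhenius in
#' temperature) and applies the dimensionless scaling factors `F_G`,
#' `F_tau` that calibrate the tissue-scale measurements to the cell-wall
#' scale. Relaxation times fall steeply with moisture: a wet matrix
#' relaxes in minutes, a glassy-dry one over weeks, so drying locks
#' stresses in.
#'
#' @param X_m moisture content d.b. (scalar or vector).
#' @param T temperature (K).
#' @param ve the `viscoelastic` section of [default_config()].
#' @return list with matrices/vectors `G` (Pa) and `tau` (s), one column or
#'   element per mode (slow, fast).
#' @export
material_functions <- function(X_m, T = 298.15,
                               ve = default_config()$viscoelastic) {
  stopifnot(all(X_m > 0))
  arr <- exp(ve$Ea_tau / 8.314 * (1 / T - 1 / ve$T_ref))
  G <- outer(X_m, seq_len(2), function(x, i) {
    ve$F_G[i] * 10^(ve$G_a[i] - ve$G_b[i] * x)
  })
  tau <- outer(X_m, seq_len(2), function(x, i) {
    ve$F_tau[i] * 10^(ve$tau_a[i] - ve$tau_b[i] * x) * arr
  })
  if (length(X_m) == 1) {
    list(G = drop(G), tau = drop(tau))
  } else {
    list(G = G, tau = tau)
  }
}

#' Advance the Maxwell internal variables
#'
#' Exact exponential update of each reference fraction toward the current
#' polymer fraction held constant over the step:
#' \eqn{\phi_{ref,i} \leftarrow \phi_s + (\phi_{ref,i} - \phi_s)
#' e^{-\Delta t/\tau_i}}. Unconditionally stable and exact for frozen
#' \eqn{\phi_s}, which is why the transport solver sub-steps it rather
#' than integrating the relaxation ODE numerically.
#'
#' @param state a [maxwell_state()].
#' @param phi_s current polymer volume fraction in (0, 1].
#' @param tau length-2 relaxation times (s).
#' @param dt time step (s), >= 0.
#' @return updated `maxwell_state`.
#' @export
advance_state <- function(state, phi_s, tau, dt) {
  stopifnot(dt >= 0, phi_s > 0, phi_s <= 1)
  if (any(tau <= 0)) stop("relaxation times must be positive")
  maxwell_state(phi_s + (state$phi_ref - phi_s) * exp(-dt / tau))
}

#' Viscoelastic stress of the cell-wall matrix
#'
#' Sum over the two Maxwell modes of
#' \eqn{G_i(\tilde\phi_i^{1/3} - \tilde\phi_i)} with
#' \eqn{\tilde\phi_i = \phi_s/\phi_{ref,i}}: zero at the reference state,
#' negative when the matrix has shrunk past its reference (drying),
#' positive when swollen. The thermodynamic module converts this to the
#' phase-2 pressure term of the water activity.
#'
#' @inheritParams advance_state
#' @param G length-2 moduli (Pa).
#' @return stress (Pa).
#' @export
maxwell_stress <- function(state, phi_s, G) {
  stopifnot(all(state$phi_ref > 0))
  pt <- phi_s / state$phi_ref
  sum(G * (pt^(1 / 3) - pt))
}
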