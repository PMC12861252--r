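#' Gas/solid volume ratio during drying
#'
#' Empirical shrinkage law for the hyphal matrix: the air-to-solid volume
#' ratio as a function of moisture content (d.b.), with an exponential
#' branch below the switch moisture `X_star` and a linear branch above.
#' The printed branch coefficients do not meet at the switch (a jump of
#' about 0.19); by default the branches are evaluated as printed with the
#' linear branch at the boundary, and `blend = TRUE` opts into a linear
#' blend over `X_m` in [0.90, 1.00] for solver smoothness.
#'
#' @param X_m moisture content d.b. (vector), >= 0.
#' @param st the `structure` section of [default_config()].
#' @return V_air / V_solid (dimensionless, > 0).
#' @export
#' @examples
#' gas_solid_ratio(c(0, 2))  # 15.311, 9.264
gas_solid_ratio <- function(X_m, st = default_config()$structure) {
  stopifnot(all(X_m >= 0))
  lo <- st$exp_a * exp(-st$exp_b * X_m) + st$exp_c
  hi <- st$lin_m * X_m + st$lin_k
  if (isTRUE(st$blend)) {
    w <- pmin(1, pmax(0, (X_m - 0.90) / 0.10))
    (1 - w) * lo + w * hi
  } else {
    ifelse(X_m < st$X_star, lo, hi)
  }
}

#' Volume fractions of the shrinking tissue
#'
#' From the gas/solid ratio law: total-to-solid volume ratio
#' `V/V_s = V_air/V_s + 1 + X_m * rho_solid / rho_water` and the air,
#' water and solid volume fractions, which close to 1 exactly.
#'
#' @inheritParams gas_solid_ratio
#' @return tibble with columns `X_m`, `V_ratio` (V_mushroom/V_solid),
#'   `phi_air`, `phi_w`, `phi_s`.
#' @export
tissue_volumes <- function(X_m, st = default_config()$structure) {
  gs <- gas_solid_ratio(X_m, st)
  Vr <- gs + 1 + X_m * st$rho_solid / st$rho_water
  tibble::tibble(
    X_m = X_m,
    V_ratio = Vr,
    phi_air = gs / Vr,
    phi_s = 1 / Vr,
    phi_w = 1 - gs / Vr - 1 / Vr
  )
}
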