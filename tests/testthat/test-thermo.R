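no_comps <- function() {
  tibble::tibble(name = character(), phase = integer(), mass_dm = numeric(),
                 density = numeric(), N_inv = numeric(), chi = numeric())
}
one_comp <- function(mass, density = 1000, N_inv, chi) {
  tibble::tibble(name = "x", phase = 1L, mass_dm = mass, density = density,
                 N_inv = N_inv, chi = chi)
}

test_that("chemical potential of mixing reproduces the closed form", {
  # pure solvent limit
  pure <- phase_composition(1, no_comps())
  expect_equal(mu_mix_water(pure), 0)
  expect_equal(water_activity_phase(pure), 1)

  # ideal athermal mixture of equal-size species: a_w = phi_w
  ideal <- phase_composition(0.5, one_comp(0.5, 1000, N_inv = 1, chi = 0))
  expect_equal(water_activity_phase(ideal), 0.5, tolerance = 1e-12)

  # single polymer, chi = 0.5, phi_w = 0.8:
  # ln a_w = ln 0.8 + 0.2 + 0.5 * 0.2 * 0.2
  poly <- phase_composition(0.8, one_comp(0.2, 1000, N_inv = 0, chi = 0.5))
  expect_equal(log(water_activity_phase(poly)),
               log(0.8) + 0.2 + 0.5 * 0.2 * 0.2, tolerance = 1e-12)
})

test_that("mixing potential rejects invalid compositions", {
  expect_error(phase_composition(-0.1, no_comps()), "negative water")
  expect_error(phase_composition(1, one_comp(-0.5, 1000, 1, 0)),
               "negative component")
  expect_error(phase_composition(1, one_comp(0.5, 1000, 2, 0)), "N must be")
  expect_error(mu_mix_water(phase_composition(0, one_comp(1, 1000, 1, 0))),
               "volume")
})

test_that("pressure term acts as exp(v_w p / RT) on the activity", {
  pure <- phase_composition(1, no_comps(), T = 298.15)
  # direct evaluation: p = 1e6 J/m^3
  expect_equal(water_activity_phase(pure, p = 1e6),
               exp(1.8e-5 * 1e6 / (8.314 * 298.15)), tolerance = 1e-12)
  # zero-pressure identity and monotonicity in p
  ph <- phase_composition(0.6, one_comp(0.4, 1200, N_inv = 0.2, chi = 0.3))
  expect_equal(water_activity_phase(ph, 0),
               exp(mu_mix_water(ph) / (8.314 * ph$T)))
  ps <- seq(-2e6, 2e6, length.out = 9)
  aws <- vapply(ps, function(p) water_activity_phase(ph, p), numeric(1))
  expect_true(all(diff(aws) > 0))
})

test_that("water partitioning honours symmetry, degeneracy and mass", {
  same <- one_comp(0.5, 1200, N_inv = 0.2, chi = 0.3)
  sp <- partition_water(2, same, same)
  expect_equal(sp$w1, 1, tolerance = 1e-7)     # identical phases: 50/50
  expect_equal(sp$w1 + sp$w2, 2, tolerance = 1e-12)  # exact conservation
  expect_lt(sp$residual, 1e-8)

  # one empty phase takes no water
  sp2 <- partition_water(1.5, same, same[0, ])
  expect_equal(sp2$w1, 1.5)
  expect_equal(sp2$residual, 0)
})

test_that("equal-activity split matches brute-force free-energy argmin", {
  solute <- one_comp(1, 1490, N_inv = 1 / 5, chi = 0.3)
  polymer <- one_comp(1, 1400, N_inv = 0, chi = 0.8)
  total <- 2  # total water equals total dry mass
  sp <- partition_water(total, solute, polymer, T = 308)

  f_grid <- seq(1e-5, 1 - 1e-5, length.out = 1e5)
  G <- vapply(f_grid, function(f) {
    fh_free_energy(f * total, solute) +
      fh_free_energy((1 - f) * total, polymer)
  }, numeric(1))
  f_star <- f_grid[which.min(G)]
  expect_equal(sp$w1 / total, f_star, tolerance = 2 / 1e5 / f_star)
})

test_that("sorption isotherm is monotone, invertible and saturates", {
  cfg <- default_config()
  X <- c(0.02, 0.05, 0.1, 0.2, 0.5, 1, 2, 3.5, 5, 9)
  aw <- sorption_isotherm(X, 308.15, cfg)
  expect_true(all(diff(aw) > 0))
  expect_true(all(aw > 0 & aw < 1))

  # dilute limit: a_w approaches 1 from below as X_m grows
  aw_tail <- sorption_isotherm(c(50, 100, 200), 308.15, cfg)
  expect_true(all(diff(aw_tail) > 0))
  expect_lt(1 - aw_tail[3], 1e-3)

  # round trip X -> a_w -> X
  aw1 <- sorption_isotherm(1, 308.15, cfg)
  expect_equal(aw_to_moisture(aw1, 308.15, cfg), 1, tolerance = 1e-6)
  expect_error(aw_to_moisture(1, 308.15, cfg), "unbounded")
})

test_that("locked-in viscoelastic stress shifts the isotherm", {
  cfg <- default_config()
  # reference state wetter than current: matrix compressed, sigma < 0,
  # the phase-2 pressure term lowers a_w so the tissue holds more water
  X <- 0.3
  eq <- mushdry:::tissue_equilibrium(X, 298.15, cfg, NULL)
  state <- maxwell_state(rep(eq$phi_s * 0.7, 2))
  aw_rel <- sorption_isotherm(X, 298.15, cfg)
  aw_str <- sorption_isotherm(X, 298.15, cfg, state = state)
  expect_lt(aw_str, aw_rel)
})
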