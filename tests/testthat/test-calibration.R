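toy_experiment <- function(time_h, yw, Tc, T_init = 25, T_air = 35) {
  experiment_record(time_h, yw, Tc,
                    ambient_schedule(0, T_air, 0.3, 0.3),
                    T_init_C = T_init, T_air_C = T_air)
}

test_that("weighted least-squares objective reproduces hand values", {
  # two Theta residuals of 0.1 and one moisture residual of 0.1:
  # 2*0.01/2 + 10*0.01/1 ... with matched sample counts the moisture
  # term is averaged over its own N
  ex <- toy_experiment(c(1, 2), c(0.8, 0.6), c(26, 27))
  den <- 10  # T_air - T_init
  sim <- tibble::tibble(time_h = c(1, 2),
                        yw_wb = c(0.8 + 0.1, 0.6),
                        T_center_C = c(26, 27) + 0.1 * den)
  # Theta residuals: 0.1, 0.1; moisture residuals: 0.1, 0
  got <- objective_lse(list(ex), list(sim))
  expect_equal(got, 2 * 0.01 / 2 + 10 * (0.01 + 0) / 2, tolerance = 1e-12)

  # perfect prediction gives exactly zero
  sim0 <- tibble::tibble(time_h = c(1, 2), yw_wb = c(0.8, 0.6),
                         T_center_C = c(26, 27))
  expect_equal(objective_lse(list(ex), list(sim0)), 0)

  # tripling moisture residuals multiplies the moisture term by 9
  simA <- tibble::tibble(time_h = c(1, 2), yw_wb = c(0.81, 0.61),
                         T_center_C = c(26, 27))
  simB <- tibble::tibble(time_h = c(1, 2), yw_wb = c(0.83, 0.63),
                         T_center_C = c(26, 27))
  expect_equal(objective_lse(list(ex), list(simB)),
               9 * objective_lse(list(ex), list(simA)), tolerance = 1e-12)

  # invariant to experiment reordering
  ex2 <- toy_experiment(c(0.5, 1.5), c(0.7, 0.5), c(28, 30))
  expect_equal(objective_lse(list(ex, ex2), list(sim, sim0)),
               objective_lse(list(ex2, ex), list(sim0, sim)))

  expect_error(toy_experiment(c(1, 2), c(0.8, 0.6), c(26, 27),
                              T_init = 35, T_air = 35), "undefined")
})

test_that("fit statistics match hand calculations", {
  expect_equal(fit_stats(c(0, 1), c(0, 1)),
               tibble::tibble(R2 = 1, RMSE = 0, MAE = 0))
  st <- fit_stats(c(0, 1), c(0.1, 0.9))
  expect_equal(st$RMSE, 0.1, tolerance = 1e-12)
  expect_equal(st$MAE, 0.1, tolerance = 1e-12)
  expect_equal(st$R2, 1 - 0.02 / 0.5, tolerance = 1e-12)

  # null model baseline: constant prediction at the mean gives R2 = 0
  y <- c(1, 2, 3, 6)
  expect_equal(fit_stats(y, rep(mean(y), 4))$R2, 0)
  # zero variance in observations: R2 undefined
  expect_true(is.na(fit_stats(c(2, 2), c(2, 2.1))$R2))
})

test_that("sequential single-factor search solves separable problems", {
  # separable quadratic with the minimizer on the grid: exact in <= 2 cycles
  obj <- function(p) (p[["a"]] - 2)^2 + 3 * (p[["b"]] + 1)^2
  grids <- list(a = seq(-3, 3), b = seq(-3, 3))
  fit <- sequential_search(obj, grids)
  expect_equal(unname(fit$par), c(2, -1))
  expect_equal(fit$value, 0)
  # budget bound: at most (cycles + 1) * sum of grid sizes evaluations
  expect_lte(fit$n_eval, 3 * sum(lengths(grids)) + 1)

  # incumbent objective never increases along the trace of accepted moves
  expect_true(all(diff(cummin(fit$trace$value)) <= 0))

  # failing objective points are skipped with a warning
  obj_bad <- function(p) if (p[["a"]] == 0) stop("boom") else (p[["a"]] - 1)^2
  expect_warning(fitb <- sequential_search(obj_bad, list(a = -2:2)),
                 "objective failed")
  expect_equal(unname(fitb$par), 1)
})

test_that("DVS simulator honours its limiting regimes", {
  pro_eq <- dvs_protocol(RH_steps = c(0.7, 0.5, 0.3, 0.5, 0.7),
                         dwell_h = 50, k_cond = 1)
  # instant relaxation (tau -> 0): no hysteresis, end states on the
  # relaxed isotherm
  cfg_fast <- default_config(viscoelastic = list(F_tau = c(1e-12, 1e-12)))
  eq <- simulate_dvs(pro_eq, cfg_fast)
  expect_equal(eq$steps$aw_end, eq$steps$RH, tolerance = 1e-4)
  i_des <- which(eq$steps$RH == 0.5 & eq$steps$branch == "desorption")
  i_ads <- which(eq$steps$RH == 0.5 & eq$steps$branch == "adsorption")
  expect_equal(eq$steps$Xm_end[i_des], eq$steps$Xm_end[i_ads],
               tolerance = 1e-4)

  # sealed sample (k = 0): moisture never changes
  sealed <- simulate_dvs(dvs_protocol(k_cond = 0), default_config())
  expect_equal(diff(range(sealed$steps$Xm_end)), 0, tolerance = 1e-12)

  # slow matrix (tau >> dwell): desorption branch holds at least as much
  # water as adsorption at every shared RH
  cfg_slow <- default_config(viscoelastic = list(F_G = c(0.1, 3),
                                                 F_tau = c(10, 100)))
  hys <- simulate_dvs(dvs_protocol(), cfg_slow)$steps
  des <- hys[hys$branch == "desorption", ]
  ads <- hys[hys$branch == "adsorption", ]
  shared <- intersect(des$RH, ads$RH)
  for (rh in shared) {
    expect_gte(des$Xm_end[des$RH == rh], ads$Xm_end[ads$RH == rh] - 1e-9)
  }
  # and the wet-end hysteresis is material, not numerical noise
  expect_gt(des$Xm_end[des$RH == 0.8] - ads$Xm_end[ads$RH == 0.8], 0.001)
})

test_that("sorption-factor refit recovers a generating quadruple", {
  # small smoke version of the full recovery (3-step protocol, 3 factors
  # distinguishable): the full-grid version lives in the acceptance suite
  pro <- dvs_protocol(RH_steps = c(0.8, 0.4, 0.8), dwell_h = 6)
  truth <- default_config(viscoelastic = list(F_G = c(1, 3), F_tau = c(10, 10)))
  obs <- simulate_dvs(pro, truth)$steps
  fit <- fit_sorption_factors(obs, pro, default_config(),
                              grid = c(0.3, 1, 3, 10, 30))
  expect_equal(fit$value, 0)
  expect_equal(unname(fit$par[c("F_G1", "F_tau00")]), c(3, 10))
})

test_that("tidiers expose fits in broom shape", {
  obj <- function(p) (p[["a"]] - 1)^2
  fit <- sequential_search(obj, list(a = 0:3))
  td <- tidy(fit)
  expect_named(td, c("term", "estimate"))
  expect_equal(td$estimate, 1)
  gl <- glance(fit)
  expect_named(gl, c("objective", "n_eval"))
  expect_equal(gl$objective, 0)
})
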