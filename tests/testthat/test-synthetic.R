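test_that("drying-record generator is exact at zero noise and seeded", {
  cfg <- fast_config()
  amb <- ambient_schedule(0, 35, 0.3, 0.3)
  g0 <- gen_drying_experiment(cfg, amb, t_end_h = 4, sample_interval_h = 0.5,
                              noise = noise_spec(0, 0, seed = 1))
  expect_equal(g0$record$data$yw_wb, g0$truth$yw_wb)
  expect_equal(g0$record$data$T_center_C, g0$truth$T_center_C)

  gA <- gen_drying_experiment(cfg, amb, t_end_h = 4,
                              noise = noise_spec(0.01, 0.2, seed = 42))
  gB <- gen_drying_experiment(cfg, amb, t_end_h = 4,
                              noise = noise_spec(0.01, 0.2, seed = 42))
  gC <- gen_drying_experiment(cfg, amb, t_end_h = 4,
                              noise = noise_spec(0.01, 0.2, seed = 43))
  expect_identical(gA$record$data, gB$record$data)
  expect_false(identical(gA$record$data$yw_wb, gC$record$data$yw_wb))
})

test_that("moisture noise has the configured magnitude", {
  cfg <- fast_config()
  cfg$solver$save_interval_h <- 0.05
  g <- gen_drying_experiment(cfg, ambient_schedule(0, 35, 0.3, 0.3),
                             t_end_h = 8, sample_interval_h = 0.05,
                             noise = noise_spec(sigma_yw = 0.01, seed = 5))
  rmse <- sqrt(mean((g$record$data$yw_wb - g$truth$yw_wb)^2))
  expect_equal(rmse, 0.01, tolerance = 0.3)  # >= 100 samples
  expect_gte(nrow(g$record$data), 100)
})

test_that("oscillating RH schedules average to the base humidity", {
  sch <- gen_rh_schedule(0.3, 0.1, period_h = 1, duration_h = 10,
                         shape = "sine")
  expect_equal(mean(sch$RH[-nrow(sch)]), 0.3, tolerance = 1e-12)
  expect_true(all(sch$RH >= 0.2 - 1e-12 & sch$RH <= 0.4 + 1e-12))

  sq <- gen_rh_schedule(0.3, 0.1, period_h = 1, duration_h = 10)
  expect_equal(mean(sq$RH[-nrow(sq)]), 0.3, tolerance = 1e-12)

  flat <- gen_rh_schedule(0.3, 0, period_h = 1, duration_h = 10)
  expect_true(all(flat$RH == 0.3))

  expect_error(gen_rh_schedule(0.3, 0.4, 1, 10), "\\[0, 1\\]")
  expect_error(gen_rh_schedule(0.95, 0.1, 1, 10), "\\[0, 1\\]")
})

test_that("humid spells under on/off control cool the interior", {
  cfg <- truth_config(geometry = list(N = 10, fresh_mass = 5e-3))
  base <- simulate_drying(cfg, ambient_schedule(0, 35, 0.3, 0.3),
                          t_end_h = 8)
  osc <- simulate_drying(
    cfg, gen_rh_schedule(0.3, 0.25, period_h = 2, duration_h = 8),
    t_end_h = 8)
  # center temperature under oscillating RH shows dips the constant-RH
  # run does not have (high-RH phases damp evaporative flux and the
  # subsequent low-RH phases re-cool)
  d_osc <- diff(osc$series$T_center_C)
  expect_gt(sum(d_osc < -0.05), 0)
  expect_gt(stats::sd(diff(osc$series$T_center_C)),
            stats::sd(diff(base$series$T_center_C)))
})

test_that("synthetic CPMG decay matches its closed form", {
  d <- gen_cpmg_decay(tibble::tibble(T2_ms = 100, amplitude = 1),
                      NECH = 200, SNR = Inf)
  expect_equal(d$signal[1], exp(-0.5 / 100), tolerance = 1e-12)
  expect_equal(d$signal, exp(-d$t_ms / 100), tolerance = 1e-12)

  # default acquisition covers 6000 ms: signals with T2 <= 1000 ms decay out
  dfull <- gen_cpmg_decay(tibble::tibble(T2_ms = 1000, amplitude = 1),
                          SNR = Inf)
  expect_equal(nrow(dfull), 12000)
  expect_lt(dplyr::last(dfull$signal), 1e-2)

  # zero populations give the zero signal
  d0 <- gen_cpmg_decay(tibble::tibble(T2_ms = numeric(), amplitude = numeric()),
                       NECH = 10, SNR = 200)
  expect_true(all(d0$signal == 0))

  # seeded reproducibility
  dA <- gen_cpmg_decay(tibble::tibble(T2_ms = 100, amplitude = 1),
                       NECH = 50, SNR = 100, seed = 2)
  dB <- gen_cpmg_decay(tibble::tibble(T2_ms = 100, amplitude = 1),
                       NECH = 50, SNR = 100, seed = 2)
  expect_identical(dA$signal, dB$signal)
})

test_that("generation-inversion round trip recovers the population count", {
  fresh <- invert_t2(gen_cpmg_decay(
    tibble::tibble(T2_ms = c(50, 400), amplitude = c(1, 0.8)), SNR = Inf))
  for (seed in 1:3) {
    d <- gen_cpmg_decay(tibble::tibble(T2_ms = c(40, 600),
                                       amplitude = c(0.6, 0.5)),
                        SNR = 150, seed = seed)
    expect_equal(count_populations(invert_t2(d), fresh), 2)
  }
})
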