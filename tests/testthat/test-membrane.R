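test_that("T2 inversion recovers synthetic spectra", {
  # noise-free single population at 100 ms
  d1 <- gen_cpmg_decay(tibble::tibble(T2_ms = 100, amplitude = 1), SNR = Inf)
  s1 <- invert_t2(d1)
  expect_equal(sum(s1$amplitude), 1, tolerance = 0.02)
  in_decade <- s1$T2_ms > 10^1.5 & s1$T2_ms < 10^2.5
  expect_gte(sum(s1$amplitude[in_decade]) / sum(s1$amplitude), 0.95)

  # zero signal inverts to the zero spectrum
  s0 <- invert_t2(gen_cpmg_decay(tibble::tibble(T2_ms = 100, amplitude = 0),
                                 NECH = 1000, SNR = Inf))
  expect_true(all(s0$amplitude == 0))

  # two well-separated components at SNR 200: two maxima, masses 0.5 each
  d2 <- gen_cpmg_decay(tibble::tibble(T2_ms = c(30, 500),
                                      amplitude = c(0.5, 0.5)),
                       SNR = 200, seed = 7)
  s2 <- invert_t2(d2)
  split_T2 <- sqrt(30 * 500)
  expect_equal(sum(s2$amplitude[s2$T2_ms < split_T2]), 0.5, tolerance = 0.1)
  expect_equal(sum(s2$amplitude[s2$T2_ms >= split_T2]), 0.5, tolerance = 0.1)
  expect_equal(count_populations(s2, s1), 2)
})

test_that("inversion residual sits at the noise floor", {
  # in the signal-dominated window the relative residual is bounded by
  # ~2/SNR; with a long pure-noise tail it approaches the noise floor
  d <- gen_cpmg_decay(tibble::tibble(T2_ms = 100, amplitude = 1),
                      NECH = 120, SNR = 200, seed = 3)
  s <- invert_t2(d, thin = 1)
  expect_lte(attr(s, "residual_rel"), 2 / 200)
})

test_that("population counting applies the 5% rule", {
  grid <- 10^seq(-1, 4, length.out = 200)
  mk <- function(centers, amps, width = 0.08) {
    a <- rep(0, length(grid))
    for (i in seq_along(centers)) {
      a <- a + amps[i] * exp(-(log10(grid / centers[i]))^2 / (2 * width^2))
    }
    tibble::tibble(T2_ms = grid, amplitude = a)
  }
  fresh <- mk(c(50, 300), c(1, 0.8))

  expect_equal(count_populations(mk(c(50, 300), c(0.5, 0.3)), fresh), 2)
  expect_equal(count_populations(mk(50, 0.04), fresh), 0)   # sub-threshold
  expect_equal(count_populations(mk(50, 0.06), fresh), 1)   # >= comparator
  expect_equal(count_populations(mk(50, 0.5), fresh), 1)

  # invariant to rescaling spectrum and reference together
  sp <- mk(c(50, 300), c(0.5, 0.055))
  for (s in c(0.1, 1, 42)) {
    sps <- sp; sps$amplitude <- s * sp$amplitude
    frs <- fresh; frs$amplitude <- s * fresh$amplitude
    expect_equal(count_populations(sps, frs), count_populations(sp, fresh))
  }

  # plateau maxima count once
  plat <- tibble::tibble(T2_ms = grid,
                         amplitude = c(rep(0, 80), rep(0.5, 20),
                                       rep(0, 100)))
  expect_equal(count_populations(plat, fresh), 1)
  expect_error(count_populations(sp, mk(50, 0)), "positive maximum")
})

test_that("membrane classifier honours strict thresholds", {
  expect_equal(classify_state(35, 0.50), "intact")
  expect_equal(classify_state(45, 0.50), "compromised")
  expect_equal(classify_state(35, 0.02), "compromised")
  # boundary semantics: exactly at threshold is intact (strict > and <)
  expect_equal(classify_state(40, 0.5), "intact")
  expect_equal(classify_state(35, 0.03), "intact")
  expect_equal(classify_state(40 + 1e-9, 0.5), "compromised")
  expect_equal(classify_state(35, 0.03 - 1e-9), "compromised")
  # vectorized and pure
  expect_equal(classify_state(c(30, 50), c(0.5, 0.5)),
               c("intact", "compromised"))
})

test_that("trajectory overlay classifies and interpolates the contour", {
  ser <- tibble::tibble(
    time_h = 0:10,
    yw_wb = seq(0.9, 0.02, length.out = 11),
    Xm_db = NA, T_center_C = seq(25, 45, length.out = 11),
    T_surface_C = NA, aw_center = NA, aw_surface = NA
  )
  res <- structure(list(series = ser), class = "drying_result")
  ov <- overlay_trajectory(res)
  # exactly one flip as the trajectory crosses the 40 degC line
  flips <- sum(diff(ov$state == "compromised") != 0)
  expect_equal(flips, 1)
  expect_equal(ov$state[1], "intact")
  expect_equal(ov$state[nrow(ov)], "compromised")

  # bilinear contour lookup: exact on a bilinear surface, NA outside
  grid <- tidyr::expand_grid(Tp_C = seq(20, 50, 5), yw = seq(0, 1, 0.1))
  grid$conductivity_uS_cm <- 2 * grid$Tp_C + 30 * grid$yw
  ov2 <- overlay_trajectory(res, times_h = c(2, 5), conductivity = grid)
  expect_equal(ov2$conductivity, 2 * ov2$Tp_C + 30 * ov2$yw,
               tolerance = 1e-10)
  out <- overlay_trajectory(res, times_h = 5,
                            conductivity = grid[grid$Tp_C <= 30, ])
  expect_true(is.na(out$conductivity))
  expect_false(is.na(out$state))
})

test_that("cool trajectories stay intact end to end", {
  ser <- tibble::tibble(time_h = 0:5, yw_wb = seq(0.9, 0.10, length.out = 6),
                        T_center_C = seq(25, 35, length.out = 6))
  res <- structure(list(series = ser), class = "drying_result")
  expect_true(all(overlay_trajectory(res)$state == "intact"))
})
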