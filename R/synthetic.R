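#' Noise specification for synthetic experiments
#'
#' @param sigma_yw Gaussian noise s.d. on wet-basis moisture.
#' @param sigma_T Gaussian noise s.d. on temperatures (K).
#' @param seed integer seed; the generators are pure functions of
#'   (parameters, seed).
#' @return list of class `noise_spec`.
#' @export
noise_spec <- function(sigma_yw = 0, sigma_T = 0, seed = 1L) {
  stopifnot(sigma_yw >= 0, sigma_T >= 0)
  structure(list(sigma_yw = sigma_yw, sigma_T = sigma_T,
                 seed = as.integer(seed)),
            class = "noise_spec")
}

#' Generate a pseudo-experimental drying record
#'
#' Runs the drying model under `config` and `ambient`, samples the
#' moisture and center-temperature curves at a fixed interval and adds
#' seeded Gaussian noise, emulating a logged drying experiment. With
#' zero noise the record equals the simulation at the sample times
#' exactly, which is what the self-consistency calibration tests rely
#' on.
#'
#' @param config model configuration holding the ground-truth
#'   parameters.
#' @param ambient an [ambient_schedule()].
#' @param t_end_h duration (h).
#' @param sample_interval_h sampling interval (h).
#' @param noise a [noise_spec()].
#' @return list with `record` (an [experiment_record()]), `truth` (the
#'   noise-free sampled tibble) and `simulation` (the full
#'   `drying_result`).
#' @export
gen_drying_experiment <- function(config = default_config(),
                                  ambient = NULL,
                                  t_end_h = 48,
                                  sample_interval_h = 0.5,
                                  noise = noise_spec()) {
  if (is.null(ambient)) {
    ambient <- ambient_schedule(0, T_air_C = 35, RH = 0.3, u_air_m_s = 0.3)
  }
  cfg <- config
  cfg$solver$save_interval_h <- sample_interval_h
  sim <- simulate_drying(cfg, ambient, t_end_h = t_end_h)
  tt <- seq(sample_interval_h, t_end_h, by = sample_interval_h)
  truth <- tibble::tibble(
    time_h = tt,
    yw_wb = stats::approx(sim$series$time_h, sim$series$yw_wb, tt)$y,
    T_center_C = stats::approx(sim$series$time_h, sim$series$T_center_C, tt)$y
  )
  old <- .Random.seed_exists()
  set.seed(noise$seed)
  rec <- truth
  rec$yw_wb <- pmin(1 - 1e-9, pmax(1e-9,
    rec$yw_wb + stats::rnorm(nrow(rec), 0, noise$sigma_yw)))
  rec$T_center_C <- rec$T_center_C + stats::rnorm(nrow(rec), 0, noise$sigma_T)
  .Random.seed_restore(old)
  list(
    record = experiment_record(rec$time_h, rec$yw_wb, rec$T_center_C,
                               ambient,
                               T_init_C = config$geometry$T_init_C,
                               T_air_C = max(ambient$T_air_C)),
    truth = truth,
    simulation = sim
  )
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' Generate an oscillating relative-humidity schedule
#'
#' Square or sine oscillation of the RH about a base value, emulating
#' the on/off humidity control of a drying oven; the mean over an
#' integer number of periods equals the base RH.
#'
#' @param base_RH base relative humidity.
#' @param amplitude oscillation amplitude (`base_RH + amplitude <= 1`,
#'   `amplitude <= base_RH`).
#' @param period_h oscillation period (h).
#' @param duration_h schedule length (h).
#' @param T_air_C,u_air_m_s constant temperature and velocity.
#' @param shape "square" or "sine".
#' @param samples_per_period time resolution.
#' @return an [ambient_schedule()].
#' @export
gen_rh_schedule <- function(base_RH, amplitude, period_h, duration_h,
                            T_air_C = 35, u_air_m_s = 0.3,
                            shape = c("square", "sine"),
                            samples_per_period = 16) {
  shape <- match.arg(shape)
  if (amplitude > base_RH || base_RH + amplitude > 1)
    stop("oscillation leaves [0, 1]: need amplitude <= base_RH and base_RH + amplitude <= 1")
  if (amplitude == 0) {
    return(ambient_schedule(c(0, duration_h), T_air_C, base_RH, u_air_m_s))
  }
  tt <- seq(0, duration_h, by = period_h / samples_per_period)
  phase <- (tt %% period_h) / period_h
  osc <- if (shape == "square") {
    ifelse(phase < 0.5, 1, -1)
  } else {
    sin(2 * pi * phase)
  }
  ambient_schedule(tt, T_air_C, base_RH + amplitude * osc, u_air_m_s)
}

#' Generate a synthetic CPMG decay
#'
#' Multi-exponential transverse-relaxation decay sampled at the echo
#' times `t_n = n TE`, plus seeded Gaussian noise scaled to the requested
#' signal-to-noise ratio.
#'
#' @param populations tibble (or data.frame) with columns `T2_ms` and
#'   `amplitude` (>= 0).
#' @param TE_ms echo time (ms).
#' @param NECH number of echoes.
#' @param SNR signal-to-noise ratio (noise s.d. = max signal / SNR);
#'   `Inf` for noise-free.
#' @param seed integer seed.
#' @return tibble of class `cpmg_decay` with columns `t_ms`, `signal`.
#' @export
#' @examples
#' d <- gen_cpmg_decay(tibble::tibble(T2_ms = 100, amplitude = 1),
#'                     NECH = 100, SNR = Inf)
#' d$signal[1]  # exp(-0.5/100)
gen_cpmg_decay <- function(populations, TE_ms = 0.5, NECH = 12000,
                           SNR = Inf, seed = 1L) {
  stopifnot(all(populations$T2_ms > 0), all(populations$amplitude >= 0),
            NECH >= 1, TE_ms > 0)
  t_n <- seq_len(NECH) * TE_ms
  S <- if (nrow(populations) == 0) {
    rep(0, NECH)
  } else {
    as.vector(exp(-outer(t_n, populations$T2_ms, "/")) %*%
                populations$amplitude)
  }
  if (is.finite(SNR) && max(S) > 0) {
    old <- .Random.seed_exists()
    set.seed(as.integer(seed))
    S <- S + stats::rnorm(NECH, 0, max(S) / SNR)
    .Random.seed_restore(old)
  }
  out <- tibble::tibble(t_ms = t_n, signal = S)
  class(out) <- c("cpmg_decay", class(out))
  out
}
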