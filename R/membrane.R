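#' Invert a CPMG decay into a T2 spectrum
#'
#' Multi-exponential inversion of a transverse-relaxation decay: solves
#' the Tikhonov-regularized non-negative least squares problem
#' \deqn{\min_{A \ge 0} \|K A - S\|^2 + \alpha^2 \|A\|^2,\quad
#'       K_{nk} = e^{-t_n/T_{2,k}}}
#' on a logarithmic relaxation-time grid. `alpha = "auto"` picks the
#' regularization by the discrepancy principle: the smallest grid alpha
#' whose residual reaches the noise level estimated from the decay tail.
#'
#' @param decay tibble with columns `t_ms` and `signal` (as from
#'   [gen_cpmg_decay()]).
#' @param grid relaxation-time grid (ms); default 128 log-spaced points
#'   over 0.1 to 1e4 ms.
#' @param alpha regularization parameter, or "auto".
#' @param thin use every `thin`-th echo to keep the kernel small; the
#'   default adapts so at most ~2000 echoes enter the inversion.
#' @return object of class `t2_spectrum`: tibble with columns `T2_ms`
#'   and `amplitude` (>= 0), with the chosen `alpha` and the relative
#'   residual as attributes.
#' @export
invert_t2 <- function(decay, grid = NULL, alpha = "auto", thin = NULL) {
  if (is.null(grid)) grid <- 10^seq(log10(0.1), log10(1e4), length.out = 128)
  stopifnot(!is.unsorted(grid, strictly = TRUE))
  if (length(decay$t_ms) < length(grid) / 4)
    stop("decay too short for the requested grid")
  if (is.null(thin)) thin <- max(1L, floor(length(decay$t_ms) / 2000))
  idx <- seq(1, length(decay$t_ms), by = thin)
  t_n <- decay$t_ms[idx]
  S <- decay$signal[idx]
  if (all(S == 0)) {
    out <- tibble::tibble(T2_ms = grid, amplitude = 0)
    return(structure(out, class = c("t2_spectrum", class(out)),
                     alpha = 0, residual_rel = 0))
  }
  K <- exp(-outer(t_n, grid, "/"))
  # first differences cancel the (slowly varying) decay, leaving the noise
  noise <- stats::sd(diff(utils::tail(S, max(10, length(S) %/% 5)))) / sqrt(2)
  target <- noise * sqrt(length(S))
  solve_a <- function(a) {
    Kaug <- rbind(K, diag(a, length(grid)))
    Saug <- c(S, rep(0, length(grid)))
    A <- pracma::lsqnonneg(Kaug, Saug)$x
    list(A = A, resid = sqrt(sum((K %*% A - S)^2)))
  }
  if (identical(alpha, "auto")) {
    alphas <- 10^seq(-4, 1, length.out = 11) * sqrt(mean(S^2))
    sol <- NULL; a_used <- alphas[1]
    for (a in alphas) {
      sol <- solve_a(a)
      a_used <- a
      if (sol$resid >= target && target > 0) break
    }
  } else {
    a_used <- alpha
    sol <- solve_a(alpha)
  }
  out <- tibble::tibble(T2_ms = grid, amplitude = sol$A)
  structure(out, class = c("t2_spectrum", class(out)),
            alpha = a_used,
            residual_rel = sol$resid / sqrt(sum(S^2)))
}

#' Count water populations in a T2 spectrum
#'
#' Counts local maxima of the spectrum whose amplitude reaches at least
#' `threshold` times the global maximum of the fresh-sample reference
#' spectrum (plateau maxima count once). Two populations indicate the
#' vacuole and cytoplasm/wall water pools are still separated by an
#' intact membrane; their merger into one is the NMR signature of
#' integrity loss.
#'
#' @param spectrum,fresh_reference `t2_spectrum` objects (tibbles with
#'   `T2_ms`, `amplitude`).
#' @param threshold relative amplitude threshold (default 5%).
#' @return integer population count.
#' @export
count_populations <- function(spectrum, fresh_reference, threshold = 0.05) {
  ref_max <- max(fresh_reference$amplitude)
  if (!(ref_max > 0)) stop("fresh reference spectrum must have positive maximum")
  a <- spectrum$amplitude
  cut <- threshold * ref_max
  n <- length(a)
  if (n < 3) return(as.integer(any(a >= cut)))
  # local maxima with plateau handling: runs of equal value count once
  count <- 0L
  i <- 2L
  while (i <= n - 1L) {
    if (a[i] > a[i - 1L]) {
      j <- i
      while (j < n && a[j + 1L] == a[j]) j <- j + 1L
      if (j <= n && (j == n || a[j + 1L] < a[j]) && a[i] >= cut)
        count <- count + 1L
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  # edge maxima
  if (a[1L] > a[2L] && a[1L] >= cut) count <- count + 1L
  if (a[n] > a[n - 1L] && a[n] >= cut) count <- count + 1L
  count
}

#' Classify cell-membrane integrity from the product state
#'
#' The membrane is compromised when the product temperature exceeds
#' `T_crit` (lipid-bilayer fluid-to-gel transition) or the moisture falls
#' below `yw_crit` wet basis (osmotic stress); the thresholds are strict
#' inequalities, so states exactly at a threshold classify as intact.
#'
#' @param T_p product temperature (degC), vectorized.
#' @param y_w moisture content wet basis in [0, 1], vectorized.
#' @param T_crit,yw_crit thresholds (default 40 degC and 3% w.b.).
#' @return character vector, "intact" or "compromised".
#' @export
#' @examples
#' classify_state(c(35, 45, 35), c(0.5, 0.5, 0.02))
classify_state <- function(T_p, y_w, T_crit = 40, yw_crit = 0.03) {
  ifelse(T_p > T_crit | y_w < yw_crit, "compromised", "intact")
}

#' Overlay a drying trajectory on the membrane state diagram
#'
#' Samples the product state (center temperature, average wet-basis
#' moisture) from a drying simulation, classifies each point, and
#' optionally interpolates a user-supplied electrical-conductivity
#' contour map (long-format grid) bilinearly at each point. Points
#' outside the contour grid get `NA` conductivity but are still
#' classified.
#'
#' @param result a `drying_result`.
#' @param times_h sample times (h); default the stored series times.
#' @param conductivity optional tibble with columns `Tp_C`, `yw`,
#'   `conductivity_uS_cm` on a rectangular grid.
#' @param T_crit,yw_crit thresholds passed to [classify_state()].
#' @return tibble with `time_h`, `Tp_C`, `yw`, `state`, `conductivity`.
#' @export
overlay_trajectory <- function(result, times_h = NULL, conductivity = NULL,
                               T_crit = 40, yw_crit = 0.03) {
  ser <- result$series
  stopifnot(nrow(ser) > 0)
  if (is.null(times_h)) times_h <- ser$time_h
  Tp <- stats::approx(ser$time_h, ser$T_center_C, xout = times_h, rule = 2)$y
  yw <- stats::approx(ser$time_h, ser$yw_wb, xout = times_h, rule = 2)$y
  cond <- rep(NA_real_, length(times_h))
  if (!is.null(conductivity)) {
    xs <- sort(unique(conductivity$Tp_C))
    ys <- sort(unique(conductivity$yw))
    z <- matrix(NA_real_, length(xs), length(ys))
    z[cbind(match(conductivity$Tp_C, xs), match(conductivity$yw, ys))] <-
      conductivity$conductivity_uS_cm
    cond <- vapply(seq_along(times_h), function(k) {
      bilinear_at(xs, ys, z, Tp[k], yw[k])
    }, numeric(1))
  }
  tibble::tibble(
    time_h = times_h, Tp_C = Tp, yw = yw,
    state = classify_state(Tp, yw, T_crit, yw_crit),
    conductivity = cond
  )
}

bilinear_at <- function(xs, ys, z, x, y) {
  if (x < xs[1] || x > xs[length(xs)] || y < ys[1] || y > ys[length(ys)])
    return(NA_real_)
  i <- max(1L, min(findInterval(x, xs), length(xs) - 1L))
  j <- max(1L, min(findInterval(y, ys), length(ys) - 1L))
  tx <- (x - xs[i]) / (xs[i + 1] - xs[i])
  ty <- (y - ys[j]) / (ys[j + 1] - ys[j])
  (1 - tx) * (1 - ty) * z[i, j] + tx * (1 - ty) * z[i + 1, j] +
    (1 - tx) * ty * z[i, j + 1] + tx * ty * z[i + 1, j + 1]
}
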