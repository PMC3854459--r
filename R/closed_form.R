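#' Eigen-rates of the two-pool burst system
#'
#' For the refilling-free burst model `NRP <-> RRP -> F` with constant
#' rates (`k2`, `k_minus2`, `k3`), the pre-fusion dynamics are linear with
#' decay rates given by the roots of
#' `lambda^2 - (k2 + k_minus2 + k3) * lambda + k2 * k3 = 0`.
#' The discriminant is nonnegative for any nonnegative rates, so both
#' roots are real; Vieta: `lambda1 + lambda2 = k2 + k_minus2 + k3` and
#' `lambda1 * lambda2 = k2 * k3`.
#'
#' @param k2,k_minus2,k3 Rates, 1/s (nonnegative, not all zero).
#' @return Named vector `c(lambda_fast, lambda_slow)` with
#'   `lambda_fast >= lambda_slow`, 1/s.
#' @export
eigenrates <- function(k2, k_minus2, k3) {
  if (any(c(k2, k_minus2, k3) < 0)) abort("Rates must be >= 0.")
  if (k2 + k_minus2 + k3 == 0) abort("At least one rate must be positive.")
  s <- k2 + k_minus2 + k3
  disc <- s^2 - 4 * k2 * k3
  stopifnot(disc >= -1e-12 * s^2)
  sq <- sqrt(max(disc, 0))
  c(lambda_fast = (s + sq) / 2, lambda_slow = (s - sq) / 2)
}

#' Closed-form burst decomposition of the two-pool model
#'
#' Analytic solution of the burst phase used for SNARE-mutation analysis.
#' Before stimulation the NRP and RRP are in equilibrium with fusion shut
#' off, so `NRP0 = V_tot * k_minus2 / (k2 + k_minus2)` and
#' `RRP0 = V_tot * k2 / (k2 + k_minus2)`. After the stimulus the
#' capacitance change is exactly a sum of two saturating exponentials,
#' `dCm(t) = A_fast * (1 - exp(-lambda_fast * t)) + A_slow * (1 -
#' exp(-lambda_slow * t))`, whose amplitudes follow from the
#' eigen-decomposition and satisfy `A_fast + A_slow = V_tot`.
#'
#' The measure-zero repeated-eigenvalue case is flagged `degenerate`; the
#' trace is then evaluated through the limit form
#' `V_tot - (V_tot + c*t) * exp(-lambda*t)` and the amplitude split is
#' undefined (`NA`).
#'
#' @param k2,k_minus2,k3 Rates, 1/s (positive).
#' @param V_tot Total burst size, fF (default 113.6, the summed published
#'   fast and slow pool sizes).
#' @return An object of class `"closed_form_burst"` with eigen-rates,
#'   time constants, amplitudes and initial pools.
#' @examples
#' cf <- closed_form_burst(k2 = 5.26, k_minus2 = 3.80, k3 = 20)
#' cf$A_fast + cf$A_slow # V_tot
#' @export
closed_form_burst <- function(k2, k_minus2, k3, V_tot = 113.6) {
  if (any(c(k2, k_minus2, k3) <= 0)) abort("Rates must be > 0.")
  if (V_tot <= 0) abort("`V_tot` must be > 0.")
  lam <- eigenrates(k2, k_minus2, k3)
  lf <- lam[["lambda_fast"]]; ls <- lam[["lambda_slow"]]
  NRP0 <- V_tot * k_minus2 / (k2 + k_minus2)
  RRP0 <- V_tot * k2 / (k2 + k_minus2)
  x0 <- c(NRP0, RRP0)
  degenerate <- (lf - ls) <= 1e-9 * lf
  if (!degenerate) {
    # eigenvectors of [[-k2, km2], [k2, -(km2+k3)]] for eigenvalues -lambda
    V <- cbind(c(k_minus2, k2 - lf), c(k_minus2, k2 - ls))
    cc <- solve(V, x0)
    A_fast <- cc[1] * (k_minus2 + k2 - lf)
    A_slow <- cc[2] * (k_minus2 + k2 - ls)
  } else {
    A_fast <- NA_real_
    A_slow <- NA_real_
  }
  structure(list(k2 = k2, k_minus2 = k_minus2, k3 = k3, V_tot = V_tot,
                 NRP0 = NRP0, RRP0 = RRP0,
                 lambda_fast = lf, lambda_slow = ls,
                 tau_fast = 1 / lf, tau_slow = 1 / ls,
                 A_fast = unname(A_fast), A_slow = unname(A_slow),
                 degenerate = degenerate),
            class = "closed_form_burst")
}

#' Evaluate the closed-form capacitance change
#'
#' @param burst A [closed_form_burst()].
#' @param t Times after stimulus onset, s.
#' @return `dCm(t)`, fF.
#' @export
closed_form_release <- function(burst, t) {
  if (!burst$degenerate) {
    burst$A_fast * (1 - exp(-burst$lambda_fast * t)) +
      burst$A_slow * (1 - exp(-burst$lambda_slow * t))
  } else {
    lam <- burst$lambda_fast
    A <- matrix(c(-burst$k2, burst$k2, burst$k_minus2,
                  -(burst$k_minus2 + burst$k3)), 2, 2)
    x0 <- c(burst$NRP0, burst$RRP0)
    cc <- sum((A + lam * diag(2)) %*% x0)
    burst$V_tot - (burst$V_tot + cc * t) * exp(-lam * t)
  }
}

#' @export
print.closed_form_burst <- function(x, ...) {
  cat("<closed-form two-pool burst>\n")
  cat(sprintf("  rates: k2 = %.4g, k_minus2 = %.4g, k3 = %.4g /s\n",
              x$k2, x$k_minus2, x$k3))
  cat(sprintf("  fast: A = %.4g fF, tau = %.4g s; slow: A = %.4g fF, tau = %.4g s\n",
              x$A_fast, x$tau_fast, x$A_slow, x$tau_slow))
  invisible(x)
}

#' @rdname tidy.burst_fit
#' @method tidy closed_form_burst
#' @export
tidy.closed_form_burst <- function(x, ...) {
  tibble::tibble(
    term = c("lambda_fast", "lambda_slow", "tau_fast", "tau_slow",
             "A_fast", "A_slow"),
    estimate = c(x$lambda_fast, x$lambda_slow, x$tau_fast, x$tau_slow,
                 x$A_fast, x$A_slow),
    unit = c("1/s", "1/s", "s", "s", "fF", "fF"))
}

#' Scan the final fusion rate in the closed-form model
#'
#' Sweeps `k3` (the fusion rate perturbed by C-terminal SNARE mutation)
#' at fixed priming rates and reports how the fast and slow time constants
#' and the fast amplitude fraction co-vary: lowering `k3` simultaneously
#' slows fast release and shifts amplitude from the fast to the slow
#' component.
#'
#' @param k3_grid Positive fusion rates to evaluate, 1/s.
#' @param k2,k_minus2 Priming rates, 1/s (defaults from the global fit to
#'   the SNARE-mutant data: 5.26 and 3.80).
#' @param V_tot Total burst, fF.
#' @return A tibble of class `"pool_scan"`, one row per `k3`.
#' @export
snare_scan <- function(k3_grid, k2 = 5.26, k_minus2 = 3.80, V_tot = 113.6) {
  if (any(k3_grid <= 0)) abort("`k3_grid` must be positive.")
  rows <- purrr::map(k3_grid, function(k3) {
    cf <- closed_form_burst(k2, k_minus2, k3, V_tot)
    tibble::tibble(k3 = k3, tau_fast = cf$tau_fast, tau_slow = cf$tau_slow,
                   A_fast = cf$A_fast, A_slow = cf$A_slow,
                   fast_fraction = cf$A_fast / V_tot)
  })
  new_pool_scan(dplyr::bind_rows(rows), independent = "k3")
}

#' Effective drain rate of a three-site fusion sensor
#'
#' The slowest decay mode of a pool draining through the sequential
#' three-identical-site Ca2+ sensor at a fixed Ca2+ level: the smallest
#' eigen-rate of the four-state chain (pool, singly, doubly, triply bound,
#' fusing at `k4` from the last state). This is the single-exponential
#' fusion rate the cascade settles into once the binding steps have
#' equilibrated.
#'
#' @param ca Ca2+ level, uM.
#' @param k3,k_minus3 Per-site on (1/(s*uM)) and off (1/s) rates.
#' @param k4 Fusion rate from the triply bound state, 1/s.
#' @return Effective fusion rate, 1/s.
#' @export
sensor_drain_rate <- function(ca, k3, k_minus3, k4) {
  b <- k3 * ca; u <- k_minus3
  A <- matrix(c(-3 * b, 3 * b, 0, 0,
                u, -(u + 2 * b), 2 * b, 0,
                0, 2 * u, -(2 * u + b), b,
                0, 0, 3 * u, -(3 * u + k4)), 4, 4)
  ev <- eigen(A, only.values = TRUE)$values
  min(abs(Re(ev)))
}

#' Reduced-PPM comparator scan
#'
#' The parallel-model counterpart of [snare_scan()]: a reduced PPM with
#' fixed starting pools and no Depot refilling, in which each pool fuses
#' at a single effective rate — the RRP at `k_RRP = 1/tau_RRP` (the
#' independent variable, standing in for the strength of the mutated
#' fusion machinery) and the SRP at `k_srp`, by default the effective
#' drain rate of the slow sensor at the post-flash Ca2+ level
#' ([sensor_drain_rate()]). The Ca2+-independent SRP-RRP interconversion
#' is retained. Each grid point is simulated for `window` seconds and
#' decomposed with [fit_burst()]. Because pool sizes and release rates
#' are independent in the PPM, the fitted fast/slow amplitude split stays
#' nearly invariant as `k_RRP` varies — the flat comparator line against
#' which the sequential model's co-varying amplitudes stand out.
#'
#' @param k_rrp_grid Positive fusion rates for the RRP, 1/s.
#' @param rrp0,srp0 Starting pool sizes, fF (published values 61.3, 52.3).
#' @param params A [ppm_params()] supplying the interconversion and the
#'   slow-sensor rates.
#' @param post_ca Post-flash Ca2+, uM.
#' @param k_srp Effective SRP fusion rate, 1/s (default from the slow
#'   sensor at `post_ca`).
#' @param window Simulated/fit window, s.
#' @return A tibble of class `"pool_scan"`, one row per `k_RRP`.
#' @export
ppm_burst_scan <- function(k_rrp_grid, rrp0 = 61.3, srp0 = 52.3,
                           params = ppm_params(), post_ca = 25,
                           k_srp = NULL, window = 5) {
  if (any(k_rrp_grid <= 0)) abort("`k_rrp_grid` must be positive.")
  if (is.null(k_srp))
    k_srp <- sensor_drain_rate(post_ca, params$k3s, params$k_minus3s, params$k4s)
  rhs <- function(t, y, parms) {
    k_rrp <- parms
    S <- y[[1]]; R <- y[[2]]
    list(c(-(params$k2 + k_srp) * S + params$k_minus2 * R,
           params$k2 * S - (params$k_minus2 + k_rrp) * R,
           k_srp * S + k_rrp * R))
  }
  times <- seq(0, window, by = 1e-3)
  rows <- purrr::map(k_rrp_grid, function(k_rrp) {
    sol <- deSolve::rk(c(srp0, rrp0, 0), times, rhs, parms = k_rrp,
                       method = deSolve::rkMethod("rk45ck"),
                       rtol = 1e-8, atol = 1e-10, maxsteps = 1e5)
    fit <- fit_burst(tibble::tibble(t = sol[, 1], dCm = sol[, 4]),
                     t0 = 0, window = window)
    dplyr::bind_cols(tibble::tibble(k_RRP = k_rrp, k_srp = k_srp), glance(fit))
  })
  new_pool_scan(dplyr::bind_rows(rows), independent = "k_RRP")
}

new_pool_scan <- function(df, independent) {
  structure(df, class = c("pool_scan", class(tibble::tibble())),
            independent = independent)
}
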