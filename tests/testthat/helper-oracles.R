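# Independent numerical oracles, kept free of the package's solver path.

# Classical fixed-step 4th-order Runge-Kutta for the wild-type SPM driven by
# a pre/post Ca step. Derivatives are written out inline so the oracle shares
# no code with the package RHS.
rk4_spm_step_oracle <- function(params, y0, t0, t1, t_step, pre, post, dt) {
  f <- function(t, y) {
    ca <- if (t < t_step) pre else post
    g <- (ca / (params$K_D + ca))^params$n
    k2 <- params$k20 + params$k2cat * g
    km2 <- params$k_minus20 + (params$k2cat * params$k_minus20 / params$k20) * g
    k1 <- params$k1Max * ca / (params$K_M + ca)
    b <- params$k3 * ca
    u <- params$k_minus3
    c(k1 - (params$k_minus1 + k2) * y[1] + km2 * y[2],
      k2 * y[1] - (km2 + 3 * b) * y[2] + u * y[3],
      3 * b * y[2] - (u + 2 * b) * y[3] + 2 * u * y[4],
      2 * b * y[3] - (2 * u + b) * y[4] + 3 * u * y[5],
      b * y[4] - (3 * u + params$k4) * y[5],
      params$k4 * y[5])
  }
  # integrate each constant-ca piece separately so no step crosses the jump
  advance <- function(y, a, b) {
    n <- ceiling((b - a) / dt)
    h <- (b - a) / n
    t <- a
    for (i in seq_len(n)) {
      k1v <- f(t, y)
      k2v <- f(t + h / 2, y + h / 2 * k1v)
      k3v <- f(t + h / 2, y + h / 2 * k2v)
      k4v <- f(t + h, y + h * k3v)
      y <- y + h / 6 * (k1v + 2 * k2v + 2 * k3v + k4v)
      t <- a + i * h
    }
    y
  }
  y <- y0
  if (t0 < t_step && t1 > t_step) {
    y <- advance(y, t0, t_step)
    y <- advance(y, t_step, t1)
  } else {
    y <- advance(y, t0, t1)
  }
  y
}

# Reference solution of the two-pool burst system by a stiff multistep solver
# (deSolve::lsoda), independent of the analytic eigen-decomposition.
lsoda_two_pool_oracle <- function(k2, k_minus2, k3, V_tot, times) {
  rhs <- function(t, y, parms) {
    list(c(-k2 * y[1] + k_minus2 * y[2],
           k2 * y[1] - (k_minus2 + k3) * y[2]))
  }
  y0 <- c(V_tot * k_minus2 / (k2 + k_minus2), V_tot * k2 / (k2 + k_minus2))
  sol <- deSolve::lsoda(y0, times, rhs, parms = NULL,
                        rtol = 1e-12, atol = 1e-14)
  V_tot - sol[, 2] - sol[, 3]
}

# synthetic cumulative-release trace built directly from the fit function
make_burst_trace <- function(A1 = 60, tau1 = 0.02, A2 = 50, tau2 = 0.2,
                             A3 = 10, t0 = 0, A0 = 0, dt = 0.005, window = 5) {
  t <- seq(t0, t0 + window, by = dt)
  tibble::tibble(t = t, dCm = burst_model(t, A0, t0, A1, tau1, A2, tau2, A3))
}
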