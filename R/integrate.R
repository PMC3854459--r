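#' Adaptive solver settings
#'
#' Controls for the fifth-order Cash-Karp Runge-Kutta integrator with
#' embedded error estimation. Defaults: `rel_tol = 1e-8`,
#' `abs_tol = 1e-10` fF, dense output every 1 ms (the resolution scale of
#' capacitance recordings).
#'
#' @param rel_tol,abs_tol Relative / absolute local error tolerances.
#' @param h_init Initial step size, s.
#' @param h_max Maximum step size, s.
#' @param dense_output_dt Output grid spacing, s.
#' @param max_steps Maximum internal steps per output interval.
#' @return A list of class `"solver_settings"`.
#' @export
solver_settings <- function(rel_tol = 1e-8, abs_tol = 1e-10,
                            h_init = 1e-4, h_max = 0.05,
                            dense_output_dt = 1e-3, max_steps = 1e5) {
  if (rel_tol <= 0 || abs_tol <= 0) abort("Tolerances must be > 0.")
  if (h_init <= 0 || h_max <= 0 || h_init > h_max)
    abort("Need 0 < h_init <= h_max.")
  if (dense_output_dt <= 0) abort("`dense_output_dt` must be > 0.")
  structure(list(rel_tol = rel_tol, abs_tol = abs_tol, h_init = h_init,
                 h_max = h_max, dense_output_dt = dense_output_dt,
                 max_steps = max_steps),
            class = "solver_settings")
}

# fast scalar rate bundle used inside the integrator RHS
spm_rate_bundle <- function(ca, params, variant) {
  g <- (ca / (params$K_D + ca))^params$n
  k2 <- params$k20 + params$k2cat * g
  km2 <- params$k_minus20 + params$k_minus2cat * g
  if (variant$mode == "destabilized_syt_null") km2 <- km2 * variant$factor
  list(k1 = params$k1Max * ca / (params$K_M + ca), k2 = k2, km2 = km2,
       unclamp = if (variant$mode == "unclamped_syt_null") params$k4 else 0)
}

#' Integrate a pool model over a Ca2+ protocol
#'
#' Drives the SPM or PPM with a piecewise [ca_protocol()] using the
#' fifth-order Runge-Kutta pair with Cash-Karp coefficients and adaptive
#' step size (via \pkg{deSolve}). Integration restarts exactly at every
#' protocol segment boundary, so no adaptive step straddles a Ca2+
#' discontinuity. Alongside the pools, two bookkeeping series are
#' integrated by the solver itself: `dCm`, the cumulative capacitance
#' change (total fused mass), and `influx`, the cumulative net Depot
#' exchange — their difference from the summed pools gives a
#' mass-conservation residual at solver accuracy.
#'
#' @param model `"spm"` or `"ppm"`.
#' @param params Matching `pool_params` (defaults to the model's preset).
#' @param protocol A [ca_protocol()] covering `t_span`.
#' @param t_span Length-2 numeric, integration window in s.
#' @param variant SPM variant (ignored for the PPM).
#' @param init `"steady"` (resting steady state at `ca(t_span[1])`) or a
#'   named vector of pool occupancies.
#' @param settings A [solver_settings()].
#' @return A tibble of class `"pool_trace"`: columns `t`, `ca`, one per
#'   pool (fF), `dCm` and `influx`.
#' @examples
#' \donttest{
#' tr <- integrate_model("spm", protocol = ca_step_protocol(), t_span = c(0, 2))
#' tail(tr)
#' }
#' @export
integrate_model <- function(model = c("spm", "ppm"), params = NULL,
                            protocol, t_span,
                            variant = spm_variant("wt"), init = "steady",
                            settings = solver_settings()) {
  model <- match.arg(model)
  variant <- as_spm_variant(variant)
  if (is.null(params))
    params <- preset_params(if (model == "spm") "spm_table1" else "ppm_table2")
  if (!inherits(protocol, "ca_protocol")) protocol <- ca_protocol(protocol)
  if (length(t_span) != 2L || t_span[2] <= t_span[1])
    abort("`t_span` must be an increasing pair of times.")
  if (t_span[1] < protocol$t_start[1])
    abort("The protocol does not cover the start of `t_span`.")

  pool_names <- if (model == "spm") spm_state_names[1:5] else ppm_state_names[1:8]
  fused_names <- if (model == "spm") "dCm" else c("Fs", "Fr")

  if (identical(init, "steady")) {
    ca0 <- ca_at(protocol, t_span[1])
    ss <- if (model == "spm") spm_steady_state(ca0, params, variant)
          else ppm_steady_state(ca0, params)
    y0 <- ss$pools
  } else {
    if (is.null(names(init)) || !all(pool_names %in% names(init)))
      abort(paste0("`init` must name the pools: ", paste(pool_names, collapse = ", ")))
    y0 <- init[pool_names]
  }
  y0 <- c(y0, setNames(rep(0, length(fused_names)), fused_names), influx = 0)

  deriv <- if (model == "spm") {
    function(t, y, parms) {
      ca <- ca_at(protocol, t)
      rb <- spm_rate_bundle(ca, params, variant)
      b <- params$k3 * ca; u <- params$k_minus3; k4 <- params$k4
      N <- y[[1]]; R <- y[[2]]; C1 <- y[[3]]; C2 <- y[[4]]; C3 <- y[[5]]
      list(c(rb$k1 - (params$k_minus1 + rb$k2) * N + rb$km2 * R,
             rb$k2 * N - (rb$km2 + 3 * b + rb$unclamp) * R + u * C1,
             3 * b * R - (u + 2 * b + rb$unclamp) * C1 + 2 * u * C2,
             2 * b * C1 - (2 * u + b + rb$unclamp) * C2 + 3 * u * C3,
             b * C2 - (3 * u + k4) * C3,
             k4 * C3 + rb$unclamp * (R + C1 + C2),
             rb$k1 - params$k_minus1 * N))
    }
  } else {
    function(t, y, parms) {
      ca <- ca_at(protocol, t)
      d <- ppm_rhs(y[1:10], ca, params)
      list(c(unname(d),
             recruitment_rate(ca, params) - params$k_minus1 * y[[1]]))
    }
  }

  # segment-wise integration: restart at every protocol discontinuity
  breaks <- protocol$t_start[protocol$t_start > t_span[1] & protocol$t_start < t_span[2]]
  edges <- unique(c(t_span[1], breaks, t_span[2]))
  dt <- settings$dense_output_dt

  pieces <- vector("list", length(edges) - 1L)
  y <- y0
  for (i in seq_along(pieces)) {
    a <- edges[i]; b <- edges[i + 1L]
    times <- seq(a, b, by = dt)
    if (tail(times, 1L) < b) times <- c(times, b)
    sol <- deSolve::rk(y, times, deriv, parms = NULL,
                       method = deSolve::rkMethod("rk45ck"),
                       rtol = settings$rel_tol, atol = settings$abs_tol,
                       hini = settings$h_init, hmax = settings$h_max,
                       maxsteps = settings$max_steps)
    if (nrow(sol) < length(times) || any(!is.finite(sol)))
      abort(sprintf("Integration failed near t = %g s (step-size underflow or divergence).",
                    sol[nrow(sol), 1]))
    y <- sol[nrow(sol), -1]
    pieces[[i]] <- if (i == 1L) sol else sol[-1L, , drop = FALSE]
  }
  out <- do.call(rbind, pieces)

  trace <- tibble::as_tibble(as.data.frame(out))
  names(trace) <- c("t", pool_names, fused_names, "influx")
  trace$ca <- ca_at(protocol, trace$t)
  if (model == "ppm") trace$dCm <- trace$Fs + trace$Fr
  trace <- trace[, c("t", "ca", pool_names, fused_names[fused_names != "dCm"],
                     "dCm", "influx")]
  structure(trace,
            class = c("pool_trace", class(tibble::tibble())),
            model = model, variant = variant$mode,
            params = params, settings = settings)
}

#' @export
print.pool_trace <- function(x, ...) {
  cat("<pool trace: ", attr(x, "model"), ", ", nrow(x), " samples, ",
      format(min(x$t)), "-", format(max(x$t)), " s>\n", sep = "")
  NextMethod()
}
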