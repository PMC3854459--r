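#' Double-exponential-plus-line burst model
#'
#' The kinetic decomposition applied to cumulative-release traces:
#' `f(t) = A0 + A1*(1 - exp(-(t - t0)/tau1)) + A2*(1 - exp(-(t - t0)/tau2))
#' + A3*(t - t0)` for `t >= t0`. `A1`/`tau1` describe the fast burst,
#' `A2`/`tau2` the slow burst, and `A3` the slope of the sustained
#' component.
#'
#' @param t Times, s.
#' @param A0 Baseline, fF.
#' @param t0 Onset, s.
#' @param A1,tau1 Fast-burst amplitude (fF) and time constant (s).
#' @param A2,tau2 Slow-burst amplitude (fF) and time constant (s).
#' @param A3 Sustained slope, fF/s.
#' @return Model values, fF.
#' @export
burst_model <- function(t, A0, t0, A1, tau1, A2, tau2, A3) {
  tt <- t - t0
  A0 + A1 * (1 - exp(-tt / tau1)) + A2 * (1 - exp(-tt / tau2)) + A3 * tt
}

#' Locate the release onset of a cumulative trace
#'
#' The onset `t0` is the inflection point of cumulative release after
#' stimulus onset: the time at which the central-difference first
#' derivative of `dCm` is maximal. A trace whose derivative has no
#' interior maximum after the stimulus (flat or monotone-derivative
#' traces) yields `stim_time` itself, carrying attribute
#' `warning_flag = TRUE`.
#'
#' @param trace A data frame with columns `t` and `dCm` covering `stim_time`.
#' @param stim_time Stimulus onset, s.
#' @param search_window Longest lag after `stim_time` considered for the
#'   inflection, s (default unbounded). Bounding the search keeps slow
#'   late release from masquerading as the onset.
#' @return The onset time `t0` (s), with attribute `warning_flag`.
#' @export
find_onset <- function(trace, stim_time, search_window = Inf) {
  if (!all(c("t", "dCm") %in% names(trace)))
    abort("`trace` must have columns `t` and `dCm`.")
  t <- trace$t; y <- trace$dCm
  if (stim_time < min(t) || stim_time > max(t))
    abort("`stim_time` is outside the trace.")
  n <- length(t)
  if (n < 3L) abort("Trace too short to differentiate.")
  # central differences on the interior samples
  dmid <- (y[3:n] - y[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  tmid <- t[2:(n - 1)]
  keep <- tmid >= stim_time & tmid <= stim_time + search_window
  if (!any(keep) || diff(range(dmid[keep])) <= 0)
    return(structure(stim_time, warning_flag = TRUE))
  i <- which.max(dmid[keep])
  if (i == sum(keep))  # derivative still rising at the window end: no interior max
    return(structure(stim_time, warning_flag = TRUE))
  structure(tmid[keep][i], warning_flag = FALSE)
}

burst_start_grid <- function(tt, yy, A0) {
  window <- max(tt)
  rise <- max(yy) - A0
  # sustained slope from the last 40% of the window
  late <- tt >= 0.6 * window
  A3_0 <- max(0, (yy[which.max(tt)] - yy[which(late)[1]]) /
                   (max(tt) - tt[which(late)[1]]))
  burst <- max(rise - A3_0 * window, 0.05 * rise, 1e-6)
  tidyr::expand_grid(tau1 = c(0.005, 0.02, 0.1), tau2 = c(0.1, 0.3, 1)) |>
    dplyr::mutate(A1 = burst / 2, A2 = burst / 2, A3 = A3_0)
}

#' Fit the burst decomposition to a cumulative-release trace
#'
#' Nonlinear least squares (Levenberg-Marquardt, multi-start) of the
#' [burst_model()] over a window after the onset. `A0` is fixed to the
#' baseline — `dCm` at the last sample before `t0` — and `t0` is fixed
#' (found with [find_onset()] when not supplied). Free parameters `A1`,
#' `tau1`, `A2`, `tau2`, `A3` are bounded below by 0 with
#' `tau` in `[1e-4, 10]` s; after fitting the exponentials are relabelled
#' so `tau1 <= tau2` (fast first).
#'
#' @param trace A data frame with columns `t` and `dCm` (fF); any
#'   two-column time/capacitance table works after renaming.
#' @param t0 Onset, s; `NULL` to locate automatically.
#' @param window Fit window length after `t0`, s (default 5).
#' @param stim_time Stimulus onset used by [find_onset()] when `t0` is
#'   `NULL` (defaults to the first sample).
#' @param onset_search Passed to [find_onset()] as `search_window`.
#' @return An object of class `"burst_fit"`; see [tidy.burst_fit()].
#' @examples
#' t <- seq(0, 5, by = 0.005)
#' y <- burst_model(t, 0, 0, A1 = 60, tau1 = 0.02, A2 = 50, tau2 = 0.2, A3 = 10)
#' fit <- fit_burst(tibble::tibble(t = t, dCm = y), t0 = 0)
#' glance(fit)
#' @export
fit_burst <- function(trace, t0 = NULL, window = 5, stim_time = NULL,
                      onset_search = Inf) {
  if (!all(c("t", "dCm") %in% names(trace)))
    abort("`trace` must have columns `t` and `dCm`.")
  flags <- character()
  if (is.null(t0)) {
    if (is.null(stim_time)) stim_time <- min(trace$t)
    t0 <- find_onset(trace, stim_time, search_window = onset_search)
    if (isTRUE(attr(t0, "warning_flag"))) flags <- c(flags, "onset_flat")
    t0 <- as.numeric(t0)
    if (t0 + window > max(trace$t) + 1e-9 &&
        stim_time + window <= max(trace$t) + 1e-9) {
      t0 <- stim_time
      flags <- c(flags, "onset_clamped")
    }
  }
  if (max(trace$t) < t0 + window - 1e-9)
    abort("Trace does not cover the fit window [t0, t0 + window].")
  before <- trace$t < t0
  A0 <- if (any(before)) trace$dCm[max(which(before))] else trace$dCm[1]

  sel <- trace$t >= t0 & trace$t <= t0 + window + 1e-12
  tt <- trace$t[sel] - t0
  yy <- trace$dCm[sel]

  starts <- burst_start_grid(tt, yy, A0)
  lower <- c(A1 = 0, tau1 = 1e-4, A2 = 0, tau2 = 1e-4, A3 = 0)
  upper <- c(A1 = Inf, tau1 = 10, A2 = Inf, tau2 = 10, A3 = Inf)

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    st <- as.list(starts[i, c("A1", "tau1", "A2", "tau2", "A3")])
    fit <- tryCatch(
      minpack.lm::nlsLM(
        yy ~ A0 + A1 * (1 - exp(-tt / tau1)) + A2 * (1 - exp(-tt / tau2)) + A3 * tt,
        start = st, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ssr <- sum(resid(fit)^2)
    if (is.null(best) || ssr < best$ssr) best <- list(fit = fit, ssr = ssr)
  }
  if (is.null(best))
    abort("Burst fit failed to converge from every start.")

  co <- coef(best$fit)
  # relabel so the fast component comes first
  if (co[["tau1"]] > co[["tau2"]]) {
    co <- co[c("A2", "tau2", "A1", "tau1", "A3")]
    names(co) <- c("A1", "tau1", "A2", "tau2", "A3")
  }
  rms <- sqrt(best$ssr / length(yy))
  total <- co[["A1"]] + co[["A2"]]
  if (total > 0 && co[["A2"]] < 1e-6 * max(total, 1))
    flags <- c(flags, "tau2_unidentifiable")
  if (co[["tau1"]] > 0 && co[["tau2"]] / co[["tau1"]] < 3)
    flags <- c(flags, "poorly_separated")
  if (total < 2 * rms)
    flags <- c(flags, "low_signal")

  structure(list(
    A0 = A0, t0 = t0,
    A1 = co[["A1"]], tau1 = co[["tau1"]],
    A2 = co[["A2"]], tau2 = co[["tau2"]],
    A3 = co[["A3"]],
    rate_fast = 1 / co[["tau1"]], rate_slow = 1 / co[["tau2"]],
    residual_rms = rms, window = window, n = length(yy),
    flags = flags,
    data = tibble::tibble(t = tt + t0, dCm = yy,
                          fitted = burst_model(tt + t0, A0, t0, co[["A1"]],
                                               co[["tau1"]], co[["A2"]],
                                               co[["tau2"]], co[["A3"]]))),
    class = "burst_fit")
}

#' Fit a trace after adding seeded measurement noise
#'
#' Adds zero-mean Gaussian noise (sd in fF) to the cumulative capacitance
#' only — the observable in the experiments being emulated — and runs
#' [fit_burst()]. Deterministic for a given `seed`; the caller's RNG state
#' is left untouched. With `noise_sd = 0` the result equals the clean fit.
#'
#' @inheritParams fit_burst
#' @param noise_sd Noise standard deviation, fF.
#' @param seed Integer seed.
#' @return A `"burst_fit"`.
#' @export
fit_burst_noisy <- function(trace, noise_sd, seed, t0 = NULL, window = 5,
                            stim_time = NULL) {
  trace$dCm <- trace$dCm + local_rnorm(seed, nrow(trace), sd = noise_sd)
  fit_burst(trace, t0 = t0, window = window, stim_time = stim_time)
}

# seeded normal draws that preserve the caller's RNG state
local_rnorm <- function(seed, n, sd) {
  if (sd == 0) return(rep(0, n))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  rnorm(n, sd = sd)
}

#' @export
print.burst_fit <- function(x, ...) {
  cat("<burst fit>  t0 =", format(x$t0), "s, A0 =", format(x$A0, digits = 4), "fF\n")
  cat(sprintf("  fast: A1 = %.3g fF, tau1 = %.4g s (rate %.3g /s)\n",
              x$A1, x$tau1, x$rate_fast))
  cat(sprintf("  slow: A2 = %.3g fF, tau2 = %.4g s (rate %.3g /s)\n",
              x$A2, x$tau2, x$rate_slow))
  cat(sprintf("  sustained: A3 = %.3g fF/s;  residual rms %.3g fF\n",
              x$A3, x$residual_rms))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Tidy and summarise burst fits
#'
#' `tidy()` returns one row per free parameter; `glance()` returns a
#' one-row summary including the fast/slow rate constants (`1/tau`).
#'
#' @param x A `"burst_fit"`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy burst_fit
#' @export
tidy.burst_fit <- function(x, ...) {
  tibble::tibble(
    term = c("A1", "tau1", "A2", "tau2", "A3"),
    estimate = c(x$A1, x$tau1, x$A2, x$tau2, x$A3),
    unit = c("fF", "s", "fF", "s", "fF/s"))
}

#' @rdname tidy.burst_fit
#' @method glance burst_fit
#' @export
glance.burst_fit <- function(x, ...) {
  tibble::tibble(
    A0 = x$A0, t0 = x$t0, A1 = x$A1, tau1 = x$tau1,
    A2 = x$A2, tau2 = x$tau2, A3 = x$A3,
    rate_fast = x$rate_fast, rate_slow = x$rate_slow,
    total_burst = x$A1 + x$A2,
    fast_fraction = if ((x$A1 + x$A2) > 0) x$A1 / (x$A1 + x$A2) else NA_real_,
    residual_rms = x$residual_rms,
    flags = paste(x$flags, collapse = ";"))
}

#' Export a burst fit as JSON
#'
#' Writes the decomposition with symbol-named keys (`A1_fF`, `tau1_s`,
#' `rate_fast_per_s`, ...).
#'
#' @param fit A `"burst_fit"`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_burst_fit <- function(fit, path) {
  out <- list(A0_fF = fit$A0, t0_s = fit$t0,
              A1_fF = fit$A1, tau1_s = fit$tau1,
              A2_fF = fit$A2, tau2_s = fit$tau2,
              A3_fF_per_s = fit$A3,
              rate_fast_per_s = fit$rate_fast,
              rate_slow_per_s = fit$rate_slow,
              residual_rms_fF = fit$residual_rms,
              flags = fit$flags)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
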