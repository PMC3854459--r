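test_that("onset detection finds the inflection point of cumulative release", {
  # saturating exponential from the stimulus: derivative maximal at onset
  t <- seq(0, 3, by = 0.002)
  y <- ifelse(t < 0.5, 0, 100 * (1 - exp(-(t - 0.5) / 0.1)))
  t0 <- find_onset(tibble::tibble(t = t, dCm = y), stim_time = 0.5)
  expect_lt(abs(as.numeric(t0) - 0.5), 0.005)
  expect_false(isTRUE(attr(t0, "warning_flag")))
  # sigmoid rise: inflection at its midpoint
  ys <- 100 / (1 + exp(-(t - 1.5) / 0.1))
  t0s <- find_onset(tibble::tibble(t = t, dCm = ys), stim_time = 0.5)
  expect_lt(abs(as.numeric(t0s) - 1.5), 0.005)
  # flat trace: flagged fallback to the stimulus time
  t0f <- find_onset(tibble::tibble(t = t, dCm = rep(1, length(t))), 0.5)
  expect_equal(as.numeric(t0f), 0.5)
  expect_true(attr(t0f, "warning_flag"))
})

test_that("noiseless synthetic decompositions are recovered to <0.1%", {
  cases <- list(
    c(A1 = 60, tau1 = 0.02, A2 = 50, tau2 = 0.2, A3 = 10),
    c(A1 = 150, tau1 = 0.018, A2 = 160, tau2 = 0.25, A3 = 50),
    c(A1 = 20, tau1 = 0.05, A2 = 80, tau2 = 1.0, A3 = 2))
  for (cs in cases) {
    tr <- make_burst_trace(cs[["A1"]], cs[["tau1"]], cs[["A2"]], cs[["tau2"]],
                           cs[["A3"]])
    fit <- fit_burst(tr, t0 = 0)
    est <- c(A1 = fit$A1, tau1 = fit$tau1, A2 = fit$A2, tau2 = fit$tau2,
             A3 = fit$A3)
    expect_equal(est, cs, tolerance = 1e-3)
    # fitted curve matches the trace within the residual bound at window end
    expect_lt(abs(fit$data$fitted[nrow(fit$data)] -
                    fit$data$dCm[nrow(fit$data)]),
              fit$residual_rms + 1e-9)
  }
})

test_that("component labelling is invariant: tau1 is always the fast one", {
  # a trace whose dominant component is slow; whatever the starts converge
  # to, labels must come out ordered
  tr <- make_burst_trace(A1 = 10, tau1 = 0.3, A2 = 90, tau2 = 0.03, A3 = 5)
  fit <- fit_burst(tr, t0 = 0)
  expect_lte(fit$tau1, fit$tau2)
  expect_equal(fit$tau1, 0.03, tolerance = 1e-3)
  expect_equal(fit$A1, 90, tolerance = 1e-3)
})

test_that("seeded noisy fits are deterministic and degrade gracefully", {
  tr <- make_burst_trace()
  f1 <- fit_burst_noisy(tr, noise_sd = 0.5, seed = 7, t0 = 0)
  f2 <- fit_burst_noisy(tr, noise_sd = 0.5, seed = 7, t0 = 0)
  expect_identical(glance(f1), glance(f2))
  # zero noise reduces to the clean fit
  f0 <- fit_burst_noisy(tr, noise_sd = 0, seed = 1, t0 = 0)
  fc <- fit_burst(tr, t0 = 0)
  expect_equal(glance(f0), glance(fc))
  # a single-exponential trace pins the second amplitude near zero
  tr1 <- make_burst_trace(A1 = 100, tau1 = 0.05, A2 = 0, tau2 = 1, A3 = 0)
  fd <- fit_burst(tr1, t0 = 0)
  expect_lt(min(fd$A1, fd$A2) / max(fd$A1, fd$A2), 1e-4)
  # overwhelming noise is flagged rather than silently trusted
  fn <- fit_burst_noisy(make_burst_trace(A1 = 1, tau1 = 0.02, A2 = 1,
                                         tau2 = 0.2, A3 = 0.1),
                        noise_sd = 50, seed = 3, t0 = 0)
  expect_true("low_signal" %in% fn$flags)
})

test_that("parameter recovery from seeded noisy fixtures is accurate in the median", {
  truth <- c(A1 = 60, tau1 = 0.02, A2 = 50, tau2 = 0.2, A3 = 10)
  tr <- make_burst_trace(truth[["A1"]], truth[["tau1"]], truth[["A2"]],
                         truth[["tau2"]], truth[["A3"]])
  errs <- vapply(1:100, function(seed) {
    fit <- fit_burst_noisy(tr, noise_sd = 0.5, seed = seed, t0 = 0)
    est <- c(fit$A1, fit$tau1, fit$A2, fit$tau2, fit$A3)
    abs(est - truth) / truth
  }, numeric(5))
  med <- apply(errs, 1, median)
  expect_true(all(med < 0.05))
})

test_that("burst fits serialise to JSON with unit-suffixed keys", {
  fit <- fit_burst(make_burst_trace(), t0 = 0)
  path <- withr::local_tempfile(fileext = ".json")
  write_burst_fit(fit, path)
  out <- jsonlite::read_json(path)
  expect_equal(out$A1_fF, fit$A1, tolerance = 1e-12)
  expect_equal(out$rate_fast_per_s, 1 / fit$tau1, tolerance = 1e-12)
})
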