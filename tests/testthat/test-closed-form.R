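test_that("eigen-rates satisfy the Vieta identities on random rate triples", {
  set.seed(31)
  for (i in 1:1000) {
    k2 <- runif(1, 0.01, 50); km2 <- runif(1, 0.01, 50); k3 <- runif(1, 0.01, 100)
    lam <- eigenrates(k2, km2, k3)
    expect_equal(sum(lam), k2 + km2 + k3, tolerance = 1e-12)
    expect_equal(prod(lam), k2 * k3, tolerance = 1e-9)
    expect_gte(lam[["lambda_fast"]], lam[["lambda_slow"]])
  }
  # decoupled case: no priming influx leaves rates {k_minus2 + k3, 0}
  lam0 <- eigenrates(0, 3, 7)
  expect_equal(unname(lam0), c(10, 0))
  # quadratic-formula oracle at the published priming rates
  s <- 5.26 + 3.80 + 20
  expect_equal(unname(eigenrates(5.26, 3.80, 20)),
               c((s + sqrt(s^2 - 4 * 5.26 * 20)) / 2,
                 (s - sqrt(s^2 - 4 * 5.26 * 20)) / 2))
})

test_that("closed-form amplitudes conserve the total burst and match a stiff ODE oracle", {
  set.seed(32)
  times <- seq(0, 2, by = 0.02)
  for (i in 1:20) {
    k2 <- runif(1, 0.5, 20); km2 <- runif(1, 0.5, 20); k3 <- runif(1, 1, 100)
    V <- runif(1, 50, 200)
    cf <- closed_form_burst(k2, km2, k3, V)
    expect_equal(cf$A_fast + cf$A_slow, V, tolerance = 1e-12)
    expect_lt(cf$tau_fast, cf$tau_slow)
    pred <- closed_form_release(cf, times)
    oracle <- lsoda_two_pool_oracle(k2, km2, k3, V, times)
    expect_equal(pred, unname(oracle), tolerance = 1e-9)
  }
  # the fused state absorbs everything eventually
  cf <- closed_form_burst(5.26, 3.8, 20)
  expect_equal(closed_form_release(cf, 1e4), cf$V_tot, tolerance = 1e-9)
})

test_that("a very fast fusion step releases the initial RRP first", {
  k2 <- 5.26; km2 <- 3.8
  cf <- closed_form_burst(k2, km2, k3 = 1e5)
  expect_equal(cf$A_fast, cf$RRP0, tolerance = 1e-3)
  expect_equal(cf$tau_fast, 1e-5, tolerance = 1e-3)
  # slow phase then proceeds at the forward priming rate
  expect_equal(cf$lambda_slow, k2, tolerance = 1e-3)
})

test_that("the repeated-eigenvalue limit form evaluates continuously", {
  # k2 = k3 with a vanishing reverse rate drives the discriminant to zero;
  # the degenerate evaluation must agree with a nearby regular case
  cf_deg <- closed_form_burst(1, 1e-20, 1)
  expect_true(cf_deg$degenerate)
  expect_true(is.na(cf_deg$A_fast))
  cf_near <- closed_form_burst(1, 1e-8, 1)
  t <- seq(0, 5, by = 0.1)
  expect_equal(closed_form_release(cf_deg, t), closed_form_release(cf_near, t),
               tolerance = 1e-5)
})

test_that("the SNARE scan reproduces the fast-to-slow amplitude shift", {
  k3_grid <- 10^seq(-0.5, 3, length.out = 30)
  scan <- snare_scan(k3_grid)
  # lowering the fusion rate slows fast release
  expect_true(all(diff(scan$tau_fast) < 0))
  # and shifts amplitude from the fast to the slow component
  expect_true(all(diff(scan$fast_fraction) > 0))
  # the fast fraction saturates at the equilibrium RRP share as k3 grows
  expect_equal(scan$fast_fraction[nrow(scan)], 5.26 / (5.26 + 3.80),
               tolerance = 0.02)
})

test_that("the reduced-PPM comparator keeps the amplitude split invariant", {
  scan <- ppm_burst_scan(k_rrp_grid = c(15, 50, 150))
  frac <- scan$fast_fraction
  expect_lt(diff(range(frac)) / mean(frac), 0.10)
  # the whole starting content is released within the window
  expect_equal(scan$total_burst[nrow(scan)], 61.3 + 52.3, tolerance = 0.01)
  # at the fast-sensor effective rate the default PPM fast burst reappears
  k_eff <- sensor_drain_rate(25, 4.4, 56, 1450)
  ref <- ppm_burst_scan(k_eff)
  expect_equal(ref$A1[1], 61.3, tolerance = 0.05)
  expect_equal(1 / ref$tau1[1], k_eff, tolerance = 0.1)
})
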