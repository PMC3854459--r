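test_that("SPM kinetics conserve mass against the symbolic balance", {
  p <- spm_params()
  # at rest with zero Ca2+ and empty pools nothing moves
  d0 <- spm_rhs(spm_state(), 0, p)
  expect_equal(unname(d0), rep(0, 6))
  # sum of all derivatives (incl. F) equals net Depot exchange, any state
  set.seed(21)
  for (i in 1:100) {
    st <- spm_state(NRP = runif(1, 0, 300), RRP = runif(1, 0, 300),
                    RRPCa = runif(1, 0, 50), RRPCa2 = runif(1, 0, 20),
                    RRPCa3 = runif(1, 0, 5), F = runif(1, 0, 500))
    ca <- runif(1, 0, 50)
    d <- spm_rhs(st, ca, p)
    expect_equal(sum(d), recruitment_rate(ca, p) - p$k_minus1 * st[["NRP"]],
                 tolerance = 1e-10)
    # the unclamped variant moves extra mass into F but conserves the total
    du <- spm_rhs(st, ca, p, "unclamped_syt_null")
    expect_equal(sum(du), recruitment_rate(ca, p) - p$k_minus1 * st[["NRP"]],
                 tolerance = 1e-10)
  }
})

test_that("PPM kinetics conserve mass", {
  p <- ppm_params()
  expect_equal(unname(ppm_rhs(ppm_state(), 0, p)), rep(0, 10))
  set.seed(22)
  for (i in 1:50) {
    st <- ppm_state(SRP = runif(1, 0, 200), SRPCa = runif(1, 0, 30),
                    SRPCa2 = runif(1, 0, 10), SRPCa3 = runif(1, 0, 5),
                    RRP = runif(1, 0, 200), RRPCa = runif(1, 0, 30),
                    RRPCa2 = runif(1, 0, 10), RRPCa3 = runif(1, 0, 5))
    ca <- runif(1, 0, 50)
    d <- ppm_rhs(st, ca, p)
    expect_equal(sum(d), recruitment_rate(ca, p) - p$k_minus1 * st[["SRP"]],
                 tolerance = 1e-10)
  }
  # with fusion shut off, total mass change is recruitment minus unpriming
  p0 <- ppm_params(k4s = 0, k4r = 0)
  st <- ppm_state(SRP = 50, SRPCa = 5, RRP = 60, RRPCa = 4)
  d <- ppm_rhs(st, 10, p0)
  expect_equal(sum(d), recruitment_rate(10, p0) - p0$k_minus1 * 50,
               tolerance = 1e-10)
})

test_that("the analytic SPM steady state annihilates the kinetics across a Ca2+ grid", {
  p <- spm_params()
  for (ca in c(0.1, 0.5, 1, 10, 100)) {
    ss <- spm_steady_state(ca, p)
    d <- spm_rhs(c(ss$pools, F = 0), ca, p)
    scale <- max(ss$fusion_flux, 1)
    expect_lt(max(abs(d[1:5])), 1e-9 * scale)
    expect_gt(d[["F"]], 0)
  }
  # variants also admit exact steady states
  for (mode in c("unclamped_syt_null", "destabilized_syt_null")) {
    ss <- spm_steady_state(0.5, p, mode)
    d <- spm_rhs(c(ss$pools, F = 0), 0.5, p, mode)
    expect_lt(max(abs(d[1:5])), 1e-9)
  }
  # no Ca2+, no recruitment: the system drains completely
  ss0 <- spm_steady_state(0, p)
  expect_equal(unname(ss0$pools), rep(0, 5))
  expect_equal(ss0$fusion_flux, 0)
})

test_that("resting fluxes match the spontaneous release rates of the model", {
  p <- spm_params()
  expect_equal(spm_steady_state(0.5, p)$fusion_flux, 1.7, tolerance = 0.05)
  expect_equal(spm_steady_state(0.5, p, "unclamped_syt_null")$fusion_flux,
               6.9, tolerance = 0.02)
  # destabilizing the RRP shifts mass into the NRP and reduces the RRP
  wt <- spm_steady_state(0.5, p)
  de <- spm_steady_state(0.5, p, "destabilized_syt_null")
  expect_lt(de$pools[["RRP"]], wt$pools[["RRP"]])
  expect_gt(de$pools[["NRP"]], wt$pools[["NRP"]])
})

test_that("the PPM steady state is stationary and fuses through both pathways", {
  p <- ppm_params()
  ss <- ppm_steady_state(0.5, p)
  d <- ppm_rhs(c(ss$pools, Fs = 0, Fr = 0), 0.5, p)
  expect_lt(max(abs(d[1:8])), 1e-9)
  expect_gt(ss$flux_slow, 0)
  expect_gt(ss$flux_fast, 0)
  # the catalyst-extended PPM reduces to similar resting rates
  pc <- preset_params("ppm_cat")
  ssc <- ppm_steady_state(0.5, pc)
  d2 <- ppm_rhs(c(ssc$pools, Fs = 0, Fr = 0), 0.5, pc)
  expect_lt(max(abs(d2[1:8])), 1e-9)
})
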