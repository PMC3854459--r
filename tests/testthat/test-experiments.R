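# Simulations here use the default solver settings; grids are kept small so
# each scan stays a few seconds.

test_that("a flash to the resting level yields no burst, only the steady leak", {
  fx <- flash_experiment("spm", post_ca = 0.5)
  flux <- spm_steady_state(0.5, spm_params())$fusion_flux
  expect_lt(fx$fit$A1 + fx$fit$A2, 0.05)
  expect_equal(fx$fit$A3, flux, tolerance = 1e-2)
})

test_that("the uncaging flash gives the biphasic decomposition in both models", {
  fs <- flash_experiment("spm")
  expect_equal(fs$fit$rate_fast, 50, tolerance = 0.25)
  expect_gt(fs$fit$A2, 0)
  fp <- flash_experiment("ppm")
  expect_gt(fp$fit$A1, 50)
  expect_gt(fp$fit$A2, 50)
  expect_gt(fp$fit$tau2 / fp$fit$tau1, 3)
  # experiments are deterministic: identical reruns
  fs2 <- flash_experiment("spm")
  expect_identical(glance(fs$fit), glance(fs2$fit))
})

test_that("the slow-component rate saturates toward the catalysed ceiling with post-flash Ca2+", {
  scan <- postflash_scan("spm", post_grid = c(10, 100, 1000))
  p <- spm_params()
  # rate_slow tracks k2(ca): half the ceiling near K_D, approaching k2cat
  expect_equal(scan$rate_slow[scan$post_ca == 100],
               p$k20 + 0.5 * p$k2cat, tolerance = 0.1)
  expect_equal(scan$rate_slow[scan$post_ca == 1000], 20, tolerance = 0.15)
  # fast rate grows monotonically with post-flash Ca2+
  expect_true(all(diff(scan$rate_fast) > 0))
})

test_that("burst amplitudes are bell-shaped in resting Ca2+ with a stable fast fraction", {
  scan <- preflash_scan("spm", pre_grid = c(0.05, 0.2, 0.45, 0.7, 3))
  # interior maximum of the fast amplitude
  imax <- which.max(scan$A1)
  expect_true(imax > 1 && imax < nrow(scan))
  expect_true(scan$pre_ca[imax] > 0.1 && scan$pre_ca[imax] < 1.5)
  # amplitudes vanish as resting Ca2+ (and hence recruitment) vanishes
  expect_lt(scan$total_burst[1], 0.25 * max(scan$total_burst))
  # fast/slow proportion roughly constant over the physiological resting range
  ff <- scan$fast_fraction[scan$pre_ca >= 0.2 & scan$pre_ca <= 0.7]
  expect_lt(diff(range(ff)) / mean(ff), 0.2)
})

test_that("selective depletion removes the fast component, which recovers at the slow one's cost", {
  scan <- selective_depletion_recovery(isi_grid = c(0.05, 5, 150))
  expect_lt(scan$recovery_fast[1], 0.2)       # immediately after depletion
  expect_true(all(diff(scan$recovery_fast) > 0))
  # slow amplitude dips below control while the fast one refills
  expect_lt(scan$recovery_slow[2], scan$recovery_slow[1])
  expect_lt(scan$recovery_slow[2], 0.95)
  # at long intervals both components return to control
  expect_equal(scan$recovery_fast[3], 1, tolerance = 0.1)
  expect_equal(scan$recovery_slow[3], 1, tolerance = 0.1)
  # the automatically chosen pulse meets the stated criterion
  d <- attr(scan, "depletion_duration")
  expect_true(d > 0 && d < 2)
})

test_that("only the catalyst-bearing models recover the fast component promptly", {
  spm <- double_flash_recovery("spm", isi_grid = c(8, 22))
  ppm <- double_flash_recovery("ppm", isi_grid = c(8, 22))
  cat22 <- double_flash_recovery("ppm", params = preset_params("ppm_cat"),
                                 isi_grid = 22)
  # the headline ordering: the SPM shows fast recovery at 8 s, the PPM none
  expect_gt(spm$recovery_fast[spm$isi == 8], ppm$recovery_fast[ppm$isi == 8])
  expect_equal(ppm$recovery_fast[ppm$isi == 8], 0)
  # grafting the catalyst onto the PPM speeds its fast recovery
  expect_gt(cat22$recovery_fast[1], ppm$recovery_fast[ppm$isi == 22])
  # the SPM's slow component recovers faster than its fast one
  expect_true(all(spm$recovery_slow > spm$recovery_fast))
  # recovery grows with the interval in the SPM
  expect_gt(spm$recovery_fast[spm$isi == 22], spm$recovery_fast[spm$isi == 8])
})

test_that("syt-1-null variants lose the fast burst in distinct ways", {
  un <- syt_null_experiment("unclamped")
  expect_equal(un$resting_flux, 6.9, tolerance = 0.01)
  expect_equal(un$wt_resting_flux, 1.7, tolerance = 0.03)
  # no fast component: nearly all burst amplitude is slow
  expect_lt(un$fit$A1 / (un$fit$A1 + un$fit$A2), 0.1)
  de <- syt_null_experiment("destabilized")
  wt <- flash_experiment("spm")
  # only a very small fast burst remains, the slow burst is slightly larger
  expect_lt(de$fit$A1, 0.2 * wt$fit$A1)
  expect_gt(de$fit$A2, wt$fit$A2)
  # spontaneous release drops when the RRP is destabilized
  expect_lt(de$resting_flux, de$wt_resting_flux)
})
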