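prot <- default_test_protocol()
aif <- generate_aif(prot)

test_that("forward model limits: vascular-only and zero-parameter cases", {
  expect_equal(forward_etm(0, 0.3, 0.05, aif), 0.05 * aif$cp)
  expect_equal(forward_etm(0, 0.3, 0, aif), rep(0, length(aif$cp)))
  expect_error(forward_etm(0.2, 0, 0.05, aif), "undefined")
})

test_that("forward model matches fine-grid quadrature of the convolution", {
  oracle <- etm_fine_grid_oracle(0.2, 0.3, 0.02, aif$times,
                                 function(t) aif_bolus(t, bolus_arrival = 55),
                                 refine = 10)
  mine <- forward_etm(0.2, 0.3, 0.02, aif)
  rel <- sqrt(sum((mine - oracle)^2) / sum(oracle^2))
  expect_lt(rel, 0.005)
})

test_that("signal conversion flags non-physical samples without failing", {
  sig <- concentration_to_signal(rep(0.5, prot$n_total_phases), prot)
  sig[20] <- -50 # impossible magnitude signal
  out <- signal_to_concentration(sig, prot)
  expect_gt(out$n_flagged, 0)
  expect_true(is.na(out$conc[20]))
  expect_false(anyNA(out$conc[-20]))
})

test_that("AIF extraction applies the hematocrit plasma correction", {
  d <- c(3, 3, 3, prot$n_total_phases)
  arr <- array(0, d)
  curve <- forward_etm(0, 0.3, 1, aif) # pure blood voxel
  arr[2, 2, 2, ] <- curve
  cv <- structure(list(conc = arr, times = aif$times, n_flagged = 0L),
                  class = "conc_volume")
  a0 <- extract_aif(cv, c(2, 2, 2), hematocrit = 0)
  expect_equal(a0$cp, curve)
  a45 <- extract_aif(cv, c(2, 2, 2), hematocrit = 0.45)
  expect_equal(a45$cp, curve / 0.55)
  expect_error(extract_aif(cv, c(1, 1, 1)), "all-zero")
})

test_that("voxel fit recovers noiseless parameters and respects bounds", {
  truth <- c(0.25, 0.35, 0.03)
  ct <- forward_etm(truth[1], truth[2], truth[3], aif)
  f <- fit_etm_voxel(ct, aif)
  expect_true(f$fit_success)
  expect_lt(abs(f$ktrans - truth[1]) / truth[1], 0.01)
  expect_lt(abs(f$ve - truth[2]) / truth[2], 0.01)
  expect_lt(abs(f$vp - truth[3]) / truth[3], 0.01)
  expect_equal(f$kep, f$ktrans / f$ve)

  fz <- fit_etm_voxel(rep(0, length(aif$times)), aif)
  expect_lt(fz$ktrans, 1e-6)
  expect_lt(fz$vp, 1e-6)
  expect_lt(fz$sse, 1e-12)

  # bounds hold for arbitrary (noisy, unmodellable) inputs
  set.seed(42)
  for (i in 1:8) {
    crv <- rnorm(length(aif$times), sd = runif(1, 0.01, 2))
    fr <- fit_etm_voxel(crv, aif)
    expect_true(fr$ktrans >= 0 && fr$ktrans <= 5)
    expect_true(fr$ve >= 0 && fr$ve <= 1)
    expect_true(fr$vp >= 0 && fr$vp <= 1)
  }
})

test_that("fitted K-trans is monotone in the ground truth (noiseless)", {
  kts <- c(0.05, 0.15, 0.4, 0.8)
  fits <- vapply(kts, function(k)
    fit_etm_voxel(forward_etm(k, 0.3, 0.03, aif), aif)$ktrans, 0.0)
  expect_true(all(diff(fits) > 0))
})

test_that("volume fit reduces to the voxel fit and flags failures", {
  d <- c(2, 2, 1, prot$n_total_phases)
  arr <- array(0, d)
  ct <- forward_etm(0.3, 0.25, 0.02, aif)
  arr[1, 1, 1, ] <- ct
  mask <- array(FALSE, d[1:3]); mask[1, 1, 1] <- TRUE
  maps <- fit_etm_volume(arr, aif, mask)
  ref <- fit_etm_voxel(ct, aif)
  expect_equal(maps$ktrans[1, 1, 1], ref$ktrans)
  expect_equal(maps$vp[1, 1, 1], ref$vp)
  expect_equal(maps$n_failed, 0L)
  expect_error(fit_etm_volume(arr, aif, array(FALSE, d[1:3])), "empty mask")
})

test_that("noiseless phantom volume fits recover the ground-truth maps", {
  prot <- default_test_protocol()
  sp <- phantom_spec(grid_shape = c(10, 10, 5), voxel_size = c(2, 2, 4),
                     radii = c(6, 6, 6), noise_sd = 0, seed = 31)
  ph <- generate_phantom(sp, prot)
  conc <- signal_to_concentration(ph$signal, prot, T10 = sp$T10)
  maps <- suppressMessages(fit_etm_volume(conc, ph$aif, ph$mask))
  expect_equal(maps$n_failed, 0L)
  for (par in c("ktrans", "ve", "vp")) {
    rel <- abs(maps[[par]][ph$mask] - ph$truth[[par]][ph$mask]) /
      ph$truth[[par]][ph$mask]
    expect_lt(median(rel), 0.01)
  }
})

test_that("noisy phantom fits degrade gracefully (median Ktrans error < 15% at SNR 20)", {
  prot <- default_test_protocol()
  s0 <- concentration_to_signal(0, prot) # baseline signal level
  sp <- phantom_spec(grid_shape = c(10, 10, 5), voxel_size = c(2, 2, 4),
                     radii = c(6, 6, 6), noise_sd = s0 / 20, seed = 77)
  ph <- generate_phantom(sp, prot)
  conc <- signal_to_concentration(ph$signal, prot, T10 = sp$T10)
  maps <- suppressMessages(fit_etm_volume(conc, ph$aif, ph$mask))
  ok <- ph$mask & maps$fit_success
  rel <- abs(maps$ktrans[ok] - ph$truth$ktrans[ok]) / ph$truth$ktrans[ok]
  expect_lt(median(rel), 0.15)
})
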