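test_that("CSF m0 constraint is a fixed proportionality", {
  expect_equal(constrain_csf_m0(1.0, 0.53), 0.53)
  expect_equal(constrain_csf_m0(1.0, 1.0), 1.0)
  expect_equal(constrain_csf_m0(2.0, 0.5), 1.0)
  expect_error(constrain_csf_m0(-1, 0.5), "tissue_water_m0")
  expect_error(constrain_csf_m0(1, 0), "ratio")
})

test_that("mixture spectrum is the exact tissue-weighted sum", {
  cm <- compartment_model()
  p <- default_protocol()
  for (pv in c(0, 0.25, 0.5, 0.75, 1)) {
    z <- pvc_spectrum(cm, pv, p, b0_shift = 0.02)
    comp <- attr(z, "components")
    expect_identical(z$signal,
                     (1 - pv) * comp$csf + pv * comp$tissue)
  }
  expect_error(pvc_spectrum(cm, 1.2, p), "pve")
})

test_that("mixture reduces to the pure compartments at pve 1 and 0", {
  cm <- compartment_model()
  p <- default_protocol()
  z_t <- simulate_zspectrum(cm$tissue_pools, p)
  z_c <- simulate_zspectrum(list(cm$csf_pool), p)
  expect_equal(pvc_spectrum(cm, 1, p)$signal, z_t$signal, tolerance = 1e-14)
  expect_equal(pvc_spectrum(cm, 0, p)$signal, z_c$signal, tolerance = 1e-14)
  # reference offset stays ~1 for the mixture at any pve
  z <- pvc_spectrum(cm, 0.6, p)
  expect_equal(z$signal[33], 1, tolerance = 1e-2)
})

test_that("CSF dilutes the apparent amide effect of a mixed voxel", {
  cm <- compartment_model()
  p <- saturation_protocol(0.55, 2, c(3.5, 300))
  apparent_apt <- vapply(c(1, 0.9, 0.8, 0.7, 0.6, 0.5), function(pv) {
    z <- pvc_spectrum(cm, pv, p)
    cm_no_amide <- cm
    cm_no_amide$tissue_pools[[2]]$m0 <- 0
    z0 <- pvc_spectrum(cm_no_amide, pv, p)
    z0$signal[1] - z$signal[1]      # apparent amide dip
  }, numeric(1))
  expect_true(all(diff(apparent_apt) < 0))
})

test_that("CSF/tissue ratio is recovered from synthetic unsaturated images", {
  set.seed(11)
  n <- 500
  pt <- runif(n, 0.2, 1)
  pc <- 1 - pt
  dims <- c(n, 1, 1)
  s0 <- array(100 * pt + 53 * pc, dims)
  est <- estimate_csf_tissue_ratio(s0, array(pt, dims), array(pc, dims),
                                   seed = 1)
  expect_equal(est$ratio, 0.530, tolerance = 5e-4)

  # pure-tissue-only mask makes the ratio unidentifiable
  s0_pure <- array(100, c(20, 1, 1))
  ones <- array(1, c(20, 1, 1)); zeros <- array(0, c(20, 1, 1))
  expect_error(estimate_csf_tissue_ratio(s0_pure, ones, zeros),
               "unidentifiable")
  expect_error(
    estimate_csf_tissue_ratio(s0[1:5, , 1, drop = FALSE],
                              array(pt[1:5], c(5, 1, 1)),
                              array(pc[1:5], c(5, 1, 1))),
    "10 usable voxels")

  # noisy: SNR 50 on the tissue signal
  set.seed(22)
  s0n <- s0 + array(rnorm(n, 0, 2), dims)
  estn <- estimate_csf_tissue_ratio(s0n, array(pt, dims), array(pc, dims),
                                    seed = 2)
  expect_equal(estn$ratio, 0.530, tolerance = 0.02)
  expect_gt(estn$sd, 0)
})
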