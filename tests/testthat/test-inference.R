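test_that("tissue PVE below 50% selects the CSF-only model", {
  expect_equal(select_model_by_pve(0.30), "csf_only")
  expect_equal(select_model_by_pve(0.49999), "csf_only")
  expect_equal(select_model_by_pve(0.50), "pvc")          # strict threshold
  expect_equal(select_model_by_pve(0.50, "four_pool"), "four_pool")
  expect_equal(select_model_by_pve(1.00), "pvc")
  expect_error(select_model_by_pve(1.5), "pve")
})

test_that("R and compiled objectives agree", {
  p <- default_protocol()
  cm <- compartment_model()
  set.seed(13)
  y <- simulate_zspectrum(cm$tissue_pools, p)$signal + rnorm(33, 0, 0.01)
  for (tag in c("four_pool", "pvc")) {
    pri <- default_priors(tag)
    ctx <- cestpvc:::build_fit_context(tag, cm, pri, p,
                                       if (tag == "pvc") 0.7 else NULL)
    for (i in 1:5) {
      u <- rnorm(nrow(ctx$free), 0, 0.5)
      th <- ctx$free$mean + ctx$free$sd * u
      nlp_r <- cestpvc:::ctx_nlp(ctx, th, y) -
        0.5 * sum(((th - ctx$free$mean) / ctx$free$sd)^2) + 0.5 * sum(u^2)
      expect_equal(nlp_r, cestpvc:::.bm_nlp_cpp(u, y, ctx$cpp),
                   tolerance = 1e-10)
    }
  }
})

test_that("noiseless data simulated at the prior means is a fixed point", {
  p <- default_protocol()
  z <- simulate_zspectrum(default_tissue_pools(), p)
  f <- fit_voxel(z, p, "four_pool", options = fit_options(compute_sd = FALSE))
  expect_voxel_converged(f)
  expect_lt(f$residual_rms, 1e-8)
  expect_equal(f$estimates[["amide.m0"]], 1e-3, tolerance = 1e-4)
  expect_equal(f$estimates[["water.t1"]], 1.3, tolerance = 1e-4)
})

test_that("a 0.1 ppm water shift is recovered and flagged in the fit", {
  p <- default_protocol()
  z <- simulate_zspectrum(default_tissue_pools(), p, b0_shift = 0.10)
  f <- fit_voxel(z, p, "four_pool", options = fit_options(compute_sd = FALSE))
  expect_voxel_converged(f)
  expect_equal(f$b0_shift, 0.10, tolerance = 0.01)
})

test_that("infinite noise returns the prior means (prior dominance)", {
  p <- default_protocol()
  z <- simulate_zspectrum(default_tissue_pools(), p)
  pri <- default_priors("four_pool")
  i <- pri$pool == "global" & pri$param == "noise_sd"
  pri$mean[i] <- log(1e6)          # noise sd = 1e6 x s0
  pri$lower[i] <- log(1e6) - 1e-9; pri$upper[i] <- log(1e6) + 1e-9
  zn <- zspectrum(z$offsets, z$signal * 0.5 + 0.2, 1)  # arbitrary data
  f <- fit_voxel(zn, p, "four_pool", priors = pri,
                 options = fit_options(compute_sd = FALSE))
  free <- pri[!pri$frozen & !i, ]
  expected <- ifelse(free$transform == "log", exp(free$mean), free$mean)
  got <- f$estimates[paste(free$pool, free$param, sep = ".")]
  expect_equal(unname(got), expected, tolerance = 1e-6)
})

test_that("denser offset sampling does not inflate posterior sds", {
  tp <- default_tissue_pools()
  p1 <- default_protocol()
  p2 <- saturation_protocol(0.55, 2,
                            c(seq(-4.5, 4.5, length.out = 64), 300, 300))
  set.seed(31)
  noise <- function(z) zspectrum(z$offsets,
                                 z$signal + rnorm(length(z$signal), 0, 0.01),
                                 1)
  z1 <- simulate_zspectrum(tp, p1)
  z2 <- simulate_zspectrum(tp, p2)
  ratios <- replicate(3, {
    f1 <- fit_voxel(noise(z1), p1, "four_pool")
    f2 <- fit_voxel(noise(z2), p2, "four_pool")
    mean(f2$sd / f1$sd, na.rm = TRUE)
  })
  expect_lte(mean(ratios), 1)
})

test_that("flagged voxels are skipped, not fitted", {
  p <- default_protocol()
  bad <- zspectrum(p$offsets, rep(0, 33), 1)
  f <- fit_voxel(bad, p, "four_pool")
  expect_true(f$flagged)
  expect_false(f$converged)
})

test_that("image fitting has no spatial coupling and applies the PVE rule", {
  p <- default_protocol()
  cm <- compartment_model()
  opts <- fit_options(compute_sd = FALSE)
  # 3 voxels: two identical pure-tissue, one low-PVE
  dims <- c(3L, 1L, 1L)
  pve <- array(c(1, 0.3, 1), dims)
  data <- array(NA_real_, c(dims, 33))
  zt <- pvc_spectrum(cm, 1, p)
  zc <- pvc_spectrum(cm, 0.3, p)
  data[1, 1, 1, ] <- zt$signal
  data[2, 1, 1, ] <- zc$signal
  data[3, 1, 1, ] <- zt$signal
  res <- fit_image(data, p, pve_map = pve, model_tag = "pvc",
                   options = opts)
  # identical voxels in different positions fit identically
  expect_equal(res$fits[[1]]$estimates, res$fits[[3]]$estimates,
               tolerance = 1e-12)
  # the pve = 0.3 voxel is CSF-only and APTR*-ineligible
  expect_equal(res$model_map[2, 1, 1], "csf_only")
  expect_false(res$eligible[2, 1, 1])
  expect_true(all(res$eligible[c(1, 3), 1, 1]))
  am <- aptr_star_image(res)
  expect_true(is.na(am$values[2, 1, 1]))
  expect_false(anyNA(am$values[c(1, 3), 1, 1]))
  # grid mismatches are reported with both shapes
  expect_error(fit_image(data, p, pve_map = array(1, c(2, 1, 1))),
               "3x1x1")
  expect_error(fit_image(data[, , , 1:10, drop = FALSE], p), "offset count")
})

test_that("pvc and four_pool coincide on pure-tissue voxels", {
  p <- default_protocol()
  cm <- compartment_model()
  opts <- fit_options(compute_sd = FALSE)
  set.seed(17)
  z <- simulate_zspectrum(cm$tissue_pools, p)
  zn <- zspectrum(z$offsets, z$signal + rnorm(33, 0, 0.005), 1)
  f4 <- fit_voxel(zn, p, "four_pool", options = opts)
  fp <- fit_voxel(zn, p, "pvc", pve = 1, options = opts)
  expect_equal(f4$estimates, fp$estimates, tolerance = 1e-6)
  expect_equal(aptr_star(f4, p), aptr_star(fp, p), tolerance = 1e-6)
})
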