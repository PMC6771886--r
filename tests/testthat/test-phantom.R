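test_that("phantom spec validates geometry and parameters", {
  pve <- array(1, c(4, 4, 1))
  lesion <- array(FALSE, c(4, 4, 1)); lesion[1, 1, 1] <- TRUE
  expect_s3_class(phantom_spec(pve, lesion), "phantom_spec")
  pve_low <- pve; pve_low[1, 1, 1] <- 0.3
  expect_error(phantom_spec(pve_low, lesion), "lesion")
  expect_error(phantom_spec(pve, amide_reduction = 0), "amide_reduction")
  expect_error(phantom_spec(pve, noise_sd = -1), "noise_sd")
})

test_that("noise-free pure-tissue phantom equals the forward simulation", {
  spec <- phantom_spec(array(1, c(2, 2, 1)), noise_sd = 0)
  ds <- generate_phantom(spec)
  z <- simulate_zspectrum(spec$compartments$tissue_pools, spec$protocol)
  for (i in 1:2) for (j in 1:2)
    expect_equal(ds$data_4d[i, j, 1, ], z$signal * z$s0, tolerance = 1e-14)
  expect_equal(ds$s0_volume[1, 1, 1], 1)
  # complementary PVE maps
  expect_equal(ds$tissue_pve + ds$csf_pve, array(1, c(2, 2, 1)))
})

test_that("phantom noise is seeded and reproducible", {
  spec <- default_stroke_spec(seed = 42)
  d1 <- generate_phantom(spec)$data_4d
  d2 <- generate_phantom(spec)$data_4d
  expect_identical(d1, d2)
  d3 <- generate_phantom(default_stroke_spec(seed = 43))$data_4d
  expect_false(identical(d1, d3))
})

test_that("add_noise matches its nominal level and seeding contract", {
  x <- array(0, c(100, 100, 10))
  expect_identical(add_noise(x, 0), x)
  y1 <- add_noise(x, 0.01, seed = 5)
  y2 <- add_noise(x, 0.01, seed = 5)
  expect_identical(y1, y2)
  # 1e5 draws: empirical sd within 2% of nominal
  expect_equal(sd(y1), 0.01, tolerance = 0.02)
})

test_that("stroke phantom carries lesion truth and mixed boundary", {
  ds <- generate_phantom(default_stroke_spec())
  expect_equal(sum(ds$roi$core), 9L)
  expect_equal(sum(ds$roi$contralateral), 9L)
  core_truth <- ds$truth[ds$truth$region == "core", ]
  tis_truth <- ds$truth[ds$truth$region == "tissue", ]
  expect_equal(unique(core_truth$amide_m0), 0.7e-3)
  expect_equal(unique(tis_truth$amide_m0), 1e-3)
  expect_true(any(ds$tissue_pve < 0.5))
  expect_true(any(ds$tissue_pve > 0 & ds$tissue_pve < 1))
})

test_that("fitting the phantom recovers the lesion contrast across seeds", {
  # scaled-down Monte-Carlo: 3 core + 3 contralateral voxels per seed
  opts <- fit_options(compute_sd = FALSE)
  hits <- 0L
  n_seeds <- 5L
  for (s in seq_len(n_seeds)) {
    ds <- generate_phantom(default_stroke_spec(seed = 100 + s))
    mask <- array(FALSE, dim = dim(ds$s0_volume))
    mask[5:7, 8, 1] <- TRUE      # 3 core voxels
    mask[10:12, 8, 1] <- TRUE    # 3 contralateral voxels
    res <- fit_image(ds$data_4d, ds$protocol, pve_map = ds$tissue_pve,
                     mask = mask, model_tag = "pvc", options = opts,
                     s0_volume = ds$s0_volume)
    am <- res$maps$amide.m0_mean
    if (mean(am[ds$roi$core], na.rm = TRUE) <
        mean(am[ds$roi$contralateral], na.rm = TRUE))
      hits <- hits + 1L
  }
  expect_gte(hits, n_seeds - 1L)
})
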