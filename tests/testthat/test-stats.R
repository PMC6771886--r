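test_that("coefficient of variation matches hand-computed values", {
  expect_equal(coefficient_of_variation(c(1, 1, 1)), 0)
  expect_equal(coefficient_of_variation(c(8, 12)), 100 * sqrt(8) / 10,
               tolerance = 1e-12)
  expect_equal(coefficient_of_variation(c(5, 5, 5, 15)), 100 * 5 / 7.5,
               tolerance = 1e-12)
  expect_error(coefficient_of_variation(c(-1, 1)), "mean is zero")
  expect_error(coefficient_of_variation(5), "at least 2")
})

test_that("repeatability aggregates per-subject CoVs as mean (SD)", {
  d <- data.frame(subject = rep(1:2, each = 3), timepoint = rep(1:3, 2),
                  value = c(10, 10, 10, 8, 12, 10))
  r <- repeatability(d, "timepoints")
  expect_equal(r$mean_cov, 10, tolerance = 1e-12)
  expect_equal(r$sd_cov, sd(c(0, 20)), tolerance = 1e-12)
  expect_equal(r$sd_cov, 14.14, tolerance = 1e-3)

  d3 <- data.frame(subject = 1:3, timepoint = 1, value = c(9, 10, 11))
  expect_equal(repeatability(d3, "subjects"), 10, tolerance = 1e-12)
  expect_error(repeatability(d3, "timepoints"), "insufficient replication")
  d1 <- data.frame(subject = 1, timepoint = 1:3, value = c(9, 10, 11))
  expect_error(repeatability(d1, "subjects"), "insufficient replication")
})

test_that("spatial variability is the within-ROI CoV", {
  expect_equal(spatial_variability(c(2, 2, 2, 2)), 0)
  expect_equal(spatial_variability(c(0.014, 0.016)),
               100 * sd(c(0.014, 0.016)) / 0.015, tolerance = 1e-12)
  expect_equal(spatial_variability(c(0.014, 0.016)), 9.43, tolerance = 1e-3)
})

test_that("CNR follows (mIC - mCO) / SDCO", {
  expect_equal(contrast_to_noise(c(10, 10), c(8, 10, 12)), 0)
  # mIC = 8, mCO = 10, SDCO = 2
  contra <- c(8, 10, 12)
  expect_equal(contrast_to_noise(rep(8, 3), contra), -1.0)
  expect_error(contrast_to_noise(c(1, 2), c(3, 3, 3)), "sd is zero")
  # a core drawn from the contralateral distribution has |CNR| near 0
  set.seed(99)
  pop <- rnorm(1000, 0.015, 0.002)
  expect_lt(abs(contrast_to_noise(sample(pop, 1000, replace = TRUE), pop)),
            0.2)
})

test_that("CSF-fraction profile bins 0-50% in 10 ranges", {
  # constant APTR* -> zero across-bin CoV
  csf <- seq(0, 0.5, length.out = 100)
  prof <- csf_fraction_profile(rep(0.015, 100), csf)
  expect_equal(prof$cov, 0)
  expect_equal(sum(prof$bin_counts), 100)
  # hand-computed: bin means 10 x 9, then 9
  a <- rep(10, 100); a[csf >= 0.45] <- 9
  prof2 <- csf_fraction_profile(a, csf)
  expect_equal(prof2$bin_means, c(rep(10, 9), 9))
  expect_equal(prof2$cov, 100 * sd(c(rep(10, 9), 9)) / 9.9,
               tolerance = 1e-12)
  # voxels beyond 50% CSF are excluded
  prof3 <- csf_fraction_profile(c(1, 1, 2), c(0.1, 0.3, 0.9))
  expect_equal(sum(prof3$bin_counts), 2L)
  expect_error(csf_fraction_profile(c(1, 2), c(0.8, 0.9)), "no voxels")
})

test_that("statistics are invariant to voxel order and scale", {
  set.seed(5)
  v <- rnorm(50, 10, 2)
  perm <- sample(50)
  expect_equal(coefficient_of_variation(v), coefficient_of_variation(v[perm]))
  expect_equal(coefficient_of_variation(v), coefficient_of_variation(3 * v),
               tolerance = 1e-12)
  expect_equal(contrast_to_noise(v[1:20], v[21:50]),
               contrast_to_noise(v[1:20], v[21:50][sample(30)]))
  csf <- runif(50, 0, 0.5)
  expect_equal(csf_fraction_profile(v, csf)$cov,
               csf_fraction_profile(v[perm], csf[perm])$cov)
})
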