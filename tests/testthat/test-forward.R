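test_that("pool constructor enforces physical parameter ranges", {
  expect_error(pool("water", m0 = -1, t1 = 1, t2 = 0.1), "m0")
  expect_error(pool("water", m0 = 1, t1 = -1, t2 = 0.1), "t1")
  expect_error(pool("water", m0 = 1, t1 = 1, t2 = 2), "t2")
  expect_error(
    cestpvc:::pool_matrix(list(pool("amide", 0.001, 30, 1, 0.02, 3.5))),
    "water")
})

test_that("relaxation-only generator has the equilibrium as fixed point", {
  w <- list(pool("water", m0 = 1, t1 = 1.3, t2 = 0.07))
  g <- assemble_generator(w, b1 = 0, offset = 0)
  meq <- c(0, 0, 1)
  expect_equal(as.numeric(g$A %*% meq + g$b), rep(0, 3), tolerance = 1e-14)
  # dimension scales as 3 x n_pools
  g4 <- assemble_generator(default_tissue_pools(), b1 = 0.55, offset = 3.5)
  expect_equal(dim(g4$A), c(12L, 12L))
  expect_length(g4$b, 12L)
})

test_that("generator matches a hand-written 2-pool Bloch-McConnell matrix", {
  # independent transcription of the standard CW 2-pool system
  m0a <- 1; m0b <- 0.01; kb <- 20
  t1a <- 1.5; t2a <- 0.08; t1b <- 1.0; t2b <- 0.02; dwb <- 3.0
  b1 <- 0.8; off <- 2.0; b0 <- 0.03; larmor <- 127.74
  w1 <- 2.675221874e8 * 1e-6 * b1
  ka <- kb * m0b / m0a                    # water -> solute (detailed balance)
  tha <- 2 * pi * larmor * (off - 0 - b0)
  thb <- 2 * pi * larmor * (off - dwb - b0)
  A <- matrix(0, 6, 6)
  A[1, ] <- c(-(1 / t2a + ka), tha, 0, kb, 0, 0)
  A[2, ] <- c(-tha, -(1 / t2a + ka), w1, 0, kb, 0)
  A[3, ] <- c(0, -w1, -(1 / t1a + ka), 0, 0, kb)
  A[4, ] <- c(ka, 0, 0, -(1 / t2b + kb), thb, 0)
  A[5, ] <- c(0, ka, 0, -thb, -(1 / t2b + kb), w1)
  A[6, ] <- c(0, 0, ka, 0, -w1, -(1 / t1b + kb))
  b <- c(0, 0, m0a / t1a, 0, 0, m0b / t1b)

  pools <- list(pool("water", m0a, 0, t1a, t2a, 0),
                pool("solute", m0b, kb, t1b, t2b, dwb))
  g <- assemble_generator(pools, b1, off, b0, larmor)
  expect_equal(unname(g$A), A, tolerance = 1e-12)
  expect_equal(unname(g$b), b, tolerance = 1e-12)
  # compiled generator builds the identical system
  gc <- cestpvc:::.bm_generator_cpp(cestpvc:::pool_matrix(pools), b1, off,
                                    b0, larmor)
  expect_equal(unname(gc$A), A, tolerance = 1e-12)
})

test_that("no saturation means no signal loss at any offset", {
  p <- default_protocol()
  p$b1 <- 0
  z <- simulate_zspectrum(default_tissue_pools(), p)
  expect_equal(z$signal, rep(1, 33), tolerance = 1e-12)
})

test_that("far-off-resonance saturation is negligible for water", {
  p <- saturation_protocol(b1 = 0.55, t_sat = 2, offsets = 300)
  z <- simulate_zspectrum(list(pool("water", 1, 0, 1.3, 0.07)), p)
  expect_lt(abs(z$signal - 1), 0.01)
})

test_that("z-spectrum is bounded and symmetric for symmetric pool pairs", {
  p <- default_protocol()
  offs <- seq(-4, 4, by = 0.5)
  psym <- saturation_protocol(0.55, 2, offs)
  pools <- list(pool("water", 1, 0, 1.3, 0.07, 0),
                pool("up", 0.002, 30, 1, 0.02, 2.2),
                pool("down", 0.002, 30, 1, 0.02, -2.2))
  z <- simulate_zspectrum(pools, psym)
  expect_true(all(z$signal >= 0 & z$signal <= 1 + 1e-6))
  expect_equal(z$signal, rev(z$signal), tolerance = 1e-10)
})

test_that("signal at the amide offset decreases with amide m0 and t_sat", {
  p <- saturation_protocol(0.55, 2, 3.5)
  sig_at <- function(m0_amide, t_sat) {
    pr <- saturation_protocol(0.55, t_sat, 3.5)
    tp <- default_tissue_pools()
    tp[[2]]$m0 <- m0_amide
    simulate_zspectrum(tp, pr)$signal
  }
  m0s <- c(0, 5e-4, 1e-3, 2e-3, 5e-3)
  sig_m0 <- vapply(m0s, sig_at, numeric(1), t_sat = 2)
  expect_true(all(diff(sig_m0) < 0))
  tsats <- c(0.5, 1, 2, 4)
  sig_ts <- vapply(tsats, function(ts) sig_at(1e-3, ts), numeric(1))
  expect_true(all(diff(sig_ts) < 0))
})

test_that("a B0 shift is equivalent to shifting all offsets", {
  tp <- default_tissue_pools()
  delta <- 0.17
  p1 <- default_protocol()
  p2 <- p1
  p2$offsets <- p1$offsets - delta
  z1 <- simulate_zspectrum(tp, p1, b0_shift = delta)
  z2 <- simulate_zspectrum(tp, p2, b0_shift = 0)
  expect_equal(z1$signal, z2$signal, tolerance = 1e-12)
})

test_that("CW-equivalent B1 follows the closed-form pulse arithmetic", {
  # zero flip -> zero amplitude
  expect_equal(cw_equivalent_b1(pulse_train(10, 0, 0.02, 0.02)), 0)
  # rectangular 180 deg, 20 ms on / 20 ms off:
  # peak = pi / (gamma * 0.02) = 0.587 uT, power-equivalent 0.587 * sqrt(0.5)
  tr <- pulse_train(50, 180, 0.02, 0.02, "rectangular")
  peak <- pi / (2.675221874e8 * 0.02) * 1e6
  expect_equal(cw_equivalent_b1(tr), peak * sqrt(0.5), tolerance = 1e-10)
  expect_equal(cw_equivalent_b1(tr), 0.415, tolerance = 1e-3)
  # duty cycle 1: CW equivalent equals the pulse amplitude
  tr1 <- pulse_train(50, 180, 0.02, 0, "rectangular")
  expect_equal(cw_equivalent_b1(tr1), peak, tolerance = 1e-10)
  # averaging over the pulse only ignores the delay
  expect_equal(cw_equivalent_b1(tr, average = "pulse"), peak,
               tolerance = 1e-10)
  # gaussian shape requires a truncation level
  expect_error(pulse_train(50, 184, 0.02, 0.02, "gaussian"), "truncation")
})

test_that("the acquisition pulse train reproduces the protocol's CW power", {
  tr <- pulse_train(50, 184, 0.02, 0.02, "gaussian",
                    gaussian_truncation = 0.01)
  expect_equal(cw_equivalent_b1(tr), 0.55, tolerance = 0.02)
  expect_equal(50 * (0.02 + 0.02), default_protocol()$t_sat)
})
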