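# Shared fixtures: random Bloch-McConnell systems and the independent
# adaptive-step ODE oracle used to validate the matrix-exponential
# propagation.

random_bm_system <- function(n_pools) {
  pools <- list(pool("water", m0 = 1, kex = 0,
                     t1 = runif(1, 0.8, 2.0), t2 = runif(1, 0.04, 0.1),
                     dw = 0))
  for (i in seq_len(n_pools - 1L)) {
    t1 <- runif(1, 0.8, 1.5)
    pools[[i + 1L]] <- pool(paste0("solute", i),
                            m0 = runif(1, 5e-4, 0.05),
                            kex = runif(1, 5, 60),
                            t1 = t1,
                            t2 = runif(1, 2e-3, min(0.05, t1)),
                            dw = runif(1, -4, 4))
  }
  protocol <- saturation_protocol(
    b1 = runif(1, 0.3, 1.2), t_sat = runif(1, 0.2, 0.35),
    offsets = c(seq(-4.5, 4.5, length.out = 32), 300))
  list(pools = pools, protocol = protocol,
       b0 = runif(1, -0.1, 0.1))
}

# Brute-force oracle: adaptive-step stiff ODE integration of dM/dt = AM + b
# from thermal equilibrium, independent of the matrix-exponential path.
ode_zspectrum <- function(pools, protocol, b0 = 0, rtol = 1e-9,
                          atol = 1e-11) {
  pm_m0 <- vapply(pools, `[[`, numeric(1), "m0")
  n <- length(pools)
  M0 <- rep(0, 3 * n)
  M0[seq(3, 3 * n, by = 3)] <- pm_m0
  vapply(protocol$offsets, function(off) {
    g <- assemble_generator(pools, protocol$b1, off, b0, protocol$larmor)
    deriv <- function(t, y, parms) list(g$A %*% y + g$b)
    out <- deSolve::ode(M0, c(0, protocol$t_sat), deriv, NULL,
                        method = "lsoda", rtol = rtol, atol = atol,
                        maxsteps = 500000)
    out[2L, 4L] / pm_m0[1L]
  }, numeric(1))
}

expect_voxel_converged <- function(fit) {
  expect_s3_class(fit, "voxel_fit")
  expect_true(fit$converged)
}
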