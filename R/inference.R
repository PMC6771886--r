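#' Default parameter priors for voxelwise fitting
#'
#' Returns the prior registry used by [fit_voxel()]: one row per model
#' parameter with its transform scale (`"log"` for concentrations and
#' exchange rates, `"linear"` for relaxation times, chemical shifts and the
#' B0 shift), the prior mean and standard deviation on that scale, box
#' bounds for the optimizer, and a `frozen` flag for parameters held fixed.
#'
#' The default free/fixed split for the tissue models: water `m0`, `t1`,
#' `t2` are free; each solute pool has free `m0`, `kex`, `t2` with `t1`
#' and chemical shift fixed; the B0 shift and the noise standard deviation
#' are always free. The `csf_only` model frees the single pool's `m0`,
#' `t1`, `t2` plus B0 shift and noise. Prior means coincide with
#' [default_tissue_pools()] so that the phantom generator and the fitter
#' share one parameter registry. Everything here is editable: the registry
#' is an ordinary data frame.
#'
#' @param model_tag One of `"four_pool"`, `"pvc"`, `"csf_only"`.
#' @return A data frame with columns `pool`, `param`, `transform`, `mean`,
#'   `sd`, `lower`, `upper`, `frozen`.
#' @examples
#' default_priors("four_pool")
#' @export
default_priors <- function(model_tag = c("four_pool", "pvc", "csf_only")) {
  model_tag <- match.arg(model_tag)
  row <- function(pool, param, transform, mean, sd, lower, upper,
                  frozen = FALSE)
    data.frame(pool = pool, param = param, transform = transform,
               mean = mean, sd = sd, lower = lower, upper = upper,
               frozen = frozen, stringsAsFactors = FALSE)
  glob <- rbind(
    row("global", "b0_shift", "linear", 0, 0.3, -2, 2),
    row("global", "noise_sd", "log", log(0.01), 2, log(1e-7), log(10))
  )
  if (model_tag == "csf_only") {
    reg <- rbind(
      row("csf", "m0", "log", log(1.0), 0.5, -5, 5),
      row("csf", "t1", "linear", 4.3, 1.0, 0.1, 10),
      row("csf", "t2", "linear", 2.0, 0.5, 0.01, 5),
      row("csf", "kex", "linear", 0, NA, 0, 0, frozen = TRUE),
      row("csf", "dw", "linear", 0, NA, 0, 0, frozen = TRUE),
      glob)
    return(reg)
  }
  rbind(
    row("water", "m0", "log", log(1.0), 0.3, -5, 5),
    row("water", "t1", "linear", 1.3, 0.3, 0.05, 10),
    row("water", "t2", "linear", 0.07, 0.03, 1e-4, 3),
    row("water", "dw", "linear", 0, NA, 0, 0, frozen = TRUE),
    row("amide", "m0", "log", log(1e-3), 1.0, -20, 0),
    row("amide", "kex", "log", log(30), 0.5, -2, 8),
    row("amide", "t2", "linear", 0.02, 0.01, 1e-4, 1),
    row("amide", "t1", "linear", 1.0, NA, 1, 1, frozen = TRUE),
    row("amide", "dw", "linear", 3.5, NA, 3.5, 3.5, frozen = TRUE),
    row("mt", "m0", "log", log(0.08), 1.0, -20, 0),
    row("mt", "kex", "log", log(25), 0.5, -2, 8),
    row("mt", "t2", "linear", 1e-5, 5e-6, 1e-7, 1e-3),
    row("mt", "t1", "linear", 1.0, NA, 1, 1, frozen = TRUE),
    row("mt", "dw", "linear", 0, NA, 0, 0, frozen = TRUE),
    row("noe", "m0", "log", log(5e-3), 1.0, -20, 0),
    row("noe", "kex", "log", log(15), 0.5, -2, 8),
    row("noe", "t2", "linear", 1e-3, 5e-4, 1e-5, 0.1),
    row("noe", "t1", "linear", 1.0, NA, 1, 1, frozen = TRUE),
    row("noe", "dw", "linear", -3.5, NA, -3.5, -3.5, frozen = TRUE),
    glob)
}

#' Fitting options
#'
#' @param max_iter Maximum optimizer iterations per stage.
#' @param tol Convergence tolerance on the objective.
#' @param compute_sd Compute Laplace-approximation posterior standard
#'   deviations (numerical Hessian at the posterior mode). Disable for
#'   large images where only point maps are needed.
#' @param max_rounds Maximum alternating rounds of model-parameter
#'   optimization and noise-parameter update; iteration stops early once
#'   both are stable.
#' @param n_starts Number of optimization starts. The first start is the
#'   prior mean; additional starts are a fixed (internally seeded, hence
#'   still deterministic) set of draws around it, and the fit with the best
#'   posterior is kept. Use 3-5 when fitting a deliberately misspecified
#'   model to strongly mixed spectra, whose posterior can be multimodal.
#' @param aptr_frame Frame in which APTR* evaluates the fitted spectra:
#'   `"b0_corrected"` (at the amide resonance after removing the fitted
#'   water shift) or `"nominal"` (at the raw +3.5 ppm offset).
#' @return A list of options.
#' @export
fit_options <- function(max_iter = 500, tol = 1e-8, compute_sd = TRUE,
                        max_rounds = 8, n_starts = 1,
                        aptr_frame = c("b0_corrected", "nominal")) {
  list(max_iter = as.integer(max_iter), tol = tol,
       compute_sd = isTRUE(compute_sd),
       max_rounds = as.integer(max_rounds),
       n_starts = as.integer(n_starts),
       aptr_frame = match.arg(aptr_frame))
}

inv_transform <- function(x, transform) ifelse(transform == "log", exp(x), x)

# Build the fitting context: base pool matrices plus the mapping from the
# free-parameter vector into them.
build_fit_context <- function(model_tag, compartments, priors, protocol,
                              pve) {
  stopifnot(inherits(compartments, "compartment_model"))
  if (model_tag == "pvc") {
    if (is.null(pve)) stop("model_tag 'pvc' requires the voxel's tissue PVE")
    if (pve < 0 || pve > 1) stop("pve must be in [0, 1]")
  }
  pm <- if (model_tag == "csf_only") {
    m <- pool_matrix(list(compartments$csf_pool))
    rownames(m) <- "csf"
    m
  } else {
    pool_matrix(compartments$tissue_pools)
  }
  # frozen pool rows take their registry values
  frz <- priors[priors$frozen & priors$pool != "global", , drop = FALSE]
  for (i in seq_len(nrow(frz)))
    if (frz$pool[i] %in% rownames(pm))
      pm[frz$pool[i], frz$param[i]] <- inv_transform(frz$mean[i],
                                                     frz$transform[i])
  free <- priors[!priors$frozen, , drop = FALSE]
  if (any(!is.finite(free$sd) | free$sd <= 0))
    stop("every free parameter needs a prior sd > 0")
  pool_rows <- free$pool != "global"
  if (!all(free$pool[pool_rows] %in% rownames(pm)))
    stop("priors refer to pools absent from the model: ",
         paste(setdiff(free$pool[pool_rows], rownames(pm)), collapse = ", "))
  ctx <- list(model_tag = model_tag, protocol = protocol, pve = pve,
              ratio = compartments$csf_tissue_ratio, pm = pm,
              pm_csf = pool_matrix(list(compartments$csf_pool)),
              free = free,
              ri = match(free$pool[pool_rows], rownames(pm)),
              ci = match(free$param[pool_rows], colnames(pm)),
              pool_rows = which(pool_rows),
              b0_idx = which(free$pool == "global" & free$param == "b0_shift"),
              sig_idx = which(free$pool == "global" &
                                free$param == "noise_sd"))
  if (length(ctx$b0_idx) != 1L || length(ctx$sig_idx) != 1L)
    stop("priors must contain free global rows 'b0_shift' and 'noise_sd'")
  # mirror of the context consumed by the compiled objective
  ctx$cpp <- list(pm = unname(ctx$pm), pm_csf = unname(ctx$pm_csf),
                  pool_pos = ctx$pool_rows - 1L, ri = ctx$ri - 1L,
                  ci = ctx$ci - 1L,
                  islog = as.integer(free$transform == "log"),
                  mean = free$mean, sd = free$sd,
                  b0_pos = ctx$b0_idx - 1L, sig_pos = ctx$sig_idx - 1L,
                  model = if (model_tag == "pvc") 1L else 0L,
                  pve = if (is.null(pve)) 1 else pve,
                  ratio = compartments$csf_tissue_ratio,
                  b1 = protocol$b1, larmor = protocol$larmor,
                  t_sat = protocol$t_sat, offsets = protocol$offsets)
  ctx
}

ctx_predict <- function(ctx, theta) {
  pm <- ctx$pm
  vals <- inv_transform(theta[ctx$pool_rows],
                        ctx$free$transform[ctx$pool_rows])
  pm[cbind(ctx$ri, ctx$ci)] <- vals
  b0 <- theta[ctx$b0_idx]
  if (ctx$model_tag == "pvc") {
    pm_csf <- ctx$pm_csf
    pm_csf[1, "m0"] <- ctx$ratio * pm[1, "m0"]
    # normalized so the fitted water m0 is the voxel's overall unsaturated
    # scale, matching S0-normalized data (cancels in APTR*)
    ((1 - ctx$pve) * sim_mz_abs(pm_csf, ctx$protocol, b0) +
       ctx$pve * sim_mz_abs(pm, ctx$protocol, b0)) /
      ((1 - ctx$pve) * ctx$ratio + ctx$pve)
  } else {
    sim_mz_abs(pm, ctx$protocol, b0)
  }
}

# negative log posterior (Gaussian noise, independent Gaussian priors on
# the transformed parameters)
ctx_nlp <- function(ctx, theta, y) {
  pred <- ctx_predict(ctx, theta)
  r <- y - pred
  sigma <- exp(theta[ctx$sig_idx])
  length(y) * theta[ctx$sig_idx] + sum(r^2) / (2 * sigma^2) +
    sum(((theta - ctx$free$mean) / ctx$free$sd)^2) / 2
}

#' Fit one z-spectrum voxel
#'
#' Maximum-a-posteriori fit of the chosen model to one measured z-spectrum
#' under independent Gaussian priors on transformed parameters and a
#' Gaussian noise model whose standard deviation is itself a free parameter
#' with a weak prior. The water-frequency (B0) shift is always free.
#' Posterior standard deviations come from a Laplace approximation
#' (inverse Hessian of the negative log posterior at the mode), reported on
#' the natural scale via the delta method. The fit is deterministic given
#' data, priors and initialization (initialization is at the prior means).
#'
#' Optimization runs in two stages of L-BFGS-B: first with the noise
#' parameter pinned at its prior mean, then jointly over all parameters.
#'
#' @param data A [zspectrum()] of measured, S0-normalized signal.
#' @param protocol The [saturation_protocol()] used for acquisition; its
#'   offsets must match `data$offsets`.
#' @param model_tag `"four_pool"`, `"pvc"`, or `"csf_only"`.
#' @param compartments A [compartment_model()].
#' @param priors Prior registry as from [default_priors()].
#' @param pve Tissue partial-volume fraction for `model_tag = "pvc"`
#'   (fixed, not fitted).
#' @param options [fit_options()].
#' @return An object of class `"voxel_fit"`: estimates and posterior sds on
#'   the natural scale (named `pool.param`), `b0_shift`, `noise_sd`,
#'   `residual_rms`, `converged`, `n_iter`, the updated pool list, and for
#'   PVC fits the constrained CSF pool and the voxel's `pve`.
#' @export
fit_voxel <- function(data, protocol,
                      model_tag = c("four_pool", "pvc", "csf_only"),
                      compartments = compartment_model(),
                      priors = NULL, pve = NULL, options = fit_options()) {
  model_tag <- match.arg(model_tag)
  stopifnot(inherits(data, "zspectrum"), inherits(protocol, "cest_protocol"))
  if (length(data$offsets) != length(protocol$offsets) ||
      max(abs(data$offsets - protocol$offsets)) > 1e-9)
    stop("data offsets do not match the protocol offsets")
  if (is.null(priors)) priors <- default_priors(model_tag)
  y <- data$signal
  if (any(!is.finite(y)) || all(y == 0)) {
    return(structure(list(model_tag = model_tag, estimates = NULL,
                          sd = NULL, b0_shift = NA_real_,
                          noise_sd = NA_real_, residual_rms = NA_real_,
                          converged = FALSE, flagged = TRUE, n_iter = 0L),
                     class = "voxel_fit"))
  }
  ctx <- build_fit_context(model_tag, compartments, priors, protocol, pve)
  free <- ctx$free
  # optimize in prior-standardized coordinates u = (theta - mean) / sd so
  # that every parameter has unit scale regardless of its physical units
  to_theta <- function(u) free$mean + free$sd * u
  lo <- (free$lower - free$mean) / free$sd
  hi <- (free$upper - free$mean) / free$sd
  u <- rep(0, nrow(free))   # initialization at the prior means
  n_iter <- 0L
  ctrl <- list(maxit = options$max_iter,
               factr = options$tol / .Machine$double.eps)

  # Alternating optimization: the model parameters are optimized at fixed
  # noise sd, then the noise parameter is updated from its 1-D conditional
  # posterior (which depends on the data only through the residual sum of
  # squares, so the update costs no spectrum evaluations). Iterating to
  # stability reaches the joint posterior mode while staying stable in the
  # zero-noise limit, where the noise sd collapses to its floor.
  fn <- function(us) .bm_nlp_cpp(us, y, ctx$cpp)
  gr <- function(us) .bm_nlp_grad_cpp(us, y, ctx$cpp, seq_along(us) - 1L)
  si <- ctx$sig_idx
  sub <- setdiff(seq_along(u), si)
  n_obs <- length(y)
  profile_sigma <- function(u) {
    ss <- sum((y - ctx_predict(ctx, to_theta(u)))^2)
    obj <- function(ls) n_obs * ls + 0.5 * ss * exp(-2 * ls) +
      ((ls - free$mean[si]) / free$sd[si])^2 / 2
    ls <- stats::optimize(obj, lower = free$lower[si],
                          upper = free$upper[si], tol = 1e-10)$minimum
    min(max((ls - free$mean[si]) / free$sd[si], lo[si]), hi[si])
  }
  run_from <- function(u0) {
    u <- u0
    fn1 <- function(us) {
      full <- u; full[sub] <- us
      .bm_nlp_cpp(full, y, ctx$cpp)
    }
    gr1 <- function(us) {
      full <- u; full[sub] <- us
      .bm_nlp_grad_cpp(full, y, ctx$cpp, sub - 1L)
    }
    conv_code <- 1L
    iters <- 0L
    for (round in seq_len(max(1L, options$max_rounds))) {
      o <- optim(u[sub], fn1, gr1, method = "L-BFGS-B",
                 lower = lo[sub], upper = hi[sub], control = ctrl)
      u[sub] <- o$par
      iters <- iters + o$counts[[1L]]
      conv_code <- o$convergence
      sig_new <- profile_sigma(u)
      stable <- abs(sig_new - u[si]) * free$sd[si] < 0.01
      u[si] <- sig_new
      if (stable && conv_code == 0L) break
    }
    list(u = u, convergence = conv_code, iters = iters,
         value = .bm_nlp_cpp(u, y, ctx$cpp))
  }

  starts <- list(u)
  if (options$n_starts > 1L) {
    # fixed auxiliary draws keep multistart fully deterministic
    rs <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    set.seed(285713L)
    for (k in seq_len(options$n_starts - 1L)) {
      u0 <- rnorm(length(u), 0, 1)
      u0 <- pmin(pmax(u0, lo), hi)
      u0[si] <- u[si]
      starts[[k + 1L]] <- u0
    }
    if (is.null(rs)) rm(list = ".Random.seed", envir = .GlobalEnv)
    else assign(".Random.seed", rs, envir = .GlobalEnv)
  }
  best <- NULL
  for (u0 in starts) {
    cand <- run_from(u0)
    n_iter <- n_iter + cand$iters
    if (is.null(best) || cand$value < best$value) best <- cand
  }
  u <- best$u
  o2 <- list(convergence = best$convergence, value = best$value)
  theta <- to_theta(u)

  est_nat <- inv_transform(theta, free$transform)
  names(est_nat) <- paste(free$pool, free$param, sep = ".")

  sd_nat <- rep(NA_real_, length(theta))
  names(sd_nat) <- names(est_nat)
  if (options$compute_sd) {
    H <- tryCatch(optimHess(u, fn, gr), error = function(e) NULL)
    if (!is.null(H)) {
      ev <- eigen(H, symmetric = TRUE)
      lam <- pmax(ev$values, max(ev$values) * 1e-10)
      cv <- ev$vectors %*% diag(1 / lam, length(lam)) %*% t(ev$vectors)
      # back from standardized to transform scale, then (delta method)
      # to the natural scale for log-transformed parameters
      sd_t <- sqrt(pmax(diag(cv), 0)) * free$sd
      sd_nat <- ifelse(free$transform == "log", sd_t * est_nat, sd_t)
      names(sd_nat) <- names(est_nat)
    }
  }

  r <- y - ctx_predict(ctx, theta)
  pm <- ctx$pm
  pm[cbind(ctx$ri, ctx$ci)] <- est_nat[ctx$pool_rows]
  pools <- lapply(rownames(pm), function(nm)
    structure(list(name = nm, m0 = pm[nm, "m0"], kex = pm[nm, "kex"],
                   t1 = pm[nm, "t1"], t2 = pm[nm, "t2"], dw = pm[nm, "dw"]),
              class = "cest_pool"))
  csf_pool <- NULL
  if (model_tag == "pvc") {
    csf_pool <- compartments$csf_pool
    csf_pool$m0 <- ctx$ratio * pm[1, "m0"]
  }
  structure(list(model_tag = model_tag, estimates = est_nat, sd = sd_nat,
                 b0_shift = theta[ctx$b0_idx],
                 noise_sd = exp(theta[ctx$sig_idx]),
                 residual_rms = sqrt(mean(r^2)),
                 converged = o2$convergence == 0, flagged = FALSE,
                 n_iter = n_iter, logpost = -o2$value, pools = pools,
                 csf_pool = csf_pool, pve = pve,
                 larmor = protocol$larmor, b1 = protocol$b1,
                 t_sat = protocol$t_sat),
            class = "voxel_fit")
}

#' @export
print.voxel_fit <- function(x, ...) {
  cat(sprintf("<voxel_fit %s> converged=%s rms=%.3g b0=%.4g ppm\n",
              x$model_tag, x$converged, x$residual_rms, x$b0_shift))
  if (!is.null(x$estimates))
    print(round(x$estimates, 6))
  invisible(x)
}

#' Choose the per-voxel model from the tissue partial-volume estimate
#'
#' Voxels whose tissue fraction is below 50% are deemed non-interpretable
#' for APT quantification: only a CSF pool is fitted there, and they are
#' excluded from all downstream APTR* analyses. The threshold is strict:
#' a voxel at exactly 0.50 receives the requested tissue model.
#'
#' @param pve Tissue partial-volume fraction in `[0, 1]`.
#' @param requested The tissue model to use where interpretable:
#'   `"pvc"` or `"four_pool"`.
#' @return `"csf_only"` or `requested`.
#' @examples
#' select_model_by_pve(0.3)            # "csf_only"
#' select_model_by_pve(0.5, "pvc")     # "pvc"
#' @export
select_model_by_pve <- function(pve, requested = c("pvc", "four_pool")) {
  requested <- match.arg(requested)
  if (!is.finite(pve) || pve < 0 || pve > 1) stop("pve must be in [0, 1]")
  if (pve < 0.50) "csf_only" else requested
}

#' Fit a 4D CEST image voxel by voxel
#'
#' Applies [select_model_by_pve()] then [fit_voxel()] independently to
#' every voxel inside the mask (there is no spatial coupling, so voxel
#' order cannot affect results). Returns per-parameter mean and sd maps,
#' residual and convergence maps, and the list of per-voxel fits for
#' downstream quantification.
#'
#' @param data_4d 4D array `[x, y, z, offset]` of S0-normalized signal (or
#'   raw signal together with `s0_volume`).
#' @param protocol A [saturation_protocol()]; `length(protocol$offsets)`
#'   must equal `dim(data_4d)[4]`.
#' @param pve_map 3D array of tissue fractions. Required for
#'   `model_tag = "pvc"`; when `NULL`, all voxels are treated as pure
#'   tissue.
#' @param mask Logical 3D array of voxels to fit; default all.
#' @param model_tag Requested tissue model, `"four_pool"` or `"pvc"`.
#' @param compartments A [compartment_model()].
#' @param priors Tissue-model prior registry (defaults per model);
#'   `csf_priors` the registry for CSF-only voxels.
#' @param csf_priors Priors for `csf_only` voxels.
#' @param options [fit_options()].
#' @param s0_volume Optional 3D array; when given, `data_4d` is divided by
#'   it voxelwise before fitting.
#' @return An object of class `"cest_fit_image"` with elements `fits`
#'   (per-voxel list, `NULL` outside mask/flagged), `maps` (named list of
#'   3D arrays: `<param>_mean`, `<param>_sd`, `residual_rms`, `converged`,
#'   `b0_shift`), `eligible` (logical array: voxels with a tissue-model
#'   fit), `model_map` (character array), plus the inputs needed to
#'   reproduce the fit.
#' @export
fit_image <- function(data_4d, protocol, pve_map = NULL, mask = NULL,
                      model_tag = c("four_pool", "pvc"),
                      compartments = compartment_model(), priors = NULL,
                      csf_priors = NULL, options = fit_options(),
                      s0_volume = NULL) {
  model_tag <- match.arg(model_tag)
  dims <- dim(data_4d)
  if (length(dims) != 4L) stop("data_4d must be a 4D array")
  if (dims[4L] != length(protocol$offsets))
    stop("offset count mismatch: data has ", dims[4L], " volumes but the ",
         "protocol lists ", length(protocol$offsets), " offsets")
  vdim <- dims[1:3]
  if (is.null(pve_map)) pve_map <- array(1, dim = vdim)
  if (!identical(dim(pve_map), vdim))
    stop("pve_map grid ", paste(dim(pve_map), collapse = "x"),
         " does not match data grid ", paste(vdim, collapse = "x"))
  if (is.null(mask)) mask <- array(TRUE, dim = vdim)
  if (!identical(dim(mask), vdim))
    stop("mask grid ", paste(dim(mask), collapse = "x"),
         " does not match data grid ", paste(vdim, collapse = "x"))
  if (!is.null(s0_volume)) {
    if (!identical(dim(s0_volume), vdim))
      stop("s0_volume grid does not match data grid")
    data_4d <- data_4d / as.vector(s0_volume)   # recycles over offsets
  }
  if (is.null(priors)) priors <- default_priors(model_tag)
  if (is.null(csf_priors)) csf_priors <- default_priors("csf_only")

  idx <- which(mask, arr.ind = TRUE)
  nvox <- nrow(idx)
  fits <- vector("list", nvox)
  model_map <- array(NA_character_, dim = vdim)
  for (v in seq_len(nvox)) {
    i <- idx[v, 1L]; j <- idx[v, 2L]; k <- idx[v, 3L]
    pve <- pve_map[i, j, k]
    tag <- select_model_by_pve(pve, model_tag)
    y <- data_4d[i, j, k, ]
    if (any(!is.finite(y)) || all(y == 0)) {
      warning(sprintf("voxel (%d,%d,%d): non-finite or all-zero data; skipped",
                      i, j, k))
      model_map[i, j, k] <- "flagged"
      next
    }
    z <- zspectrum(protocol$offsets, y, s0 = 1)
    fits[[v]] <- fit_voxel(z, protocol, tag, compartments,
                           priors = if (tag == "csf_only") csf_priors
                                    else priors,
                           pve = if (tag == "pvc") pve else NULL,
                           options = options)
    model_map[i, j, k] <- tag
  }

  pnames <- unique(unlist(lapply(fits, function(f)
    if (!is.null(f) && !is.null(f$estimates)) names(f$estimates))))
  maps <- list()
  for (pn in pnames) {
    m <- array(NA_real_, dim = vdim); s <- array(NA_real_, dim = vdim)
    for (v in seq_len(nvox)) {
      f <- fits[[v]]
      if (is.null(f) || is.null(f$estimates) ||
          !pn %in% names(f$estimates)) next
      m[idx[v, 1L], idx[v, 2L], idx[v, 3L]] <- f$estimates[[pn]]
      s[idx[v, 1L], idx[v, 2L], idx[v, 3L]] <- f$sd[[pn]]
    }
    maps[[paste0(pn, "_mean")]] <- m
    maps[[paste0(pn, "_sd")]] <- s
  }
  for (nm in c("residual_rms", "b0_shift")) {
    m <- array(NA_real_, dim = vdim)
    for (v in seq_len(nvox)) {
      f <- fits[[v]]
      if (!is.null(f)) m[idx[v, 1L], idx[v, 2L], idx[v, 3L]] <- f[[nm]]
    }
    maps[[nm]] <- m
  }
  conv <- array(NA, dim = vdim)
  elig <- array(FALSE, dim = vdim)
  for (v in seq_len(nvox)) {
    f <- fits[[v]]
    if (is.null(f)) next
    conv[idx[v, 1L], idx[v, 2L], idx[v, 3L]] <- f$converged
    elig[idx[v, 1L], idx[v, 2L], idx[v, 3L]] <-
      f$model_tag %in% c("four_pool", "pvc") && !isTRUE(f$flagged)
  }
  maps$converged <- conv
  structure(list(fits = fits, voxels = idx, maps = maps, eligible = elig,
                 model_map = model_map, model_tag = model_tag,
                 pve_map = pve_map, mask = mask, protocol = protocol,
                 compartments = compartments, options = options),
            class = "cest_fit_image")
}

#' @export
print.cest_fit_image <- function(x, ...) {
  cat(sprintf("<cest_fit_image %s> %d voxels fitted, %d APTR*-eligible\n",
              x$model_tag, sum(!vapply(x$fits, is.null, logical(1))),
              sum(x$eligible)))
  invisible(x)
}
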