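// Continuous-wave multi-pool Bloch-McConnell simulation core.
//
// Magnetization is stacked per pool as (Mx, My, Mz), water first, so the
// generator A is 3*n_pools square. Exchange follows a star topology
// (every solute pool exchanges with water only) with detailed balance:
// the water->pool rate is kex * m0_pool / m0_water.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// gamma for 1H in rad s^-1 uT^-1 (2.675221874e8 rad s^-1 T^-1 * 1e-6)
static const double GAMMA_UT = 267.5221874;

// pools: n x 5 matrix, columns m0, kex, t1, t2, dw (water is row 0).
// offset, dw, b0 in ppm; larmor in MHz so ppm * larmor = Hz.
static arma::mat build_generator(const arma::mat& pools, double b1_uT,
                                 double offset_ppm, double b0_ppm,
                                 double larmor_mhz, arma::vec& bvec) {
  const arma::uword n = pools.n_rows;
  const double w1 = GAMMA_UT * b1_uT;
  arma::mat A(3 * n, 3 * n, arma::fill::zeros);
  bvec.zeros(3 * n);

  const double m0w = pools(0, 0);
  double c_water = 0.0;  // total exchange loss rate of water
  for (arma::uword i = 1; i < n; ++i)
    c_water += pools(i, 1) * pools(i, 0) / m0w;

  for (arma::uword i = 0; i < n; ++i) {
    const double m0 = pools(i, 0);
    const double r1 = 1.0 / pools(i, 2);
    const double r2 = 1.0 / pools(i, 3);
    const double dw = pools(i, 4);
    // off-resonance of this pool at the current saturation offset, rad/s
    const double theta = 2.0 * M_PI * larmor_mhz * (offset_ppm - dw - b0_ppm);
    const double closs = (i == 0) ? c_water : pools(i, 1);
    const arma::uword x = 3 * i, y = 3 * i + 1, z = 3 * i + 2;

    A(x, x) = -(r2 + closs);  A(x, y) =  theta;
    A(y, x) = -theta;         A(y, y) = -(r2 + closs);  A(y, z) = w1;
    A(z, y) = -w1;            A(z, z) = -(r1 + closs);
    bvec(z) = r1 * m0;

    if (i > 0) {
      const double k_sw = pools(i, 1);            // solute -> water
      const double k_ws = k_sw * m0 / m0w;        // water -> solute
      for (arma::uword c = 0; c < 3; ++c) {
        A(c, 3 * i + c) += k_sw;   // water gains from solute
        A(3 * i + c, c) += k_ws;   // solute gains from water
      }
    }
  }
  return A;
}

// [[Rcpp::export(name = ".bm_generator_cpp")]]
List bm_generator_cpp(const arma::mat& pools, double b1_uT, double offset_ppm,
                      double b0_ppm, double larmor_mhz) {
  arma::vec b;
  arma::mat A = build_generator(pools, b1_uT, offset_ppm, b0_ppm, larmor_mhz, b);
  return List::create(Named("A") = A, Named("b") = b);
}

// Propagate from thermal equilibrium for t_sat seconds and return the water
// longitudinal magnetization at each saturation offset (absolute units).
static arma::vec sim_core(const arma::mat& pools, double b1_uT,
                          const arma::vec& offsets_ppm, double b0_ppm,
                          double larmor_mhz, double t_sat) {
  const arma::uword n = pools.n_rows;
  arma::vec m0(3 * n, arma::fill::zeros);
  for (arma::uword i = 0; i < n; ++i) m0(3 * i + 2) = pools(i, 0);

  arma::vec out(offsets_ppm.n_elem);
  for (arma::uword j = 0; j < offsets_ppm.n_elem; ++j) {
    arma::vec b;
    arma::mat A = build_generator(pools, b1_uT, offsets_ppm(j), b0_ppm,
                                  larmor_mhz, b);
    arma::vec x;
    bool ok = arma::solve(x, A, b, arma::solve_opts::no_approx);
    if (!ok) {
      if (b1_uT == 0.0) {
        // homogeneous branch: equilibrium is the fixed point, no saturation
        out(j) = pools(0, 0);
        continue;
      }
      stop("singular Bloch-McConnell generator at offset %g ppm",
           offsets_ppm(j));
    }
    // M(t) = expm(A t) (M0 + A^-1 b) - A^-1 b
    arma::mat E = arma::expmat(A * t_sat);
    arma::vec mt = E * (m0 + x) - x;
    if (!mt.is_finite())
      stop("non-finite magnetization at offset %g ppm", offsets_ppm(j));
    out(j) = mt(2);
  }
  return out;
}

// [[Rcpp::export(name = ".bm_zspectrum_cpp")]]
arma::vec bm_zspectrum_cpp(const arma::mat& pools, double b1_uT,
                           const arma::vec& offsets_ppm, double b0_ppm,
                           double larmor_mhz, double t_sat) {
  return sim_core(pools, b1_uT, offsets_ppm, b0_ppm, larmor_mhz, t_sat);
}

// ---------------------------------------------------------------------------
// MAP objective (negative log posterior) for voxel fitting, with a
// forward-difference gradient in prior-standardized coordinates. Mirrors
// the R-level ctx_nlp()/ctx_predict(); the two are asserted equal in the
// test suite.

struct FitCtx {
  arma::mat pm, pm_csf;
  arma::uvec pool_pos, ri, ci;   // free-vector positions -> pm entries
  arma::uvec islog;              // per free parameter
  arma::vec mean, sd;
  arma::uword b0_pos, sig_pos;
  int model;                     // 0 = single compartment, 1 = pvc mixture
  double pve, ratio;
  double b1, larmor, t_sat;
  arma::vec offsets;
};

static FitCtx unpack_ctx(const List& ctx) {
  FitCtx C;
  C.pm = as<arma::mat>(ctx["pm"]);
  C.pm_csf = as<arma::mat>(ctx["pm_csf"]);
  C.pool_pos = as<arma::uvec>(ctx["pool_pos"]);
  C.ri = as<arma::uvec>(ctx["ri"]);
  C.ci = as<arma::uvec>(ctx["ci"]);
  C.islog = as<arma::uvec>(ctx["islog"]);
  C.mean = as<arma::vec>(ctx["mean"]);
  C.sd = as<arma::vec>(ctx["sd"]);
  C.b0_pos = as<arma::uword>(ctx["b0_pos"]);
  C.sig_pos = as<arma::uword>(ctx["sig_pos"]);
  C.model = as<int>(ctx["model"]);
  C.pve = as<double>(ctx["pve"]);
  C.ratio = as<double>(ctx["ratio"]);
  C.b1 = as<double>(ctx["b1"]);
  C.larmor = as<double>(ctx["larmor"]);
  C.t_sat = as<double>(ctx["t_sat"]);
  C.offsets = as<arma::vec>(ctx["offsets"]);
  return C;
}

static arma::vec predict_one(const FitCtx& C, const arma::vec& u) {
  arma::vec theta = C.mean + C.sd % u;
  arma::mat pm = C.pm;
  for (arma::uword k = 0; k < C.pool_pos.n_elem; ++k) {
    const arma::uword p = C.pool_pos(k);
    pm(C.ri(k), C.ci(k)) = C.islog(p) ? std::exp(theta(p)) : theta(p);
  }
  const double b0 = theta(C.b0_pos);
  if (C.model == 1) {
    arma::mat pmc = C.pm_csf;
    pmc(0, 0) = C.ratio * pm(0, 0);
    // normalized so that the fitted water m0 is the voxel's overall
    // unsaturated scale (matches S0-normalized data; cancels in APTR*)
    const double denom = (1.0 - C.pve) * C.ratio + C.pve;
    return ((1.0 - C.pve) * sim_core(pmc, C.b1, C.offsets, b0, C.larmor,
                                     C.t_sat) +
            C.pve * sim_core(pm, C.b1, C.offsets, b0, C.larmor, C.t_sat)) /
           denom;
  }
  return sim_core(pm, C.b1, C.offsets, b0, C.larmor, C.t_sat);
}

static double nlp_one(const FitCtx& C, const arma::vec& u,
                      const arma::vec& y) {
  arma::vec pred = predict_one(C, u);
  if (!pred.is_finite()) return 1e30;
  const double lsig = C.mean(C.sig_pos) + C.sd(C.sig_pos) * u(C.sig_pos);
  const double ss = arma::accu(arma::square(y - pred));
  return y.n_elem * lsig + 0.5 * ss * std::exp(-2.0 * lsig) +
         0.5 * arma::accu(arma::square(u));
}

// [[Rcpp::export(name = ".bm_nlp_cpp")]]
double bm_nlp_cpp(const arma::vec& u, const arma::vec& y, const List& ctx) {
  return nlp_one(unpack_ctx(ctx), u, y);
}

// Gradient over the active coordinates (0-based). Model coordinates use a
// forward-difference Jacobian of the prediction, so the likelihood part of
// the gradient is exact in the residual (in particular it vanishes with
// the residual, keeping zero-noise fits at the optimum); the noise
// coordinate is analytic.
// [[Rcpp::export(name = ".bm_nlp_grad_cpp")]]
arma::vec bm_nlp_grad_cpp(const arma::vec& u, const arma::vec& y,
                          const List& ctx, const arma::uvec& active,
                          double h = 1e-6) {
  FitCtx C = unpack_ctx(ctx);
  const arma::vec pred0 = predict_one(C, u);
  const arma::vec r = y - pred0;
  const double lsig = C.mean(C.sig_pos) + C.sd(C.sig_pos) * u(C.sig_pos);
  const double w = std::exp(-2.0 * lsig);
  arma::vec g(active.n_elem);
  for (arma::uword k = 0; k < active.n_elem; ++k) {
    const arma::uword j = active(k);
    if (j == C.sig_pos) {
      // d/dlsig [n lsig + ss/2 e^{-2 lsig}] * d lsig/du_j + prior
      g(k) = (y.n_elem - arma::accu(arma::square(r)) * w) * C.sd(j) + u(j);
      continue;
    }
    arma::vec u2 = u;
    u2(j) += h;
    arma::vec dpred = (predict_one(C, u2) - pred0) / h;
    g(k) = -w * arma::dot(r, dpred) + u(j);
  }
  return g;
}
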