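// Batched inner-loop kernels for the annealing samplers: per-chain BFGS MAP
// solves (Poisson CT and phase-retrieval objectives) and batched unadjusted
// Langevin subiterations. Dimensions are small (D ~ 10) so dense BFGS is
// cheaper and more robust than limited-memory variants.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Fast local normal generator (Marsaglia-Tsang ziggurat over a 32-bit
// Mersenne twister) for the Langevin subiteration loops, which consume O(1e8)
// draws per study; seeded explicitly from the R level so runs stay
// reproducible.
struct NormGen {
  std::mt19937 eng;
  std::uint32_t kn[128];
  double wn[128], fn[128];
  explicit NormGen(double seed) : eng(static_cast<std::uint32_t>(
      static_cast<std::uint64_t>(seed) & 0xffffffffu)) {
    const double m1 = 2147483648.0;
    double dn = 3.442619855899, tn = dn;
    const double vn = 9.91256303526217e-3;
    double q = vn / std::exp(-0.5 * dn * dn);
    kn[0] = static_cast<std::uint32_t>((dn / q) * m1);
    kn[1] = 0;
    wn[0] = q / m1;
    wn[127] = dn / m1;
    fn[0] = 1.0;
    fn[127] = std::exp(-0.5 * dn * dn);
    for (int i = 126; i >= 1; --i) {
      dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
      kn[i + 1] = static_cast<std::uint32_t>((dn / tn) * m1);
      tn = dn;
      fn[i] = std::exp(-0.5 * dn * dn);
      wn[i] = dn / m1;
    }
  }
  double unif() { return (eng() + 0.5) * 2.3283064365386963e-10; }
  double nfix(std::int32_t hz, std::uint32_t iz) {
    const double r = 3.442619855899;
    for (;;) {
      double x = hz * wn[iz];
      if (iz == 0) {
        double y;
        do {
          x = -std::log(unif()) * 0.2904764;   // 1/r
          y = -std::log(unif());
        } while (y + y < x * x);
        return (hz > 0) ? r + x : -r - x;
      }
      if (fn[iz] + unif() * (fn[iz - 1] - fn[iz]) < std::exp(-0.5 * x * x))
        return x;
      hz = static_cast<std::int32_t>(eng());
      iz = static_cast<std::uint32_t>(hz) & 127u;
      if (static_cast<std::uint32_t>(std::labs(hz)) < kn[iz]) return hz * wn[iz];
    }
  }
  double draw() {
    std::int32_t hz = static_cast<std::int32_t>(eng());
    std::uint32_t iz = static_cast<std::uint32_t>(hz) & 127u;
    return (static_cast<std::uint32_t>(std::labs(hz)) < kn[iz])
      ? hz * wn[iz] : nfix(hz, iz);
  }
  void fill(mat& Z) {
    double* p = Z.memptr();
    for (uword i = 0; i < Z.n_elem; ++i) p[i] = draw();
  }
};

// Negative log prediction density (constants dropped) and its gradient.
// type 0: Poisson counts, mean I0*exp(-F m); type 1: squared-linear Gaussian,
// f(m) = (F m)^2 with noise sd tau. Gaussian factor N(m; m0, beta2 I).
static double obj_grad(int type, const mat& F, double extra, const vec& y,
                       const vec& m0, double beta2, const vec& m, vec& g) {
  vec u = F * m;
  double val;
  if (type == 0) {
    vec lam = extra * exp(-clamp(u, -700.0, 700.0));
    val = accu(lam + y % u);
    g = F.t() * (y - lam);
  } else {
    vec f = square(u);
    vec r = f - y;
    double tau2 = extra * extra;
    val = 0.5 * dot(r, r) / tau2;
    g = 2.0 * (F.t() * (r % u)) / tau2;
  }
  vec d = m - m0;
  val += 0.5 * dot(d, d) / beta2;
  g += d / beta2;
  return val;
}

// Dense BFGS with a Wolfe-type backtracking/expansion line search.
static vec bfgs_solve(int type, const mat& F, double extra, const vec& y,
                      const vec& m0, double beta2, const vec& init,
                      int maxit) {
  const int D = init.n_elem;
  vec m = init, g(D), gnew(D);
  double fval = obj_grad(type, F, extra, y, m0, beta2, m, g);
  mat Hinv = eye(D, D) * beta2;      // prior curvature as initial scaling
  const double c1 = 1e-4, c2 = 0.9;
  for (int it = 0; it < maxit; ++it) {
    if (norm(g, 2) < 1e-10 * std::max(1.0, std::abs(fval))) break;
    vec p = -(Hinv * g);
    double gp = dot(g, p);
    if (gp >= 0) { p = -g; gp = dot(g, p); Hinv = eye(D, D); }
    double alpha = 1.0, fnew = fval;
    vec m_old = m;
    bool ok = false;
    for (int ls = 0; ls < 30; ++ls) {
      vec mtry = m + alpha * p;
      fnew = obj_grad(type, F, extra, y, m0, beta2, mtry, gnew);
      if (std::isfinite(fnew) && fnew <= fval + c1 * alpha * gp) {
        // expand once if the curvature condition is far from active
        if (ls == 0 && std::abs(dot(gnew, p)) > c2 * std::abs(gp) &&
            fnew < fval + c1 * 2.0 * alpha * gp) {
          vec m2 = m + 2.0 * alpha * p;
          vec g2(D);
          double f2 = obj_grad(type, F, extra, y, m0, beta2, m2, g2);
          if (std::isfinite(f2) && f2 < fnew) { mtry = m2; fnew = f2; gnew = g2; }
        }
        m = mtry; ok = true; break;
      }
      alpha *= 0.5;
    }
    if (!ok) break;                  // line-search failure: keep best iterate
    vec s = m - m_old;
    vec yk = gnew - g;
    double sy = dot(s, yk);
    if (sy > 1e-12) {
      double rho = 1.0 / sy;
      mat I = eye(D, D);
      Hinv = (I - rho * s * yk.t()) * Hinv * (I - rho * yk * s.t()) +
             rho * (s * s.t());
    }
    g = gnew;
    fval = fnew;
  }
  return m;
}

// [[Rcpp::export]]
arma::mat map_batch_cpp(int type, const arma::mat& F, double extra,
                        const arma::mat& Y, const arma::mat& M0,
                        double beta2, int maxit) {
  const int n = M0.n_rows;
  mat out(n, M0.n_cols);
  const bool shared_y = (Y.n_rows == 1);
  for (int i = 0; i < n; ++i) {
    vec y = shared_y ? Y.row(0).t() : Y.row(i).t();
    out.row(i) = bfgs_solve(type, F, extra, y, M0.row(i).t(), beta2,
                            M0.row(i).t(), maxit).t();
  }
  return out;
}

// Batched unadjusted Langevin on the prediction target
// loglike(m) + log N(m; m0, beta2 I) for the binary-mask Gaussian likelihood.
// obs holds 0-based observed coordinate indices.
// [[Rcpp::export]]
arma::mat ula_mask_cpp(arma::mat M, const arma::mat& M0,
                       const arma::uvec& obs, const arma::vec& y,
                       double tau, double beta2, double eta, int nsub,
                       double seed) {
  const double tau2 = tau * tau;
  const double sq = std::sqrt(2.0 * eta);
  const int n = M.n_rows, D = M.n_cols;
  NormGen rng(seed);
  mat Z(n, D);
  for (int s = 0; s < nsub; ++s) {
    mat grad = (M0 - M) / beta2;
    for (uword k = 0; k < obs.n_elem; ++k) {
      uword j = obs[k];
      grad.col(j) -= (M.col(j) - y[k]) / tau2;
    }
    rng.fill(Z);
    M += eta * grad + sq * Z;
  }
  return M;
}

// Same for the Poisson-count likelihood with mean map I0*exp(-C m).
// [[Rcpp::export]]
arma::mat ula_poisson_cpp(arma::mat M, const arma::mat& M0,
                          const arma::mat& C, double I0, const arma::vec& y,
                          double beta2, double eta, int nsub, double seed) {
  const double sq = std::sqrt(2.0 * eta);
  const int n = M.n_rows, D = M.n_cols;
  NormGen rng(seed);
  mat Z(n, D);
  for (int s = 0; s < nsub; ++s) {
    mat U = M * C.t();
    mat lam = I0 * exp(-clamp(U, -700.0, 700.0));
    lam.each_row() -= y.t();
    mat grad = lam * C + (M0 - M) / beta2;
    rng.fill(Z);
    M += eta * grad + sq * Z;
  }
  return M;
}
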