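// Differential-evolution MCMC with sampling from past states and snooker
// moves, specialized to the benchmark targets: Gaussian-mixture prior times
// {none, linear-Gaussian, Poisson-count, squared-linear-Gaussian} likelihood.
// The inner loop is allocation-free: O(10^7) chain-iterations per reference
// run are routine for the harder studies.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// log prior x log likelihood at x (length D), all raw loops.
struct Target {
  const mat& means;        // K x D
  const cube& Pinv;        // D x D x K
  const vec& lw;           // K
  int type;                // 0 none, 1 linear-Gauss, 2 Poisson, 3 squared-linear
  const mat& F;            // Kdim x D
  double extra;            // tau or I0
  const vec& y;
  std::vector<double> dbuf, ubuf;
  Target(const mat& means_, const cube& Pinv_, const vec& lw_, int type_,
         const mat& F_, double extra_, const vec& y_)
    : means(means_), Pinv(Pinv_), lw(lw_), type(type_), F(F_), extra(extra_),
      y(y_), dbuf(means_.n_cols), ubuf(F_.n_rows) {}

  double logpost(const double* x) {
    const int K = means.n_rows, D = means.n_cols;
    double best = -std::numeric_limits<double>::infinity();
    double terms[16];
    for (int i = 0; i < K; ++i) {
      for (int j = 0; j < D; ++j) dbuf[j] = x[j] - means(i, j);
      const double* P = Pinv.slice_memptr(i);
      double q = 0;
      for (int k = 0; k < D; ++k) {
        double acc = 0;
        for (int j = 0; j < D; ++j) acc += P[k * D + j] * dbuf[j];
        q += acc * dbuf[k];
      }
      terms[i] = lw[i] - 0.5 * q;
      if (terms[i] > best) best = terms[i];
    }
    double s = 0;
    for (int i = 0; i < K; ++i) s += std::exp(terms[i] - best);
    double lp = best + std::log(s);
    if (type == 0) return lp;
    const int Kd = F.n_rows, D2 = means.n_cols;
    const double* Fp = F.memptr();          // column-major Kd x D
    for (int k = 0; k < Kd; ++k) ubuf[k] = 0;
    for (int j = 0; j < D2; ++j) {
      const double xj = x[j];
      const double* col = Fp + (std::size_t)j * Kd;
      for (int k = 0; k < Kd; ++k) ubuf[k] += col[k] * xj;
    }
    if (type == 1) {
      double ss = 0;
      for (int k = 0; k < Kd; ++k) { double r = ubuf[k] - y[k]; ss += r * r; }
      return lp - 0.5 * ss / (extra * extra);
    }
    if (type == 2) {
      double ss = 0;
      for (int k = 0; k < Kd; ++k) {
        double u = std::min(std::max(ubuf[k], -700.0), 700.0);
        ss += extra * std::exp(-u) + y[k] * ubuf[k];
      }
      return lp - ss;
    }
    double ss = 0;
    for (int k = 0; k < Kd; ++k) {
      double r = ubuf[k] * ubuf[k] - y[k];
      ss += r * r;
    }
    return lp - 0.5 * ss / (extra * extra);
  }
};

// [[Rcpp::export]]
Rcpp::List demc_cpp(const arma::mat& means, const arma::cube& Pinv,
                    const arma::vec& lw, int type, const arma::mat& F,
                    double extra, const arma::vec& y, const arma::mat& init,
                    const arma::mat& archive0, int n_iter, int thin,
                    double seed) {
  const int n_chains = init.n_rows, D = init.n_cols;
  if (means.n_rows > 16) Rcpp::stop("at most 16 mixture components supported");
  std::mt19937_64 eng(static_cast<std::uint64_t>(seed));
  std::normal_distribution<double> rnorm(0.0, 1.0);
  std::uniform_real_distribution<double> runif(0.0, 1.0);
  Target tgt(means, Pinv, lw, type, F, extra, y);
  const double gamma0 = 2.38 / std::sqrt(2.0 * D);
  const double b_eps = 1e-6;
  const int thin_arch = 10;
  const int n_stored = n_iter / thin;
  // archive rows stored contiguously per state (row-major layout by hand)
  const std::size_t max_arch = archive0.n_rows + (n_iter / thin_arch + 1) * n_chains;
  std::vector<double> arch(max_arch * D);
  for (uword r = 0; r < archive0.n_rows; ++r)
    for (int j = 0; j < D; ++j) arch[r * D + j] = archive0(r, j);
  std::size_t na = archive0.n_rows;
  mat X = init;                 // n_chains x D, column-major (small)
  std::vector<double> xc(D), prop(D);
  vec lp(n_chains);
  for (int c = 0; c < n_chains; ++c) {
    for (int j = 0; j < D; ++j) xc[j] = X(c, j);
    lp[c] = tgt.logpost(xc.data());
  }
  cube chains(n_chains, n_stored, D);
  mat lps(n_chains, n_stored);
  for (int it = 1; it <= n_iter; ++it) {
    std::uniform_int_distribution<std::size_t> ridx(0, na - 1);
    for (int c = 0; c < n_chains; ++c) {
      for (int j = 0; j < D; ++j) xc[j] = X(c, j);
      double logcorr = 0.0;
      bool moved = true;
      if (runif(eng) < 0.1) {
        // snooker move along the direction to a random archive state
        const double* z = &arch[ridx(eng) * D];
        double nd2 = 0;
        for (int j = 0; j < D; ++j) {
          double d = xc[j] - z[j];
          nd2 += d * d;
        }
        if (nd2 > 0) {
          const double* z1 = &arch[ridx(eng) * D];
          const double* z2 = &arch[ridx(eng) * D];
          double proj = 0;
          for (int j = 0; j < D; ++j) proj += (z1[j] - z2[j]) * (xc[j] - z[j]);
          double gs = 1.2 + runif(eng);
          double nd2p = 0;
          for (int j = 0; j < D; ++j) {
            prop[j] = xc[j] + gs * proj / nd2 * (xc[j] - z[j]);
            double d = prop[j] - z[j];
            nd2p += d * d;
          }
          logcorr = 0.5 * (D - 1) * (std::log(nd2p) - std::log(nd2));
        } else moved = false;
      } else {
        double gam = (runif(eng) < 0.1) ? 1.0 : gamma0;
        const double* z1 = &arch[ridx(eng) * D];
        const double* z2 = &arch[ridx(eng) * D];
        for (int j = 0; j < D; ++j)
          prop[j] = xc[j] + gam * (z1[j] - z2[j]) + b_eps * rnorm(eng);
      }
      if (moved) {
        double lp_p = tgt.logpost(prop.data());
        if (std::isfinite(lp_p) &&
            std::log(runif(eng)) < lp_p - lp[c] + logcorr) {
          for (int j = 0; j < D; ++j) X(c, j) = prop[j];
          lp[c] = lp_p;
        }
      }
    }
    if (it % thin_arch == 0) {
      for (int c = 0; c < n_chains; ++c)
        for (int j = 0; j < D; ++j) arch[(na + c) * D + j] = X(c, j);
      na += n_chains;
    }
    if (it % thin == 0) {
      int s = it / thin - 1;
      for (int c = 0; c < n_chains; ++c) {
        for (int j = 0; j < D; ++j) chains(c, s, j) = X(c, j);
        lps(c, s) = lp[c];
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("chains") = chains,
                            Rcpp::Named("logpost") = lps);
}
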