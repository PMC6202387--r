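// Core numerical routines: graphical lasso (block coordinate descent) and
// bivariate standard-normal probabilities (Genz's BVND quadrature).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static double phid(double x) { return 0.5 * erfc(-x * M_SQRT1_2); }

// P(X > dh, Y > dk) for standard bivariate normal with correlation r.
// Genz (2004) hybrid: Gauss-Legendre on the asin(r) transform for |r| < 0.925,
// tail-difference formula otherwise. Absolute error < 5e-16.
static double bvnd(double dh, double dk, double r) {
  static const double w6[] = {0.1713244923791705, 0.3607615730481384,
                              0.4679139345726904};
  static const double x6[] = {0.9324695142031522, 0.6612093864662647,
                              0.2386191860831970};
  static const double w12[] = {0.04717533638651177, 0.1069393259953183,
                               0.1600783285433464,  0.2031674267230659,
                               0.2334925365383547,  0.2491470458134029};
  static const double x12[] = {0.9815606342467191, 0.9041172563704750,
                               0.7699026741943050, 0.5873179542866171,
                               0.3678314989981802, 0.1252334085114692};
  static const double w20[] = {0.01761400713915212, 0.04060142980038694,
                               0.06267204833410906, 0.08327674157670475,
                               0.1019301198172404,  0.1181945319615184,
                               0.1316886384491766,  0.1420961093183821,
                               0.1491729864726037,  0.1527533871307259};
  static const double x20[] = {0.9931285991850949, 0.9639719272779138,
                               0.9122344282513259, 0.8391169718222188,
                               0.7463319064601508, 0.6360536807265150,
                               0.5108670019508271, 0.3737060887154196,
                               0.2277858511416451, 0.07652652113349733};
  const double twopi = 6.283185307179586;
  const double *w, *x;
  int ng;
  if (std::fabs(r) < 0.3)      { ng = 3;  w = w6;  x = x6;  }
  else if (std::fabs(r) < 0.75){ ng = 6;  w = w12; x = x12; }
  else                         { ng = 10; w = w20; x = x20; }

  double h = dh, k = dk, hk = h * k, bvn = 0.0;
  if (std::fabs(r) < 0.925) {
    if (std::fabs(r) > 0) {
      double hs = (h * h + k * k) / 2.0, asr = std::asin(r);
      for (int i = 0; i < ng; i++) {
        for (int is = -1; is <= 1; is += 2) {
          double sn = std::sin(asr * (is * x[i] + 1.0) / 2.0);
          bvn += w[i] * std::exp((sn * hk - hs) / (1.0 - sn * sn));
        }
      }
      bvn = bvn * asr / (2.0 * twopi);
    }
    bvn += phid(-h) * phid(-k);
  } else {
    if (r < 0) { k = -k; hk = -hk; }
    if (std::fabs(r) < 1) {
      double as = (1.0 - r) * (1.0 + r), a = std::sqrt(as);
      double bs = (h - k) * (h - k);
      double c = (4.0 - hk) / 8.0, d = (12.0 - hk) / 16.0;
      double asr2 = -(bs / as + hk) / 2.0;
      if (asr2 > -100.0)
        bvn = a * std::exp(asr2) *
              (1.0 - c * (bs - as) * (1.0 - d * bs / 5.0) / 3.0 +
               c * d * as * as / 5.0);
      if (-hk < 100.0) {
        double b = std::sqrt(bs), sp = std::sqrt(twopi) * phid(-b / a);
        bvn -= std::exp(-hk / 2.0) * sp * b *
               (1.0 - c * bs * (1.0 - d * bs / 5.0) / 3.0);
      }
      a /= 2.0;
      for (int i = 0; i < ng; i++) {
        for (int is = -1; is <= 1; is += 2) {
          double xs = a * (is * x[i] + 1.0);
          xs = xs * xs;
          double rs = std::sqrt(1.0 - xs);
          double asr2b = -(bs / xs + hk) / 2.0;
          if (asr2b > -100.0) {
            double sp = 1.0 + c * xs * (1.0 + d * xs);
            double ep = std::exp(-hk * xs / (2.0 * (1.0 + rs) * (1.0 + rs))) / rs;
            bvn += a * w[i] * std::exp(asr2b) * (ep - sp);
          }
        }
      }
      bvn = -bvn / twopi;
    }
    if (r > 0) bvn += phid(-std::max(h, k));
    else {
      bvn = -bvn;
      if (k > h) bvn += phid(k) - phid(h);
    }
  }
  return std::max(0.0, std::min(1.0, bvn));
}

// P(X <= h, Y <= k), correlation rho; +-Inf allowed.
// [[Rcpp::export(name = ".bvn_cdf")]]
double bvn_cdf(double h, double k, double rho) {
  if (h == R_NegInf || k == R_NegInf) return 0.0;
  if (h == R_PosInf) return phid(k);
  if (k == R_PosInf) return phid(h);
  return bvnd(-h, -k, rho);
}

// Cell probabilities of a discretized bivariate normal: thresholds tau_x
// (length Kx-1) and tau_y cut the plane into Kx x Ky rectangles.
// [[Rcpp::export(name = ".bvn_cell_probs")]]
NumericMatrix bvn_cell_probs(NumericVector tau_x, NumericVector tau_y,
                             double rho) {
  int kx = tau_x.size() + 1, ky = tau_y.size() + 1;
  std::vector<double> ax(kx + 1), ay(ky + 1);
  ax[0] = R_NegInf; ax[kx] = R_PosInf;
  for (int i = 0; i < kx - 1; i++) ax[i + 1] = tau_x[i];
  ay[0] = R_NegInf; ay[ky] = R_PosInf;
  for (int j = 0; j < ky - 1; j++) ay[j + 1] = tau_y[j];
  // CDF grid then finite differences keeps each cell to one subtraction chain
  arma::mat F(kx + 1, ky + 1);
  for (int i = 0; i <= kx; i++)
    for (int j = 0; j <= ky; j++) F(i, j) = bvn_cdf(ax[i], ay[j], rho);
  NumericMatrix P(kx, ky);
  for (int i = 0; i < kx; i++)
    for (int j = 0; j < ky; j++)
      P(i, j) = std::max(0.0, F(i + 1, j + 1) - F(i, j + 1) - F(i + 1, j) + F(i, j));
  return P;
}

// One graphical-lasso fit by block coordinate descent (Friedman et al. 2008),
// off-diagonal penalty only. W: working covariance estimate (modified in
// place across warm starts), B: p x p matrix of column regression coefs.
// When `mask` is non-null the penalty is dropped and entries outside the
// mask are constrained to zero (support-restricted MLE refit).
static bool glasso_bcd(const arma::mat &S, double lam, arma::mat &W,
                       arma::mat &B, double tol, int maxit,
                       const arma::umat *mask = nullptr) {
  int p = S.n_rows;
  W.diag() = S.diag();          // no diagonal penalty
  for (int it = 0; it < maxit; it++) {
    double max_change = 0.0;
    for (int j = 0; j < p; j++) {
      // lasso subproblem: min .5 b' W11 b - s12' b + lam |b|_1
      arma::vec beta(p, arma::fill::zeros);
      for (int i = 0; i < p; i++) if (i != j) beta(i) = B(i, j);
      double inner_tol = tol * 0.1;
      for (int in_it = 0; in_it < 500; in_it++) {
        double in_change = 0.0;
        for (int i = 0; i < p; i++) {
          if (i == j) continue;
          if (mask && !(*mask)(i, j)) { beta(i) = 0.0; continue; }
          double grad = S(i, j);
          for (int k = 0; k < p; k++)
            if (k != j && k != i) grad -= W(i, k) * beta(k);
          double bnew;
          double z = grad;
          double l = mask ? 0.0 : lam;
          if (z > l) bnew = (z - l) / W(i, i);
          else if (z < -l) bnew = (z + l) / W(i, i);
          else bnew = 0.0;
          double d = std::fabs(bnew - beta(i));
          if (d > in_change) in_change = d;
          beta(i) = bnew;
        }
        if (in_change < inner_tol) break;
      }
      // update column j of W: w12 = W11 * beta
      for (int i = 0; i < p; i++) {
        if (i == j) continue;
        double wij = 0.0;
        for (int k = 0; k < p; k++)
          if (k != j) wij += W(i, k) * beta(k);
        double d = std::fabs(wij - W(i, j));
        if (d > max_change) max_change = d;
        W(i, j) = wij;
        W(j, i) = wij;
        B(i, j) = beta(i);
      }
    }
    if (max_change < tol) return true;
  }
  return false;
}

static arma::mat recover_precision(const arma::mat &W, const arma::mat &B) {
  int p = W.n_rows;
  arma::mat K(p, p, arma::fill::zeros);
  for (int j = 0; j < p; j++) {
    double dot = 0.0;
    for (int i = 0; i < p; i++) if (i != j) dot += W(i, j) * B(i, j);
    double kjj = 1.0 / (W(j, j) - dot);
    K(j, j) = kjj;
    for (int i = 0; i < p; i++) if (i != j) K(i, j) = -B(i, j) * kjj;
  }
  // exact zeros of B must survive symmetrization
  for (int j = 0; j < p; j++)
    for (int i = j + 1; i < p; i++) {
      double v;
      if (B(i, j) == 0.0 && B(j, i) == 0.0) v = 0.0;
      else v = (K(i, j) + K(j, i)) / 2.0;
      K(i, j) = v; K(j, i) = v;
    }
  return K;
}

// [[Rcpp::export(name = ".glasso_single")]]
List glasso_single(const arma::mat &S, double lam, double tol, int maxit) {
  int p = S.n_rows;
  arma::mat W = S, B(p, p, arma::fill::zeros);
  bool conv = glasso_bcd(S, lam, W, B, tol, maxit);
  arma::mat K = recover_precision(W, B);
  return List::create(_["K"] = K, _["W"] = W, _["converged"] = conv);
}

// Maximum-likelihood precision matrix restricted to a given support
// (zeros outside the mask), by the same block coordinate descent with the
// penalty dropped.
// [[Rcpp::export(name = ".glasso_refit")]]
List glasso_refit(const arma::mat &S, const arma::umat &support, double tol,
                  int maxit) {
  int p = S.n_rows;
  arma::mat W = S, B(p, p, arma::fill::zeros);
  arma::umat mask = support;
  mask.diag().ones();
  bool conv = glasso_bcd(S, 0.0, W, B, tol, maxit, &mask);
  arma::mat K = recover_precision(W, B);
  return List::create(_["K"] = K, _["converged"] = conv);
}

// Warm-started path over a decreasing lambda grid.  Returns the penalized
// precision matrix per lambda, per-lambda convergence flags, the Gaussian
// log-likelihood ingredients (log det K, tr(SK)) of the support-restricted
// MLE refit of each selected support, and the upper-triangle nonzero edge
// count used by EBIC scoring.
// [[Rcpp::export(name = ".glasso_path")]]
List glasso_path(const arma::mat &S, const arma::vec &lambdas, double tol,
                 int maxit) {
  int p = S.n_rows, nl = lambdas.n_elem;
  arma::mat W = S, B(p, p, arma::fill::zeros);
  arma::cube Ks(p, p, nl);
  LogicalVector conv(nl);
  NumericVector logdet(nl), trSK(nl);
  IntegerVector ecount(nl);
  arma::mat Wr = S, Br(p, p, arma::fill::zeros);   // refit warm starts
  for (int l = 0; l < nl; l++) {
    conv[l] = glasso_bcd(S, lambdas(l), W, B, tol, maxit);
    arma::mat K = recover_precision(W, B);
    Ks.slice(l) = K;
    int e = 0;
    arma::umat mask(p, p, arma::fill::zeros);
    for (int j = 0; j < p; j++)
      for (int i = 0; i < p; i++)
        if (i != j && K(i, j) != 0.0) mask(i, j) = 1;
    for (int j = 0; j < p; j++)
      for (int i = j + 1; i < p; i++) if (mask(i, j)) e++;
    ecount[l] = e;
    mask.diag().ones();
    // support-restricted MLE for the likelihood entering EBIC
    for (int j = 0; j < p; j++)
      for (int i = 0; i < p; i++)
        if (!mask(i, j)) Br(i, j) = 0.0;
    bool cr = glasso_bcd(S, 0.0, Wr, Br, tol, maxit, &mask);
    conv[l] = conv[l] && cr;
    arma::mat Kr = recover_precision(Wr, Br);
    double ld, sign;
    arma::log_det(ld, sign, Kr);
    logdet[l] = ld;
    trSK[l] = arma::accu(S % Kr);
  }
  return List::create(_["K"] = Ks, _["converged"] = conv,
                      _["logdet"] = logdet, _["trSK"] = trSK,
                      _["ecount"] = ecount);
}
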