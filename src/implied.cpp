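// Hot path for the MR-DoC2 moment structure and ML discrepancy.
// Parameter vector layout (shared with R/params.R, keep in sync):
//   0 ra, 1 rc, 2 re, 3 rf, 4 a1, 5 c1, 6 e1, 7 a2, 8 c2, 9 e2,
//   10 g1, 11 g2, 12 b1, 13 b3, 14 b2, 15 b4, 16 sigma_x, 17 sigma_y
// Variable order of the pair 8-vector:
//   ph1_t1, ph2_t1, ps1_t1, ps2_t1, ph1_t2, ph2_t2, ps1_t2, ps2_t2

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat implied_cov_cpp(const vec& th, const double share) {
  const double ra = th(0), rc = th(1), re = th(2), rf = th(3);
  const double a1 = th(4), c1 = th(5), e1 = th(6);
  const double a2 = th(7), c2 = th(8), e2 = th(9);
  const double g1 = th(10), g2 = th(11);
  const double b1 = th(12), b3 = th(13), b2 = th(14), b4 = th(15);
  const double sx = th(16), sy = th(17);

  const double d = 1.0 - g1 * g2;
  // reciprocal-causation reduced form (I - B)^-1, B = [[0, g2], [g1, 0]]
  mat W = {{1.0 / d, g2 / d}, {g1 / d, 1.0 / d}};
  mat Lam = {{a1, c1, e1, 0.0, 0.0, 0.0}, {0.0, 0.0, 0.0, a2, c2, e2}};
  mat G = {{b1, b4}, {b2, b3}};
  mat Sps = {{sx * sx, rf * sx * sy}, {rf * sx * sy, sy * sy}};

  // within-person latent covariance (A1,C1,E1,A2,C2,E2)
  mat Pw(6, 6, fill::eye);
  Pw(0, 3) = Pw(3, 0) = ra;
  Pw(1, 4) = Pw(4, 1) = rc;
  Pw(2, 5) = Pw(5, 2) = re;
  // cross-twin latent covariance: A scaled by the genetic share, C shared
  // fully, E uncorrelated across twins
  mat Px(6, 6, fill::zeros);
  Px(0, 0) = Px(3, 3) = share;
  Px(0, 3) = Px(3, 0) = share * ra;
  Px(1, 1) = Px(4, 4) = 1.0;
  Px(1, 4) = Px(4, 1) = rc;
  mat Sps_x = share * Sps;

  mat Cpp_w = W * (Lam * Pw * Lam.t() + G * Sps * G.t()) * W.t();
  mat Cps_w = W * G * Sps;
  mat Cpp_x = W * (Lam * Px * Lam.t() + G * Sps_x * G.t()) * W.t();
  mat Cps_x = W * G * Sps_x;

  mat S(8, 8);
  S.submat(0, 0, 1, 1) = Cpp_w;
  S.submat(0, 2, 1, 3) = Cps_w;
  S.submat(2, 0, 3, 1) = Cps_w.t();
  S.submat(2, 2, 3, 3) = Sps;
  S.submat(4, 4, 5, 5) = Cpp_w;
  S.submat(4, 6, 5, 7) = Cps_w;
  S.submat(6, 4, 7, 5) = Cps_w.t();
  S.submat(6, 6, 7, 7) = Sps;
  S.submat(0, 4, 1, 5) = Cpp_x;
  S.submat(0, 6, 1, 7) = Cps_x;
  S.submat(2, 4, 3, 5) = Cps_x.t();
  S.submat(2, 6, 3, 7) = Sps_x;
  S.submat(4, 0, 7, 3) = S.submat(0, 4, 3, 7).t();
  return 0.5 * (S + S.t());
}

// [[Rcpp::export]]
arma::mat cpp_implied_cov(const arma::vec& theta, const double share) {
  return implied_cov_cpp(theta, share);
}

// One zygosity group's contribution to the ML discrepancy
// n * (ln|Sigma| + tr(S Sigma^-1) - ln|S| - p). An indefinite Sigma gets a
// penalty that grows with the eigenvalue violation, so line searches that
// overshoot the admissible region are steered back instead of stalling on a
// flat cliff.
static double group_discrepancy(const mat& Sigma, const mat& S, const double ldS,
                                const double n) {
  mat L;
  if (!chol(L, Sigma, "lower")) {
    vec ev;
    if (!eig_sym(ev, Sigma)) return 2e5;
    return 1e5 + 1e4 * (1.0 - ev.min());
  }
  const double ldSig = 2.0 * sum(log(L.diag()));
  mat X = solve(trimatl(L), S);
  mat Y = solve(trimatu(L.t()), X);
  const double tr = trace(Y);
  return n * (ldSig + tr - ldS - static_cast<double>(S.n_rows));
}

static double ml_discrepancy_at(const vec& x, const uvec& free_idx,
                                const vec& theta_fixed, const bool ra_constr,
                                const double ra_m,
                                const mat& S_mz, const double ldS_mz,
                                const double n_mz,
                                const mat& S_dz, const double ldS_dz,
                                const double n_dz) {
  vec th = theta_fixed;
  for (uword i = 0; i < free_idx.n_elem; ++i) th(free_idx(i)) = x(i);
  if (ra_constr) th(0) = ra_m * th(3);
  if (std::abs(th(10) * th(11)) >= 0.999) {
    return 1e5 + 1e4 * std::abs(th(10) * th(11));
  }

  double F = 0.0;
  if (n_mz > 0) {
    // MZ co-twins carry identical polygenic scores: the 8x8 pair covariance
    // is singular, so the MZ likelihood lives on the 6 non-degenerate
    // coordinates (both phenotypes of both twins, twin-1's two scores).
    mat Sig = implied_cov_cpp(th, 1.0);
    mat Sig6 = Sig.submat(0, 0, 5, 5);
    F += group_discrepancy(Sig6, S_mz, ldS_mz, n_mz);
  }
  if (n_dz > 0) {
    mat Sig = implied_cov_cpp(th, 0.5);
    F += group_discrepancy(Sig, S_dz, ldS_dz, n_dz);
  }
  return F;
}

// [[Rcpp::export]]
double cpp_ml_discrepancy(const arma::vec& x, const arma::uvec& free_idx,
                          const arma::vec& theta_fixed, const bool ra_constr,
                          const double ra_m,
                          const arma::mat& S_mz, const double ldS_mz,
                          const double n_mz,
                          const arma::mat& S_dz, const double ldS_dz,
                          const double n_dz) {
  return ml_discrepancy_at(x, free_idx, theta_fixed, ra_constr, ra_m,
                           S_mz, ldS_mz, n_mz, S_dz, ldS_dz, n_dz);
}

// Central-difference gradient of the discrepancy, computed without leaving
// C++ (one callback per optimizer iteration instead of 2k).
// [[Rcpp::export]]
arma::vec cpp_ml_gradient(const arma::vec& x, const arma::uvec& free_idx,
                          const arma::vec& theta_fixed, const bool ra_constr,
                          const double ra_m,
                          const arma::mat& S_mz, const double ldS_mz,
                          const double n_mz,
                          const arma::mat& S_dz, const double ldS_dz,
                          const double n_dz) {
  const uword k = x.n_elem;
  vec g(k);
  for (uword j = 0; j < k; ++j) {
    const double h = 1e-7 * std::max(1.0, std::abs(x(j)));
    vec xp = x; xp(j) += h;
    vec xm = x; xm(j) -= h;
    const double fp = ml_discrepancy_at(xp, free_idx, theta_fixed, ra_constr,
                                        ra_m, S_mz, ldS_mz, n_mz,
                                        S_dz, ldS_dz, n_dz);
    const double fm = ml_discrepancy_at(xm, free_idx, theta_fixed, ra_constr,
                                        ra_m, S_mz, ldS_mz, n_mz,
                                        S_dz, ldS_dz, n_dz);
    g(j) = (fp - fm) / (2.0 * h);
  }
  return g;
}
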