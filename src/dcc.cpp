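// Likelihood filters for the two-stage DCC estimator and a batched
// threshold -> normalized-angle -> diffusion-embedding kernel used by the
// shuffle-heavy receptor-contribution loops. Numerics mirror the R
// reference implementations in R/gradients.R exactly.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// GARCH(1,1) conditional-variance filter: h_t = omega + alpha r_{t-1}^2 +
// beta h_{t-1}, h_1 = unconditional sample variance.
// [[Rcpp::export]]
arma::vec garch11_filter(const arma::vec& r, double omega, double alpha,
                         double beta) {
  const int T = r.n_elem;
  vec h(T);
  h(0) = arma::var(r);
  for (int t = 1; t < T; ++t) {
    h(t) = omega + alpha * r(t - 1) * r(t - 1) + beta * h(t - 1);
  }
  return h;
}

// Gaussian quasi negative log-likelihood of GARCH(1,1).
// [[Rcpp::export]]
double garch11_negloglik(const arma::vec& r, double omega, double alpha,
                         double beta) {
  if (omega <= 0.0 || alpha < 0.0 || beta < 0.0 || alpha + beta >= 1.0) {
    return 1e10;
  }
  vec h = garch11_filter(r, omega, alpha, beta);
  if (h.min() <= 0.0) return 1e10;
  double nll = 0.5 * arma::accu(arma::log(h) + arma::square(r) / h);
  return std::isfinite(nll) ? nll : 1e10;
}

// DCC(1,1) correlation recursion on standardized residuals E (T x N) with
// correlation targeting: Q_t = (1-a-b) S + a e_{t-1} e_{t-1}' + b Q_{t-1}.
// Returns the stage-2 negative quasi log-likelihood (correlation part).
// [[Rcpp::export]]
double dcc_negloglik(const arma::mat& E, const arma::mat& S, double a,
                     double b) {
  if (a < 0.0 || b < 0.0 || a + b >= 1.0) return 1e10;
  const int T = E.n_rows;
  mat Q = S;
  double nll = 0.0;
  for (int t = 0; t < T; ++t) {
    if (t > 0) {
      Q = (1.0 - a - b) * S + a * (E.row(t - 1).t() * E.row(t - 1)) +
          b * Q;
    }
    vec q = Q.diag();
    mat R = Q / arma::sqrt(q * q.t());
    mat L;
    if (!arma::chol(L, R, "lower")) return 1e10;
    vec z = arma::solve(arma::trimatl(L), E.row(t).t());
    nll += arma::accu(arma::log(L.diag())) + 0.5 * arma::dot(z, z) -
           0.5 * arma::dot(E.row(t), E.row(t));
  }
  return std::isfinite(nll) ? nll : 1e10;
}

// Composite (pairwise bivariate) DCC(1,1) negative quasi log-likelihood:
// the sum of 2-dimensional DCC likelihoods over region pairs with shared
// scalar parameters. Avoids the large-N bias of the joint likelihood that
// shrinks `a` towards zero. The 2x2 recursion has closed-form terms, so no
// Cholesky is needed and the correlation stays in (-1, 1).
// [[Rcpp::export]]
double dcc_composite_negloglik(const arma::mat& E, const arma::mat& S,
                               double a, double b,
                               const arma::umat& pairs) {
  if (a < 0.0 || b < 0.0 || a + b >= 1.0) return 1e10;
  const int T = E.n_rows;
  const double ab1 = 1.0 - a - b;
  double nll = 0.0;
  for (uword p = 0; p < pairs.n_rows; ++p) {
    const uword i = pairs(p, 0), j = pairs(p, 1);
    const double sij = S(i, j);
    double qii = 1.0, qjj = 1.0, qij = sij;
    for (int t = 0; t < T; ++t) {
      if (t > 0) {
        const double ei = E(t - 1, i), ej = E(t - 1, j);
        qii = ab1 + a * ei * ei + b * qii;
        qjj = ab1 + a * ej * ej + b * qjj;
        qij = ab1 * sij + a * ei * ej + b * qij;
      }
      const double r = qij / std::sqrt(qii * qjj);
      const double d = 1.0 - r * r;
      const double x = E(t, i), y = E(t, j);
      nll += 0.5 * (std::log(d) +
                    (x * x + y * y - 2.0 * r * x * y) / d -
                    (x * x + y * y));
    }
  }
  return std::isfinite(nll) ? nll : 1e10;
}

// Full DCC filter: per-frame conditional correlation matrices (N x N x T).
// [[Rcpp::export]]
arma::cube dcc_filter(const arma::mat& E, const arma::mat& S, double a,
                      double b) {
  const int T = E.n_rows, N = E.n_cols;
  cube Rt(N, N, T);
  mat Q = S;
  for (int t = 0; t < T; ++t) {
    if (t > 0) {
      Q = (1.0 - a - b) * S + a * (E.row(t - 1).t() * E.row(t - 1)) +
          b * Q;
    }
    vec q = Q.diag();
    mat R = Q / arma::sqrt(q * q.t());
    R.diag().ones();
    Rt.slice(t) = R;
  }
  return Rt;
}

// Row-threshold (top `keep` per row, ties to the lower column index,
// diagonal excluded), normalized-angle affinity, symmetrize. Mirrors
// threshold_rows() + normalized_angle().
static mat angle_affinity(const mat& C, int keep) {
  const int n = C.n_rows;
  mat Th(n, n, fill::zeros);
  for (int i = 0; i < n; ++i) {
    rowvec row = C.row(i);
    row(i) = -datum::inf;
    uvec idx = arma::stable_sort_index(row.t(), "descend");
    for (int k = 0; k < keep; ++k) Th(i, idx(k)) = C(i, idx(k));
  }
  vec nr = arma::sqrt(arma::sum(arma::square(Th), 1));
  mat Tn = Th.each_col() / nr;
  mat cosine = Tn * Tn.t();
  cosine = arma::clamp(cosine, -1.0, 1.0);
  mat A = 1.0 - arma::acos(cosine) / datum::pi;
  return (A + A.t()) / 2.0;
}

// Diffusion embedding of an affinity matrix; returns eigenvalues (desc,
// trivial dropped) and multi-scale-scaled components. Mirrors
// diffusion_embed() with diffusion_time = 0.
static void embed_affinity(const mat& A, double alpha, vec& lam_nt,
                           mat& comps) {
  const int n = A.n_rows;
  vec d = arma::sum(A, 1);
  mat W = A / (arma::pow(d, alpha) * arma::pow(d.t(), alpha));
  vec dw = arma::sum(W, 1);
  vec sq = arma::sqrt(dw);
  mat S = W / (sq * sq.t());
  vec lam;
  mat V;
  arma::eig_sym(lam, V, S);              // ascending
  lam = arma::reverse(lam);
  V = arma::fliplr(V);
  mat psi = V.each_col() / sq;
  double psi00 = psi(0, 0);
  lam_nt = lam.subvec(1, n - 1);
  comps = psi.cols(1, n - 1) / psi00;
  for (int k = 0; k < n - 1; ++k) {
    comps.col(k) *= lam_nt(k) / (1.0 - lam_nt(k));
  }
}

// Batched gradient explained variance for a stack of connectivity matrices,
// with components matched to reference maps by largest absolute Pearson
// correlation. Returns, per matrix and reference column: the matched
// component's explained variance and the absolute correlation.
// [[Rcpp::export]]
Rcpp::List batch_gradient_ev(const arma::cube& mats, double density,
                             double alpha, const arma::mat& ref,
                             int n_components) {
  const int B = mats.n_slices, n = mats.n_rows, K = ref.n_cols;
  int keep = (int)std::ceil(density * (n - 1));
  mat ev_out(B, K), cor_out(B, K);
  mat refz = ref.each_row() - arma::mean(ref, 0);
  for (int s = 0; s < B; ++s) {
    mat A = angle_affinity(mats.slice(s), keep);
    vec lam_nt;
    mat comps;
    embed_affinity(A, alpha, lam_nt, comps);
    vec ev = arma::square(lam_nt) / arma::accu(arma::square(lam_nt));
    int nc = std::min((int)comps.n_cols, n_components);
    mat sub = comps.cols(0, nc - 1);
    mat R = arma::abs(arma::cor(refz, sub));  // K x nc
    for (int k = 0; k < K; ++k) {
      uword j = R.row(k).index_max();
      ev_out(s, k) = ev(j);
      cor_out(s, k) = R(k, j);
    }
  }
  return Rcpp::List::create(Rcpp::Named("ev") = ev_out,
                            Rcpp::Named("cor") = cor_out);
}

// Element-wise mean of cube slices within bins (1-based labels, NA = skip).
// [[Rcpp::export]]
arma::cube bin_mean_slices(const arma::cube& Rt,
                           const arma::ivec& assignment, int n_bins) {
  const int N = Rt.n_rows;
  cube out(N, N, n_bins, fill::zeros);
  vec counts(n_bins, fill::zeros);
  for (uword t = 0; t < Rt.n_slices; ++t) {
    int b = assignment(t);
    if (b == NA_INTEGER || b < 1 || b > n_bins) continue;
    out.slice(b - 1) += Rt.slice(t);
    counts(b - 1) += 1.0;
  }
  for (int b = 0; b < n_bins; ++b) {
    if (counts(b) == 0) Rcpp::stop("empty arousal bin %d", b + 1);
    out.slice(b) /= counts(b);
  }
  return out;
}
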