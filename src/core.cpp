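// Core MAP objective and gradient for the clone-assignment model.
//
// The objective marginalizes the per-cell clone assignment z_n exactly
// (log-sum-exp over clones); the per-gene dosage indicator k_g and per-SNP
// allele indicator a_s enter through their Bernoulli means p_k, p_a
// (delta-method treatment: the expectation is taken inside the
// multinomial/binomial mean). Continuous parameters are optimized in
// unconstrained space with change-of-variables Jacobians included, so the
// optimum is the MAP of the transformed model.
//
// Parameter packing (all blocks optional by dimension):
//   m0 (G), m1 (G), kappa (G, absent when k is fixed at 1), rho (C),
//   psi (N*D), w (G*D), cchi (D), xa (S)

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

static const double PROB_FLOOR = 1e-12;
static const double BAF_FLOOR = 1e-6;

static inline vec softplus_v(const vec& x) {
  return log1p(exp(-abs(x))) + arma::max(x, zeros<vec>(x.n_elem));
}
static inline vec sigmoid_v(const vec& x) { return 1.0 / (1.0 + exp(-x)); }

// [[Rcpp::export]]
Rcpp::List core_obj_grad(const arma::vec& par,
                         const arma::mat& X,       // N x G raw counts
                         const arma::vec& l,       // N cell totals
                         const arma::mat& lambda,  // G x C clone CN
                         const arma::mat& Rr,      // N x S ref counts
                         const arma::mat& Tt,      // N x S total counts
                         const arma::mat& B,       // S x C clone BAF
                         const arma::vec& mu_prime,
                         const double mu_sd,
                         const int D,
                         const bool fix_k,
                         const bool want_grad,
                         const bool want_q) {
  const uword N = std::max(X.n_rows, Rr.n_rows);
  const uword G = X.n_cols;
  const uword C = lambda.n_cols > 0 ? lambda.n_cols : B.n_cols;
  const uword S = B.n_rows;
  const uword Gk = fix_k ? 0 : G;
  const bool use_expr = G > 0;

  // ---- unpack ----
  uword o = 0;
  vec m0, m1, kappa;
  if (use_expr) {
    m0 = par.subvec(o, o + G - 1); o += G;
    m1 = par.subvec(o, o + G - 1); o += G;
    if (!fix_k) { kappa = par.subvec(o, o + G - 1); o += G; }
  }
  vec rho = par.subvec(o, o + C - 1); o += C;
  mat Psi, W;
  vec cchi;
  if (use_expr && D > 0) {
    Psi = reshape(par.subvec(o, o + N * D - 1), N, D); o += N * D;
    W = reshape(par.subvec(o, o + G * D - 1), G, D); o += G * D;
    cchi = par.subvec(o, o + D - 1); o += D;
  }
  vec xa;
  if (S > 0) { xa = par.subvec(o, o + S - 1); o += S; }

  // ---- transforms ----
  vec mu0, mu1, s0, s1, p;
  if (use_expr) {
    mu0 = softplus_v(m0); mu1 = softplus_v(m1);
    s0 = sigmoid_v(m0); s1 = sigmoid_v(m1);
    p = fix_k ? vec(G, fill::ones) : sigmoid_v(kappa);
  }
  vec pi = exp(rho - rho.max());
  pi /= accu(pi);
  vec chi;
  if (use_expr && D > 0) chi = exp(cchi);
  vec pa;
  if (S > 0) pa = sigmoid_v(xa);

  // ---- forward pass ----
  mat A(N, C, fill::zeros);
  mat E, alpha, Smat, f, logf, log1mf;
  vec xe;
  if (use_expr) {
    alpha.set_size(G, C);
    for (uword c = 0; c < C; ++c) {
      alpha.col(c) = p % mu0 % lambda.col(c) + (1.0 - p) % mu1;
    }
    alpha = arma::max(alpha, PROB_FLOOR * ones<mat>(G, C));
    if (D > 0) {
      mat Eta = Psi * W.t();
      xe = sum(X % Eta, 1);
      E = exp(Eta);
    } else {
      E = ones<mat>(N, G);
      xe = zeros<vec>(N);
    }
    Smat = E * alpha;                 // N x C
    mat Xlog = X * log(alpha);        // N x C
    for (uword c = 0; c < C; ++c) {
      A.col(c) += Xlog.col(c) + xe - l % log(Smat.col(c));
    }
  }
  if (S > 0) {
    f.set_size(S, C);
    for (uword c = 0; c < C; ++c) {
      f.col(c) = pa % B.col(c) + (1.0 - pa) % (1.0 - B.col(c));
    }
    f = clamp(f, BAF_FLOOR, 1.0 - BAF_FLOOR);
    logf = log(f); log1mf = log(1.0 - f);
    A += Rr * logf + (Tt - Rr) * log1mf;
  }
  for (uword c = 0; c < C; ++c) A.col(c) += std::log(pi(c));

  vec amax = arma::max(A, 1);
  vec lse = amax + log(sum(exp(A.each_col() - amax), 1));
  mat q = exp(A.each_col() - lse);
  double obj = accu(lse);

  // ---- priors / Jacobians ----
  const double sd2 = mu_sd * mu_sd;
  if (use_expr) {
    obj += -0.5 * accu(square(m0 - mu_prime)) / sd2
         - 0.5 * accu(square(m1 - mu_prime)) / sd2;
    if (!fix_k) obj += accu(log(p) + log(1.0 - p));
    if (D > 0) {
      obj += -0.5 * accu(square(Psi));
      for (int i = 0; i < D; ++i) {
        obj += 0.5 * G * cchi(i) - 0.5 * chi(i) * accu(square(W.col(i)))
             + 2.0 * cchi(i) - chi(i);
      }
    }
  }
  if (S > 0) obj += accu(log(pa) + log(1.0 - pa));

  Rcpp::List out;
  out["objective"] = obj;
  if (want_q) out["q"] = q;
  if (!want_grad) return out;

  // ---- gradient ----
  vec grad(par.n_elem, fill::zeros);
  o = 0;
  mat V;  // N x C, v_nc = q_nc * l_n / S_nc
  if (use_expr) {
    V.set_size(N, C);
    for (uword c = 0; c < C; ++c) V.col(c) = q.col(c) % l / Smat.col(c);
    mat XtQ = X.t() * q;    // G x C
    mat EtV = E.t() * V;    // G x C
    vec g_m0(G, fill::zeros), g_m1(G, fill::zeros), g_kap(G, fill::zeros);
    for (uword c = 0; c < C; ++c) {
      vec gA = XtQ.col(c) / alpha.col(c) - EtV.col(c);
      g_m0 += gA % (p % lambda.col(c));
      g_m1 += gA % (1.0 - p);
      if (!fix_k) g_kap += gA % (mu0 % lambda.col(c) - mu1);
    }
    g_m0 = g_m0 % s0 - (m0 - mu_prime) / sd2;
    g_m1 = g_m1 % s1 - (m1 - mu_prime) / sd2;
    grad.subvec(o, o + G - 1) = g_m0; o += G;
    grad.subvec(o, o + G - 1) = g_m1; o += G;
    if (!fix_k) {
      g_kap = g_kap % (p % (1.0 - p)) + (1.0 - 2.0 * p);
      grad.subvec(o, o + G - 1) = g_kap; o += G;
    }
  }
  {
    rowvec qs = sum(q, 0);
    vec g_rho = qs.t() - double(N) * pi;
    grad.subvec(o, o + C - 1) = g_rho; o += C;
  }
  if (use_expr && D > 0) {
    mat M = X - E % (V * alpha.t());     // N x G residuals
    mat g_Psi = M * W - Psi;
    mat g_W = M.t() * Psi;
    for (int i = 0; i < D; ++i) g_W.col(i) -= chi(i) * W.col(i);
    grad.subvec(o, o + N * D - 1) = vectorise(g_Psi); o += N * D;
    grad.subvec(o, o + G * D - 1) = vectorise(g_W); o += G * D;
    vec g_cchi(D);
    for (int i = 0; i < D; ++i) {
      g_cchi(i) = 0.5 * G + 2.0 - chi(i) - 0.5 * chi(i) * accu(square(W.col(i)));
    }
    grad.subvec(o, o + D - 1) = g_cchi; o += D;
  }
  if (S > 0) {
    vec g_xa(S, fill::zeros);
    mat RtQ = Rr.t() * q;          // S x C
    mat TtQ = (Tt - Rr).t() * q;   // S x C
    for (uword c = 0; c < C; ++c) {
      vec gF = RtQ.col(c) / f.col(c) - TtQ.col(c) / (1.0 - f.col(c));
      g_xa += gF % (2.0 * B.col(c) - 1.0);
    }
    g_xa = g_xa % (pa % (1.0 - pa)) + (1.0 - 2.0 * pa);
    grad.subvec(o, o + S - 1) = g_xa; o += S;
  }
  out["gradient"] = grad;
  return out;
}
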