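// Per-transcript EM-REML fitting engine.
//
// Fits the reduced model m1 (biological + residual variance) and the full
// model m2 (+ blending variance) for every transcript of an expression
// matrix, via Henderson's mixed model equations with variance ratios
// lambda_j = sigma_e^2 / sigma_j^2.  Random-effect blocks arrive already
// whitened (G = I after eigen-reparameterization on the R side), so the EM
// updates take the textbook form
//   sigma_j^2 <- (u_j'u_j + sigma_e^2 tr(C^jj)) / q_j
//   sigma_e^2 <- e'y / (n - p).
// Convergence: sqrt(|B_{n-1}-B_n|^2 / |B_n|^2) < eps on the vector of
// variance components.
//
// The sigma_2^2 = 0 boundary is decided by the REML score at zero
// (evaluated at the m1 optimum): a non-positive score makes the m1 solution
// the m2 REML solution exactly, avoiding the sublinear EM crawl toward the
// boundary.  Treatment contrasts are tested with Kenward-Roger adjusted
// Wald F statistics using the expected REML information.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

struct EMOut {
  vec sig;        // block variances
  double sige;
  int iters;
  bool converged;
};

static bool safe_inv_sympd(mat& out, const mat& A) {
  if (inv_sympd(out, A)) return true;
  return pinv(out, symmatu(A));
}

// REML log-likelihood, dense evaluation:
// -1/2 [ log|V| + log|X'V^-1 X| + y'Py + (n-p) log 2pi ]
static double reml_ll(const vec& y, const mat& X,
                      const std::vector<const mat*>& A,
                      const vec& sig, double sige) {
  const int n = y.n_elem, p = X.n_cols;
  mat V = sige * eye(n, n);
  for (size_t j = 0; j < A.size(); ++j) V += sig(j) * (*A[j]);
  mat Vinv;
  if (!safe_inv_sympd(Vinv, V)) return NA_REAL;
  mat XtVi = X.t() * Vinv;
  mat XtViX = symmatu(XtVi * X);
  vec XtViy = XtVi * y;
  double ldV, sgn, ldX;
  log_det(ldV, sgn, V);
  log_det(ldX, sgn, XtViX);
  vec b = solve(XtViX, XtViy);
  double yPy = dot(y, Vinv * y) - dot(XtViy, b);
  return -0.5 * (ldV + ldX + yPy + (n - p) * std::log(2.0 * M_PI));
}

static EMOut em_fit(const vec& y, const mat& W, const mat& WtW, int p,
                    const std::vector<uword>& start,
                    const std::vector<uword>& len,
                    double eps, int max_iter, double floorv,
                    double init_sige, const vec& init_sig) {
  const int n = y.n_elem;
  const int K = start.size();
  vec Wty = W.t() * y;
  const double yty = dot(y, y);
  vec sig = init_sig;
  double sige = init_sige;
  EMOut out;
  out.converged = false;
  int it = 0;
  while (it < max_iter) {
    ++it;
    vec Bold(K + 1);
    for (int j = 0; j < K; ++j) Bold(j) = sig(j);
    Bold(K) = sige;
    mat C = WtW;
    for (int j = 0; j < K; ++j)
      C.submat(start[j], start[j], start[j] + len[j] - 1,
               start[j] + len[j] - 1).diag() += sige / sig(j);
    mat Cinv;
    if (!safe_inv_sympd(Cinv, C)) break;
    vec sol = Cinv * Wty;
    double ety = yty - dot(sol, Wty);
    double sige_new = std::max(ety / (n - p), floorv);
    for (int j = 0; j < K; ++j) {
      vec uj = sol.subvec(start[j], start[j] + len[j] - 1);
      double trC = trace(Cinv.submat(start[j], start[j],
                                     start[j] + len[j] - 1,
                                     start[j] + len[j] - 1));
      sig(j) = std::max((dot(uj, uj) + sige * trC) / len[j], floorv);
    }
    sige = sige_new;
    double num = (Bold(K) - sige) * (Bold(K) - sige);
    double den = sige * sige;
    for (int j = 0; j < K; ++j) {
      num += (Bold(j) - sig(j)) * (Bold(j) - sig(j));
      den += sig(j) * sig(j);
    }
    if (std::sqrt(num / den) < eps) { out.converged = true; break; }
  }
  out.sig = sig;
  out.sige = sige;
  out.iters = it;
  return out;
}

struct KROut { double F; double ddf; double p; };

// Kenward-Roger adjusted F test of the (ell x p) contrast L, with the
// variance-parameter covariance taken from the inverse expected REML
// information.  A[] are dV/dtheta for the block variances; the residual
// derivative (identity) is appended internally.
static KROut kr_ftest(const vec& y, const mat& X,
                      const std::vector<const mat*>& A,
                      const vec& sig, double sige, const mat& L) {
  const int n = y.n_elem, p = X.n_cols;
  const int K = A.size() + 1;
  const int ell = L.n_rows;
  KROut out; out.F = NA_REAL; out.ddf = NA_REAL; out.p = NA_REAL;

  mat V = sige * eye(n, n);
  for (size_t j = 0; j < A.size(); ++j) V += sig(j) * (*A[j]);
  mat Vinv;
  if (!safe_inv_sympd(Vinv, V)) return out;
  mat XtVi = X.t() * Vinv;                       // p x n
  mat Phi;
  if (!safe_inv_sympd(Phi, symmatu(XtVi * X))) return out;
  vec beta = Phi * (XtVi * y);
  mat Pm = Vinv - XtVi.t() * Phi * XtVi;         // n x n

  mat Ieye = eye(n, n);
  std::vector<const mat*> D(A);
  D.push_back(&Ieye);

  std::vector<mat> Bp(K), PM(K);                 // Bp_i = X'Vi Mi (p x n)
  for (int i = 0; i < K; ++i) {
    Bp[i] = XtVi * (*D[i]);
    PM[i] = Pm * (*D[i]);
  }
  mat Info(K, K);
  for (int i = 0; i < K; ++i)
    for (int j = i; j < K; ++j)
      Info(i, j) = Info(j, i) = 0.5 * accu(PM[i] % PM[j].t());
  mat Wc;
  if (!safe_inv_sympd(Wc, Info)) return out;

  std::vector<mat> Pi(K), SPhi(K);
  for (int i = 0; i < K; ++i) {
    Pi[i] = -(Bp[i] * XtVi.t());                 // p x p
    Pi[i] = 0.5 * (Pi[i] + Pi[i].t());
  }
  mat Lam(p, p, fill::zeros);
  for (int i = 0; i < K; ++i)
    for (int j = 0; j < K; ++j) {
      mat Qij = Bp[i] * Vinv * Bp[j].t();
      Lam += Wc(i, j) * (Qij - Pi[i] * Phi * Pi[j]);
    }
  mat PhiA = Phi + 2.0 * Phi * Lam * Phi;
  PhiA = symmatu(PhiA);

  vec Lb = L * beta;
  mat LPhiAL;
  if (!safe_inv_sympd(LPhiAL, symmatu(L * PhiA * L.t()))) return out;
  double F = as_scalar(Lb.t() * LPhiAL * Lb) / ell;

  mat LPhiL;
  if (!safe_inv_sympd(LPhiL, symmatu(L * Phi * L.t()))) return out;
  mat Theta = L.t() * LPhiL * L;                 // p x p
  std::vector<mat> Si(K);
  for (int i = 0; i < K; ++i) Si[i] = Phi * Pi[i] * Phi;
  double A1 = 0.0, A2 = 0.0;
  for (int i = 0; i < K; ++i)
    for (int j = 0; j < K; ++j) {
      double ti = trace(Theta * Si[i]);
      double tj = trace(Theta * Si[j]);
      A1 += Wc(i, j) * ti * tj;
      A2 += Wc(i, j) * trace(Theta * Si[i] * Theta * Si[j]);
    }
  double g = ((ell + 1.0) * A1 - (ell + 4.0) * A2) / ((ell + 2.0) * A2);
  double denom = 3.0 * ell + 2.0 * (1.0 - g);
  double c1 = g / denom, c2 = (ell - g) / denom, c3 = (ell + 2.0 - g) / denom;
  double Bq = (A1 + 6.0 * A2) / (2.0 * ell);
  double Estar = 1.0 / (1.0 - A2 / ell);
  double Vstar = (2.0 / ell) * (1.0 + c1 * Bq) /
                 ((1.0 - c2 * Bq) * (1.0 - c2 * Bq) * (1.0 - c3 * Bq));
  double rho = Vstar / (2.0 * Estar * Estar);
  double m;
  if (ell * rho - 1.0 > 1e-10)
    m = 4.0 + (ell + 2.0) / (ell * rho - 1.0);
  else
    m = 1e7;
  double lam;
  if (Estar > 0 && m > 2.0)
    lam = m / (Estar * (m - 2.0));
  else { lam = 1.0; m = n - p; }
  out.F = lam * F;
  out.ddf = m;
  out.p = R::pf(out.F, ell, m, 0, 0);
  return out;
}

// REML score dl/dsigma2^2 evaluated at sigma2^2 = 0 with the remaining
// components at their m1 optimum.
static double score_at_zero(const vec& y, const mat& Pm, const mat& A2) {
  vec Py = Pm * y;
  return -0.5 * (accu(Pm % A2) - as_scalar(Py.t() * A2 * Py));
}

// [[Rcpp::export]]
arma::mat cpp_fit_transcripts(const arma::mat& Y, const arma::mat& X,
                              const arma::mat& Z1, const arma::mat& Z2,
                              const arma::mat& L, double eps, int max_iter,
                              double floor_rel, bool do_kr) {
  const int m = Y.n_rows, n = Y.n_cols, p = X.n_cols;
  const int q1 = Z1.n_cols, q2 = Z2.n_cols;

  mat A1, A2;
  if (q1 > 0) A1 = Z1 * Z1.t();
  if (q2 > 0) A2 = Z2 * Z2.t();

  // m1 system: [X Z1]; m2 system: [X Z1 Z2]
  mat W1 = (q1 > 0) ? join_rows(X, Z1) : X;
  mat W2 = (q2 > 0) ? join_rows(W1, Z2) : W1;
  mat W1tW1 = symmatu(W1.t() * W1);
  mat W2tW2 = symmatu(W2.t() * W2);
  std::vector<uword> st1, ln1, st2, ln2;
  if (q1 > 0) { st1.push_back(p); ln1.push_back(q1); }
  st2 = st1; ln2 = ln1;
  if (q2 > 0) { st2.push_back(p + q1); ln2.push_back(q2); }

  mat XtX = symmatu(X.t() * X);
  mat XtXinv; safe_inv_sympd(XtXinv, XtX);

  const int NC = 19;
  mat res(m, NC);
  res.fill(NA_REAL);

  for (int g = 0; g < m; ++g) {
    vec y = Y.row(g).t();
    vec beta0 = XtXinv * (X.t() * y);
    vec r = y - X * beta0;
    double v0 = dot(r, r) / (n - p);
    if (v0 <= 0) continue;  // constant y: degenerate, left NA
    double floorv = floor_rel * var(y);
    if (floorv <= 0) continue;

    // ---- m1 ----
    vec sig1v; double sige1; double ll1; int it1; bool cv1;
    std::vector<const mat*> Am1;
    if (q1 > 0) Am1.push_back(&A1);
    if (q1 > 0) {
      EMOut f1 = em_fit(y, W1, W1tW1, p, st1, ln1, eps, max_iter, floorv,
                        v0, vec{v0 / 2.0});
      sig1v = f1.sig; sige1 = f1.sige; it1 = f1.iters; cv1 = f1.converged;
    } else {
      sig1v = vec(); sige1 = v0; it1 = 0; cv1 = true;
    }
    ll1 = reml_ll(y, X, Am1, sig1v, sige1);
    res(g, 0) = (q1 > 0) ? sig1v(0) : NA_REAL;
    res(g, 1) = sige1;
    res(g, 2) = ll1;
    res(g, 3) = it1;
    res(g, 4) = cv1 ? 1 : 0;
    if (do_kr) {
      KROut k1 = kr_ftest(y, X, Am1, sig1v, sige1, L);
      res(g, 5) = k1.F; res(g, 6) = k1.ddf; res(g, 7) = k1.p;
    }

    // ---- m2 ----
    if (q2 == 0) continue;
    // score for sigma2^2 at zero, at the m1 optimum
    mat V1 = sige1 * eye(n, n);
    if (q1 > 0) V1 += sig1v(0) * A1;
    mat V1inv; safe_inv_sympd(V1inv, V1);
    mat XtVi1 = X.t() * V1inv;
    mat Phi1; safe_inv_sympd(Phi1, symmatu(XtVi1 * X));
    mat Pm1 = V1inv - XtVi1.t() * Phi1 * XtVi1;
    double sc0 = score_at_zero(y, Pm1, A2);
    res(g, 18) = sc0;

    bool boundary = (sc0 <= 0);
    if (!boundary) {
      vec init2 = (q1 > 0) ? vec{v0 / 2.0, v0 / 2.0} : vec{v0 / 2.0};
      EMOut f2 = em_fit(y, W2, W2tW2, p, st2, ln2, eps, max_iter, floorv,
                        v0, init2);
      int i2 = (q1 > 0) ? 1 : 0;
      if (f2.sig(i2) <= 1.5 * floorv) {
        boundary = true;
      } else {
        std::vector<const mat*> Am2;
        if (q1 > 0) Am2.push_back(&A1);
        Am2.push_back(&A2);
        double ll2 = reml_ll(y, X, Am2, f2.sig, f2.sige);
        res(g, 8) = (q1 > 0) ? f2.sig(0) : NA_REAL;
        res(g, 9) = f2.sig(i2);
        res(g, 10) = f2.sige;
        res(g, 11) = ll2;
        res(g, 12) = f2.iters;
        res(g, 13) = f2.converged ? 1 : 0;
        res(g, 14) = 0;
        if (do_kr) {
          KROut k2 = kr_ftest(y, X, Am2, f2.sig, f2.sige, L);
          res(g, 15) = k2.F; res(g, 16) = k2.ddf; res(g, 17) = k2.p;
        }
      }
    }
    if (boundary) {
      // m2 REML solution sits on the boundary: identical to m1
      res(g, 8) = res(g, 0);
      res(g, 9) = 0.0;
      res(g, 10) = sige1;
      res(g, 11) = ll1;
      res(g, 12) = 0;
      res(g, 13) = 1;
      res(g, 14) = 1;
      res(g, 15) = res(g, 5);
      res(g, 16) = res(g, 6);
      res(g, 17) = res(g, 7);
    }
  }
  return res;
}

// Single-model EM fit on whitened blocks; returns estimates, loglik and the
// per-iteration loglik trace (used by the R-level em_reml_fit wrapper and
// the monotonicity tests).
// [[Rcpp::export]]
Rcpp::List cpp_em_single(const arma::vec& y, const arma::mat& X,
                         const Rcpp::List& Zblocks, double eps, int max_iter,
                         double floor_rel, const arma::vec& init_sig,
                         double init_sige, bool trace_ll) {
  const int n = y.n_elem, p = X.n_cols;
  const int K = Zblocks.size();
  mat W = X;
  std::vector<uword> st, ln;
  std::vector<mat> Zs(K);
  std::vector<mat> Amats(K);
  std::vector<const mat*> Aptr;
  for (int j = 0; j < K; ++j) {
    Zs[j] = Rcpp::as<mat>(Zblocks[j]);
    st.push_back(W.n_cols); ln.push_back(Zs[j].n_cols);
    W = join_rows(W, Zs[j]);
    Amats[j] = Zs[j] * Zs[j].t();
  }
  for (int j = 0; j < K; ++j) Aptr.push_back(&Amats[j]);
  mat WtW = symmatu(W.t() * W);
  double floorv = floor_rel * var(y);

  // iterate manually so we can record the loglik path
  vec sig = init_sig;
  double sige = init_sige;
  bool converged = false;
  int it = 0;
  double crit = NA_REAL;
  std::vector<double> llpath;
  vec Wty = W.t() * y;
  double yty = dot(y, y);
  while (it < max_iter && K > 0) {
    ++it;
    vec Bold(K + 1);
    for (int j = 0; j < K; ++j) Bold(j) = sig(j);
    Bold(K) = sige;
    mat C = WtW;
    for (int j = 0; j < K; ++j)
      C.submat(st[j], st[j], st[j] + ln[j] - 1, st[j] + ln[j] - 1).diag()
        += sige / sig(j);
    mat Cinv;
    if (!safe_inv_sympd(Cinv, C)) break;
    vec sol = Cinv * Wty;
    double ety = yty - dot(sol, Wty);
    double sige_new = std::max(ety / (n - p), floorv);
    for (int j = 0; j < K; ++j) {
      vec uj = sol.subvec(st[j], st[j] + ln[j] - 1);
      double trC = trace(Cinv.submat(st[j], st[j], st[j] + ln[j] - 1,
                                     st[j] + ln[j] - 1));
      sig(j) = std::max((dot(uj, uj) + sige * trC) / ln[j], floorv);
    }
    sige = sige_new;
    if (trace_ll) llpath.push_back(reml_ll(y, X, Aptr, sig, sige));
    double num = (Bold(K) - sige) * (Bold(K) - sige);
    double den = sige * sige;
    for (int j = 0; j < K; ++j) {
      num += (Bold(j) - sig(j)) * (Bold(j) - sig(j));
      den += sig(j) * sig(j);
    }
    crit = std::sqrt(num / den);
    if (crit < eps) { converged = true; break; }
  }
  if (K == 0) { sige = yty > 0 ? dot(y - X * solve(WtW, Wty), y) / (n - p) : 0;
                converged = true; }
  double ll = reml_ll(y, X, Aptr, sig, sige);
  return Rcpp::List::create(
    Rcpp::Named("sig") = sig, Rcpp::Named("sige") = sige,
    Rcpp::Named("loglik") = ll, Rcpp::Named("iterations") = it,
    Rcpp::Named("converged") = converged,
    Rcpp::Named("criterion") = crit,
    Rcpp::Named("loglik_trace") = llpath);
}
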