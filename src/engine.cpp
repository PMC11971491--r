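// Fitting engine hot paths: time-domain basis modification and the
// partially constrained penalized NNLS. Fourier transforms are done in R
// (stats::mvfft), whose tuned mixed-radix FFT outperforms the fallback
// available here.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// per-signal time-domain modification: fid * env * exp((2i pi f - pi d) t)
// [[Rcpp::export]]
arma::cx_mat eng_modify(const arma::cx_mat& fids, const arma::vec& tvec,
                        const arma::cx_vec& env, const arma::vec& f,
                        const arma::vec& d) {
  const uword n = fids.n_rows, nb = fids.n_cols;
  cx_mat out(n, nb);
  const double twopi = 2.0 * M_PI;
  for (uword i = 0; i < nb; ++i) {
    for (uword k = 0; k < n; ++k) {
      double damp = std::exp(-M_PI * d[i] * tvec[k]);
      out(k, i) = fids(k, i) * env[k] * std::polar(damp, twopi * f[i] * tvec[k]);
    }
  }
  return out;
}

// Penalized least squares with non-negativity on the first ncon columns
// (Lawson-Hanson active set restricted to the constrained block; the
// remaining columns are always free and carry the penalty matrix P).
// [[Rcpp::export]]
arma::vec eng_pnnls(const arma::mat& A, const arma::vec& y, int ncon,
                    const arma::mat& P) {
  const uword ntot = A.n_cols;
  const uword nfree = ntot - (uword)ncon;
  mat G = A.t() * A;
  if (nfree > 0)
    G.submat(ncon, ncon, ntot - 1, ntot - 1) += P;
  vec b = A.t() * y;

  std::vector<bool> passive(ntot, false);
  for (uword j = (uword)ncon; j < ntot; ++j) passive[j] = true;
  vec x(ntot, fill::zeros);

  auto solve_passive = [&](uvec& Pidx) -> vec {
    vec z;
    mat Gs = G.submat(Pidx, Pidx);
    bool ok = solve(z, Gs, b.elem(Pidx), solve_opts::no_approx);
    if (!ok) {
      // degenerate subproblem: fall back to a tiny ridge
      Gs.diag() += 1e-10 * trace(Gs) / Gs.n_rows;
      z = solve(Gs, b.elem(Pidx));
    }
    return z;
  };

  auto passive_idx = [&]() {
    std::vector<uword> v;
    for (uword j = 0; j < ntot; ++j) if (passive[j]) v.push_back(j);
    return uvec(v);
  };

  // initial solve over the free block
  if (nfree > 0) {
    uvec Pidx = passive_idx();
    vec z = solve_passive(Pidx);
    x.elem(Pidx) = z;
  }

  const double tol = 1e-10 * std::max(1.0, norm(b, "inf"));
  int outer_guard = 30 * (int)ntot;
  while (outer_guard-- > 0) {
    vec w = b - G * x;
    int jbest = -1; double wbest = tol;
    for (uword j = 0; j < (uword)ncon; ++j)
      if (!passive[j] && w[j] > wbest) { wbest = w[j]; jbest = (int)j; }
    if (jbest < 0) break;
    passive[jbest] = true;
    int inner_guard = 10 * (int)ntot;
    while (inner_guard-- > 0) {
      uvec Pidx = passive_idx();
      vec z = solve_passive(Pidx);
      // feasibility check on the constrained part of the passive set
      double alpha = 1.0; int drop = -1;
      for (uword k = 0; k < Pidx.n_elem; ++k) {
        uword j = Pidx[k];
        if (j < (uword)ncon && z[k] <= 0) {
          double denom = x[j] - z[k];
          double a = denom > 0 ? x[j] / denom : 0.0;
          if (a < alpha) { alpha = a; drop = (int)j; }
        }
      }
      if (drop < 0) {
        x.zeros();
        x.elem(Pidx) = z;
        break;
      }
      vec xP = x.elem(Pidx);
      xP += alpha * (z - xP);
      x.zeros();
      x.elem(Pidx) = xP;
      for (uword j = 0; j < (uword)ncon; ++j)
        if (passive[j] && x[j] <= 1e-14) { passive[j] = false; x[j] = 0; }
    }
  }
  return x;
}
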