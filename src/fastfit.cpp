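#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Accumulated dynamic-time-warping distance between two multivariate
// series (rows = time index, cols = dimensions), unconstrained window,
// symmetric step pattern D(i,j) = c(i,j) + min(D(i-1,j), D(i,j-1), D(i-1,j-1)).
// Local cost is the Euclidean norm across dimensions.
// [[Rcpp::export]]
double dtw_dist_cpp(const arma::mat& a, const arma::mat& b) {
  const uword n = a.n_rows, m = b.n_rows;
  vec prev(m), cur(m);
  for (uword i = 0; i < n; ++i) {
    for (uword j = 0; j < m; ++j) {
      double c = norm(a.row(i) - b.row(j), 2);
      double best;
      if (i == 0 && j == 0)      best = 0.0;
      else if (i == 0)           best = cur(j - 1);
      else if (j == 0)           best = prev(j);
      else                       best = std::min(prev(j),
                                    std::min(cur(j - 1), prev(j - 1)));
      cur(j) = c + best;
    }
    prev = cur;
  }
  return prev(m - 1);
}

// Helper: assemble A = XtX + sum_j lambda_j S_j (S_j embedded in its block).
static mat build_A(const mat& XtX, const std::vector<mat>& S,
                   const uvec& bstart, const vec& lambda) {
  mat A = XtX;
  for (size_t j = 0; j < S.size(); ++j) {
    const uword s = bstart(j), k = S[j].n_rows;
    A.submat(s, s, s + k - 1, s + k - 1) += lambda(j) * S[j];
  }
  return A;
}

// Penalized least-squares additive model with one smoothing parameter per
// term, selected by profiled REML (or GCV) on a log-spaced lambda grid via
// coordinate descent.  Column 0 of X is the unpenalized intercept; term j
// occupies columns bstart[j] .. bstart[j]+k_j-1.  Each S_j must be strictly
// positive definite (difference penalty plus null-space shrinkage ridge), so
// that lambda -> Inf removes the whole term.
//
// Per-term update uses the rank-k Woodbury identity around the current A0:
// A(lam) = A0 + delta * U U' with S_j = U_j U_j' (Cholesky), delta = lam -
// lam_cur, which makes every grid evaluation O(q k) after one q x q Cholesky.
// [[Rcpp::export]]
Rcpp::List penreg_fit_cpp(const arma::mat& X, const arma::vec& y,
                          const arma::uvec& bstart, const arma::uvec& bsize,
                          const Rcpp::List& Slist, const arma::vec& lam_grid,
                          const int sweeps, const std::string criterion) {
  const uword n = X.n_rows, q = X.n_cols, nt = bsize.n_elem;
  const mat XtX = X.t() * X;
  const vec b = X.t() * y;
  const double yty = dot(y, y);

  std::vector<mat> S(nt), Lc(nt);
  vec logdetS(nt), kk(nt);
  for (uword j = 0; j < nt; ++j) {
    S[j] = Rcpp::as<mat>(Slist[j]);
    Lc[j] = chol(S[j], "lower");
    logdetS(j) = 2.0 * sum(log(Lc[j].diag()));
    kk(j) = (double)bsize(j);
  }

  const double Mp = (double)(q - sum(bsize));  // unpenalized dimensions
  vec lambda(nt, fill::ones);
  const uword G = lam_grid.n_elem;

  auto penalty_of = [&](const vec& beta, const vec& lam) {
    double pen = 0.0;
    for (uword l = 0; l < nt; ++l) {
      const uword s = bstart(l), k = bsize(l);
      const vec bl = beta.subvec(s, s + k - 1);
      pen += lam(l) * as_scalar(bl.t() * S[l] * bl);
    }
    return pen;
  };

  for (int sw = 0; sw < sweeps; ++sw) {
    for (uword j = 0; j < nt; ++j) {
      const mat A0 = build_A(XtX, S, bstart, lambda);
      mat L0;
      if (!chol(L0, A0, "lower")) Rcpp::stop("penalized normal equations not positive definite");
      const double logdetA0 = 2.0 * sum(log(L0.diag()));
      const vec v = solve(trimatu(L0.t()), solve(trimatl(L0), b));

      const uword s = bstart(j), k = bsize(j);
      mat U(q, k, fill::zeros);
      U.submat(s, 0, s + k - 1, k - 1) = Lc[j];
      const mat W0 = solve(trimatu(L0.t()), solve(trimatl(L0), U));
      const mat M = U.t() * W0;
      vec mu; mat Q;
      eig_sym(mu, Q, symmatu(M));
      const mat Wt = W0 * Q;                  // q x k
      const vec wb = Q.t() * (U.t() * v);     // k

      // GCV bookkeeping (trace terms), only when requested
      double trP0 = 0.0; vec Gdiag;
      if (criterion == "GCV") {
        const mat P0 = solve(trimatu(L0.t()), solve(trimatl(L0), XtX));
        trP0 = trace(P0);
        const mat WX = Wt.t() * XtX * Wt;     // k x k
        Gdiag = WX.diag();
      }

      double best_score = datum::inf;
      double best_lam = lambda(j);
      vec lam_try = lambda;
      for (uword g = 0; g < G; ++g) {
        const double lam = lam_grid(g);
        const double delta = lam - lambda(j);
        vec beta; double logdetA;
        vec denom;
        bool at_base = std::abs(delta) < 1e-14;
        if (at_base) {
          beta = v;
          logdetA = logdetA0;
        } else {
          const vec one_p = 1.0 + delta * mu;
          if (one_p.min() <= 0.0) continue;   // numerically inadmissible
          logdetA = logdetA0 + sum(log(one_p));
          denom = 1.0 / delta + mu;
          beta = v - Wt * (wb / denom);
        }
        lam_try(j) = lam;
        const double pen = penalty_of(beta, lam_try);
        double rss = yty - dot(beta, b) - pen;
        if (rss < 1e-300) rss = 1e-300;

        double score;
        if (criterion == "GCV") {
          double edf = trP0;
          if (!at_base) edf -= sum(Gdiag / denom);
          const double dn = n - edf;
          score = (dn > 0.5) ? n * rss / (dn * dn) : datum::inf;
        } else {  // REML (profiled Gaussian restricted likelihood, constants dropped)
          double ldS = 0.0;
          for (uword l = 0; l < nt; ++l)
            ldS += kk(l) * std::log(lam_try(l)) + logdetS(l);
          score = (n - Mp) * std::log(rss + pen) + logdetA - ldS;
        }
        if (score < best_score - 1e-12) {
          best_score = score;
          best_lam = lam;
        }
      }
      lambda(j) = best_lam;
    }
  }

  // final fit at selected lambdas
  const mat A = build_A(XtX, S, bstart, lambda);
  mat L;
  if (!chol(L, A, "lower")) Rcpp::stop("penalized normal equations not positive definite");
  const vec beta = solve(trimatu(L.t()), solve(trimatl(L), b));
  const mat Ainv = inv_sympd(symmatu(A));
  const mat F = Ainv * XtX;          // influence: edf_j = tr(F) over block j
  vec edf(nt);
  for (uword j = 0; j < nt; ++j) {
    const uword s = bstart(j), k = bsize(j);
    edf(j) = trace(F.submat(s, s, s + k - 1, s + k - 1));
  }
  const vec resid = y - X * beta;
  const double rss = dot(resid, resid);
  const double edf_total = trace(F);

  return Rcpp::List::create(
    Rcpp::Named("beta") = beta,
    Rcpp::Named("lambda") = lambda,
    Rcpp::Named("edf") = edf,
    Rcpp::Named("edf_total") = edf_total,
    Rcpp::Named("rss") = rss,
    Rcpp::Named("Ainv") = Ainv);
}
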