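#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Draw an n x length(mafs) matrix of additive genotype codes under HWE,
// one independent Binomial(2, maf) column per SNP. Uses R's RNG stream so
// results are reproducible under set.seed() on the R side.
// [[Rcpp::export]]
IntegerMatrix cpp_hwe_genotypes(int n, NumericVector mafs) {
  int m = mafs.size();
  IntegerMatrix G(n, m);
  for (int j = 0; j < m; ++j) {
    double p = mafs[j], q = 1.0 - p;
    double c0 = q * q, c1 = c0 + 2.0 * p * q;
    for (int i = 0; i < n; ++i) {
      double u = unif_rand();
      G(i, j) = (u < c0) ? 0 : ((u < c1) ? 1 : 2);
    }
  }
  return G;
}

// n x m matrix of iid Bernoulli(p) draws (one haplotype layer of alleles).
// [[Rcpp::export]]
IntegerMatrix cpp_bernoulli_matrix(int n, int m, double p) {
  IntegerMatrix L(n, m);
  for (int j = 0; j < m; ++j)
    for (int i = 0; i < n; ++i)
      L(i, j) = (unif_rand() < p) ? 1 : 0;
  return L;
}

// Disease status by one Bernoulli draw per causal SNP per individual, OR-ed.
// probs is 3 x n_causal: row g+1 holds P(D_U | G = g) for that SNP.
// Draw order is individual-major, causal-SNP-minor; every draw is consumed
// so the stream position is independent of the outcomes.
// [[Rcpp::export]]
IntegerVector cpp_disease_status(IntegerMatrix G, NumericMatrix probs) {
  int n = G.nrow(), m = G.ncol();
  if (probs.nrow() != 3 || probs.ncol() != m)
    stop("probs must be a 3 x ncol(G) matrix");
  // transpose G once so the individual-major scan is cache friendly
  std::vector<int> Gt((size_t)n * m);
  for (int j = 0; j < m; ++j)
    for (int i = 0; i < n; ++i)
      Gt[(size_t)i * m + j] = G(i, j);
  IntegerVector D(n);
  for (int i = 0; i < n; ++i) {
    int d = 0;
    const int* gi = &Gt[(size_t)i * m];
    for (int j = 0; j < m; ++j) {
      if (unif_rand() < probs(gi[j], j)) d = 1;
    }
    D[i] = d;
  }
  return D;
}

// Logistic-regression deviance by IRLS for the likelihood-ratio set test.
// X must already contain an intercept column. Returns ok = false when the
// weighted normal equations are singular (e.g. aliased columns); the caller
// then falls back to stats::glm.fit, which handles aliasing by pivoting.
// [[Rcpp::export]]
List cpp_logistic_deviance(const arma::mat& X, const arma::vec& y,
                           int maxit = 30, double tol = 1e-9) {
  const arma::uword n = X.n_rows, p = X.n_cols;
  arma::vec beta(p, arma::fill::zeros);
  double ybar = arma::mean(y);
  beta[0] = std::log(ybar / (1.0 - ybar));
  arma::vec eta = X * beta;
  double dev = arma::datum::inf;
  bool converged = false, ok = true;
  for (int it = 0; it < maxit; ++it) {
    arma::vec mu = 1.0 / (1.0 + arma::exp(-eta));
    mu = arma::clamp(mu, 1e-10, 1.0 - 1e-10);
    arma::vec w = mu % (1.0 - mu);
    arma::vec z = eta + (y - mu) / w;
    arma::mat Xw = X.each_col() % w;
    arma::mat A = X.t() * Xw;
    arma::vec b = X.t() * (w % z);
    arma::vec newbeta;
    bool solved = arma::solve(newbeta, A, b,
                              arma::solve_opts::likely_sympd +
                              arma::solve_opts::no_approx);
    if (!solved) { ok = false; break; }
    beta = newbeta;
    eta = X * beta;
    arma::vec mu2 = arma::clamp(1.0 / (1.0 + arma::exp(-eta)),
                                1e-12, 1.0 - 1e-12);
    double newdev = 0.0;
    for (arma::uword i = 0; i < n; ++i)
      newdev += (y[i] > 0.5) ? -2.0 * std::log(mu2[i])
                             : -2.0 * std::log(1.0 - mu2[i]);
    if (std::abs(newdev - dev) / (0.1 + std::abs(newdev)) < tol) {
      dev = newdev;
      converged = true;
      break;
    }
    dev = newdev;
  }
  return List::create(_["deviance"] = dev,
                      _["converged"] = converged,
                      _["ok"] = ok);
}
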