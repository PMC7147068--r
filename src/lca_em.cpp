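#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// One full EM run for the binary latent class model.
// Y: N x J in {0,1}; pi0: K; rho0: K x J. Returns final parameters,
// posterior, the log-likelihood trace and convergence information.
// rho is clamped to [eps, 1-eps] after every M-step; a class whose
// posterior mass collapses to zero is re-seeded from Uniform(0.05, 0.95)
// using R's RNG stream so runs stay reproducible under set.seed().
// [[Rcpp::export(name = ".em_run_cpp")]]
List em_run_cpp(const arma::mat& Y, arma::vec pi, arma::mat rho,
                double tol, int max_iter, double eps) {
  const arma::uword N = Y.n_rows, J = Y.n_cols, K = pi.n_elem;
  arma::mat Yc = 1.0 - Y;
  arma::mat post(N, K, arma::fill::zeros);
  std::vector<double> trace;
  trace.reserve(64);
  double ll = -arma::datum::inf;
  bool converged = false;
  bool reseeded = false;
  int it = 0;

  for (it = 1; it <= max_iter; ++it) {
    // E-step in log space
    arma::mat lrho = arma::log(arma::clamp(rho, eps, 1.0 - eps));
    arma::mat lrhoc = arma::log(arma::clamp(1.0 - rho, eps, 1.0 - eps));
    arma::mat lf = Y * lrho.t() + Yc * lrhoc.t();   // N x K
    lf.each_row() += arma::log(pi).t();
    arma::vec m = arma::max(lf, 1);
    arma::mat w = arma::exp(lf.each_col() - m);
    arma::vec s = arma::sum(w, 1);
    double ll_new = arma::accu(m + arma::log(s));
    post = w.each_col() / s;
    trace.push_back(ll_new);

    if (it > 1) {
      double slack = 1e-8 * (1.0 + std::abs(ll));
      if (ll_new < ll - slack)
        stop("EM log-likelihood decreased (%.10g -> %.10g) at iteration %d",
             ll, ll_new, it);
      if (std::abs(ll_new - ll) < tol * std::abs(ll)) {
        ll = ll_new;
        converged = true;
        break;
      }
    }
    ll = ll_new;

    // M-step
    arma::rowvec mass = arma::sum(post, 0);   // 1 x K
    for (arma::uword k = 0; k < K; ++k) {
      if (mass(k) <= 0.0) {
        // degenerate class: re-seed its response probabilities
        for (arma::uword j = 0; j < J; ++j)
          rho(k, j) = R::runif(0.05, 0.95);
        reseeded = true;
      } else {
        rho.row(k) = (post.col(k).t() * Y) / mass(k);
      }
    }
    rho = arma::clamp(rho, eps, 1.0 - eps);
    pi = (mass / (double) N).t();
    pi = arma::clamp(pi, 1e-12, 1.0);
    pi /= arma::accu(pi);
  }
  if (it > max_iter) it = max_iter;

  return List::create(
    _["pi"] = pi, _["rho"] = rho, _["posterior"] = post,
    _["loglik"] = ll, _["trace"] = trace, _["converged"] = converged,
    _["n_iterations"] = it, _["reseeded"] = reseeded);
}

// Exhaustive grid maximisation of the two-class LCA log-likelihood over
// pi1 in {step, 2*step, ...} and every rho vector on the same grid,
// independently per class. Used as a brute-force validator for EM on
// tiny instances. pats: distinct response patterns (npat x J, 0/1);
// counts: multiplicity of each pattern. Label symmetry lets pi1 stop
// at 0.5.
// [[Rcpp::export(name = ".grid_loglik_k2_cpp")]]
double grid_loglik_k2_cpp(const IntegerMatrix& pats,
                          const NumericVector& counts, double step) {
  const int npat = pats.nrow(), J = pats.ncol();
  const int nv = (int) std::floor((1.0 - 2.0 * step) / step + 1.5);
  std::vector<double> vals(nv);
  for (int i = 0; i < nv; ++i) vals[i] = step * (i + 1);
  long G = 1;
  for (int j = 0; j < J; ++j) {
    G *= nv;
    if (G > 50000000L) stop("grid too large: reduce J or increase step");
  }
  // per-pattern density for every candidate rho vector
  std::vector<double> F((size_t) npat * G);
  std::vector<int> idx(J, 0);
  for (long g = 0; g < G; ++g) {
    for (int p = 0; p < npat; ++p) {
      double f = 1.0;
      for (int j = 0; j < J; ++j) {
        double r = vals[idx[j]];
        f *= pats(p, j) ? r : (1.0 - r);
      }
      F[(size_t) p + (size_t) npat * g] = f;
    }
    for (int j = 0; j < J; ++j) { if (++idx[j] < nv) break; idx[j] = 0; }
  }
  double best = R_NegInf;
  const int npi = (int) std::floor((0.5 - step) / step + 1.5);
  for (int ip = 0; ip < npi; ++ip) {
    double pi1 = step * (ip + 1);
    for (long c1 = 0; c1 < G; ++c1) {
      const double* f1 = &F[(size_t) npat * c1];
      for (long c2 = 0; c2 < G; ++c2) {
        const double* f2 = &F[(size_t) npat * c2];
        double S = 0.0;
        for (int p = 0; p < npat; ++p)
          S += counts[p] * std::log(pi1 * f1[p] + (1.0 - pi1) * f2[p]);
        if (S > best) best = S;
      }
    }
    checkUserInterrupt();
  }
  return best;
}
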