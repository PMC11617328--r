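// Blocked Gibbs sampler for the multilevel meta-analytic model
//
//   z_i ~ N(x_i' beta + a_{sp(i)} + u_{sp(i)} + s_{st(i)}, v_i)
//   a ~ MVN(0, sigma2_phylo * A),  u ~ N(0, sigma2_species I),
//   s ~ N(0, sigma2_study I),      v_i known (= 1/(n_i - 3)).
//
// beta and all random-effect vectors are drawn jointly from their Gaussian
// full conditional; each variance component gets a half-Cauchy(scale) prior
// via the inverse-gamma scale-mixture parameter expansion:
//   sigma2 | lambda ~ IG(1/2, 1/lambda),  lambda ~ IG(1/2, 1/scale^2)
// giving conjugate IG updates for both. beta has a flat improper prior.
//
// The deviance reported per retained draw is the marginal one -- random
// effects integrated out, so D is a function of (beta, sigma2) only:
//   D = -2 log MVN(z; X beta, Sigma),
//   Sigma = s2p Za A Za' + s2u Zu Zu' + s2s Zs Zs' + diag(v).
// The plug-in deviance D(theta_bar) uses the posterior mean of beta and
// the geometric mean (mean on the log scale) of each variance component.
//
// Uses R's RNG so set.seed() in R makes runs reproducible.

#include <RcppArmadillo.h>
using namespace Rcpp;

static double rinvgamma(double shape, double rate) {
  // X ~ IG(shape, rate)  <=>  1/X ~ Gamma(shape, rate)
  return 1.0 / R::rgamma(shape, 1.0 / rate);
}

// marginal deviance of z ~ MVN(X beta, s2p Ka + s2u Ku + s2s Ks + diag(v))
static double marginal_deviance(const arma::vec& resid_fixed,
                                const arma::vec& v,
                                const std::vector<const arma::mat*>& K,
                                const arma::vec& sigma2) {
  const int n = resid_fixed.n_elem;
  bool any_re = false;
  for (int c = 0; c < 3; ++c) if (K[c]) any_re = true;
  if (!any_re) {
    double dev = n * std::log(2.0 * M_PI) + arma::accu(arma::log(v))
      + arma::accu(arma::square(resid_fixed) / v);
    return dev;
  }
  arma::mat Sigma = arma::diagmat(v);
  for (int c = 0; c < 3; ++c) if (K[c]) Sigma += sigma2(c) * (*K[c]);
  arma::mat L;
  if (!arma::chol(L, Sigma, "lower")) stop("marginal covariance not PD");
  arma::vec sol = arma::solve(arma::trimatl(L), resid_fixed);
  return n * std::log(2.0 * M_PI) + 2.0 * arma::accu(arma::log(L.diag()))
    + arma::dot(sol, sol);
}

// [[Rcpp::export(name = ".gibbs_meta")]]
List gibbs_meta(const arma::vec& z,
                const arma::vec& v,
                const arma::mat& X,
                const arma::imat& blocks,     // per component: [start, size] (0-based), size 0 = absent
                const arma::mat& Aphy,        // relatedness matrix (phylo block), possibly 0x0
                const arma::mat& Ainv,        // its inverse, possibly 0x0
                const arma::mat& W,           // full design [X | Za | Zu | Zs], n x q
                const arma::vec& sigma2_init, // length 3: phylo, species, study
                const arma::ivec& sigma2_fixed, // 1 = hold at init value, no update
                double prior_scale,
                int iterations, int burnin, int thin) {
  const int n = z.n_elem;
  const int q = W.n_cols;
  const int p = X.n_cols;

  arma::vec vinv = 1.0 / v;
  arma::mat WtVinvW = W.t() * (W.each_col() % vinv);
  arma::vec WtVinvz = W.t() * (z % vinv);

  // per-component marginal covariance kernels
  arma::mat Ka, Ku, Ks;
  std::vector<const arma::mat*> K(3, nullptr);
  for (int c = 0; c < 3; ++c) {
    int start = blocks(c, 0), size = blocks(c, 1);
    if (size == 0) continue;
    arma::mat Zc = W.cols(start, start + size - 1);
    if (c == 0) { Ka = Zc * Aphy * Zc.t(); K[0] = &Ka; }
    if (c == 1) { Ku = Zc * Zc.t(); K[1] = &Ku; }
    if (c == 2) { Ks = Zc * Zc.t(); K[2] = &Ks; }
  }

  arma::vec sigma2 = sigma2_init;
  arma::vec lambda(3, arma::fill::ones);

  const int n_keep = (iterations - burnin + thin - 1) / thin;
  arma::mat beta_draws(n_keep, p);
  arma::mat sigma2_draws(n_keep, 3, arma::fill::zeros);
  arma::mat fitted_draws(n_keep, n);
  arma::vec deviance(n_keep);

  RNGScope scope;
  arma::mat Q(q, q), U;
  arma::vec theta(q), eps(q);
  int keep = 0;

  for (int it = 0; it < iterations; ++it) {
    // --- joint Gaussian draw of beta and random effects ---
    Q = WtVinvW;
    for (int c = 0; c < 3; ++c) {
      int start = blocks(c, 0), size = blocks(c, 1);
      if (size == 0) continue;
      if (c == 0) {
        Q.submat(start, start, start + size - 1, start + size - 1) += Ainv / sigma2(0);
      } else {
        for (int j = 0; j < size; ++j) Q(start + j, start + j) += 1.0 / sigma2(c);
      }
    }
    if (!arma::chol(U, Q)) stop("Gibbs update: full-conditional precision not PD");
    for (int j = 0; j < q; ++j) eps(j) = R::norm_rand();
    // theta = Q^{-1} b + U^{-1} eps
    theta = arma::solve(arma::trimatl(U.t()), WtVinvz);
    theta = arma::solve(arma::trimatu(U), theta + eps);

    // --- variance components ---
    for (int c = 0; c < 3; ++c) {
      int start = blocks(c, 0), size = blocks(c, 1);
      if (size == 0 || sigma2_fixed(c)) continue;
      arma::vec b = theta.subvec(start, start + size - 1);
      double ss = (c == 0) ? arma::as_scalar(b.t() * Ainv * b) : arma::dot(b, b);
      sigma2(c) = rinvgamma(0.5 * (size + 1.0), 1.0 / lambda(c) + 0.5 * ss);
      lambda(c) = rinvgamma(1.0, 1.0 / (prior_scale * prior_scale) + 1.0 / sigma2(c));
    }

    if (it >= burnin && (it - burnin) % thin == 0) {
      arma::vec beta_cur = theta.subvec(0, p - 1);
      beta_draws.row(keep) = beta_cur.t();
      sigma2_draws.row(keep) = sigma2.t();
      fitted_draws.row(keep) = (W * theta).t();
      deviance(keep) = marginal_deviance(z - X * beta_cur, v, K, sigma2);
      ++keep;
    }
  }

  // plug-in deviance at posterior mean beta, geometric-mean sigma2
  arma::vec beta_bar = arma::mean(beta_draws, 0).t();
  arma::vec sigma2_bar(3, arma::fill::zeros);
  for (int c = 0; c < 3; ++c) {
    if (blocks(c, 1) > 0) {
      sigma2_bar(c) = std::exp(arma::mean(arma::log(sigma2_draws.col(c))));
    }
  }
  double dhat = marginal_deviance(z - X * beta_bar, v, K, sigma2_bar);

  return List::create(
    Named("beta") = beta_draws,
    Named("sigma2") = sigma2_draws,
    Named("fitted") = fitted_draws,
    Named("deviance") = deviance,
    Named("dhat") = dhat);
}
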