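// Joint negative binomial location-scale likelihood and gradient.
//
// Parametrization: NB2 with overdispersion sigma = 1/theta, so
//   Var(y) = mu + sigma * mu^2
//   log NB(y; mu, sigma) = lgamma(y + 1/sigma) - lgamma(1/sigma) - lgamma(y+1)
//                          + (1/sigma) * log(1/(1 + sigma*mu))
//                          + y * log(sigma*mu / (1 + sigma*mu))
// Both mu and sigma are modeled on a log link:
//   log mu_i    = X_mu_i    . beta_mu + offset_i
//   log sigma_i = X_sigma_i . beta_sigma
//
// For sigma below SIGMA_SMALL the Poisson limit with a first-order
// correction is used: log NB ~ log Pois(y; mu) + (sigma/2) * ((y-mu)^2 - y),
// which keeps the log-likelihood and its gradient in eta_sigma continuous
// as sigma -> 0 (lgamma differences of huge arguments lose precision).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

static const double SIGMA_SMALL = 1e-6;
static const double SIGMA_MAX   = 1e8;

// [[Rcpp::export]]
double nb_loglik_vec(const arma::vec& y, const arma::vec& mu,
                     const arma::vec& sigma) {
  const arma::uword n = y.n_elem;
  double ll = 0.0;
  for (arma::uword i = 0; i < n; ++i) {
    const double yi = y[i], mi = mu[i];
    double si = sigma[i];
    if (si > SIGMA_MAX) si = SIGMA_MAX;
    if (si < SIGMA_SMALL) {
      // Poisson limit + first-order overdispersion correction
      ll += yi * std::log(mi) - mi - std::lgamma(yi + 1.0);
      ll += 0.5 * si * ((yi - mi) * (yi - mi) - yi);
    } else {
      const double r = 1.0 / si;
      ll += std::lgamma(yi + r) - std::lgamma(r) - std::lgamma(yi + 1.0)
          - r * std::log1p(si * mi)
          + yi * (std::log(si * mi) - std::log1p(si * mi));
    }
  }
  return ll;
}

// Negative log-likelihood for the stacked parameter vector
// beta = c(beta_mu, beta_sigma).
// [[Rcpp::export]]
double nb_negll(const arma::vec& beta, const arma::vec& y,
                const arma::mat& Xmu, const arma::mat& Xsigma,
                const arma::vec& offset) {
  const arma::uword pm = Xmu.n_cols;
  const arma::uword ps = Xsigma.n_cols;
  arma::vec eta_mu = Xmu * beta.head(pm) + offset;
  arma::vec eta_s  = Xsigma * beta.tail(ps);
  // guard against overflow during line searches
  eta_mu = arma::clamp(eta_mu, -300.0, 300.0);
  eta_s  = arma::clamp(eta_s, -300.0, 60.0);
  arma::vec mu = arma::exp(eta_mu);
  arma::vec sigma = arma::exp(eta_s);
  double ll = nb_loglik_vec(y, mu, sigma);
  if (!std::isfinite(ll)) ll = -1e300;
  return -ll;
}

// Per-observation first and second derivatives of the log-likelihood with
// respect to the linear predictors eta_mu = log mu and eta_sigma = log sigma.
static void nb_eta_derivs(const arma::vec& y, const arma::vec& eta_mu,
                          const arma::vec& eta_s,
                          arma::vec& dmu, arma::vec& ds,
                          arma::vec& hmu, arma::vec& hs) {
  const arma::uword n = y.n_elem;
  for (arma::uword i = 0; i < n; ++i) {
    const double yi = y[i];
    const double mi = std::exp(eta_mu[i]);
    double si = std::exp(eta_s[i]);
    if (si > SIGMA_MAX) si = SIGMA_MAX;
    if (si < SIGMA_SMALL) {
      dmu[i] = yi - mi - si * mi * (yi - mi);
      hmu[i] = mi;                      // Poisson Fisher information
      ds[i]  = 0.5 * si * ((yi - mi) * (yi - mi) - yi);
      hs[i]  = std::fabs(ds[i]);
    } else {
      const double r = 1.0 / si;
      dmu[i] = yi - mi * (yi + r) / (mi + r);
      // Fisher-type weight for eta_mu: E[-d2] = mu * r / (mu + r)
      hmu[i] = mi * r / (mi + r);
      const double dldr = R::digamma(yi + r) - R::digamma(r)
        + std::log(r) - std::log(r + mi) + 1.0 - (r + yi) / (r + mi);
      const double d2ldr2 = R::trigamma(yi + r) - R::trigamma(r)
        + 1.0 / r - 1.0 / (r + mi) + (yi - mi) / ((r + mi) * (r + mi));
      ds[i] = -r * dldr;
      // d2 ll / d eta_s^2 = r^2 * d2ldr2 + r * dldr; negate for curvature
      double h = -(r * r * d2ldr2 + r * dldr);
      if (!(h > 1e-10)) h = 1e-10;      // keep Newton system PD
      hs[i] = h;
    }
  }
}

// GAMLSS-style alternating maximizer: Fisher-scoring IRLS for beta_mu
// given sigma (cheap: no special functions), damped Newton for beta_sigma
// given mu (one digamma/trigamma pass per outer iteration), repeated until
// the joint gradient is small and the log-likelihood stabilizes.
static bool als_core(const arma::vec& y, const arma::mat& Xmu,
                     const arma::mat& Xsigma, const arma::vec& offset,
                     arma::vec& bmu, arma::vec& bs, const int maxit,
                     const double reltol, const double gradtol,
                     double& ll_out, double& gnorm_out, int& iter_out) {
  const arma::uword n = y.n_elem;
  const double ETA_S_MIN = std::log(1e-8), ETA_S_MAX = std::log(1e6);

  arma::vec dmu(n), ds(n), hmu(n), hs(n), em(n), es(n), sig(n);
  auto predict = [&]() {
    em = arma::clamp(Xmu * bmu + offset, -300.0, 300.0);
    es = arma::clamp(Xsigma * bs, ETA_S_MIN, ETA_S_MAX);
    sig = arma::exp(es);
  };
  auto loglik = [&](const arma::vec& bm, const arma::vec& bsg) {
    arma::vec e1 = arma::clamp(Xmu * bm + offset, -300.0, 300.0);
    arma::vec e2 = arma::clamp(Xsigma * bsg, ETA_S_MIN, ETA_S_MAX);
    double ll = nb_loglik_vec(y, arma::exp(e1), arma::exp(e2));
    return std::isfinite(ll) ? ll : -1e300;
  };
  // mean-model score and Fisher weights; no special functions needed
  auto meanDerivs = [&]() {
    for (arma::uword i = 0; i < n; ++i) {
      const double mi = std::exp(em[i]), si = sig[i];
      const double r = 1.0 / std::max(si, 1e-12);
      dmu[i] = y[i] - mi * (y[i] + r) / (mi + r);
      hmu[i] = mi * r / (mi + r);
    }
  };

  double ll = loglik(bmu, bs);
  (void)reltol;
  int it = 0;
  bool converged = false;
  double gnorm = NA_REAL;
  for (; it < maxit && !converged; ++it) {
    // up to 3 IRLS mean steps given sigma
    for (int j = 0; j < 3; ++j) {
      predict();
      meanDerivs();
      if (arma::abs(Xmu.t() * dmu).max() <=
          0.1 * gradtol * (1.0 + std::fabs(ll))) break;
      arma::mat A = Xmu.t() * (Xmu.each_col() % hmu);
      A.diag() += 1e-10;
      arma::vec step;
      if (!arma::solve(step, A, Xmu.t() * dmu)) break;
      double t = 1.0;
      for (int h = 0; h < 30; ++h, t *= 0.5) {
        double llNew = loglik(bmu + t * step, bs);
        if (llNew >= ll - 1e-12) { bmu += t * step; ll = llNew; break; }
      }
    }
    // one full derivative pass: convergence check + dispersion Newton step
    predict();
    nb_eta_derivs(y, em, es, dmu, ds, hmu, hs);
    const double gmu = arma::abs(Xmu.t() * dmu).max();
    arma::vec gs = Xsigma.t() * ds;
    gnorm = std::max(gmu, arma::abs(gs).max());
    if (gnorm <= gradtol * (1.0 + std::fabs(ll))) { converged = true; break; }
    arma::mat A = Xsigma.t() * (Xsigma.each_col() % hs);
    A.diag() += 1e-10;
    arma::vec step;
    if (arma::solve(step, A, gs)) {
      double t = 1.0;
      for (int h = 0; h < 30; ++h, t *= 0.5) {
        double llNew = loglik(bmu, bs + t * step);
        if (llNew >= ll - 1e-12) { bs += t * step; ll = llNew; break; }
      }
    }
  }
  ll_out = ll; gnorm_out = gnorm; iter_out = it;
  return converged;
}

// R-facing wrapper returning list(beta, loglik, iter, converged, gradnorm).
// [[Rcpp::export]]
Rcpp::List nb_ls_fit(const arma::vec& y, const arma::mat& Xmu,
                     const arma::mat& Xsigma, const arma::vec& offset,
                     const arma::vec& start, const int maxit = 200,
                     const double reltol = 1e-10,
                     const double gradtol = 1e-4) {
  const arma::uword pm = Xmu.n_cols, ps = Xsigma.n_cols;
  arma::vec bmu = start.head(pm), bs = start.tail(ps);
  double ll, gnorm; int it;
  bool conv = als_core(y, Xmu, Xsigma, offset, bmu, bs, maxit, reltol,
                       gradtol, ll, gnorm, it);
  arma::vec beta(pm + ps);
  beta.head(pm) = bmu; beta.tail(ps) = bs;
  return Rcpp::List::create(
    Rcpp::Named("beta") = beta, Rcpp::Named("loglik") = ll,
    Rcpp::Named("iter") = it, Rcpp::Named("converged") = conv,
    Rcpp::Named("gradnorm") = gnorm);
}

// Permutation loop for the sex-dispersion coefficient: shuffles the
// entries of design column `sexCol` (1-based; same column in both design
// matrices), refits from `start`, and records beta_sigma[sexCol] per
// permutation (NaN when that refit did not converge). Uses R's RNG, so
// results are reproducible under set.seed().
// [[Rcpp::export]]
arma::vec nb_perm_beta(const arma::vec& y, const arma::mat& X,
                       const arma::vec& offset, const arma::vec& start,
                       const int sexCol, const int B,
                       const int maxit = 200, const double reltol = 1e-10,
                       const double gradtol = 1e-4) {
  const arma::uword pm = X.n_cols;
  const arma::uword sc = static_cast<arma::uword>(sexCol - 1);
  arma::vec male = X.col(sc);
  arma::mat Xp = X;
  arma::vec out(B);
  const arma::uword n = y.n_elem;
  for (int b = 0; b < B; ++b) {
    // Fisher-Yates with R's RNG (matches sample()'s distribution,
    // though not its exact stream)
    arma::vec perm = male;
    for (arma::uword i = n - 1; i > 0; --i) {
      arma::uword j = static_cast<arma::uword>(
        R::unif_rand() * static_cast<double>(i + 1));
      if (j > i) j = i;
      std::swap(perm[i], perm[j]);
    }
    Xp.col(sc) = perm;
    arma::vec bmu = start.head(pm), bs = start.tail(pm);
    double ll, gnorm; int it;
    bool conv = als_core(y, Xp, Xp, offset, bmu, bs, maxit, reltol,
                         gradtol, ll, gnorm, it);
    out[b] = conv ? bs[sc] : NA_REAL;
  }
  return out;
}

// Gradient of the negative log-likelihood w.r.t. c(beta_mu, beta_sigma).
// [[Rcpp::export]]
arma::vec nb_negll_grad(const arma::vec& beta, const arma::vec& y,
                        const arma::mat& Xmu, const arma::mat& Xsigma,
                        const arma::vec& offset) {
  const arma::uword n = y.n_elem;
  const arma::uword pm = Xmu.n_cols;
  const arma::uword ps = Xsigma.n_cols;
  arma::vec eta_mu = arma::clamp(Xmu * beta.head(pm) + offset, -300.0, 300.0);
  arma::vec eta_s  = arma::clamp(Xsigma * beta.tail(ps), -300.0, 60.0);
  arma::vec dmu(n), ds(n);
  for (arma::uword i = 0; i < n; ++i) {
    const double yi = y[i];
    const double mi = std::exp(eta_mu[i]);
    double si = std::exp(eta_s[i]);
    if (si > SIGMA_MAX) si = SIGMA_MAX;
    if (si < SIGMA_SMALL) {
      dmu[i] = yi - mi - si * mi * (yi - mi);
      ds[i]  = 0.5 * si * ((yi - mi) * (yi - mi) - yi);
    } else {
      const double r = 1.0 / si;
      // d ll / d eta_mu = y - mu * (y + r) / (mu + r)
      dmu[i] = yi - mi * (yi + r) / (mi + r);
      // d ll / d r, then d ll / d eta_sigma = -r * d ll / d r
      const double dldr = R::digamma(yi + r) - R::digamma(r)
        + std::log(r) - std::log(r + mi) + 1.0 - (r + yi) / (r + mi);
      ds[i] = -r * dldr;
    }
  }
  arma::vec g(pm + ps);
  g.head(pm) = -(Xmu.t() * dmu);
  g.tail(ps) = -(Xsigma.t() * ds);
  return g;
}
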