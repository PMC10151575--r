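// Gibbs samplers for threshold (probit) and linear whole-genome regression
// models, and for the relationship-matrix animal model.
//
// All random numbers come from R's RNG so runs are reproducible with
// set.seed() on the R side.  Residual variance is fixed (1 for probit,
// pi^2/3 for the logit-scale approximation); marker-effect variances get
// scaled-inverse-chi-square updates, 2x2 covariances inverse-Wishart.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// truncated standard-deviation-sd normal draw, constrained to sign
static double rtnorm(double mu, double sd, bool positive) {
  double u;
  if (positive) {
    double lo = R::pnorm(0.0, mu, sd, 1, 0); // P(X < 0)
    u = lo + R::unif_rand() * (1.0 - lo);
  } else {
    double hi = R::pnorm(0.0, mu, sd, 1, 0);
    u = R::unif_rand() * hi;
  }
  if (u < 1e-15) u = 1e-15;
  if (u > 1.0 - 1e-15) u = 1.0 - 1e-15;
  return R::qnorm(u, mu, sd, 1, 0);
}

// scaled-inverse-chi-square draw: (nu*S + ss) / chisq(nu + n)
static double rsichisq(double nu, double S, double ss, double n) {
  return (nu * S + ss) / R::rchisq(nu + n);
}

// 2x2 inverse-Wishart via Bartlett on the Wishart of the inverted scale
static arma::mat riwish2(double df, const arma::mat& S) {
  arma::mat Sinv = arma::inv_sympd(arma::symmatu(S));
  arma::mat L = arma::chol(Sinv, "lower");
  arma::mat A(2, 2, arma::fill::zeros);
  A(0, 0) = std::sqrt(R::rchisq(df));
  A(1, 1) = std::sqrt(R::rchisq(df - 1.0));
  A(1, 0) = R::norm_rand();
  arma::mat LA = L * A;           // W = LA LA' ~ Wishart(df, Sinv)
  arma::mat W = LA * LA.t();
  return arma::inv_sympd(arma::symmatu(W));
}

// Univariate threshold (probit) marker-effects model.
//   liability = X b + sum_n m_n beta_n delta_n + e,  e ~ N(0, 1)
// prior_type: 0 = Bayes-C0 (all in, common var), 1 = Bayes-C (point mass,
// common var; pi estimated when estimate_pi), 2 = Bayes-B (point mass,
// marker-specific var).
// [[Rcpp::export(name = ".cpp_threshold_marker")]]
List cpp_threshold_marker(const arma::ivec& y, const arma::mat& X,
                          const arma::mat& M, int prior_type, double pi0,
                          bool estimate_pi, int niter, int burnin, int thin,
                          double nu, double scale_var, double fixed_var,
                          bool save_liab) {
  const int n = M.n_rows, p = M.n_cols, q = X.n_cols;
  const double varE = 1.0;
  const int nsave = (niter - burnin) / thin;

  arma::vec xx(q), mm(p);
  for (int j = 0; j < q; ++j) xx(j) = arma::dot(X.col(j), X.col(j));
  for (int j = 0; j < p; ++j) mm(j) = arma::dot(M.col(j), M.col(j));
  // markers with zero dose variance are never included
  arma::uvec informative = arma::find(mm - arma::square(arma::sum(M, 0).t()) / n > 1e-12);

  arma::vec b(q, arma::fill::zeros), beta(p, arma::fill::zeros);
  arma::ivec delta(p, arma::fill::zeros);
  arma::vec sigma2m(p);
  sigma2m.fill(scale_var);
  double sigma2c = scale_var;      // common variance (Bayes-C/C0)
  double pi = (prior_type == 0) ? 0.0 : pi0;

  // initial liabilities: modest +/- values consistent with y
  arma::vec liab(n), ycorr(n);
  for (int i = 0; i < n; ++i) liab(i) = (y(i) == 1) ? 0.5 : -0.5;
  ycorr = liab; // b = beta = 0

  arma::mat effects(nsave, p, arma::fill::zeros);
  arma::mat fixed(nsave, q, arma::fill::zeros);
  arma::vec genvar(nsave, arma::fill::zeros), pis(nsave, arma::fill::zeros),
      sig(nsave, arma::fill::zeros);
  arma::vec pip(p, arma::fill::zeros);
  arma::mat liabs;
  if (save_liab) liabs.zeros(nsave, n);

  int isave = 0;
  for (int it = 1; it <= niter; ++it) {
    // --- liabilities
    for (int i = 0; i < n; ++i) {
      double mu = liab(i) - ycorr(i);
      double lnew = rtnorm(mu, std::sqrt(varE), y(i) == 1);
      ycorr(i) += lnew - liab(i);
      liab(i) = lnew;
    }
    // --- fixed effects; a weak normal prior (variance fixed_var) anchors
    // contemporary groups whose outcomes are all 0 or all 1
    for (int j = 0; j < q; ++j) {
      double r = arma::dot(X.col(j), ycorr) + xx(j) * b(j);
      double lhs = xx(j) + (std::isfinite(fixed_var) ? varE / fixed_var : 0.0);
      double bn = r / lhs + R::norm_rand() * std::sqrt(varE / lhs);
      ycorr += X.col(j) * (b(j) - bn);
      b(j) = bn;
    }
    // --- marker effects
    int nin = 0;
    for (arma::uword k = 0; k < informative.n_elem; ++k) {
      int j = informative(k);
      double old = beta(j) * delta(j);
      double C = mm(j);
      double r = arma::dot(M.col(j), ycorr) + C * old;
      double s2 = (prior_type == 2) ? sigma2m(j) : sigma2c;
      int dnew = 1;
      if (prior_type != 0) {
        double v0 = C * varE;
        double v1 = C * C * s2 + C * varE;
        double logodds = std::log(1.0 - pi) - std::log(pi) +
            0.5 * (std::log(v0 / v1) + r * r * (1.0 / v0 - 1.0 / v1));
        double pincl = 1.0 / (1.0 + std::exp(-logodds));
        dnew = (R::unif_rand() < pincl) ? 1 : 0;
      }
      if (dnew == 1) {
        double lhs = C + varE / s2;
        double bn = r / lhs + R::norm_rand() * std::sqrt(varE / lhs);
        if (bn != old) ycorr += M.col(j) * (old - bn);
        beta(j) = bn;
        delta(j) = 1;
        ++nin;
      } else {
        if (old != 0.0) ycorr += M.col(j) * old;
        beta(j) = 0.0;
        delta(j) = 0;
      }
      // marker-specific variance update (Bayes-B)
      if (prior_type == 2) {
        if (delta(j) == 1)
          sigma2m(j) = rsichisq(nu, scale_var, beta(j) * beta(j), 1.0);
        else
          sigma2m(j) = rsichisq(nu, scale_var, 0.0, 0.0);
      }
    }
    // --- common effect variance (Bayes-C/C0)
    if (prior_type != 2) {
      double ss = 0.0;
      for (int j = 0; j < p; ++j)
        if (delta(j) == 1 || prior_type == 0) ss += beta(j) * beta(j);
      int k = 0;
      for (int j = 0; j < p; ++j) k += (prior_type == 0) ? 1 : delta(j);
      sigma2c = rsichisq(nu, scale_var, ss, (double)k);
    }
    // --- pi update (Bayes-Cpi): uniform prior on pi = P(delta = 0)
    if (estimate_pi && prior_type != 0) {
      int pinf = informative.n_elem;
      pi = R::rbeta((double)(pinf - nin) + 1.0, (double)nin + 1.0);
      if (pi > 1.0 - 1e-9) pi = 1.0 - 1e-9;
      if (pi < 1e-9) pi = 1e-9;
    }
    // --- save
    if (it > burnin && (it - burnin) % thin == 0 && isave < nsave) {
      arma::vec eff = beta % arma::conv_to<arma::vec>::from(delta);
      if (prior_type == 0) eff = beta;
      effects.row(isave) = eff.t();
      fixed.row(isave) = b.t();
      arma::vec g = M * eff;
      genvar(isave) = arma::var(g);
      pis(isave) = pi;
      sig(isave) = (prior_type == 2) ? arma::mean(sigma2m) : sigma2c;
      for (int j = 0; j < p; ++j) pip(j) += (prior_type == 0) ? 1.0 : delta(j);
      if (save_liab) liabs.row(isave) = liab.t();
      ++isave;
    }
  }
  pip /= std::max(1, isave);
  List out = List::create(
      _["effects"] = effects, _["fixed"] = fixed, _["genvar"] = genvar,
      _["pi"] = pis, _["sigma2"] = sig, _["pip"] = pip);
  if (save_liab) out["liab"] = liabs;
  return out;
}

// Bivariate linear Bayes-C0 model on the union of the two trait datasets.
//   Y (n x 2, NA allowed) = X1 b1 | X2 b2 + M B + E, rows of E ~ N(0, R)
// Missing phenotypes are imputed each round from the conditional normal
// implied by R (data augmentation), so updates use complete data.
// [[Rcpp::export(name = ".cpp_bivariate_linear")]]
List cpp_bivariate_linear(arma::mat Y, const arma::umat& obs,
                          const arma::mat& X1, const arma::mat& X2,
                          const arma::mat& M, int niter, int burnin, int thin,
                          double nu, const arma::mat& Sg, const arma::mat& Sr) {
  const int n = M.n_rows, p = M.n_cols;
  const int q1 = X1.n_cols, q2 = X2.n_cols;
  const int nsave = (niter - burnin) / thin;

  arma::vec mm(p);
  for (int j = 0; j < p; ++j) mm(j) = arma::dot(M.col(j), M.col(j));
  arma::vec x1x(q1), x2x(q2);
  for (int j = 0; j < q1; ++j) x1x(j) = arma::dot(X1.col(j), X1.col(j));
  for (int j = 0; j < q2; ++j) x2x(j) = arma::dot(X2.col(j), X2.col(j));

  arma::vec b1(q1, arma::fill::zeros), b2(q2, arma::fill::zeros);
  arma::mat B(p, 2, arma::fill::zeros);
  arma::mat G = Sg, R = Sr;
  // initialize missing entries at the observed-trait mean
  for (int t = 0; t < 2; ++t) {
    arma::uvec o = arma::find(obs.col(t) == 1);
    double mu = arma::mean(Y.elem(o + (arma::uword)t * n));
    for (int i = 0; i < n; ++i) if (!obs(i, t)) Y(i, t) = mu;
  }
  arma::mat Ycorr = Y; // residuals (b = B = 0)

  arma::mat gcov(nsave, 3), gsamp(nsave, 3), rsamp(nsave, 3);
  arma::cube beff;
  beff.zeros(p, 2, nsave);

  int isave = 0;
  for (int it = 1; it <= niter; ++it) {
    arma::mat Rinv = arma::inv_sympd(arma::symmatu(R));
    // --- impute missing phenotypes from conditional residual distribution
    for (int t = 0; t < 2; ++t) {
      int o = 1 - t;
      double cslope = R(t, o) / R(o, o);
      double csd = std::sqrt(R(t, t) - R(t, o) * cslope);
      for (int i = 0; i < n; ++i) {
        if (!obs(i, t)) {
          double enew = cslope * Ycorr(i, o) + csd * R::norm_rand();
          Y(i, t) += enew - Ycorr(i, t);
          Ycorr(i, t) = enew;
        }
      }
    }
    // --- fixed effects (flat prior), single-site with correlated residuals
    for (int t = 0; t < 2; ++t) {
      const arma::mat& X = (t == 0) ? X1 : X2;
      const arma::vec& xx = (t == 0) ? x1x : x2x;
      arma::vec& bt = (t == 0) ? b1 : b2;
      int o = 1 - t;
      for (arma::uword j = 0; j < X.n_cols; ++j) {
        // conditional on other trait's residuals via R^{-1}
        double lhs = xx(j) * Rinv(t, t);
        double rhs = Rinv(t, t) * (arma::dot(X.col(j), Ycorr.col(t)) + xx(j) * bt(j)) +
                     Rinv(t, o) * arma::dot(X.col(j), Ycorr.col(o));
        double bn = rhs / lhs + R::norm_rand() / std::sqrt(lhs);
        Ycorr.col(t) += X.col(j) * (bt(j) - bn);
        bt(j) = bn;
      }
    }
    // --- marker effects: joint 2-vector update, all markers in (Bayes-C0);
    // 2x2 algebra done in closed form (this loop dominates runtime)
    double gdet = G(0, 0) * G(1, 1) - G(0, 1) * G(0, 1);
    double gi00 = G(1, 1) / gdet, gi11 = G(0, 0) / gdet,
           gi01 = -G(0, 1) / gdet;
    for (int j = 0; j < p; ++j) {
      if (mm(j) < 1e-12) continue;
      double o0 = B(j, 0), o1 = B(j, 1);
      double r0 = arma::dot(M.col(j), Ycorr.col(0)) + mm(j) * o0;
      double r1 = arma::dot(M.col(j), Ycorr.col(1)) + mm(j) * o1;
      // precision P = mm * Rinv + Ginv, covariance Pc = P^{-1}
      double p00 = mm(j) * Rinv(0, 0) + gi00;
      double p01 = mm(j) * Rinv(0, 1) + gi01;
      double p11 = mm(j) * Rinv(1, 1) + gi11;
      double pdet = p00 * p11 - p01 * p01;
      double c00 = p11 / pdet, c11 = p00 / pdet, c01 = -p01 / pdet;
      double q0 = Rinv(0, 0) * r0 + Rinv(0, 1) * r1;
      double q1 = Rinv(1, 0) * r0 + Rinv(1, 1) * r1;
      double mu0 = c00 * q0 + c01 * q1;
      double mu1 = c01 * q0 + c11 * q1;
      // lower Cholesky of Pc
      double l00 = std::sqrt(c00);
      double l10 = c01 / l00;
      double l11 = std::sqrt(std::max(c11 - l10 * l10, 0.0));
      double z0 = R::norm_rand(), z1 = R::norm_rand();
      double b0 = mu0 + l00 * z0;
      double b1 = mu1 + l10 * z0 + l11 * z1;
      Ycorr.col(0) += M.col(j) * (o0 - b0);
      Ycorr.col(1) += M.col(j) * (o1 - b1);
      B(j, 0) = b0; B(j, 1) = b1;
    }
    // --- G (marker-effect covariance): inverse-Wishart
    G = riwish2(nu + p, nu * Sg + B.t() * B);
    // --- R (residual covariance): inverse-Wishart on complete-data residuals
    R = riwish2(nu + n, nu * Sr + Ycorr.t() * Ycorr);
    // --- save
    if (it > burnin && (it - burnin) % thin == 0 && isave < nsave) {
      arma::mat gv = M * B;                 // genomic values per trait
      arma::mat C = arma::cov(gv);          // genome-wide genetic (co)variance
      gcov(isave, 0) = C(0, 0); gcov(isave, 1) = C(0, 1); gcov(isave, 2) = C(1, 1);
      gsamp(isave, 0) = G(0, 0); gsamp(isave, 1) = G(0, 1); gsamp(isave, 2) = G(1, 1);
      rsamp(isave, 0) = R(0, 0); rsamp(isave, 1) = R(0, 1); rsamp(isave, 2) = R(1, 1);
      beff.slice(isave) = B;
      ++isave;
    }
  }
  return List::create(_["gencov"] = gcov, _["G"] = gsamp, _["R"] = rsamp,
                      _["effects"] = beff);
}

// Threshold animal model with relationship-matrix eigendecomposition
// K = U diag(d) U'.  liability = X b + U alpha + e; alpha_i ~ N(0, s2a d_i),
// e ~ N(0, varE) with varE fixed by the link.
// [[Rcpp::export(name = ".cpp_animal_threshold")]]
List cpp_animal_threshold(const arma::ivec& y, const arma::mat& X,
                          const arma::mat& U, const arma::vec& d, double varE,
                          int niter, int burnin, int thin, double nu,
                          double scale_a, double fixed_var, bool save_liab) {
  const int n = U.n_rows, q = X.n_cols;
  const int nsave = (niter - burnin) / thin;

  arma::vec xx(q);
  for (int j = 0; j < q; ++j) xx(j) = arma::dot(X.col(j), X.col(j));

  arma::vec b(q, arma::fill::zeros), alpha(n, arma::fill::zeros),
      a(n, arma::fill::zeros);
  double s2a = scale_a;
  arma::vec liab(n);
  for (int i = 0; i < n; ++i) liab(i) = (y(i) == 1) ? 0.5 : -0.5;

  arma::vec s2a_s(nsave), h2_s(nsave);
  arma::mat fixed(nsave, q);
  arma::mat liabs;
  if (save_liab) liabs.zeros(nsave, n);
  arma::vec amean(n, arma::fill::zeros);

  int isave = 0;
  for (int it = 1; it <= niter; ++it) {
    // --- liabilities given fit
    arma::vec fit = X * b + a;
    for (int i = 0; i < n; ++i)
      liab(i) = rtnorm(fit(i), std::sqrt(varE), y(i) == 1);
    // --- fixed effects given liab, a: single-site pass with a weak normal
    // prior anchoring all-0/all-1 contemporary groups
    arma::vec e = liab - a - X * b;
    for (int j = 0; j < q; ++j) {
      double r = arma::dot(X.col(j), e) + xx(j) * b(j);
      double lhs = xx(j) + (std::isfinite(fixed_var) ? varE / fixed_var : 0.0);
      double bn = r / lhs + R::norm_rand() * std::sqrt(varE / lhs);
      e += X.col(j) * (b(j) - bn);
      b(j) = bn;
    }
    // --- breeding values in the eigenbasis: diagonal full conditional
    arma::vec r = U.t() * (liab - X * b);
    for (int i = 0; i < n; ++i) {
      double prec = 1.0 / varE + 1.0 / (s2a * d(i));
      double mu = (r(i) / varE) / prec;
      alpha(i) = mu + R::norm_rand() / std::sqrt(prec);
    }
    a = U * alpha;
    // --- additive variance
    double ss = 0.0;
    for (int i = 0; i < n; ++i) ss += alpha(i) * alpha(i) / d(i);
    s2a = rsichisq(nu, scale_a, ss, (double)n);
    // --- save
    if (it > burnin && (it - burnin) % thin == 0 && isave < nsave) {
      s2a_s(isave) = s2a;
      h2_s(isave) = s2a / (s2a + varE);
      fixed.row(isave) = b.t();
      amean += a;
      if (save_liab) liabs.row(isave) = liab.t();
      ++isave;
    }
  }
  amean /= std::max(1, isave);
  List out = List::create(_["sigma2a"] = s2a_s, _["h2"] = h2_s,
                          _["fixed"] = fixed, _["ebv"] = amean);
  if (save_liab) out["liab"] = liabs;
  return out;
}
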