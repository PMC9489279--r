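// MCMC sampler for the phylogenetic mixed model on the liability scale:
//   l = X beta + sum_t alpha_t Z_t eta_t + e,   e ~ N(0, s2e I)
//   eta_t ~ N(0, s2eta_t G_t),  G_phylo = A (MRCA-depth matrix), else I
//   reported variance of term t is s2_t = alpha_t^2 * s2eta_t
//   gaussian family: y = l observed
//   binomial family: y_i ~ Binom(n_i, logistic(l_i)), l latent
// The (alpha, s2eta) pair is the redundant multiplicative parameter
// expansion; alpha ~ N(alpha_mu, alpha_V), s2eta ~ IW(V, nu) (scalar
// inverse-gamma), together inducing a scaled-F marginal prior on s2_t.
// All randomness comes from R's RNG so set.seed() in R fixes the chain.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static double softplus(double x) {
  // log(1 + exp(x)) without overflow
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

static arma::vec rnorm_vec(arma::uword n) {
  arma::vec z(n);
  for (arma::uword i = 0; i < n; ++i) z[i] = norm_rand();
  return z;
}

static double rinvgamma(double shape, double rate) {
  // R::rgamma uses shape/scale
  return 1.0 / R::rgamma(shape, 1.0 / rate);
}

// [[Rcpp::export(name = ".pmm_sampler_cpp")]]
List pmm_sampler(const arma::vec& y,         // counts (binomial) or response
                 const arma::vec& ntrials,   // binomial trials (unused o/w)
                 int family,                 // 0 gaussian, 1 binomial
                 const arma::mat& X,
                 const arma::mat& Z,         // all random columns, may be 0-col
                 const arma::ivec& term_sizes,
                 const List& Ginv_list,
                 double fixed_var,
                 double pe_nu, double pe_V, double pe_alpha_mu, double pe_alpha_V,
                 double resid_nu, double resid_V,
                 double fix_resid,           // > 0: residual variance fixed
                 int niter, int burnin, int thin,
                 double step_init) {
  const arma::uword n = X.n_rows, p = X.n_cols;
  const arma::uword T = term_sizes.n_elem;
  arma::uword q = Z.n_cols;

  std::vector<arma::mat> Ginv(T);
  std::vector<arma::uword> off(T);
  {
    arma::uword o = 0;
    for (arma::uword t = 0; t < T; ++t) {
      Ginv[t] = as<arma::mat>(Ginv_list[t]);
      off[t] = o;
      o += (arma::uword) term_sizes[t];
    }
    if (o != q) stop("term_sizes do not match ncol(Z)");
  }

  arma::vec beta(p, arma::fill::zeros);
  arma::vec eta(q, arma::fill::zeros);
  arma::vec alpha(T, arma::fill::ones);
  arma::vec s2eta(T, arma::fill::ones);
  double s2e = (fix_resid > 0.0) ? fix_resid : 1.0;

  arma::vec liab(n);
  if (family == 1) {
    for (arma::uword i = 0; i < n; ++i) {
      double ph = (y[i] + 0.5) / (ntrials[i] + 1.0);
      liab[i] = std::log(ph / (1.0 - ph));
    }
  } else {
    liab = y;
  }

  arma::vec step(n);
  step.fill(step_init);
  arma::vec acc_win(n, arma::fill::zeros);   // window acceptance counts
  double acc_total = 0.0;                    // post-burn-in acceptances
  long   acc_n = 0;

  const int S = (niter - burnin) / thin;
  if (S < 1) stop("no stored draws: check niter/burnin/thin");
  arma::mat beta_s(S, p), sigma2_s(S, T), alpha_s(S, T);
  arma::vec s2e_s(S), dev_s(S);
  arma::mat liab_s, fitted_s(S, n);
  if (family == 1) liab_s.set_size(S, n);

  // binomial log-likelihood constant term sum(lchoose(n, k))
  double lconst = 0.0;
  if (family == 1)
    for (arma::uword i = 0; i < n; ++i)
      lconst += R::lchoose(ntrials[i], y[i]);

  const arma::mat XtX = X.t() * X;
  int s = 0;

  for (int it = 0; it < niter; ++it) {
    // --- current random-effect contribution, per term ---
    arma::mat V(n, T);                       // V.col(t) = Z_t eta_t
    for (arma::uword t = 0; t < T; ++t)
      V.col(t) = Z.cols(off[t], off[t] + term_sizes[t] - 1) *
        eta.subvec(off[t], off[t] + term_sizes[t] - 1);
    arma::vec u_contrib(n, arma::fill::zeros);
    for (arma::uword t = 0; t < T; ++t) u_contrib += alpha[t] * V.col(t);
    arma::vec mu = X * beta + u_contrib;

    // --- (1) binomial: Metropolis update of liabilities ---
    if (family == 1) {
      bool adapting = it < burnin;
      // proposal scale rides on the current residual sd so the adapted
      // multiplier stays calibrated while s2e moves during burn-in
      double pscale = std::sqrt(s2e);
      for (arma::uword i = 0; i < n; ++i) {
        double cur = liab[i];
        double prop = cur + step[i] * pscale * norm_rand();
        double lp_cur = y[i] * cur - ntrials[i] * softplus(cur)
          - 0.5 * (cur - mu[i]) * (cur - mu[i]) / s2e;
        double lp_prop = y[i] * prop - ntrials[i] * softplus(prop)
          - 0.5 * (prop - mu[i]) * (prop - mu[i]) / s2e;
        bool acc = std::log(unif_rand()) < lp_prop - lp_cur;
        if (acc) liab[i] = prop;
        if (adapting) acc_win[i] += acc ? 1.0 : 0.0;
        else { acc_total += acc ? 1.0 : 0.0; ++acc_n; }
      }
      if (adapting && (it + 1) % 25 == 0) {
        for (arma::uword i = 0; i < n; ++i) {
          double rate = acc_win[i] / 25.0;
          step[i] *= std::exp(rate - 0.44);   // target 0.44 acceptance
          step[i] = std::min(std::max(step[i], 1e-3), 20.0);
        }
        acc_win.zeros();
      }
    }

    // --- (2) joint Gibbs draw of (beta, eta) ---
    {
      arma::mat W(n, p + q);
      W.cols(0, p - 1) = X;
      for (arma::uword t = 0; t < T; ++t)
        W.cols(p + off[t], p + off[t] + term_sizes[t] - 1) =
          alpha[t] * Z.cols(off[t], off[t] + term_sizes[t] - 1);
      arma::mat P = W.t() * W / s2e;
      for (arma::uword j = 0; j < p; ++j) P(j, j) += 1.0 / fixed_var;
      for (arma::uword t = 0; t < T; ++t)
        P.submat(p + off[t], p + off[t],
                 p + off[t] + term_sizes[t] - 1,
                 p + off[t] + term_sizes[t] - 1) += Ginv[t] / s2eta[t];
      arma::vec rhs = W.t() * liab / s2e;
      arma::mat R;
      if (!arma::chol(R, P))
        stop("non-positive-definite precision in location update at iteration %d", it + 1);
      arma::vec m = arma::solve(arma::trimatu(R),
                                arma::solve(arma::trimatl(R.t()), rhs));
      arma::vec draw = m + arma::solve(arma::trimatu(R), rnorm_vec(p + q));
      if (!draw.is_finite())
        stop("NaN in location draw at iteration %d", it + 1);
      beta = draw.head(p);
      if (q > 0) eta = draw.tail(q);
    }

    // --- (3) working-scale parameters alpha (joint T-dim normal) ---
    if (T > 0) {
      for (arma::uword t = 0; t < T; ++t)
        V.col(t) = Z.cols(off[t], off[t] + term_sizes[t] - 1) *
          eta.subvec(off[t], off[t] + term_sizes[t] - 1);
      arma::vec r0 = liab - X * beta;
      arma::mat Pa = V.t() * V / s2e;
      Pa.diag() += 1.0 / pe_alpha_V;
      arma::vec ra = V.t() * r0 / s2e + pe_alpha_mu / pe_alpha_V;
      arma::mat Ra;
      if (!arma::chol(Ra, Pa))
        stop("non-positive-definite precision in alpha update at iteration %d", it + 1);
      arma::vec ma = arma::solve(arma::trimatu(Ra),
                                 arma::solve(arma::trimatl(Ra.t()), ra));
      alpha = ma + arma::solve(arma::trimatu(Ra), rnorm_vec(T));
    }

    // --- (4) base variances of the expanded terms ---
    for (arma::uword t = 0; t < T; ++t) {
      arma::vec et = eta.subvec(off[t], off[t] + term_sizes[t] - 1);
      double ss = arma::as_scalar(et.t() * Ginv[t] * et);
      s2eta[t] = rinvgamma((pe_nu + term_sizes[t]) / 2.0,
                           (pe_nu * pe_V + ss) / 2.0);
    }

    // --- (5) residual variance (inverse-Wishart, scalar) ---
    arma::vec fitted = X * beta;
    for (arma::uword t = 0; t < T; ++t)
      fitted += alpha[t] * Z.cols(off[t], off[t] + term_sizes[t] - 1) *
        eta.subvec(off[t], off[t] + term_sizes[t] - 1);
    if (fix_resid <= 0.0) {
      arma::vec r = liab - fitted;
      s2e = rinvgamma((resid_nu + n) / 2.0,
                      (resid_nu * resid_V + arma::dot(r, r)) / 2.0);
    }

    // --- store ---
    if (it >= burnin && (it - burnin) % thin == 0 && s < S) {
      beta_s.row(s) = beta.t();
      for (arma::uword t = 0; t < T; ++t) {
        sigma2_s(s, t) = alpha[t] * alpha[t] * s2eta[t];
        alpha_s(s, t) = alpha[t];
      }
      s2e_s[s] = s2e;
      fitted_s.row(s) = fitted.t();
      double dev = 0.0;
      if (family == 1) {
        for (arma::uword i = 0; i < n; ++i)
          dev += y[i] * liab[i] - ntrials[i] * softplus(liab[i]);
        dev = -2.0 * (dev + lconst);
        liab_s.row(s) = liab.t();
      } else {
        arma::vec r = y - fitted;
        dev = n * std::log(2.0 * M_PI * s2e) + arma::dot(r, r) / s2e;
      }
      if (!std::isfinite(dev))
        stop("NaN deviance at iteration %d", it + 1);
      dev_s[s] = dev;
      ++s;
    }
  }

  double acc_rate = acc_n > 0 ? acc_total / acc_n : NA_REAL;
  return List::create(
    _["beta"] = beta_s, _["sigma2"] = sigma2_s, _["alpha"] = alpha_s,
    _["sigma2_e"] = s2e_s, _["deviance"] = dev_s,
    _["liability"] = liab_s, _["fitted"] = fitted_s,
    _["accept_rate"] = acc_rate, _["step"] = step);
}
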