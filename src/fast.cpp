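// Fitting and concordance kernels used inside the bootstrap / simulation
// loops, where call overhead of the usual model-fitting interfaces dominates.
// Numerical conventions match the user-facing wrappers in R/ (which are
// cross-checked against stats::glm, survival::coxph and survival::concordance
// in the test suite).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static double logit_loglik(const arma::vec& eta, const arma::vec& y) {
  // sum(y*eta - log(1+exp(eta))), computed stably
  double ll = 0.0;
  for (arma::uword i = 0; i < eta.n_elem; ++i) {
    double e = eta[i];
    double lse = (e > 0) ? e + std::log1p(std::exp(-e)) : std::log1p(std::exp(e));
    ll += y[i] * e - lse;
  }
  return ll;
}

// Maximum-likelihood logistic regression by Newton-Raphson (IRLS) with
// step-halving. X must already contain the intercept column.
// [[Rcpp::export(name = ".logit_fit_cpp")]]
List logit_fit_cpp(const arma::mat& X, const arma::vec& y,
                   double tol = 1e-8, int maxit = 100) {
  const arma::uword p = X.n_cols;
  arma::vec beta(p, arma::fill::zeros);
  arma::vec eta = X * beta;
  double ll = logit_loglik(eta, y);
  double gnorm = R_PosInf;
  bool converged = false;
  int iter = 0;

  for (iter = 0; iter < maxit; ++iter) {
    arma::vec mu = 1.0 / (1.0 + arma::exp(-eta));
    arma::vec g = X.t() * (y - mu);
    gnorm = arma::abs(g).max();
    if (gnorm < tol) { converged = true; break; }
    arma::vec w = mu % (1.0 - mu) + 1e-12;
    arma::mat H = X.t() * (X.each_col() % w);
    arma::vec step;
    if (!arma::solve(step, H, g, arma::solve_opts::likely_sympd)) break;
    double f = 1.0;
    bool moved = false;
    double lltol = 1e-10 * (std::fabs(ll) + 1.0);
    for (int h = 0; h < 25; ++h) {
      arma::vec bnew = beta + f * step;
      arma::vec enew = X * bnew;
      double llnew = logit_loglik(enew, y);
      if (std::isfinite(llnew) && llnew >= ll - lltol) {
        beta = bnew; eta = enew; ll = llnew; moved = true; break;
      }
      f *= 0.5;
    }
    if (!moved) {
      // no improvement possible within rounding: converged if the proposed
      // step was already negligible
      converged = arma::abs(step).max() < 1e-6;
      break;
    }
    if (arma::abs(beta).max() > 100.0) break;  // separation guard
    // at large n the absolute gradient tolerance is below the floating-point
    // noise of the score sum; a vanishing Newton increment is convergence
    if (f * arma::abs(step).max() < 1e-10) { converged = true; break; }
  }

  return List::create(_["coef"] = beta, _["converged"] = converged,
                      _["iterations"] = iter, _["grad_norm"] = gnorm,
                      _["loglik"] = ll,
                      _["separated"] = arma::abs(beta).max() > 100.0);
}

// Partial log-likelihood, gradient and observed information for a Cox model
// with Breslow tie handling. Data must be sorted by ascending time.
static void cox_quantities(const arma::vec& time, const arma::ivec& status,
                           const arma::mat& X, const arma::vec& beta,
                           double& ll, arma::vec& grad, arma::mat& info,
                           bool derivs) {
  const int n = time.n_elem;
  const arma::uword p = X.n_cols;
  arma::vec eta = X * beta;
  arma::vec w = arma::exp(arma::clamp(eta, -500.0, 500.0));
  double s0 = 0.0;
  arma::vec s1(p, arma::fill::zeros);
  arma::mat s2(p, p, arma::fill::zeros);
  ll = 0.0;
  if (derivs) { grad.zeros(p); info.zeros(p, p); }

  int i = n - 1;
  while (i >= 0) {
    int j = i;
    while (j >= 0 && time[j] == time[i]) {
      s0 += w[j];
      if (derivs) {
        s1 += w[j] * X.row(j).t();
        s2 += w[j] * (X.row(j).t() * X.row(j));
      }
      --j;
    }
    for (int k = i; k > j; --k) {
      if (status[k] == 1) {
        ll += eta[k] - std::log(s0);
        if (derivs) {
          arma::vec xbar = s1 / s0;
          grad += X.row(k).t() - xbar;
          info += s2 / s0 - xbar * xbar.t();
        }
      }
    }
    i = j;
  }
}

// Cox proportional hazards fit (Breslow ties) by Newton-Raphson with
// step-halving. time/status/X must be sorted by ascending time. Covariates
// should be centred by the caller for numerical stability; coefficients are
// unaffected by centring.
// [[Rcpp::export(name = ".cox_fit_cpp")]]
List cox_fit_cpp(const arma::vec& time, const arma::ivec& status,
                 const arma::mat& X, double tol = 1e-8, int maxit = 100) {
  const arma::uword p = X.n_cols;
  arma::vec beta(p, arma::fill::zeros);
  arma::vec grad(p);
  arma::mat info(p, p);
  double ll;
  cox_quantities(time, status, X, beta, ll, grad, info, true);
  double gnorm = arma::abs(grad).max();
  bool converged = gnorm < tol;
  int iter = 0;

  while (!converged && iter < maxit) {
    ++iter;
    arma::vec step;
    if (!arma::solve(step, info, grad, arma::solve_opts::likely_sympd)) break;
    double f = 1.0;
    bool moved = false;
    double lltol = 1e-10 * (std::fabs(ll) + 1.0);
    for (int h = 0; h < 25; ++h) {
      arma::vec bnew = beta + f * step;
      double llnew;
      arma::vec gdum; arma::mat idum;
      cox_quantities(time, status, X, bnew, llnew, gdum, idum, false);
      if (std::isfinite(llnew) && llnew >= ll - lltol) {
        beta = bnew; ll = llnew; moved = true; break;
      }
      f *= 0.5;
    }
    if (!moved) {
      converged = arma::abs(step).max() < 1e-6;
      break;
    }
    if (arma::abs(beta).max() > 50.0) break;  // monotone-likelihood guard
    cox_quantities(time, status, X, beta, ll, grad, info, true);
    gnorm = arma::abs(grad).max();
    converged = gnorm < tol || f * arma::abs(step).max() < 1e-10;
  }

  return List::create(_["coef"] = beta, _["converged"] = converged,
                      _["iterations"] = iter, _["grad_norm"] = gnorm,
                      _["loglik"] = ll);
}

static arma::vec midranks(const arma::vec& x) {
  const arma::uword n = x.n_elem;
  arma::uvec ord = arma::sort_index(x);
  arma::vec ranks(n);
  arma::uword i = 0;
  while (i < n) {
    arma::uword j = i;
    while (j + 1 < n && x[ord[j + 1]] == x[ord[i]]) ++j;
    double r = 0.5 * (static_cast<double>(i) + static_cast<double>(j)) + 1.0;
    for (arma::uword k = i; k <= j; ++k) ranks[ord[k]] = r;
    i = j + 1;
  }
  return ranks;
}

// Mann-Whitney C-statistic with 0.5 credit for ties, via midranks.
// [[Rcpp::export(name = ".cstat_cpp")]]
double cstat_cpp(const arma::vec& risk, const arma::ivec& y) {
  arma::vec ranks = midranks(risk);
  double n1 = 0.0, s = 0.0;
  for (arma::uword i = 0; i < risk.n_elem; ++i) {
    if (y[i] == 1) { n1 += 1.0; s += ranks[i]; }
  }
  double n0 = static_cast<double>(risk.n_elem) - n1;
  if (n1 == 0.0 || n0 == 0.0) return NA_REAL;
  return (s - n1 * (n1 + 1.0) / 2.0) / (n0 * n1);
}

// Harrell's overall C for one or more prediction columns over the SAME
// usable-pair set. A pair is usable iff the strictly smaller observed time
// belongs to an event; tied observed times are not orderable and are skipped.
// Concordant pairs (earlier subject has the higher predicted risk) score 1,
// prediction ties score tie_credit.
// [[Rcpp::export(name = ".concordance_cpp")]]
List concordance_cpp(const arma::vec& time, const arma::ivec& status,
                     const arma::mat& risk, double tie_credit = 0.5) {
  const int n = time.n_elem;
  const arma::uword m = risk.n_cols;
  arma::vec credit(m, arma::fill::zeros);
  double usable = 0.0;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      int a, b;
      if (time[i] < time[j]) { a = i; b = j; }
      else if (time[j] < time[i]) { a = j; b = i; }
      else continue;
      if (status[a] != 1) continue;
      usable += 1.0;
      for (arma::uword k = 0; k < m; ++k) {
        double ra = risk(a, k), rb = risk(b, k);
        if (ra > rb) credit[k] += 1.0;
        else if (ra == rb) credit[k] += tie_credit;
      }
    }
  }
  return List::create(_["c"] = credit / std::max(usable, 1.0),
                      _["usable"] = usable);
}
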