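#include <Rcpp.h>
using namespace Rcpp;

// Metropolis-within-Gibbs sampler for the Poisson log-linear model with an
// intrinsic Besag CAR random effect:
//   Y_i ~ Poisson(E_i * exp(beta0 + X_i beta + u_i))
//   beta_j ~ N(0, 1/beta_prec), beta0 flat, u ~ ICAR(tau), tau ~ Gamma(a, b)
// Random-walk updates for beta0 and beta with Robbins-Monro adaptation
// towards 0.44 acceptance, single-site random-walk updates for u_i against
// the CAR full conditional, conjugate gamma update for tau, and the
// sum-to-zero constraint re-imposed every sweep (the mean of u is absorbed
// into the intercept, leaving the likelihood untouched).
//
// Uses R's RNG, so results are reproducible under set.seed().

static inline double sq(double x) { return x * x; }

// [[Rcpp::export]]
List car_mcmc_cpp(IntegerVector y, NumericVector E, NumericMatrix X,
                  IntegerVector nbr_flat, IntegerVector nbr_start,
                  double beta_prec, double tau_shape, double tau_rate,
                  int n_burn, int n_keep, int thin) {
  const int n = y.size();
  const int p = X.ncol();
  const int n_iter = n_burn + n_keep * thin;

  NumericVector beta(p, 0.0);
  double beta0 = 0.0;
  NumericVector u(n, 0.0);
  double tau = 1.0;

  // crude data-driven start for the intercept: log(sum Y / sum E)
  double sy = 0.0, sE = 0.0;
  for (int i = 0; i < n; ++i) { sy += y[i]; sE += E[i]; }
  if (sy > 0.0) beta0 = std::log(sy / sE);

  NumericVector eta(n), mu(n);
  for (int i = 0; i < n; ++i) { eta[i] = beta0; mu[i] = E[i] * std::exp(eta[i]); }

  IntegerVector deg(n);
  for (int i = 0; i < n; ++i) deg[i] = nbr_start[i + 1] - nbr_start[i];

  // adaptive log proposal scales
  double ls0 = std::log(0.1);
  NumericVector lsb(p, std::log(0.1));
  NumericVector lsu(n, std::log(0.5));
  const double target = 0.44;

  // adaptive-Metropolis block update for theta = (beta0, beta): running
  // mean/covariance accumulated during burn-in, proposal 2.38/sqrt(d) * L z
  const int d_th = p + 1;
  NumericVector am_mean(d_th, 0.0);
  NumericMatrix am_cov(d_th, d_th);
  NumericMatrix am_chol(d_th, d_th);
  bool am_ready = false;
  int am_n = 0;

  NumericVector beta0_keep(n_keep);
  NumericMatrix beta_keep(n_keep, p);
  NumericMatrix u_keep(n_keep, n);
  NumericVector sig2_keep(n_keep);
  double acc0 = 0.0; NumericVector accb(p, 0.0); double accu = 0.0;

  RNGScope scope;
  int kept = 0;
  for (int it = 0; it < n_iter; ++it) {
    const bool adapting = it < n_burn;
    const double gain = 1.0 / std::pow(it + 10.0, 0.6);

    // --- intercept (flat prior) ---
    {
      double d = R::rnorm(0.0, std::exp(ls0));
      double smu = 0.0;
      for (int i = 0; i < n; ++i) smu += mu[i];
      double dll = d * sy - (std::exp(d) - 1.0) * smu;
      if (!R_finite(dll))
        stop("non-finite log-posterior change at iteration %d (intercept)",
             it + 1);
      double alpha = std::min(1.0, std::exp(dll));
      if (R::unif_rand() < alpha) {
        beta0 += d;
        double f = std::exp(d);
        for (int i = 0; i < n; ++i) { eta[i] += d; mu[i] *= f; }
        if (!adapting) acc0 += 1.0;
      }
      if (adapting) ls0 += gain * (alpha - target);
    }

    // --- fixed effects ---
    for (int j = 0; j < p; ++j) {
      double d = R::rnorm(0.0, std::exp(lsb[j]));
      double dll = -0.5 * beta_prec * (sq(beta[j] + d) - sq(beta[j]));
      for (int i = 0; i < n; ++i) {
        double dx = d * X(i, j);
        dll += y[i] * dx - mu[i] * (std::exp(dx) - 1.0);
      }
      if (!R_finite(dll))
        stop("non-finite log-posterior change at iteration %d (beta %d)",
             it + 1, j + 1);
      double alpha = std::min(1.0, std::exp(dll));
      if (R::unif_rand() < alpha) {
        beta[j] += d;
        for (int i = 0; i < n; ++i) {
          double dx = d * X(i, j);
          eta[i] += dx; mu[i] *= std::exp(dx);
        }
        if (!adapting) accb[j] += 1.0;
      }
      if (adapting) lsb[j] += gain * (alpha - target);
    }

    // --- joint block updates of (beta0, beta) against the posterior ridge ---
    for (int rep = 0; rep < 3 && am_ready; ++rep) {
      std::vector<double> z(d_th), step(d_th, 0.0);
      for (int j = 0; j < d_th; ++j) z[j] = R::norm_rand();
      const double fac = 2.38 / std::sqrt((double)d_th);
      for (int j = 0; j < d_th; ++j) {
        for (int k = 0; k <= j; ++k) step[j] += am_chol(j, k) * z[k];
        step[j] *= fac;
      }
      double dll = 0.0;
      for (int j = 0; j < p; ++j)
        dll += -0.5 * beta_prec * (sq(beta[j] + step[j + 1]) - sq(beta[j]));
      for (int i = 0; i < n; ++i) {
        double dx = step[0];
        for (int j = 0; j < p; ++j) dx += step[j + 1] * X(i, j);
        dll += y[i] * dx - mu[i] * (std::exp(dx) - 1.0);
      }
      if (!R_finite(dll))
        stop("non-finite log-posterior change at iteration %d (block)",
             it + 1);
      if (R::unif_rand() < std::exp(dll)) {
        beta0 += step[0];
        for (int j = 0; j < p; ++j) beta[j] += step[j + 1];
        for (int i = 0; i < n; ++i) {
          double dx = step[0];
          for (int j = 0; j < p; ++j) dx += step[j + 1] * X(i, j);
          eta[i] += dx; mu[i] *= std::exp(dx);
        }
      }
    }
    if (adapting && it >= n_burn / 4) {
      // running mean and covariance of theta over the later burn-in
      // (the initial transient would inflate the proposal covariance)
      ++am_n;
      std::vector<double> th(d_th);
      th[0] = beta0;
      for (int j = 0; j < p; ++j) th[j + 1] = beta[j];
      for (int j = 0; j < d_th; ++j) {
        double delta = th[j] - am_mean[j];
        am_mean[j] += delta / am_n;
        for (int k = 0; k <= j; ++k)
          am_cov(j, k) += delta * (th[k] - am_mean[k]);
      }
      if (am_n >= 100 && am_n % 50 == 0) {
        // Cholesky of cov/(n-1) + jitter; lower triangle
        std::vector<double> A(d_th * d_th, 0.0);
        for (int j = 0; j < d_th; ++j)
          for (int k = 0; k <= j; ++k)
            A[j * d_th + k] = am_cov(j, k) / (am_n - 1) +
              (j == k ? 1e-8 : 0.0);
        bool okchol = true;
        for (int j = 0; j < d_th && okchol; ++j) {
          for (int k = 0; k <= j; ++k) {
            double s = A[j * d_th + k];
            for (int q = 0; q < k; ++q)
              s -= am_chol(j, q) * am_chol(k, q);
            if (j == k) {
              if (s <= 0.0) { okchol = false; break; }
              am_chol(j, j) = std::sqrt(s);
            } else {
              am_chol(j, k) = s / am_chol(k, k);
            }
          }
        }
        if (okchol) am_ready = true;
      }
    }

    // --- CAR effects, single site ---
    for (int i = 0; i < n; ++i) {
      double ubar = 0.0;
      for (int k = nbr_start[i]; k < nbr_start[i + 1]; ++k)
        ubar += u[nbr_flat[k]];
      ubar /= deg[i];
      double d = R::rnorm(0.0, std::exp(lsu[i]));
      double un = u[i] + d;
      double dll = y[i] * d - mu[i] * (std::exp(d) - 1.0)
        - 0.5 * tau * deg[i] * (sq(un - ubar) - sq(u[i] - ubar));
      if (!R_finite(dll))
        stop("non-finite log-posterior change at iteration %d (u %d)",
             it + 1, i + 1);
      double alpha = std::min(1.0, std::exp(dll));
      if (R::unif_rand() < alpha) {
        u[i] = un; eta[i] += d; mu[i] *= std::exp(d);
        if (!adapting) accu += 1.0;
      }
      if (adapting) lsu[i] += gain * (alpha - target);
    }

    // --- re-impose sum-to-zero, absorbing the mean into the intercept ---
    {
      double m = 0.0;
      for (int i = 0; i < n; ++i) m += u[i];
      m /= n;
      for (int i = 0; i < n; ++i) u[i] -= m;
      beta0 += m;
    }

    // --- conjugate update for the CAR precision ---
    {
      double ss = 0.0;  // u' Q u = sum over edges (u_i - u_j)^2
      for (int i = 0; i < n; ++i)
        for (int k = nbr_start[i]; k < nbr_start[i + 1]; ++k) {
          int j = nbr_flat[k];
          if (j > i) ss += sq(u[i] - u[j]);
        }
      tau = R::rgamma(tau_shape + 0.5 * (n - 1), 1.0 / (tau_rate + 0.5 * ss));
      if (!R_finite(tau) || tau <= 0.0)
        stop("non-finite CAR precision at iteration %d", it + 1);
    }

    if (it >= n_burn && (it - n_burn) % thin == thin - 1) {
      beta0_keep[kept] = beta0;
      for (int j = 0; j < p; ++j) beta_keep(kept, j) = beta[j];
      for (int i = 0; i < n; ++i) u_keep(kept, i) = u[i];
      sig2_keep[kept] = 1.0 / tau;
      ++kept;
    }
  }

  double denom = n_keep * (double)thin;
  return List::create(
    _["beta0"] = beta0_keep, _["beta"] = beta_keep, _["u"] = u_keep,
    _["sigma2_u"] = sig2_keep,
    _["accept"] = List::create(_["beta0"] = acc0 / denom,
                               _["beta"] = accb / denom,
                               _["u"] = accu / (denom * n)));
}
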