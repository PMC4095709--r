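// Weighted-likelihood EM for the two-level mixtures
//   f(y) = (1 - pi) * sum_k gamma_k N(y; mu_k, sigma2_k) + pi * f1(y)
// with f1 either a fixed-bounds uniform (NUDGE / iNUDGE) or a pair of
// shifted exponentials with fixed offsets (GNG). The E- and M-steps are
// fused into a single allocation-free pass per iteration; only the inner
// loop lives here, while initialization, restarts and model selection are
// R-level. Zero-weight observations are skipped everywhere: they carry no
// likelihood and no M-step mass.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static const double MASS_EPS = 1e-10;   // responsibility-collapse threshold
static const double DENS_EPS = 1e-300;  // zero-density guard

// family: 0 = uniform f1, 1 = shifted-exponential pair
// [[Rcpp::export]]
Rcpp::List em_run_cpp(const arma::vec& y, const arma::vec& w, int family,
                      double pi0, arma::vec gamma, arma::vec mu,
                      arma::vec sigma2, double rho, double beta1,
                      double beta2, double a, double b, double xi1,
                      double xi2, double tol, int max_iter,
                      double var_floor) {
  const uword n = y.n_elem;
  const uword K = mu.n_elem;
  double pi = pi0;

  std::vector<double> cnorm(K), half_prec(K), dk(K);
  std::vector<double> S0(K), S1(K), S2(K);
  std::vector<double> trace;
  trace.reserve(64);
  bool converged = false, floor_hit = false, frozen = false;
  int iter = 0;
  const double du = (family == 0) ? 1.0 / (b - a) : 0.0;
  const double sw = accu(w);
  double ll_final = 0.0;

  for (iter = 0; iter <= max_iter; ++iter) {
    const bool update = iter < max_iter;  // last pass only evaluates loglik
    for (uword k = 0; k < K; ++k) {
      cnorm[k] = (1.0 - pi) * gamma[k] / std::sqrt(2.0 * M_PI * sigma2[k]);
      half_prec[k] = 0.5 / sigma2[k];
      S0[k] = S1[k] = S2[k] = 0.0;
    }
    const double c1 = (family == 1) ? pi * rho / beta1 : pi * du;
    const double c2 = (family == 1) ? pi * (1.0 - rho) / beta2 : 0.0;
    double T1 = 0.0, T2 = 0.0, TB1 = 0.0, TB2 = 0.0, ll = 0.0;

    for (uword i = 0; i < n; ++i) {
      const double yi = y[i], wi = w[i];
      double tot = 0.0, d1 = 0.0, d2 = 0.0;
      for (uword k = 0; k < K; ++k) {
        const double z = yi - mu[k];
        dk[k] = cnorm[k] * std::exp(-z * z * half_prec[k]);
        tot += dk[k];
      }
      if (family == 1) {
        if (yi < -xi1) { d1 = c1 * std::exp(-(-yi - xi1) / beta1); tot += d1; }
        else if (yi > xi2) { d2 = c2 * std::exp(-(yi - xi2) / beta2); tot += d2; }
      } else if (yi >= a && yi <= b) {
        d1 = c1; tot += d1;
      }
      if (wi <= 0) continue;
      if (tot < DENS_EPS) {
        Rcpp::stop("mixture density underflowed to zero at observation %d "
                   "(y = %g); check uniform bounds / exponential offsets",
                   (int)(i + 1), yi);
      }
      ll += wi * std::log(tot);
      if (!update) continue;
      const double s = wi / tot;
      for (uword k = 0; k < K; ++k) {
        const double r = dk[k] * s;
        S0[k] += r; S1[k] += r * yi; S2[k] += r * yi * yi;
      }
      if (d1 > 0.0) { const double r = d1 * s; T1 += r; TB1 += r * (-yi - xi1); }
      if (d2 > 0.0) { const double r = d2 * s; T2 += r; TB2 += r * (yi - xi2); }
    }
    trace.push_back(ll);
    ll_final = ll;
    if (!update) break;

    // M-step: weighted-moment updates; fixed a, b, xi1, xi2 untouched
    const double pi_new = (T1 + T2) / sw;
    double mass_norm = 0.0;
    for (uword k = 0; k < K; ++k) mass_norm += S0[k];

    double delta = std::abs(pi_new - pi);
    pi = pi_new;
    for (uword k = 0; k < K; ++k) {
      if (mass_norm > MASS_EPS) {
        const double g_new = S0[k] / mass_norm;
        delta = std::max(delta, std::abs(g_new - gamma[k]));
        gamma[k] = g_new;
      }
      if (S0[k] < MASS_EPS) { frozen = true; continue; }
      const double mu_new = S1[k] / S0[k];
      double s2_new = S2[k] / S0[k] - mu_new * mu_new;
      if (s2_new < var_floor) { s2_new = var_floor; floor_hit = true; }
      delta = std::max(delta, std::abs(mu_new - mu[k]));
      delta = std::max(delta, std::abs(s2_new - sigma2[k]));
      mu[k] = mu_new;
      sigma2[k] = s2_new;
    }
    if (family == 1) {
      if (T1 + T2 > MASS_EPS) {
        const double rho_new = T1 / (T1 + T2);
        delta = std::max(delta, std::abs(rho_new - rho));
        rho = rho_new;
      }
      if (T1 > MASS_EPS) {
        const double b1_new = std::max(TB1 / T1, MASS_EPS);
        delta = std::max(delta, std::abs(b1_new - beta1));
        beta1 = b1_new;
      } else if (pi > MASS_EPS && rho > MASS_EPS) {
        frozen = true;
      }
      if (T2 > MASS_EPS) {
        const double b2_new = std::max(TB2 / T2, MASS_EPS);
        delta = std::max(delta, std::abs(b2_new - beta2));
        beta2 = b2_new;
      } else if (pi > MASS_EPS && rho < 1.0 - MASS_EPS) {
        frozen = true;
      }
    }

    if (delta < tol) { converged = true; ++iter; break; }
    if (iter % 64 == 0) Rcpp::checkUserInterrupt();
  }
  const int n_iter = std::min(iter, max_iter);

  if (converged) {
    // final-parameter log-likelihood not yet in hand: one evaluation pass
    double ll = 0.0;
    for (uword i = 0; i < n; ++i) {
      const double yi = y[i], wi = w[i];
      if (wi <= 0) continue;
      double tot = 0.0;
      for (uword k = 0; k < K; ++k) {
        const double z = yi - mu[k];
        tot += (1.0 - pi) * gamma[k] / std::sqrt(2.0 * M_PI * sigma2[k]) *
               std::exp(-z * z * 0.5 / sigma2[k]);
      }
      if (family == 1) {
        if (yi < -xi1) tot += pi * rho / beta1 * std::exp(-(-yi - xi1) / beta1);
        else if (yi > xi2) tot += pi * (1.0 - rho) / beta2 * std::exp(-(yi - xi2) / beta2);
      } else if (yi >= a && yi <= b) {
        tot += pi * du;
      }
      ll += wi * std::log(std::max(tot, DENS_EPS));
    }
    trace.push_back(ll);
    ll_final = ll;
  }

  return Rcpp::List::create(
    Rcpp::Named("pi") = pi, Rcpp::Named("gamma") = gamma,
    Rcpp::Named("mu") = mu, Rcpp::Named("sigma2") = sigma2,
    Rcpp::Named("rho") = rho, Rcpp::Named("beta1") = beta1,
    Rcpp::Named("beta2") = beta2,
    Rcpp::Named("loglik") = ll_final,
    Rcpp::Named("loglik_trace") = Rcpp::NumericVector(trace.begin(), trace.end()),
    Rcpp::Named("n_iter") = n_iter, Rcpp::Named("converged") = converged,
    Rcpp::Named("floor_hit") = floor_hit, Rcpp::Named("frozen") = frozen);
}
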