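#include <Rcpp.h>
using namespace Rcpp;

static inline double invlogit(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// Marginal CJS log-likelihood of the whole (weight-collapsed) dataset,
// including the categorical sex terms: known-sex histories contribute
// log f (or log(1-f)) plus their sex-conditional likelihood; unknown-sex
// histories contribute the log of the f-weighted two-sex mixture.
//
// All per-occasion matrices are stored transposed (T rows x n columns)
// so the inner time loop walks contiguous memory. `farm` is 1-based
// (0 before first capture). Interval (t-1, t] survival uses the
// carry-forward covariates of occasion t-1 and gamma[t]; recapture at t
// uses the covariates of t and rho[t]. The latent alive state is summed
// out with the chi backward recursion.

static double history_ll(const int* y, const int* farm, const double* selev,
                         const int* edge, const int* firstyear,
                         const int T, const int f0, const int male,
                         const double* beta0, const double* beta1,
                         const double beta2,
                         const double* alpha0, const double* alpha1,
                         const double* delta, const double* gamma,
                         const double* rho,
                         double* phi, double* p) {
  if (f0 == T - 1) return 0.0;  // first captured at final occasion
  int last = f0;
  for (int t = f0 + 1; t < T; ++t) {
    const bool juv = firstyear[t] == 1;
    const int cls = juv ? 2 : (male ? 0 : 1);
    const double lphi = beta0[cls] + beta1[cls] * selev[t - 1] +
      beta2 * edge[t - 1] + delta[farm[t - 1] - 1] + gamma[t];
    const double lp = alpha0[0] + (juv ? alpha0[1] : 0.0) +
      (alpha1[0] + (juv ? alpha1[1] : 0.0)) * selev[t] + rho[t];
    phi[t] = invlogit(lphi);
    p[t] = invlogit(lp);
    if (y[t] == 1) last = t;
  }
  double ll = 0.0;
  for (int t = f0 + 1; t <= last; ++t)
    ll += std::log(phi[t]) +
      (y[t] == 1 ? std::log(p[t]) : std::log1p(-p[t]));
  double chi = 1.0;  // chi_{T-1} = 1, backward to chi_last
  for (int t = T - 1; t > last; --t)
    chi = (1.0 - phi[t]) + phi[t] * (1.0 - p[t]) * chi;
  return ll + std::log(chi);
}

// [[Rcpp::export]]
double cjs_loglik_cpp(IntegerVector first, IntegerMatrix y,
                      IntegerMatrix farm, NumericMatrix selev,
                      IntegerMatrix edge, IntegerMatrix firstyear,
                      IntegerVector sex_code, NumericVector weight,
                      NumericVector beta0, NumericVector beta1, double beta2,
                      NumericVector alpha0, NumericVector alpha1,
                      double f_male, NumericVector delta, NumericVector gamma,
                      NumericVector rho) {
  const int n = first.size();
  const int T = y.nrow();  // transposed layout: T x n
  const double lf = std::log(f_male), l1f = std::log1p(-f_male);
  const int* yp = INTEGER(y); const int* fp = INTEGER(farm);
  const double* sp = REAL(selev); const int* ep = INTEGER(edge);
  const int* fyp = INTEGER(firstyear);
  const double* b0 = REAL(beta0); const double* b1 = REAL(beta1);
  const double* a0 = REAL(alpha0); const double* a1 = REAL(alpha1);
  const double* dl = REAL(delta); const double* gm = REAL(gamma);
  const double* rh = REAL(rho);
  std::vector<double> phi(T), p(T);
  double total = 0.0;
  for (int i = 0; i < n; ++i) {
    const int off = i * T;
    const int f0 = first[i] - 1;  // 0-based
    double ll;
    if (sex_code[i] == 0) {        // known male
      ll = lf + history_ll(yp + off, fp + off, sp + off, ep + off, fyp + off,
                           T, f0, 1, b0, b1, beta2, a0, a1, dl, gm, rh,
                           phi.data(), p.data());
    } else if (sex_code[i] == 1) { // known female
      ll = l1f + history_ll(yp + off, fp + off, sp + off, ep + off, fyp + off,
                            T, f0, 0, b0, b1, beta2, a0, a1, dl, gm, rh,
                            phi.data(), p.data());
    } else {                       // unknown: mixture, log-sum-exp
      const double lm = lf + history_ll(yp + off, fp + off, sp + off,
                                        ep + off, fyp + off, T, f0, 1,
                                        b0, b1, beta2, a0, a1, dl, gm, rh,
                                        phi.data(), p.data());
      const double lw = l1f + history_ll(yp + off, fp + off, sp + off,
                                         ep + off, fyp + off, T, f0, 0,
                                         b0, b1, beta2, a0, a1, dl, gm, rh,
                                         phi.data(), p.data());
      const double m = std::max(lm, lw);
      ll = m + std::log(std::exp(lm - m) + std::exp(lw - m));
    }
    total += weight[i] * ll;
  }
  return total;
}
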