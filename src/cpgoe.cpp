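#include <Rcpp.h>
using namespace Rcpp;

// First-order Markov chain simulation over the DNA alphabet.
// P is a 4x4 row-stochastic transition matrix (rows/cols in A,C,G,T order),
// pi0 the distribution of the first base. Uses R's RNG so results are
// reproducible under set.seed().
// [[Rcpp::export]]
std::string sim_markov_chain(int n, NumericMatrix P, NumericVector pi0) {
  static const char bases[] = "ACGT";
  if (n < 1) return std::string();
  double cpi[4];
  double cP[4][4];
  double acc = 0.0;
  for (int j = 0; j < 4; ++j) {
    acc += pi0[j];
    cpi[j] = acc;
  }
  cpi[3] = 1.0;  // guard against rounding
  for (int i = 0; i < 4; ++i) {
    acc = 0.0;
    for (int j = 0; j < 4; ++j) {
      acc += P(i, j);
      cP[i][j] = acc;
    }
    cP[i][3] = 1.0;
  }
  std::string s(n, 'A');
  double u = unif_rand();
  int st = 0;
  while (u > cpi[st] && st < 3) ++st;
  s[0] = bases[st];
  for (int k = 1; k < n; ++k) {
    u = unif_rand();
    int nx = 0;
    while (u > cP[st][nx] && nx < 3) ++nx;
    st = nx;
    s[k] = bases[st];
  }
  return s;
}

// One EM run for a univariate Gaussian mixture from given initial
// parameters. Components are NOT sorted here; the R driver does that.
// Returns the parameters, the per-iteration log-likelihood trace
// (non-decreasing by the EM guarantee), and a convergence flag.
// Convergence: successive log-likelihood improvement < tol.
// [[Rcpp::export]]
List gmm_em_run(NumericVector x, NumericVector w0, NumericVector mu0,
                NumericVector var0, bool equal_var, double tol,
                int max_iter, double var_floor) {
  const int n = x.size();
  const int K = w0.size();
  std::vector<double> w(w0.begin(), w0.end());
  std::vector<double> mu(mu0.begin(), mu0.end());
  std::vector<double> var(var0.begin(), var0.end());
  std::vector<double> trace;
  trace.reserve(64);
  NumericMatrix resp(n, K);
  std::vector<double> lc(K), prec(K), logd(K);
  const double log2pi = std::log(2.0 * M_PI);
  double ll = R_NegInf, ll_old = R_NegInf;
  bool converged = false, degenerate = false;
  int iter = 0;

  for (iter = 1; iter <= max_iter; ++iter) {
    // E-step: log-likelihood at current parameters + responsibilities
    for (int k = 0; k < K; ++k) {
      lc[k] = std::log(w[k]) - 0.5 * (log2pi + std::log(var[k]));
      prec[k] = 0.5 / var[k];
    }
    ll = 0.0;
    for (int i = 0; i < n; ++i) {
      double m = R_NegInf;
      for (int k = 0; k < K; ++k) {
        double z = x[i] - mu[k];
        logd[k] = lc[k] - prec[k] * z * z;
        if (logd[k] > m) m = logd[k];
      }
      double s = 0.0;
      for (int k = 0; k < K; ++k) s += std::exp(logd[k] - m);
      double lse = m + std::log(s);
      ll += lse;
      for (int k = 0; k < K; ++k) resp(i, k) = std::exp(logd[k] - lse);
    }
    trace.push_back(ll);
    if (iter > 1 && std::fabs(ll - ll_old) < tol) {
      converged = true;
      break;
    }
    ll_old = ll;

    // M-step
    double shared = 0.0;
    for (int k = 0; k < K; ++k) {
      double nk = 0.0, sx = 0.0;
      for (int i = 0; i < n; ++i) {
        nk += resp(i, k);
        sx += resp(i, k) * x[i];
      }
      if (nk < 1e-10) {
        degenerate = true;
        break;
      }
      double mk = sx / nk;
      double sv = 0.0;
      for (int i = 0; i < n; ++i) {
        double z = x[i] - mk;
        sv += resp(i, k) * z * z;
      }
      w[k] = nk / n;
      mu[k] = mk;
      if (equal_var) {
        shared += sv;
      } else {
        var[k] = std::max(sv / nk, var_floor);
      }
    }
    if (degenerate) break;
    if (equal_var) {
      double v = std::max(shared / n, var_floor);
      for (int k = 0; k < K; ++k) var[k] = v;
    }
  }

  if (iter > max_iter) iter = max_iter;
  if (!converged && !degenerate) {
    // loop exhausted max_iter: re-evaluate ll at the final parameters
    for (int k = 0; k < K; ++k) {
      lc[k] = std::log(w[k]) - 0.5 * (log2pi + std::log(var[k]));
      prec[k] = 0.5 / var[k];
    }
    ll = 0.0;
    for (int i = 0; i < n; ++i) {
      double m = R_NegInf;
      for (int k = 0; k < K; ++k) {
        double z = x[i] - mu[k];
        logd[k] = lc[k] - prec[k] * z * z;
        if (logd[k] > m) m = logd[k];
      }
      double s = 0.0;
      for (int k = 0; k < K; ++k) s += std::exp(logd[k] - m);
      ll += m + std::log(s);
    }
    trace.push_back(ll);
  }
  return List::create(
      _["weights"] = NumericVector(w.begin(), w.end()),
      _["means"] = NumericVector(mu.begin(), mu.end()),
      _["variances"] = NumericVector(var.begin(), var.end()),
      _["loglik"] = ll,
      _["ll_trace"] = NumericVector(trace.begin(), trace.end()),
      _["n_iter"] = iter,
      _["converged"] = converged,
      _["degenerate"] = degenerate);
}

// Posterior responsibilities for fixed parameters (used by classify()).
// [[Rcpp::export]]
NumericMatrix gmm_posterior(NumericVector x, NumericVector w,
                            NumericVector mu, NumericVector var) {
  const int n = x.size();
  const int K = w.size();
  NumericMatrix resp(n, K);
  std::vector<double> logw(K), logd(K);
  const double log2pi = std::log(2.0 * M_PI);
  for (int k = 0; k < K; ++k) logw[k] = std::log(w[k]);
  for (int i = 0; i < n; ++i) {
    double m = R_NegInf;
    for (int k = 0; k < K; ++k) {
      double z = x[i] - mu[k];
      logd[k] = logw[k] - 0.5 * (log2pi + std::log(var[k]) + z * z / var[k]);
      if (logd[k] > m) m = logd[k];
    }
    double s = 0.0;
    for (int k = 0; k < K; ++k) s += std::exp(logd[k] - m);
    double lse = m + std::log(s);
    for (int k = 0; k < K; ++k) resp(i, k) = std::exp(logd[k] - lse);
  }
  return resp;
}
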