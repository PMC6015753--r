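// Adaptive Metropolis-within-Gibbs sampler for the tracer mixing model.
//
// The model list is assembled by build_model_internals() on the R side;
// the scalar-parameter layout here must match param_layout() exactly
// (cross-checked by tests against the pure-R likelihood).
//
// Layout of the unconstrained parameter vector theta:
//   [beta0 (K-1)]
//   [fixed coefs, F blocks of (K-1)]
//   for each random factor r: [offsets L_r x (K-1), level-major][log gamma_r]
//   error params: residual -> J log sigma; proc*mult -> J log xi; process -> none
//   source params (summary/raw): [mu K x J, source-major][log omega K x J]
//   source params (raw+covariance): [mu K x J][per source: J log-diag then
//     J(J-1)/2 row-major lower-triangle Cholesky entries]
//
// For the diagonal treatments the sampler keeps per-row caches (p, mixing
// weights, mixture mean, process variance, final variance, per-tracer
// log-likelihood) so that error- and source-parameter updates cost O(N)
// instead of O(N*K*J); composition parameters (beta0, coefficients,
// random offsets) recompute only the rows they touch. The covariance
// treatment couples tracers and falls back to full row recomputation.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

constexpr double LOG2PI = 1.8378770664093453;

struct Model {
  int N, J, K, Km1, F, R;
  NumericMatrix Y;        // N x J
  NumericMatrix V;        // K x (K-1) ILR basis
  NumericMatrix lambda;   // K x J discrimination means
  NumericMatrix tau2;     // K x J discrimination variances
  NumericMatrix conc;     // K x J (ignored unless use_conc)
  bool use_conc;
  int error_kind;         // 0 residual, 1 process, 2 process*multiplicative
  int src_treat;          // 0 fixed, 1 summary, 2 raw, 3 raw+covariance
  NumericMatrix src_mean; // K x J observed summaries
  NumericMatrix src_sd;   // K x J
  IntegerVector src_n;    // K
  NumericMatrix raw;      // ntot x J (treat 2/3)
  IntegerVector raw_id;   // ntot, 1-based source index
  NumericMatrix Xfix;     // N x F
  IntegerMatrix ran_index;// N x R, 1-based level
  IntegerVector ran_L;    // R
  NumericVector alpha;    // K
  double coef_sd, gamma_upper, sigma_upper, xi_scale, mu_prior_sd;

  int off_beta0, off_B;
  std::vector<int> off_ran, off_gamma;
  int off_err, n_err, off_mu, off_om, P;
  std::vector<std::vector<std::vector<int>>> rows_by_level; // [r][l] -> rows

  explicit Model(const List& m) :
    Y(as<NumericMatrix>(m["Y"])), V(as<NumericMatrix>(m["V"])),
    lambda(as<NumericMatrix>(m["lambda"])), tau2(as<NumericMatrix>(m["tau2"])),
    conc(as<NumericMatrix>(m["conc"])), use_conc(as<bool>(m["use_conc"])),
    error_kind(as<int>(m["error_kind"])), src_treat(as<int>(m["src_treat"])),
    src_mean(as<NumericMatrix>(m["src_mean"])), src_sd(as<NumericMatrix>(m["src_sd"])),
    src_n(as<IntegerVector>(m["src_n"])), raw(as<NumericMatrix>(m["raw"])),
    raw_id(as<IntegerVector>(m["raw_id"])), Xfix(as<NumericMatrix>(m["Xfix"])),
    ran_index(as<IntegerMatrix>(m["ran_index"])), ran_L(as<IntegerVector>(m["ran_L"])),
    alpha(as<NumericVector>(m["alpha"])),
    coef_sd(as<double>(m["coef_sd"])), gamma_upper(as<double>(m["gamma_upper"])),
    sigma_upper(as<double>(m["sigma_upper"])), xi_scale(as<double>(m["xi_scale"])),
    mu_prior_sd(as<double>(m["mu_prior_sd"]))
  {
    N = Y.nrow(); J = Y.ncol(); K = V.nrow(); Km1 = K - 1;
    F = Xfix.ncol(); R = ran_L.size();
    off_beta0 = 0;
    off_B = off_beta0 + Km1;
    int pos = off_B + F * Km1;
    off_ran.resize(R); off_gamma.resize(R);
    rows_by_level.resize(R);
    for (int r = 0; r < R; ++r) {
      off_ran[r] = pos;
      pos += ran_L[r] * Km1;
      off_gamma[r] = pos++;
      rows_by_level[r].assign(ran_L[r], {});
      for (int i = 0; i < N; ++i)
        rows_by_level[r][ran_index(i, r) - 1].push_back(i);
    }
    off_err = pos;
    n_err = (error_kind == 0 || error_kind == 2) ? J : 0;
    pos += n_err;
    off_mu = pos;
    if (src_treat == 1 || src_treat == 2) {
      pos += K * J; off_om = pos; pos += K * J;
    } else if (src_treat == 3) {
      pos += K * J; off_om = pos; pos += K * (J + J * (J - 1) / 2);
    } else {
      off_om = pos;
    }
    P = pos;
  }

  double smu(const std::vector<double>& th, int k, int j) const {
    return src_treat == 0 ? src_mean(k, j) : th[off_mu + k * J + j];
  }
  double svar(const std::vector<double>& th, int k, int j) const {
    if (src_treat == 0) return src_sd(k, j) * src_sd(k, j);
    double om = std::exp(th[off_om + k * J + j]);
    return om * om;
  }
  void chol_k(const std::vector<double>& th, int k, std::vector<double>& L) const {
    int base = off_om + k * (J + J * (J - 1) / 2);
    std::fill(L.begin(), L.end(), 0.0);
    for (int j = 0; j < J; ++j) L[j * J + j] = std::exp(th[base + j]);
    int q = base + J;
    for (int j1 = 1; j1 < J; ++j1)
      for (int j2 = 0; j2 < j1; ++j2) L[j1 * J + j2] = th[q++];
  }
};

inline double dnorm_log(double x, double mu, double sd) {
  double z = (x - mu) / sd;
  return -0.5 * LOG2PI - std::log(sd) - 0.5 * z * z;
}

inline double dchisq_log(double x, double df) {
  if (x <= 0.0) return R_NegInf;
  double h = df / 2.0;
  return -h * std::log(2.0) - std::lgamma(h) + (h - 1.0) * std::log(x) - x / 2.0;
}

// Composition for row i under theta: p (K), written into p_out.
void row_composition(const Model& M, const std::vector<double>& th, int i,
                     double* p_out) {
  const int K = M.K, Km1 = M.Km1;
  std::vector<double> z(Km1);
  for (int c = 0; c < Km1; ++c) {
    double v = th[M.off_beta0 + c];
    for (int f = 0; f < M.F; ++f) v += M.Xfix(i, f) * th[M.off_B + f * Km1 + c];
    for (int r = 0; r < M.R; ++r)
      v += th[M.off_ran[r] + (M.ran_index(i, r) - 1) * Km1 + c];
    z[c] = v;
  }
  double mx = R_NegInf;
  for (int k = 0; k < K; ++k) {
    double y = 0.0;
    for (int c = 0; c < Km1; ++c) y += M.V(k, c) * z[c];
    p_out[k] = y; if (y > mx) mx = y;
  }
  double s = 0.0;
  for (int k = 0; k < K; ++k) { p_out[k] = std::exp(p_out[k] - mx); s += p_out[k]; }
  for (int k = 0; k < K; ++k) p_out[k] /= s;
}

// Full mixture log-likelihood for row i (any treatment, incl. covariance).
double row_loglik(const Model& M, const std::vector<double>& th, int i) {
  const int J = M.J, K = M.K;
  std::vector<double> p(K);
  row_composition(M, th, i, p.data());

  std::vector<double> q(K * J);
  if (M.use_conc) {
    for (int j = 0; j < J; ++j) {
      double tot = 0.0;
      for (int k = 0; k < K; ++k) { q[k * J + j] = p[k] * M.conc(k, j); tot += q[k * J + j]; }
      for (int k = 0; k < K; ++k) q[k * J + j] /= tot;
    }
  } else {
    for (int k = 0; k < K; ++k)
      for (int j = 0; j < J; ++j) q[k * J + j] = p[k];
  }

  std::vector<double> mean(J, 0.0);
  for (int j = 0; j < J; ++j)
    for (int k = 0; k < K; ++k)
      mean[j] += q[k * J + j] * (M.smu(th, k, j) + M.lambda(k, j));

  if (M.src_treat == 3) {
    std::vector<double> L(J * J), Sk(J * J), Om(J * J, 0.0);
    for (int k = 0; k < K; ++k) {
      M.chol_k(th, k, L);
      for (int a = 0; a < J; ++a)
        for (int b = 0; b <= a; ++b) {
          double v = 0.0;
          for (int c = 0; c <= b; ++c) v += L[a * J + c] * L[b * J + c];
          Sk[a * J + b] = Sk[b * J + a] = v;
        }
      for (int a = 0; a < J; ++a) Sk[a * J + a] += M.tau2(k, a);
      for (int a = 0; a < J; ++a)
        for (int b = 0; b < J; ++b)
          Om[a * J + b] += q[k * J + a] * q[k * J + b] * Sk[a * J + b];
    }
    if (M.error_kind == 2) {
      for (int a = 0; a < J; ++a)
        for (int b = 0; b < J; ++b)
          Om[a * J + b] *= std::sqrt(std::exp(th[M.off_err + a]) *
                                     std::exp(th[M.off_err + b]));
    }
    std::vector<double> C(J * J, 0.0), w(J);
    for (int a = 0; a < J; ++a)
      for (int b = 0; b <= a; ++b) {
        double v = Om[a * J + b];
        for (int c = 0; c < b; ++c) v -= C[a * J + c] * C[b * J + c];
        if (a == b) {
          if (v <= 0.0) return R_NegInf;
          C[a * J + a] = std::sqrt(v);
        } else {
          C[a * J + b] = v / C[b * J + b];
        }
      }
    double ll = -0.5 * J * LOG2PI, quad = 0.0;
    for (int a = 0; a < J; ++a) {
      double v = M.Y(i, a) - mean[a];
      for (int c = 0; c < a; ++c) v -= C[a * J + c] * w[c];
      w[a] = v / C[a * J + a];
      ll -= std::log(C[a * J + a]);
      quad += w[a] * w[a];
    }
    return ll - 0.5 * quad;
  }

  double ll = 0.0;
  for (int j = 0; j < J; ++j) {
    double var;
    if (M.error_kind == 0) {
      double sg = std::exp(th[M.off_err + j]);
      var = sg * sg;
    } else {
      var = 0.0;
      for (int k = 0; k < K; ++k) {
        double qk = q[k * J + j];
        var += qk * qk * (M.svar(th, k, j) + M.tau2(k, j));
      }
      if (M.error_kind == 2) var *= std::exp(th[M.off_err + j]);
    }
    if (!(var > 0.0)) return R_NegInf;
    ll += dnorm_log(M.Y(i, j), mean[j], std::sqrt(var));
  }
  return ll;
}

double src_loglik(const Model& M, const std::vector<double>& th) {
  if (M.src_treat == 0) return 0.0;
  const int J = M.J, K = M.K;
  double ll = 0.0;
  if (M.src_treat == 1) {
    for (int k = 0; k < K; ++k)
      for (int j = 0; j < J; ++j) {
        double mu = th[M.off_mu + k * J + j];
        double om = std::exp(th[M.off_om + k * J + j]);
        double n = M.src_n[k];
        ll += dnorm_log(M.src_mean(k, j), mu, om / std::sqrt(n));
        if (n > 1.5) {
          double stat = (n - 1.0) * M.src_sd(k, j) * M.src_sd(k, j) / (om * om);
          ll += dchisq_log(stat, n - 1.0) + std::log((n - 1.0) / (om * om));
        }
      }
  } else if (M.src_treat == 2) {
    for (int r = 0; r < M.raw.nrow(); ++r) {
      int k = M.raw_id[r] - 1;
      for (int j = 0; j < J; ++j) {
        double mu = th[M.off_mu + k * J + j];
        double om = std::exp(th[M.off_om + k * J + j]);
        ll += dnorm_log(M.raw(r, j), mu, om);
      }
    }
  } else {
    std::vector<double> L(J * J), w(J);
    for (int r = 0; r < M.raw.nrow(); ++r) {
      int k = M.raw_id[r] - 1;
      M.chol_k(th, k, L);
      double lr = -0.5 * J * LOG2PI, quad = 0.0;
      for (int a = 0; a < J; ++a) {
        double v = M.raw(r, a) - th[M.off_mu + k * J + a];
        for (int c = 0; c < a; ++c) v -= L[a * J + c] * w[c];
        w[a] = v / L[a * J + a];
        lr -= std::log(L[a * J + a]);
        quad += w[a] * w[a];
      }
      ll += lr - 0.5 * quad;
    }
  }
  return ll;
}

double log_prior(const Model& M, const std::vector<double>& th) {
  const int K = M.K, Km1 = M.Km1, J = M.J;
  double lp = 0.0;
  {
    std::vector<double> p(K);
    double mx = R_NegInf;
    for (int k = 0; k < K; ++k) {
      double y = 0.0;
      for (int c = 0; c < Km1; ++c) y += M.V(k, c) * th[M.off_beta0 + c];
      p[k] = y; if (y > mx) mx = y;
    }
    double s = 0.0;
    for (int k = 0; k < K; ++k) { p[k] = std::exp(p[k] - mx); s += p[k]; }
    for (int k = 0; k < K; ++k) {
      p[k] /= s;
      lp += (M.alpha[k] - 1.0) * std::log(p[k]) + std::log(p[k]);
    }
    lp += 0.5 * std::log((double)K);
  }
  for (int f = 0; f < M.F; ++f)
    for (int c = 0; c < Km1; ++c)
      lp += dnorm_log(th[M.off_B + f * Km1 + c], 0.0, M.coef_sd);
  for (int r = 0; r < M.R; ++r) {
    double g = std::exp(th[M.off_gamma[r]]);
    if (g >= M.gamma_upper) return R_NegInf;
    lp += 2.0 * th[M.off_gamma[r]];   // gamma^2 ~ U(0, up^2) + log-scale Jacobian
    for (int l = 0; l < M.ran_L[r]; ++l)
      for (int c = 0; c < Km1; ++c)
        lp += dnorm_log(th[M.off_ran[r] + l * Km1 + c], 0.0, g);
  }
  if (M.error_kind == 0) {
    for (int j = 0; j < J; ++j) {
      double sg = std::exp(th[M.off_err + j]);
      if (sg >= M.sigma_upper) return R_NegInf;
      lp += th[M.off_err + j];
    }
  } else if (M.error_kind == 2) {
    for (int j = 0; j < J; ++j) {
      double xi = std::exp(th[M.off_err + j]);
      double r = xi / M.xi_scale;
      lp += th[M.off_err + j] - std::log1p(r * r);
    }
  }
  if (M.src_treat == 1 || M.src_treat == 2) {
    for (int k = 0; k < K; ++k)
      for (int j = 0; j < J; ++j) {
        lp += dnorm_log(th[M.off_mu + k * J + j], 0.0, M.mu_prior_sd);
        double u = th[M.off_om + k * J + j];
        lp += -0.002 * u - 0.001 * std::exp(-2.0 * u);
      }
  } else if (M.src_treat == 3) {
    for (int k = 0; k < K; ++k) {
      for (int j = 0; j < J; ++j)
        lp += dnorm_log(th[M.off_mu + k * J + j], 0.0, M.mu_prior_sd);
      int base = M.off_om + k * (J + J * (J - 1) / 2);
      for (int j = 0; j < J; ++j) {
        double u = th[base + j];
        lp += -0.002 * u - 0.001 * std::exp(-2.0 * u);
      }
      for (int q = 0; q < J * (J - 1) / 2; ++q)
        lp += dnorm_log(th[base + J + q], 0.0, 100.0);
    }
  }
  return lp;
}

// Per-row caches for the diagonal (non-covariance) fast path.
struct Cache {
  std::vector<double> p;     // N x K
  std::vector<double> q;     // N x K x J mixing weights
  std::vector<double> mean;  // N x J
  std::vector<double> pvar;  // N x J process part sum q^2 (omega^2 + tau^2)
  std::vector<double> var;   // N x J final variance
  std::vector<double> llj;   // N x J per-tracer log-likelihood
  std::vector<double> rowll; // N
  void alloc(int N, int K, int J) {
    p.assign(N * K, 0.0); q.assign(N * K * J, 0.0);
    mean.assign(N * J, 0.0); pvar.assign(N * J, 0.0);
    var.assign(N * J, 0.0); llj.assign(N * J, 0.0); rowll.assign(N, 0.0);
  }
};

// Recompute every cache entry for row i; returns false on non-finite.
bool refresh_row(const Model& M, const std::vector<double>& th, int i, Cache& C) {
  const int K = M.K, J = M.J;
  row_composition(M, th, i, &C.p[i * K]);
  for (int j = 0; j < J; ++j) {
    if (M.use_conc) {
      double tot = 0.0;
      for (int k = 0; k < K; ++k) {
        C.q[(i * K + k) * J + j] = C.p[i * K + k] * M.conc(k, j);
        tot += C.q[(i * K + k) * J + j];
      }
      for (int k = 0; k < K; ++k) C.q[(i * K + k) * J + j] /= tot;
    } else {
      for (int k = 0; k < K; ++k) C.q[(i * K + k) * J + j] = C.p[i * K + k];
    }
    double m = 0.0, pv = 0.0;
    for (int k = 0; k < K; ++k) {
      double qk = C.q[(i * K + k) * J + j];
      m += qk * (M.smu(th, k, j) + M.lambda(k, j));
      pv += qk * qk * (M.svar(th, k, j) + M.tau2(k, j));
    }
    C.mean[i * J + j] = m;
    C.pvar[i * J + j] = pv;
    double v;
    if (M.error_kind == 0) {
      double sg = std::exp(th[M.off_err + j]);
      v = sg * sg;
    } else if (M.error_kind == 2) {
      v = pv * std::exp(th[M.off_err + j]);
    } else {
      v = pv;
    }
    if (!(v > 0.0)) return false;
    C.var[i * J + j] = v;
    C.llj[i * J + j] = dnorm_log(M.Y(i, j), m, std::sqrt(v));
    if (!R_finite(C.llj[i * J + j])) return false;
  }
  double s = 0.0;
  for (int j = 0; j < J; ++j) s += C.llj[i * J + j];
  C.rowll[i] = s;
  return true;
}

} // namespace

// [[Rcpp::export]]
List logpost_components_cpp(List model, NumericVector theta) {
  Model M(model);
  if ((int)theta.size() != M.P)
    stop("theta has length %d but the model expects %d", theta.size(), M.P);
  std::vector<double> th(theta.begin(), theta.end());
  NumericVector rowll(M.N);
  for (int i = 0; i < M.N; ++i) rowll[i] = row_loglik(M, th, i);
  return List::create(_["rowll"] = rowll,
                      _["src"] = src_loglik(M, th),
                      _["prior"] = log_prior(M, th),
                      _["n_par"] = M.P);
}

// [[Rcpp::export]]
List run_chain_cpp(List model, NumericVector theta_init, int n_iter, int n_burn,
                   int thin, int adapt_batch, bool likelihood_off) {
  Model M(model);
  const int P = M.P, N = M.N, J = M.J, K = M.K, Km1 = M.Km1;
  if ((int)theta_init.size() != P)
    stop("theta_init has length %d but the model expects %d", theta_init.size(), P);
  std::vector<double> th(theta_init.begin(), theta_init.end());
  const bool fast = (M.src_treat != 3) && !likelihood_off;
  const bool slow = (M.src_treat == 3) && !likelihood_off;

  // classify parameters
  // 0 composition (recompute rows), 1 error param j, 2 source mu (k,j),
  // 3 source log-omega (k,j), 4 gamma (prior only), 5 covariance source param
  std::vector<int> cls(P, 0), par_j(P, -1), par_k(P, -1);
  std::vector<const std::vector<int>*> par_rows(P, nullptr); // null = all rows
  for (int r = 0; r < M.R; ++r) {
    for (int l = 0; l < M.ran_L[r]; ++l)
      for (int c = 0; c < Km1; ++c)
        par_rows[M.off_ran[r] + l * Km1 + c] = &M.rows_by_level[r][l];
    cls[M.off_gamma[r]] = 4;
  }
  for (int j = 0; j < M.n_err; ++j) { cls[M.off_err + j] = 1; par_j[M.off_err + j] = j; }
  if (M.src_treat == 1 || M.src_treat == 2) {
    for (int k = 0; k < K; ++k)
      for (int j = 0; j < J; ++j) {
        cls[M.off_mu + k * J + j] = 2; par_k[M.off_mu + k * J + j] = k;
        par_j[M.off_mu + k * J + j] = j;
        cls[M.off_om + k * J + j] = 3; par_k[M.off_om + k * J + j] = k;
        par_j[M.off_om + k * J + j] = j;
      }
  } else if (M.src_treat == 3) {
    for (int p = M.off_mu; p < P; ++p) cls[p] = 5;
  }

  Cache C;
  std::vector<double> rowll_slow(N), prop_rows(N);
  double cur_src = 0.0, cur_prior = log_prior(M, th);
  if (!R_finite(cur_prior)) stop("initial state has zero prior density");
  if (fast) {
    C.alloc(N, K, J);
    for (int i = 0; i < N; ++i)
      if (!refresh_row(M, th, i, C))
        stop("non-finite initial log-likelihood at mixture row %d", i + 1);
    cur_src = src_loglik(M, th);
  } else if (slow) {
    for (int i = 0; i < N; ++i) {
      rowll_slow[i] = row_loglik(M, th, i);
      if (!R_finite(rowll_slow[i]))
        stop("non-finite initial log-likelihood at mixture row %d", i + 1);
    }
    cur_src = src_loglik(M, th);
  }

  // scratch buffers for fast partial updates
  Cache S;
  if (fast) S.alloc(N, K, J);
  std::vector<double> scr_mean(N), scr_pvar(N), scr_var(N), scr_llj(N);

  std::vector<double> lstep(P, std::log(0.5));
  std::vector<int> n_acc(P, 0), n_try(P, 0), b_acc(P, 0), b_try(P, 0);
  int n_save = (n_iter - n_burn) / thin;
  NumericMatrix draws(n_save, P), ll_out(n_save, N);
  int saved = 0, batch_no = 0;

  // Covariance-adaptive joint update over the global composition block
  // (beta0 + fixed coefficients): componentwise moves mix poorly when the
  // ILR coordinates are strongly correlated a posteriori.
  const int bd = Km1 + M.F * Km1;
  std::vector<double> bmean(bd, 0.0), bM2(bd * bd, 0.0), bchol(bd * bd, 0.0);
  std::vector<double> bx(bd), bz(bd), bdx(bd);
  for (int a = 0; a < bd; ++a) bchol[a * bd + a] = 1.0;
  double blscale = std::log(0.1 / std::sqrt((double)bd));
  long bn = 0;
  int blk_acc = 0, blk_try = 0;

  for (int it = 1; it <= n_iter; ++it) {
    for (int p = 0; p < P; ++p) {
      double old = th[p];
      th[p] = old + std::exp(lstep[p]) * norm_rand();
      double new_prior = log_prior(M, th);
      double dlp = new_prior - cur_prior;
      double new_src = cur_src;
      bool ok = R_finite(new_prior);
      int mode = -1;              // which accept-bookkeeping path was used
      int nrows = 0;
      const std::vector<int>* rows = nullptr;
      int jj = par_j[p], kk = par_k[p];

      if (ok && fast) {
        switch (cls[p]) {
        case 0: { // composition: refresh affected rows fully (into scratch)
          mode = 0;
          rows = par_rows[p];
          nrows = rows ? (int)rows->size() : N;
          for (int a = 0; a < nrows && ok; ++a) {
            int i = rows ? (*rows)[a] : a;
            ok = refresh_row(M, th, i, S);
            if (ok) dlp += S.rowll[i] - C.rowll[i];
          }
          break;
        }
        case 1: { // error parameter for tracer jj: variance-only change
          mode = 1;
          double e = std::exp(th[p]);
          for (int i = 0; i < N && ok; ++i) {
            double v = (M.error_kind == 0) ? e * e : C.pvar[i * J + jj] * e;
            if (!(v > 0.0)) { ok = false; break; }
            scr_var[i] = v;
            scr_llj[i] = dnorm_log(M.Y(i, jj), C.mean[i * J + jj], std::sqrt(v));
            ok = R_finite(scr_llj[i]);
            dlp += scr_llj[i] - C.llj[i * J + jj];
          }
          break;
        }
        case 2: { // source mean (kk, jj): mean shift by q * dmu
          mode = 2;
          new_src = src_loglik(M, th);
          ok = R_finite(new_src);
          dlp += new_src - cur_src;
          double dmu = th[p] - old;
          for (int i = 0; i < N && ok; ++i) {
            scr_mean[i] = C.mean[i * J + jj] + C.q[(i * K + kk) * J + jj] * dmu;
            scr_llj[i] = dnorm_log(M.Y(i, jj), scr_mean[i],
                                   std::sqrt(C.var[i * J + jj]));
            ok = R_finite(scr_llj[i]);
            dlp += scr_llj[i] - C.llj[i * J + jj];
          }
          break;
        }
        case 3: { // source SD (kk, jj): process-variance shift by q^2 * domega2
          mode = 3;
          new_src = src_loglik(M, th);
          ok = R_finite(new_src);
          dlp += new_src - cur_src;
          double o_new = std::exp(th[p]), o_old = std::exp(old);
          double dv = o_new * o_new - o_old * o_old;
          bool resid = (M.error_kind == 0);
          double xi_j = (M.error_kind == 2) ? std::exp(th[M.off_err + jj]) : 1.0;
          for (int i = 0; i < N && ok; ++i) {
            double qk = C.q[(i * K + kk) * J + jj];
            double pv = C.pvar[i * J + jj] + qk * qk * dv;
            scr_pvar[i] = pv;
            double v = resid ? C.var[i * J + jj] : pv * xi_j;
            if (!(v > 0.0)) { ok = false; break; }
            scr_var[i] = v;
            if (resid) {
              scr_llj[i] = C.llj[i * J + jj];   // likelihood untouched
            } else {
              scr_llj[i] = dnorm_log(M.Y(i, jj), C.mean[i * J + jj], std::sqrt(v));
              ok = R_finite(scr_llj[i]);
              dlp += scr_llj[i] - C.llj[i * J + jj];
            }
          }
          break;
        }
        case 4: mode = 4; break;   // gamma: prior-only
        }
      } else if (ok && slow) {
        mode = 5;
        if (cls[p] == 5 || cls[p] == 2 || cls[p] == 3) {
          new_src = src_loglik(M, th);
          ok = R_finite(new_src);
          dlp += new_src - cur_src;
        }
        if (ok && cls[p] != 4) {
          rows = par_rows[p];
          nrows = rows ? (int)rows->size() : N;
          for (int a = 0; a < nrows && ok; ++a) {
            int i = rows ? (*rows)[a] : a;
            prop_rows[a] = row_loglik(M, th, i);
            ok = R_finite(prop_rows[a]);
            dlp += prop_rows[a] - rowll_slow[i];
          }
        }
      }

      ++n_try[p]; ++b_try[p];
      if (ok && std::log(unif_rand()) < dlp) {
        cur_prior = new_prior;
        cur_src = new_src;
        switch (mode) {
        case 0:
          for (int a = 0; a < nrows; ++a) {
            int i = rows ? (*rows)[a] : a;
            for (int k = 0; k < K; ++k) C.p[i * K + k] = S.p[i * K + k];
            for (int k = 0; k < K; ++k)
              for (int j = 0; j < J; ++j)
                C.q[(i * K + k) * J + j] = S.q[(i * K + k) * J + j];
            for (int j = 0; j < J; ++j) {
              C.mean[i * J + j] = S.mean[i * J + j];
              C.pvar[i * J + j] = S.pvar[i * J + j];
              C.var[i * J + j] = S.var[i * J + j];
              C.llj[i * J + j] = S.llj[i * J + j];
            }
            C.rowll[i] = S.rowll[i];
          }
          break;
        case 1:
          for (int i = 0; i < N; ++i) {
            C.rowll[i] += scr_llj[i] - C.llj[i * J + jj];
            C.var[i * J + jj] = scr_var[i];
            C.llj[i * J + jj] = scr_llj[i];
          }
          break;
        case 2:
          for (int i = 0; i < N; ++i) {
            C.rowll[i] += scr_llj[i] - C.llj[i * J + jj];
            C.mean[i * J + jj] = scr_mean[i];
            C.llj[i * J + jj] = scr_llj[i];
          }
          break;
        case 3:
          for (int i = 0; i < N; ++i) {
            C.rowll[i] += scr_llj[i] - C.llj[i * J + jj];
            C.pvar[i * J + jj] = scr_pvar[i];
            C.var[i * J + jj] = scr_var[i];
            C.llj[i * J + jj] = scr_llj[i];
          }
          break;
        case 5:
          if (cls[p] != 4) {
            for (int a = 0; a < nrows; ++a)
              rowll_slow[rows ? (*rows)[a] : a] = prop_rows[a];
          }
          break;
        }
        ++n_acc[p]; ++b_acc[p];
      } else {
        th[p] = old;
      }
    }
    // joint block proposal on (beta0, fixed coefficients)
    if (bd > 0) {
      for (int a = 0; a < bd; ++a) bz[a] = norm_rand();
      double sc = std::exp(blscale);
      for (int a = 0; a < bd; ++a) {
        double v = 0.0;
        for (int b = 0; b <= a; ++b) v += bchol[a * bd + b] * bz[b];
        bdx[a] = sc * v;
      }
      std::vector<double> old_blk(bd);
      for (int a = 0; a < bd; ++a) { old_blk[a] = th[a]; th[a] += bdx[a]; }
      double new_prior = log_prior(M, th);
      double dlp = new_prior - cur_prior;
      bool ok = R_finite(new_prior);
      if (ok && fast) {
        for (int i = 0; i < N && ok; ++i) {
          ok = refresh_row(M, th, i, S);
          if (ok) dlp += S.rowll[i] - C.rowll[i];
        }
      } else if (ok && slow) {
        for (int i = 0; i < N && ok; ++i) {
          prop_rows[i] = row_loglik(M, th, i);
          ok = R_finite(prop_rows[i]);
          dlp += prop_rows[i] - rowll_slow[i];
        }
      }
      ++blk_try;
      if (ok && std::log(unif_rand()) < dlp) {
        cur_prior = new_prior;
        if (fast) { std::swap(C.p, S.p); std::swap(C.q, S.q);
          std::swap(C.mean, S.mean); std::swap(C.pvar, S.pvar);
          std::swap(C.var, S.var); std::swap(C.llj, S.llj);
          std::swap(C.rowll, S.rowll); }
        else if (slow) std::swap(rowll_slow, prop_rows);
        ++blk_acc;
      } else {
        for (int a = 0; a < bd; ++a) th[a] = old_blk[a];
      }
      // running moments of the block, burn-in only
      if (it <= n_burn) {
        ++bn;
        for (int a = 0; a < bd; ++a) bx[a] = th[a];
        for (int a = 0; a < bd; ++a) {
          double d1 = bx[a] - bmean[a];
          bmean[a] += d1 / bn;
          for (int b = 0; b <= a; ++b)
            bM2[a * bd + b] += d1 * (bx[b] - bmean[b]);
        }
      }
    }

    if (it <= n_burn && it % adapt_batch == 0) {
      ++batch_no;
      double delta = std::min(0.05, 1.0 / std::sqrt((double)batch_no));
      for (int p = 0; p < P; ++p) {
        double rate = b_try[p] ? (double)b_acc[p] / b_try[p] : 0.44;
        lstep[p] += (rate > 0.44 ? delta : -delta);
        b_acc[p] = 0; b_try[p] = 0;
      }
      if (bd > 0) {
        double rate = blk_try ? (double)blk_acc / blk_try : 0.25;
        blscale += (rate > 0.25 ? delta : -delta);
        blk_acc = 0; blk_try = 0;
        if (bn > 10 * bd) {
          // refresh proposal Cholesky from the running covariance
          std::vector<double> cov(bd * bd);
          for (int a = 0; a < bd; ++a)
            for (int b = 0; b <= a; ++b) {
              double v = bM2[a * bd + b] / (bn - 1);
              if (a == b) v += 1e-8;
              cov[a * bd + b] = cov[b * bd + a] = v;
            }
          std::vector<double> ch(bd * bd, 0.0);
          bool pd = true;
          for (int a = 0; a < bd && pd; ++a)
            for (int b = 0; b <= a && pd; ++b) {
              double v = cov[a * bd + b];
              for (int c = 0; c < b; ++c) v -= ch[a * bd + c] * ch[b * bd + c];
              if (a == b) {
                if (v <= 0.0) { pd = false; break; }
                ch[a * bd + a] = std::sqrt(v);
              } else {
                ch[a * bd + b] = v / ch[b * bd + b];
              }
            }
          if (pd) bchol = ch;
        }
      }
    }
    if (it > n_burn && (it - n_burn) % thin == 0 && saved < n_save) {
      for (int p = 0; p < P; ++p) draws(saved, p) = th[p];
      for (int i = 0; i < N; ++i)
        ll_out(saved, i) = fast ? C.rowll[i] : (slow ? rowll_slow[i] : 0.0);
      ++saved;
    }
  }
  NumericVector acc(P);
  for (int p = 0; p < P; ++p) acc[p] = n_try[p] ? (double)n_acc[p] / n_try[p] : NA_REAL;
  return List::create(_["draws"] = draws, _["loglik"] = ll_out,
                      _["accept"] = acc, _["n_par"] = P);
}
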