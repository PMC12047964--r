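#include <Rcpp.h>
#include <map>
using namespace Rcpp;

// Truncated-normal-on-[0,1] log density, with the log normalizer memoized per
// distinct (mu) -- the state space only produces dosages in {0, 1/3, 1/2, 2/3, 1}.
static inline double tn_log_norm(double mu, double sigma,
                                 std::map<double, double> &cache) {
  std::map<double, double>::iterator it = cache.find(mu);
  if (it != cache.end()) return it->second;
  double z = R::pnorm(1.0, mu, sigma, 1, 0) - R::pnorm(0.0, mu, sigma, 1, 0);
  double lz = std::log(z);
  cache[mu] = lz;
  return lz;
}

// Exact-boundary observations are point-mass events: they are scored as the
// density w.r.t. (delta0 + delta1 + Lebesgue), with the atom mass spread over
// a sub-measurement-precision bin of width BAF_ATOM_WIDTH so that atom-less
// states keep a finite (continuous-density) likelihood at the boundary.  The
// width is a common constant across states, so only atom presence matters.
#define BAF_ATOM_WIDTH 1e-6

static inline double emit_one(double b, double mu, int K, double pi0,
                              double sigma, bool else_atom,
                              std::map<double, double> &cache) {
  if (ISNAN(b)) return 0.0;  // missing observation: unit likelihood
  if (K == 0) {
    return R::dnorm(b, 0.5, sigma, 1) - tn_log_norm(0.5, sigma, cache);
  }
  double lcont = R::dnorm(b, mu, sigma, 1) - tn_log_norm(mu, sigma, cache);
  double atom_at = (mu == 0.0) ? 0.0 : (mu == 1.0 ? 1.0 : (else_atom ? 1.0 : -1.0));
  if (atom_at < 0.0) return lcont;  // pure truncated normal, no atom
  if (b == atom_at) {
    return std::log(pi0 / BAF_ATOM_WIDTH + (1.0 - pi0) * std::exp(lcont));
  }
  return std::log1p(-pi0) + lcont;
}

// [[Rcpp::export]]
NumericMatrix emission_matrix_cpp(NumericMatrix mu, IntegerVector K,
                                  NumericVector baf, double pi0, double sigma,
                                  bool else_atom) {
  int S = mu.nrow(), L = mu.ncol();
  if (K.size() != S) stop("K length must match rows of mu");
  if (baf.size() != L) stop("baf length must match cols of mu");
  NumericMatrix out(S, L);
  std::map<double, double> cache;
  for (int i = 0; i < L; i++) {
    double b = baf[i];
    for (int s = 0; s < S; s++) {
      out(s, i) = emit_one(b, mu(s, i), K[s], pi0, sigma, else_atom, cache);
    }
  }
  return out;
}

struct StepTrans {
  // per-K-group transition ingredients at one inter-site gap
  double qs, qd;          // base off-diagonal probs (within-K / between-K)
  std::vector<double> scale;  // per-K-group row scaling
  std::vector<double> diag;   // per-K-group diagonal
};

static void step_trans(double d, double r, double a, const std::vector<int> &nK,
                       int S, StepTrans &st) {
  double qs = r * d, qd = a * d;
  int G = (int)nK.size();
  double worst = 0.0;
  for (int g = 0; g < G; g++) {
    if (nK[g] == 0) continue;
    double off = qs * (nK[g] - 1) + qd * (S - nK[g]);
    if (off > worst) worst = off;
  }
  if (worst > 0.99) {
    // rate-to-probability transform for pathological gaps, then cap rows
    qs = 1.0 - std::exp(-r * d);
    qd = 1.0 - std::exp(-a * d);
  }
  st.qs = qs;
  st.qd = qd;
  st.scale.assign(G, 1.0);
  st.diag.assign(G, 1.0);
  for (int g = 0; g < G; g++) {
    if (nK[g] == 0) continue;
    double off = qs * (nK[g] - 1) + qd * (S - nK[g]);
    double sc = 1.0;
    if (off > 0.99) {
      sc = 0.99 / off;
      off = 0.99;
    }
    st.scale[g] = sc;
    st.diag[g] = 1.0 - off;
  }
}

// Forward/backward over the full joint state space.  Transitions depend on
// states only through their ploidy-class group (rate r within a group, a
// across groups), so a step costs O(S) using per-group sums.  `K` holds
// integer group ids (>= 0), e.g. the ploidy-class index of each state.
// [[Rcpp::export]]
List hmm_fb_cpp(NumericMatrix logE, IntegerVector K, NumericVector d, double r,
                double a, bool want_gamma) {
  int S = logE.nrow(), L = logE.ncol();
  if (L < 2) stop("need at least 2 sites");
  if (d.size() != L - 1) stop("d must have length L-1");
  int Kmax = 0;
  for (int s = 0; s < S; s++)
    if (K[s] > Kmax) Kmax = K[s];
  int G = Kmax + 1;
  std::vector<int> nK(G, 0);
  for (int s = 0; s < S; s++) nK[K[s]]++;

  NumericMatrix alpha(S, L);  // scaled forward variables
  std::vector<double> mshift(L);
  double ll = 0.0;

  // init: uniform prior over states
  {
    double m = logE(0, 0);
    for (int s = 1; s < S; s++)
      if (logE(s, 0) > m) m = logE(s, 0);
    mshift[0] = m;
    double c = 0.0;
    for (int s = 0; s < S; s++) {
      alpha(s, 0) = std::exp(logE(s, 0) - m) / S;
      c += alpha(s, 0);
    }
    for (int s = 0; s < S; s++) alpha(s, 0) /= c;
    ll = m + std::log(c);
  }

  StepTrans st;
  std::vector<double> w(S), Gsum(G), pred(S);
  for (int i = 1; i < L; i++) {
    step_trans(d[i - 1], r, a, nK, S, st);
    double Tot = 0.0;
    std::fill(Gsum.begin(), Gsum.end(), 0.0);
    for (int s = 0; s < S; s++) {
      w[s] = alpha(s, i - 1) * st.scale[K[s]];
      Gsum[K[s]] += w[s];
      Tot += w[s];
    }
    double m = R_NegInf;
    for (int s = 0; s < S; s++)
      if (logE(s, i) > m) m = logE(s, i);
    mshift[i] = m;
    double c = 0.0;
    for (int s = 0; s < S; s++) {
      double off = st.qs * (Gsum[K[s]] - w[s]) + st.qd * (Tot - Gsum[K[s]]);
      pred[s] = off + alpha(s, i - 1) * st.diag[K[s]];
      double v = pred[s] * std::exp(logE(s, i) - m);
      alpha(s, i) = v;
      c += v;
    }
    for (int s = 0; s < S; s++) alpha(s, i) /= c;
    ll += m + std::log(c);
  }

  double ll_b = NA_REAL;
  NumericMatrix gamma;
  if (want_gamma) {
    gamma = NumericMatrix(S, L);
    std::vector<double> beta(S, 1.0), v(S), H(G), raw(S);
    double logscaleB = 0.0;
    for (int s = 0; s < S; s++) gamma(s, L - 1) = alpha(s, L - 1) * beta[s];
    for (int i = L - 2; i >= 0; i--) {
      step_trans(d[i], r, a, nK, S, st);
      double m = mshift[i + 1];
      double V = 0.0;
      std::fill(H.begin(), H.end(), 0.0);
      for (int s = 0; s < S; s++) {
        v[s] = std::exp(logE(s, i + 1) - m) * beta[s];
        H[K[s]] += v[s];
        V += v[s];
      }
      double c = 0.0;
      for (int s = 0; s < S; s++) {
        double off = st.scale[K[s]] *
                     (st.qs * (H[K[s]] - v[s]) + st.qd * (V - H[K[s]]));
        raw[s] = off + st.diag[K[s]] * v[s];
        c += raw[s];
      }
      logscaleB += m + std::log(c);
      double gs = 0.0;
      for (int s = 0; s < S; s++) {
        beta[s] = raw[s] / c;
        double g = alpha(s, i) * beta[s];
        gamma(s, i) = g;
        gs += g;
      }
      for (int s = 0; s < S; s++) gamma(s, i) /= gs;
    }
    // backward-based total likelihood: sum_s (1/S) E_1[s] beta_1[s]
    double m0 = mshift[0], acc = 0.0;
    for (int s = 0; s < S; s++)
      acc += std::exp(logE(s, 0) - m0) / S * beta[s];
    ll_b = logscaleB + m0 + std::log(acc);
    // normalize gamma at the last site too
    double gs = 0.0;
    for (int s = 0; s < S; s++) gs += gamma(s, L - 1);
    for (int s = 0; s < S; s++) gamma(s, L - 1) /= gs;
  }

  if (want_gamma)
    return List::create(_["loglik"] = ll, _["loglik_backward"] = ll_b,
                        _["gamma"] = gamma);
  return List::create(_["loglik"] = ll);
}
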