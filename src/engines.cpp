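#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Sample the number of recrossings from the geometric law
// P(N = n) = (1 - beta) beta^n by inverting the closed cumulative form
// P(N <= n) = 1 - beta^(n+1): N = min{n : F(n) >= x} = ceil(z) - 1 with
// z = ln(1 - x)/ln(beta), x ~ U(0, 1).  (ceil(z) - 1 equals floor(z) except
// on the exact CDF boundaries, where it matches the continuous inverse
// z - 1.)
static double sample_recross(double beta) {
  if (beta <= 0.0) return 0.0;
  double x = unif_rand();
  // unif_rand() is in (0, 1); log1p(-x) is safe
  double N = std::ceil(std::log1p(-x) / std::log(beta)) - 1.0;
  return N < 0.0 ? 0.0 : N;
}

// Multinormal approximation to the multinomial: mean N q, covariance
// N (diag(q) - q q^T), realized with m - 1 standard normals and the
// Householder matrix Q = I - 2 v v^T whose final column is u (u_a = sqrt(q_a)).
// Counts are integerized by clipping at zero and largest-remainder repair.
static void allocate_multinormal(double N, const std::vector<double>& q,
                                 std::vector<double>& counts) {
  int m = q.size();
  counts.assign(m, 0.0);
  if (m == 1) { counts[0] = N; return; }
  std::vector<double> u(m), v(m), z(m, 0.0);
  for (int a = 0; a < m; ++a) u[a] = std::sqrt(q[a]);
  // v = (e_m - u) / ||e_m - u||
  double nv = 0.0;
  for (int a = 0; a < m; ++a) {
    v[a] = ((a == m - 1) ? 1.0 : 0.0) - u[a];
    nv += v[a] * v[a];
  }
  nv = std::sqrt(nv);
  bool degenerate = nv < 1e-14; // q concentrated on the last component
  for (int a = 0; a < m && !degenerate; ++a) v[a] /= nv;
  for (int a = 0; a < m - 1; ++a) z[a] = norm_rand();
  double vz = 0.0;
  if (!degenerate) for (int a = 0; a < m; ++a) vz += v[a] * z[a];
  double sqN = std::sqrt(N);
  for (int a = 0; a < m; ++a) {
    double qz = z[a] - (degenerate ? 0.0 : 2.0 * v[a] * vz); // (Qz)_a
    counts[a] = N * q[a] + sqN * u[a] * qz;
  }
  // integerize: clip, floor, distribute the remainder to the largest
  // fractional parts so the total is exactly N
  std::vector<double> rem(m);
  double S = 0.0;
  for (int a = 0; a < m; ++a) {
    double r = counts[a] < 0.0 ? 0.0 : counts[a];
    counts[a] = std::floor(r);
    rem[a] = r - counts[a];
    S += counts[a];
  }
  double D = N - S;
  while (D > 0.5) {
    int best = 0;
    for (int a = 1; a < m; ++a) if (rem[a] > rem[best]) best = a;
    counts[best] += 1.0;
    rem[best] = -1.0;
    D -= 1.0;
  }
  while (D < -0.5) {
    int best = 0;
    for (int a = 1; a < m; ++a) if (counts[a] > counts[best]) best = a;
    counts[best] -= 1.0;
    D += 1.0;
  }
}

static void allocate_exact(double N, const std::vector<double>& q,
                           std::vector<double>& counts) {
  int m = q.size();
  counts.assign(m, 0.0);
  if (m == 1) { counts[0] = N; return; }
  std::vector<int> rn(m);
  std::vector<double> qq(q);
  ::rmultinom((int) N, qq.data(), m, rn.data());
  for (int a = 0; a < m; ++a) counts[a] = rn[a];
}

// decide the allocation route per the multinormal switch rule
static void allocate_counts(double N, double beta, const std::vector<double>& q,
                            std::vector<double>& counts) {
  int m = q.size();
  if (N <= 0.0 || m == 0) { counts.assign(m, 0.0); return; }
  if (m == 1) { counts.assign(1, N); return; }
  bool normal = (beta > 0.95 && N > 1000.0) || N > 2147483000.0;
  if (normal) allocate_multinormal(N, q, counts);
  else allocate_exact(N, q, counts);
}

// [[Rcpp::export]]
NumericVector cpp_sample_recross(double beta, int n) {
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = sample_recross(beta);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_allocate(double N, NumericVector q, double beta,
                           std::string method) {
  std::vector<double> qq(q.begin(), q.end());
  std::vector<double> counts;
  if (method == "multinomial") allocate_exact(N, qq, counts);
  else if (method == "multinormal") allocate_multinormal(N, qq, counts);
  else allocate_counts(N, beta, qq, counts);
  return NumericVector(counts.begin(), counts.end());
}

static int sample_cum(const double* cum, int len) {
  double x = unif_rand();
  for (int a = 0; a < len - 1; ++a) if (x <= cum[a]) return a;
  return len - 1;
}

// xoshiro256++ (Blackman & Vigna): local fast uniform generator for the
// standard-kMC inner loop, seeded from R's RNG so that results remain a
// deterministic function of set.seed().
struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro() {
    // splitmix64 expansion of a 64-bit seed drawn from R's RNG
    uint64_t seed = (uint64_t)(unif_rand() * 4294967296.0) << 32 |
                    (uint64_t)(unif_rand() * 4294967296.0);
    for (int i = 0; i < 4; ++i) {
      seed += 0x9e3779b97f4a7c15ULL;
      uint64_t z = seed;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {  // in [0, 1)
    return (next() >> 11) * 0x1.0p-53;
  }
};

// Standard rejection-free kMC over n_runs trajectories.  Waiting times are
// exponential per visit; per-trajectory totals are accumulated as per-node
// Gamma(visits, tau) draws, which is identical in distribution to summing
// the individual exponential waits and removes a log() from the inner loop.
// [[Rcpp::export]]
List cpp_run_standard(int n_runs, NumericVector p0cum,
                      IntegerVector ptr, IntegerVector tgt,
                      NumericVector cum, NumericVector tau,
                      int n_trans, double max_steps) {
  NumericVector t_out(n_runs), s_out(n_runs);
  IntegerVector end_out(n_runs);
  LogicalVector cens(n_runs);
  std::vector<double> visits(n_trans, 0.0);
  Xoshiro rng;
  const int* ptr_ = INTEGER(ptr);
  const int* tgt_ = INTEGER(tgt);
  const double* cum_ = REAL(cum);
  for (int r = 0; r < n_runs; ++r) {
    int cur = sample_cum(REAL(p0cum), p0cum.size());
    double s = 0.0;
    bool censored = false;
    for (int k = 0; k < n_trans; ++k) visits[k] = 0.0; // n_trans is small
    while (true) {
      if (s >= max_steps) { censored = true; break; }
      visits[cur] += 1.0;
      s += 1.0;
      int o = ptr_[cur];
      int len = ptr_[cur + 1] - o;
      int pick = 0;
      if (len > 1) {
        double x = rng.unif();
        while (pick < len - 1 && x > cum_[o + pick]) ++pick;
      }
      int nxt = tgt_[o + pick];
      if (nxt >= n_trans) { end_out[r] = nxt; break; }
      cur = nxt;
    }
    double t = 0.0;
    for (int j = 0; j < n_trans; ++j) {
      if (visits[j] > 0.0) t += R::rgamma(visits[j], tau[j]);
    }
    t_out[r] = t;
    s_out[r] = s;
    cens[r] = censored;
    if (censored) end_out[r] = cur;
  }
  return List::create(_["t"] = t_out, _["s"] = s_out,
                      _["end"] = end_out, _["censored"] = cens);
}

struct LfTables {
  // standard step tables
  const int *ptr, *tgt;
  const double *cum, *tau;
  // leapfrog tables
  const double *beta, *omb, *tau_lf, *taubar;
  const int *rc_ptr, *rc_j;
  const double *rc_q, *rc_tau;
  const int *ex_ptr, *ex_tgt, *ex_kind, *ex_iptr, *im_j;
  const double *ex_cum, *im_cum, *im_tau;
  int n_trans;
};

// One leapfrog move from transient node cur.  Returns next node (engine
// index), adds waiting time to *t and implicit steps to *s.
static int lf_move(const LfTables& tb, int cur, int wait_mode,
                   double* t, double* s, std::vector<double>& counts) {
  double beta = tb.beta[cur];
  double N = sample_recross(beta);
  int r0 = tb.rc_ptr[cur], r1 = tb.rc_ptr[cur + 1];
  int m = r1 - r0;
  double w = 0.0;
  if (N > 0.0 && m > 0) {
    if (wait_mode == 2) {
      // mean waiting per recrossing times the sampled count
      w += N * tb.taubar[cur];
    } else {
      std::vector<double> q(tb.rc_q + r0, tb.rc_q + r1);
      allocate_counts(N, beta, q, counts);
      if (wait_mode == 0) {
        for (int a = 0; a < m; ++a) {
          w += counts[a] * (tb.tau[cur] + tb.rc_tau[r0 + a]);
        }
      } else {
        // exact: each recrossing is a pair of exponential waits
        w += R::rgamma(N, tb.tau[cur]);
        for (int a = 0; a < m; ++a) {
          if (counts[a] > 0.0) w += R::rgamma(counts[a], tb.rc_tau[r0 + a]);
        }
      }
    }
  }
  *s += 2.0 * N;
  // exit step(s)
  int e0 = tb.ex_ptr[cur];
  int elen = tb.ex_ptr[cur + 1] - e0;
  int pick = e0 + sample_cum(&tb.ex_cum[e0], elen);
  w += -tb.tau[cur] * std::log(unif_rand());
  if (tb.ex_kind[pick] == 0) {
    *s += 1.0;
  } else {
    int i0 = tb.ex_iptr[pick];
    int ilen = tb.ex_iptr[pick + 1] - i0;
    int jm = i0 + sample_cum(&tb.im_cum[i0], ilen);
    w += -tb.im_tau[jm] * std::log(unif_rand());
    *s += 2.0;
  }
  *t += w;
  return tb.ex_tgt[pick];
}

static LfTables unpack_tables(List st, List lf, int n_trans) {
  LfTables tb;
  tb.ptr = INTEGER(st["ptr"]); tb.tgt = INTEGER(st["tgt"]);
  tb.cum = REAL(st["cum"]); tb.tau = REAL(st["tau"]);
  tb.beta = REAL(lf["beta"]); tb.omb = REAL(lf["omb"]);
  tb.tau_lf = REAL(lf["tau_lf"]); tb.taubar = REAL(lf["taubar"]);
  tb.rc_ptr = INTEGER(lf["rc_ptr"]); tb.rc_j = INTEGER(lf["rc_j"]);
  tb.rc_q = REAL(lf["rc_q"]); tb.rc_tau = REAL(lf["rc_tau"]);
  tb.ex_ptr = INTEGER(lf["ex_ptr"]); tb.ex_tgt = INTEGER(lf["ex_tgt"]);
  tb.ex_kind = INTEGER(lf["ex_kind"]); tb.ex_iptr = INTEGER(lf["ex_iptr"]);
  tb.im_j = INTEGER(lf["im_j"]); tb.ex_cum = REAL(lf["ex_cum"]);
  tb.im_cum = REAL(lf["im_cum"]); tb.im_tau = REAL(lf["im_tau"]);
  tb.n_trans = n_trans;
  return tb;
}

// Leapfrog kMC: per visit, leapfrog if beta exceeds the threshold, else a
// standard step (with its exponential wait sampled directly).
// [[Rcpp::export]]
List cpp_run_leapfrog(int n_runs, NumericVector p0cum, List st, List lf,
                      int n_trans, double threshold, int wait_mode,
                      double max_steps) {
  LfTables tb = unpack_tables(st, lf, n_trans);
  NumericVector t_out(n_runs), s_out(n_runs);
  IntegerVector end_out(n_runs);
  LogicalVector cens(n_runs);
  std::vector<double> counts;
  for (int r = 0; r < n_runs; ++r) {
    int cur = sample_cum(REAL(p0cum), p0cum.size());
    double t = 0.0, s = 0.0;
    bool censored = false;
    while (true) {
      if (s >= max_steps) { censored = true; break; }
      if (tb.beta[cur] > threshold) {
        cur = lf_move(tb, cur, wait_mode, &t, &s, counts);
      } else {
        int o = tb.ptr[cur];
        int len = tb.ptr[cur + 1] - o;
        int pick = sample_cum(&tb.cum[o], len);
        t += -tb.tau[cur] * std::log(unif_rand());
        s += 1.0;
        cur = tb.tgt[o + pick];
      }
      if (cur >= n_trans) { end_out[r] = cur; break; }
    }
    t_out[r] = t;
    s_out[r] = s;
    cens[r] = censored;
    if (censored) end_out[r] = cur;
  }
  return List::create(_["t"] = t_out, _["s"] = s_out,
                      _["end"] = end_out, _["censored"] = cens);
}

// Single leapfrog move, exposed for unit-level use.
// [[Rcpp::export]]
List cpp_lf_move(int cur, List st, List lf, int n_trans, int wait_mode) {
  LfTables tb = unpack_tables(st, lf, n_trans);
  std::vector<double> counts;
  double t = 0.0, s = 0.0;
  int nxt = lf_move(tb, cur, wait_mode, &t, &s, counts);
  return List::create(_["next_node"] = nxt, _["waiting"] = t,
                      _["steps"] = s);
}
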