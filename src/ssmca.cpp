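// Core numerics: exact conditional posterior of one latent under the
// max-superposition spike-and-slab model, inverse-transform sampling,
// Gibbs sweeps, and the batched E-step with sufficient-statistic
// accumulation.  All randomness comes from counter-based per-datapoint
// streams so results are independent of execution order.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

static const double LOG2PI = 1.8378770664093454836;

// ---------------------------------------------------------------------------
// counter-based RNG: splitmix64 seeding of xoshiro256++
// ---------------------------------------------------------------------------

static inline uint64_t sm64(uint64_t& x) {
  uint64_t z = (x += 0x9e3779b97f4a7c15ULL);
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

struct Xosh {
  uint64_t s[4];
  explicit Xosh(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = sm64(x);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  // strictly inside (0,1)
  double runif() { return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0); }
};

// child stream for (seed, iteration, datapoint)
static inline uint64_t child_seed(uint64_t master, uint64_t iter, uint64_t n) {
  uint64_t x = master;
  uint64_t a = sm64(x);
  x = a ^ (iter * 0xd1342543de82ef95ULL + 0x2545f4914f6cdd1dULL);
  uint64_t b = sm64(x);
  x = b ^ (n * 0xda942042e4dd58b5ULL + 0x9e6c63d0a2896a97ULL);
  return sm64(x);
}

// ---------------------------------------------------------------------------
// log-space helpers
// ---------------------------------------------------------------------------

static inline double logspace_sub_(double lx, double ly) {
  // log(exp(lx) - exp(ly)) for lx >= ly
  if (ly == R_NegInf) return lx;
  double d = ly - lx;
  if (d >= 0.0) return R_NegInf;
  return lx + log1p(-std::exp(d));
}

static inline double log_phi_diff(double a, double b) {
  // log(Phi(b) - Phi(a)), a < b, either may be infinite
  if (a >= b) return R_NegInf;
  if (a > 0.0)
    return logspace_sub_(R::pnorm(a, 0.0, 1.0, 0, 1), R::pnorm(b, 0.0, 1.0, 0, 1));
  return logspace_sub_(R::pnorm(b, 0.0, 1.0, 1, 1), R::pnorm(a, 0.0, 1.0, 1, 1));
}

// quantile of N(m,t^2) truncated to [L,U] at interior fraction q in [0,1],
// computed in whichever tail is numerically safer
static double invert_trunc_norm(double m, double t, double L, double U, double q) {
  if (q <= 0.0) return L > R_NegInf ? L : m - 38.0 * t;
  if (q >= 1.0) return U < R_PosInf ? U : m + 38.0 * t;
  double a = (L == R_NegInf) ? R_NegInf : (L - m) / t;
  double b = (U == R_PosInf) ? R_PosInf : (U - m) / t;
  double x;
  if (a >= 0.0) {                      // both bounds in the upper tail
    double la = R::pnorm(a, 0.0, 1.0, 0, 1);  // log Phi_c(a)
    double lb = (b == R_PosInf) ? R_NegInf : R::pnorm(b, 0.0, 1.0, 0, 1);
    double lt = la + log1p(-q * (1.0 - std::exp(lb - la)));
    x = m + t * R::qnorm(lt, 0.0, 1.0, 0, 1);
  } else if (b <= 0.0) {               // both bounds in the lower tail
    double lb = R::pnorm(b, 0.0, 1.0, 1, 1);  // log Phi(b)
    double la = (a == R_NegInf) ? R_NegInf : R::pnorm(a, 0.0, 1.0, 1, 1);
    double lt = lb + log1p(-(1.0 - q) * (1.0 - std::exp(la - lb)));
    x = m + t * R::qnorm(lt, 0.0, 1.0, 1, 1);
  } else {                             // straddles the mean region
    double pa = (a == R_NegInf) ? 0.0 : R::pnorm(a, 0.0, 1.0, 1, 0);
    double pb = (b == R_PosInf) ? 1.0 : R::pnorm(b, 0.0, 1.0, 1, 0);
    x = m + t * R::qnorm(pa + q * (pb - pa), 0.0, 1.0, 1, 0);
  }
  if (!std::isfinite(x)) x = m;
  if (L > R_NegInf && x < L) x = L;
  if (U < R_PosInf && x > U) x = U;
  return x;
}

// ---------------------------------------------------------------------------
// piecewise conditional posterior of one latent
// ---------------------------------------------------------------------------

struct Cond {
  // M transition points, M+1 segments; coefficients include the slab
  // quadratic and (when spiked) log(pi)
  std::vector<double> bnd, A, B, C, logmass;
  double loglik0;        // assembled likelihood value at s_h = 0 (no slab)
  double spike_logmass;  // log((1-pi) * lik(0))
  double lognorm;
  // scratch
  std::vector<double> P, lc, ra, rb, rc;
  std::vector<int> ord;

  void build_segments(const double* y, const double* comp, const double* w,
                      int D, double sigma, double mu_pr, double sigma_pr) {
    const double i2s2 = 1.0 / (2.0 * sigma * sigma);
    P.clear(); lc.clear(); ra.clear(); rb.clear(); rc.clear();
    double Ltot = 0.0;
    for (int d = 0; d < D; ++d) {
      double l = -(y[d] - comp[d]) * (y[d] - comp[d]) * i2s2;
      Ltot += l;
      if (w[d] > 0.0) {
        P.push_back(comp[d] / w[d]);
        lc.push_back(l);
        ra.push_back(-w[d] * w[d] * i2s2);
        rb.push_back(2.0 * y[d] * w[d] * i2s2);
        rc.push_back(-y[d] * y[d] * i2s2);
      }
    }
    loglik0 = Ltot;
    const int M = (int)P.size();
    ord.resize(M);
    for (int i = 0; i < M; ++i) ord[i] = i;
    std::stable_sort(ord.begin(), ord.end(),
                     [&](int i, int j) { return P[i] < P[j]; });
    const double sa = -1.0 / (2.0 * sigma_pr * sigma_pr);
    const double sb = mu_pr / (sigma_pr * sigma_pr);
    const double sc = -mu_pr * mu_pr / (2.0 * sigma_pr * sigma_pr)
                      - std::log(sigma_pr) - 0.5 * LOG2PI;
    bnd.resize(M); A.resize(M + 1); B.resize(M + 1); C.resize(M + 1);
    double aA = 0.0, aB = 0.0, aC = Ltot;
    A[0] = sa; B[0] = sb; C[0] = aC + sc;
    for (int j = 1; j <= M; ++j) {
      int i = ord[j - 1];
      aA += ra[i]; aB += rb[i]; aC += rc[i] - lc[i];
      A[j] = aA + sa; B[j] = aB + sb; C[j] = aC + sc;
      bnd[j - 1] = P[i];
    }
  }

  void add_spike_and_normalize(double pi) {
    const int S = (int)A.size();
    const double lpi = (pi > 0.0) ? std::log(pi) : R_NegInf;
    logmass.resize(S);
    spike_logmass = (pi < 1.0) ? log1p(-pi) + loglik0 : R_NegInf;
    // quick upper bounds, then exact masses only for contending segments
    std::vector<double> bound(S), mm(S), tt(S), pk(S);
    double maxb = spike_logmass;
    for (int j = 0; j < S; ++j) {
      double a = A[j], b = B[j], c = C[j] + lpi;
      double m = -b / (2.0 * a), t = std::sqrt(-0.5 / a);
      double k = c - a * m * m;
      mm[j] = m; tt[j] = t; pk[j] = k;
      double L = (j == 0) ? R_NegInf : bnd[j - 1];
      double U = (j == S - 1) ? R_PosInf : bnd[j];
      double lw = (L == R_NegInf || U == R_PosInf)
                      ? R_PosInf
                      : (U > L ? std::log(U - L) : R_NegInf);
      double lg = std::log(t) + 0.5 * LOG2PI;
      // sup of the log-density over the segment (mode clamped into [L,U])
      double mc = m;
      if (mc < L) mc = L;
      if (mc > U) mc = U;
      double sup = a * mc * mc + b * mc + c;
      bound[j] = sup + std::min(lw, lg);
      if (bound[j] > maxb) maxb = bound[j];
    }
    double acc = spike_logmass;
    for (int j = 0; j < S; ++j) {
      if (bound[j] < maxb - 40.0) { logmass[j] = R_NegInf; continue; }
      double L = (j == 0) ? R_NegInf : bnd[j - 1];
      double U = (j == S - 1) ? R_PosInf : bnd[j];
      double al = (L == R_NegInf) ? R_NegInf : (L - mm[j]) / tt[j];
      double be = (U == R_PosInf) ? R_PosInf : (U - mm[j]) / tt[j];
      logmass[j] = pk[j] + std::log(tt[j]) + 0.5 * LOG2PI + log_phi_diff(al, be);
      if (!std::isfinite(logmass[j])) logmass[j] = R_NegInf;
      acc = (acc > logmass[j])
                ? acc + log1p(std::exp(logmass[j] - acc))
                : (logmass[j] == R_NegInf ? acc : logmass[j] + log1p(std::exp(acc - logmass[j])));
    }
    lognorm = acc;
    // fold log(pi) into the stored coefficients so that exp(A s^2 + B s + C)
    // is the actual (unnormalized) slab-side density
    for (int j = 0; j < S; ++j) C[j] += lpi;
  }

  double draw(double u) const {
    const int S = (int)A.size();
    // segment containing 0 (first segment whose upper bound exceeds 0)
    int j0 = S - 1;
    for (int j = 0; j < S - 1; ++j)
      if (bnd[j] > 0.0) { j0 = j; break; }
    double m0 = -B[j0] / (2.0 * A[j0]), t0 = std::sqrt(-0.5 / A[j0]);
    double L0 = (j0 == 0) ? R_NegInf : bnd[j0 - 1];
    double U0 = (j0 == S - 1) ? R_PosInf : bnd[j0];
    double p0 = std::exp(logmass[j0] - lognorm);
    double below = 0.0;
    if (p0 > 0.0 && L0 < 0.0) {
      double al = (L0 == R_NegInf) ? R_NegInf : (L0 - m0) / t0;
      double lb = pk_of(j0) + std::log(t0) + 0.5 * LOG2PI +
                  log_phi_diff(al, (0.0 - m0) / t0);
      below = std::exp(lb - lognorm);
      if (below > p0) below = p0;
    }
    double above = p0 - below;
    double pspike = std::exp(spike_logmass - lognorm);
    double cum = 0.0;
    for (int j = 0; j < j0; ++j) {
      double p = std::exp(logmass[j] - lognorm);
      if (u <= cum + p && p > 0.0)
        return seg_draw(j, (u - cum) / p);
      cum += p;
    }
    if (u <= cum + below && below > 0.0)
      return invert_trunc_norm(m0, t0, L0, 0.0, (u - cum) / below);
    cum += below;
    if (u <= cum + pspike) return 0.0;
    cum += pspike;
    if (u <= cum + above && above > 0.0)
      return invert_trunc_norm(m0, t0, 0.0, U0, (u - cum) / above);
    cum += above;
    for (int j = j0 + 1; j < S; ++j) {
      double p = std::exp(logmass[j] - lognorm);
      if (u <= cum + p && p > 0.0)
        return seg_draw(j, (u - cum) / p);
      cum += p;
    }
    return 0.0;  // fp fallthrough: essentially impossible
  }

 private:
  double pk_of(int j) const {
    double m = -B[j] / (2.0 * A[j]);
    return C[j] - A[j] * m * m;
  }
  double seg_draw(int j, double q) const {
    const int S = (int)A.size();
    double m = -B[j] / (2.0 * A[j]), t = std::sqrt(-0.5 / A[j]);
    double L = (j == 0) ? R_NegInf : bnd[j - 1];
    double U = (j == S - 1) ? R_PosInf : bnd[j];
    return invert_trunc_norm(m, t, L, U, q);
  }
};

// competitor max at each pixel, floored at the silent background 0
static inline void competitor_max(const NumericMatrix& W,
                                  const std::vector<int>& sel, const double* s,
                                  int skip_h, std::vector<double>& comp) {
  const int D = W.nrow();
  std::fill(comp.begin(), comp.end(), 0.0);
  for (int idx : sel) {
    if (idx == skip_h || s[idx] == 0.0) continue;
    const double sv = s[idx];
    const double* wc = &W(0, idx);
    for (int d = 0; d < D; ++d) {
      double v = wc[d] * sv;
      if (v > comp[d]) comp[d] = v;
    }
  }
}

// ---------------------------------------------------------------------------
// exported single-operation entry points (unit-test surface)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List build_segments_cpp(NumericVector y, NumericVector s, int h,
                        NumericMatrix W, double sigma, double mu_pr,
                        double sigma_pr) {
  const int D = W.nrow(), H = W.ncol();
  if (h < 1 || h > H) stop("latent index out of range");
  std::vector<int> sel(H);
  for (int i = 0; i < H; ++i) sel[i] = i;
  std::vector<double> comp(D);
  competitor_max(W, sel, REAL(s), h - 1, comp);
  Cond c;
  c.build_segments(REAL(y), comp.data(), &W(0, h - 1), D, sigma, mu_pr, sigma_pr);
  return List::create(_["boundaries"] = wrap(c.bnd), _["A"] = wrap(c.A),
                      _["B"] = wrap(c.B), _["C"] = wrap(c.C),
                      _["loglik_at_zero"] = c.loglik0);
}

// [[Rcpp::export]]
List add_spike_cpp(NumericVector boundaries, NumericVector A, NumericVector B,
                   NumericVector C, double loglik_at_zero, double pi) {
  Cond c;
  c.bnd = as<std::vector<double>>(boundaries);
  c.A = as<std::vector<double>>(A);
  c.B = as<std::vector<double>>(B);
  c.C = as<std::vector<double>>(C);
  c.loglik0 = loglik_at_zero;
  c.add_spike_and_normalize(pi);
  return List::create(_["boundaries"] = wrap(c.bnd), _["A"] = wrap(c.A),
                      _["B"] = wrap(c.B), _["C"] = wrap(c.C),
                      _["log_masses"] = wrap(c.logmass),
                      _["spike_log_mass"] = c.spike_logmass,
                      _["log_norm"] = c.lognorm,
                      _["loglik_at_zero"] = c.loglik0);
}

// [[Rcpp::export]]
double draw_piecewise_cpp(NumericVector boundaries, NumericVector A,
                          NumericVector B, NumericVector C,
                          NumericVector log_masses, double spike_log_mass,
                          double log_norm, double u) {
  if (!(u > 0.0 && u < 1.0)) stop("u must lie in the open interval (0,1)");
  Cond c;
  c.bnd = as<std::vector<double>>(boundaries);
  c.A = as<std::vector<double>>(A);
  c.B = as<std::vector<double>>(B);
  c.C = as<std::vector<double>>(C);
  c.logmass = as<std::vector<double>>(log_masses);
  c.spike_logmass = spike_log_mass;
  c.lognorm = log_norm;
  return c.draw(u);
}

// [[Rcpp::export]]
IntegerVector select_latents_cpp(NumericVector scores, int H_prime,
                                 int n_random, double seed) {
  const int H = scores.size();
  if (H_prime > H) stop("H_prime exceeds the number of latents");
  if (n_random > H_prime) stop("n_random exceeds H_prime");
  std::vector<int> ord(H);
  for (int i = 0; i < H; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(), [&](int i, int j) {
    if (scores[i] != scores[j]) return scores[i] > scores[j];
    return i < j;
  });
  int ntop = H_prime - n_random;
  int nr = n_random;
  if (H - ntop < nr) nr = H - ntop;  // H'==H: nothing left to randomize
  std::vector<int> out(ord.begin(), ord.begin() + ntop);
  if (nr > 0) {
    Xosh rng((uint64_t)seed);
    std::vector<int> rest(ord.begin() + ntop, ord.end());
    for (int i = 0; i < nr; ++i) {
      int j = i + (int)(rng.runif() * (rest.size() - i));
      if (j >= (int)rest.size()) j = (int)rest.size() - 1;
      std::swap(rest[i], rest[j]);
      out.push_back(rest[i]);
    }
  }
  IntegerVector res(out.size());
  for (size_t i = 0; i < out.size(); ++i) res[i] = out[i] + 1;
  return res;
}

// internal selection used by the batched routines (per-point stream)
static std::vector<int> select_internal(const NumericMatrix& W,
                                        const std::vector<double>& wnorm,
                                        const double* y, int H_prime,
                                        int n_random, Xosh& rng) {
  const int D = W.nrow(), H = W.ncol();
  std::vector<double> sc(H);
  for (int h = 0; h < H; ++h) {
    if (wnorm[h] <= 0.0) { sc[h] = R_NegInf; continue; }
    double dot = 0.0;
    const double* wc = &W(0, h);
    for (int d = 0; d < D; ++d) dot += wc[d] * y[d];
    sc[h] = dot / wnorm[h];
  }
  std::vector<int> ord(H);
  for (int i = 0; i < H; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(), [&](int i, int j) {
    if (sc[i] != sc[j]) return sc[i] > sc[j];
    return i < j;
  });
  int ntop = H_prime - n_random;
  int nr = n_random;
  if (H - ntop < nr) nr = H - ntop;
  std::vector<int> out(ord.begin(), ord.begin() + ntop);
  for (int i = 0; i < nr; ++i) {
    int j = i + (int)(rng.runif() * (H - ntop - i));
    if (j >= H - ntop) j = H - ntop - 1;
    std::swap(ord[ntop + i], ord[ntop + j]);
    out.push_back(ord[ntop + i]);
  }
  return out;
}

// one systematic-scan sweep over the selected latents
static void sweep_once(const double* y, const NumericMatrix& W,
                       const std::vector<int>& sel, double* s, double sigma,
                       double pi, double mu_pr, double sigma_pr, Xosh& rng,
                       Cond& c, std::vector<double>& comp) {
  const int D = W.nrow();
  for (int h : sel) {
    competitor_max(W, sel, s, h, comp);
    c.build_segments(y, comp.data(), &W(0, h), D, sigma, mu_pr, sigma_pr);
    c.add_spike_and_normalize(pi);
    s[h] = c.draw(rng.runif());
  }
}

// [[Rcpp::export]]
NumericMatrix gibbs_sweep_cpp(NumericVector y, NumericVector s_init,
                              IntegerVector sel, NumericMatrix W, double sigma,
                              double pi, double mu_pr, double sigma_pr,
                              int n_samples, double seed) {
  const int D = W.nrow(), H = W.ncol();
  if (sel.size() == 0) stop("empty selection");
  if (y.size() != D || s_init.size() != H) stop("dimension mismatch");
  std::vector<int> sv(sel.size());
  for (int i = 0; i < sel.size(); ++i) sv[i] = sel[i] - 1;
  std::vector<double> s(REAL(s_init), REAL(s_init) + H), comp(D);
  Cond c;
  Xosh rng((uint64_t)seed);
  NumericMatrix out(n_samples, H);
  for (int k = 0; k < n_samples; ++k) {
    sweep_once(REAL(y), W, sv, s.data(), sigma, pi, mu_pr, sigma_pr, rng, c, comp);
    for (int h = 0; h < H; ++h) out(k, h) = s[h];
  }
  return out;
}

// render (floored max) and argmax bookkeeping for the accumulators
static inline double render_px(const NumericMatrix& W,
                               const std::vector<int>& sel_sorted,
                               const double* s, int d, int* amax) {
  double best = 0.0;
  int bh = -1;
  for (int h : sel_sorted) {
    if (s[h] == 0.0) continue;
    double v = W(d, h) * s[h];
    if (v > best) { best = v; bh = h; }
  }
  *amax = bh;
  return best;
}

static double joint_loglik(const double* y, const NumericMatrix& W,
                           const std::vector<int>& sel_sorted, const double* s,
                           int H, double sigma, double pi, double mu_pr,
                           double sigma_pr) {
  const int D = W.nrow();
  double ll = 0.0;
  int am;
  for (int d = 0; d < D; ++d) {
    double r = render_px(W, sel_sorted, s, d, &am);
    ll += R::dnorm(y[d], r, sigma, 1);
  }
  int nact = 0;
  for (int h = 0; h < H; ++h)
    if (s[h] != 0.0) {
      ++nact;
      ll += R::dnorm(s[h], mu_pr, sigma_pr, 1);
    }
  if (pi > 0.0) ll += nact * std::log(pi);
  else if (nact > 0) ll = R_NegInf;
  if (pi < 1.0) ll += (H - nact) * log1p(-pi);
  else if (nact < H) ll = R_NegInf;
  return ll;
}

// [[Rcpp::export]]
List estep_batch_cpp(NumericMatrix Y, NumericMatrix W, double sigma, double pi,
                     double mu_pr, double sigma_pr, int H_prime, int n_random,
                     int n_samples, double seed, int iter,
                     bool return_samples = false) {
  const int N = Y.nrow(), D = Y.ncol(), H = W.ncol();
  if (W.nrow() != D) stop("dimension mismatch between Y and W");
  const int burn = n_samples / 3;
  const int K_used = n_samples - burn;
  if (K_used < 1) stop("n_samples too small for 1/3 burn-in");

  std::vector<double> wnorm(H);
  for (int h = 0; h < H; ++h) {
    double ss = 0.0;
    for (int d = 0; d < D; ++d) ss += W(d, h) * W(d, h);
    wnorm[h] = std::sqrt(ss);
  }

  NumericMatrix star_sy(D, H), star_ss(D, H), star_count(D, H);
  NumericVector dsum(H), dsumsq(H), dcount(H);
  double resid = 0.0, active_sum = 0.0, ll_sum = 0.0;
  List samples(return_samples ? N : 0), selections(return_samples ? N : 0);

  std::vector<double> yrow(D), s(H), comp(D);
  Cond c;
  for (int n = 0; n < N; ++n) {
    for (int d = 0; d < D; ++d) yrow[d] = Y(n, d);
    Xosh rng(child_seed((uint64_t)seed, (uint64_t)iter, (uint64_t)n));
    std::vector<int> sel =
        select_internal(W, wnorm, yrow.data(), H_prime, n_random, rng);
    std::vector<int> sel_sorted(sel);
    std::sort(sel_sorted.begin(), sel_sorted.end());
    std::fill(s.begin(), s.end(), 0.0);
    NumericMatrix smp;
    if (return_samples) smp = NumericMatrix(K_used, H);
    for (int k = 0; k < n_samples; ++k) {
      sweep_once(yrow.data(), W, sel, s.data(), sigma, pi, mu_pr, sigma_pr,
                 rng, c, comp);
      if (k < burn) continue;
      if (return_samples)
        for (int h = 0; h < H; ++h) smp(k - burn, h) = s[h];
      int am, nact = 0;
      for (int d = 0; d < D; ++d) {
        double r = render_px(W, sel_sorted, s.data(), d, &am);
        double e = r - yrow[d];
        resid += e * e;
        if (am >= 0) {
          star_sy(d, am) += s[am] * yrow[d];
          star_ss(d, am) += s[am] * s[am];
          star_count(d, am) += 1.0;
        }
      }
      for (int h : sel_sorted) {
        if (s[h] != 0.0) {
          ++nact;
          dsum[h] += s[h];
          dsumsq[h] += s[h] * s[h];
          dcount[h] += 1.0;
        }
      }
      active_sum += (double)nact / H;
      ll_sum += joint_loglik(yrow.data(), W, sel_sorted, s.data(), H, sigma,
                             pi, mu_pr, sigma_pr);
    }
    if (return_samples) {
      samples[n] = smp;
      IntegerVector si(sel.size());
      for (size_t i = 0; i < sel.size(); ++i) si[i] = sel[i] + 1;
      selections[n] = si;
    }
  }
  List out = List::create(
      _["star_sy"] = star_sy, _["star_ss"] = star_ss,
      _["star_count"] = star_count, _["star_sq_resid"] = resid,
      _["dstar_sum"] = dsum, _["dstar_sumsq"] = dsumsq,
      _["dstar_count"] = dcount, _["active_sum"] = active_sum,
      _["n_data"] = N, _["n_dim"] = D, _["n_latent"] = H,
      _["k_used"] = K_used, _["mean_joint_loglik"] = ll_sum / (N * K_used));
  if (return_samples) {
    out["samples"] = samples;
    out["selections"] = selections;
  }
  return out;
}

// [[Rcpp::export]]
List reconstruct_batch_cpp(NumericMatrix Y, NumericMatrix W, double sigma,
                           double pi, double mu_pr, double sigma_pr,
                           int H_prime, int n_random, int n_samples,
                           double seed, bool want_yhat = true,
                           bool want_shat = false) {
  const int N = Y.nrow(), D = Y.ncol(), H = W.ncol();
  if (W.nrow() != D) stop("dimension mismatch between Y and W");
  const int burn = n_samples / 3;
  if (n_samples - burn < 1) stop("n_samples too small for 1/3 burn-in");

  std::vector<double> wnorm(H);
  for (int h = 0; h < H; ++h) {
    double ss = 0.0;
    for (int d = 0; d < D; ++d) ss += W(d, h) * W(d, h);
    wnorm[h] = std::sqrt(ss);
  }
  NumericVector mse(N), nact(N), jll(N);
  NumericMatrix Yhat(want_yhat ? N : 0, want_yhat ? D : 0);
  NumericMatrix Shat(want_shat ? N : 0, want_shat ? H : 0);

  std::vector<double> yrow(D), s(H), sbest(H), comp(D);
  Cond c;
  for (int n = 0; n < N; ++n) {
    for (int d = 0; d < D; ++d) yrow[d] = Y(n, d);
    Xosh rng(child_seed((uint64_t)seed, 0ULL, (uint64_t)n));
    std::vector<int> sel =
        select_internal(W, wnorm, yrow.data(), H_prime, n_random, rng);
    std::vector<int> sel_sorted(sel);
    std::sort(sel_sorted.begin(), sel_sorted.end());
    std::fill(s.begin(), s.end(), 0.0);
    double best = R_NegInf;
    for (int k = 0; k < n_samples; ++k) {
      sweep_once(yrow.data(), W, sel, s.data(), sigma, pi, mu_pr, sigma_pr,
                 rng, c, comp);
      if (k < burn) continue;
      double ll = joint_loglik(yrow.data(), W, sel_sorted, s.data(), H, sigma,
                               pi, mu_pr, sigma_pr);
      if (ll > best) { best = ll; sbest = s; }
    }
    jll[n] = best;
    int am, na = 0;
    double sq = 0.0;
    for (int d = 0; d < D; ++d) {
      double r = render_px(W, sel_sorted, sbest.data(), d, &am);
      if (want_yhat) Yhat(n, d) = r;
      double e = yrow[d] - r;
      sq += e * e;
    }
    for (int h = 0; h < H; ++h) {
      if (sbest[h] != 0.0) ++na;
      if (want_shat) Shat(n, h) = sbest[h];
    }
    mse[n] = sq;
    nact[n] = na;
  }
  List out = List::create(_["mse"] = mse, _["n_active"] = nact,
                          _["joint_loglik"] = jll);
  if (want_yhat) out["Y_hat"] = Yhat;
  if (want_shat) out["S_hat"] = Shat;
  return out;
}

// [[Rcpp::export]]
NumericMatrix render_batch_cpp(NumericMatrix S, NumericMatrix W) {
  const int N = S.nrow(), H = S.ncol(), D = W.nrow();
  if (W.ncol() != H) stop("dimension mismatch between S and W");
  NumericMatrix out(N, D);
  for (int n = 0; n < N; ++n)
    for (int h = 0; h < H; ++h) {
      double sv = S(n, h);
      if (sv == 0.0) continue;
      for (int d = 0; d < D; ++d) {
        double v = W(d, h) * sv;
        if (v > out(n, d)) out(n, d) = v;
      }
    }
  return out;
}
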