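// Gibbs sampler for the Bayesian admixture model: each allele copy originates
// from one of K clusters; cluster allele frequencies P get independent
// Dirichlet(lambda) priors per (cluster, locus), unit ancestry vectors Q get a
// symmetric Dirichlet(alpha) prior, and alpha is given a uniform prior on
// (0, alpha_max] updated by random-walk Metropolis. Blocked sweeps:
// Z | P,Q  ->  P | Z  ->  Q | Z  ->  alpha | Q.
// A self-contained xoshiro256++ stream keeps runs reproducible from one seed
// independently of R's RNG state.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

namespace {

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    // splitmix64 expansion of the seed
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
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
  inline double unif() {  // (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  bool have_spare = false;
  double spare = 0.0;
  inline double normal() {  // Marsaglia polar
    if (have_spare) { have_spare = false; return spare; }
    double u, v, s2;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      s2 = u * u + v * v;
    } while (s2 >= 1.0 || s2 == 0.0);
    double m = std::sqrt(-2.0 * std::log(s2) / s2);
    spare = v * m; have_spare = true;
    return u * m;
  }
  double gamma(double shape) {  // Marsaglia-Tsang; shape boost below 1
    if (shape < 1.0) {
      double g = gamma(shape + 1.0);
      return g * std::pow(unif(), 1.0 / shape);
    }
    double d = shape - 1.0 / 3.0;
    double c = 1.0 / std::sqrt(9.0 * d);
    for (;;) {
      double x, v;
      do { x = normal(); v = 1.0 + c * x; } while (v <= 0.0);
      v = v * v * v;
      double u = unif();
      if (u < 1.0 - 0.0331 * x * x * x * x) return d * v;
      if (std::log(u) < 0.5 * x * x + d * (1.0 - v + std::log(v))) return d * v;
    }
  }
};

inline double clamp_pos(double x) { return x < 1e-300 ? 1e-300 : x; }

}  // namespace

// [[Rcpp::export]]
List gibbs_admixture_cpp(int n_units, IntegerVector unit, IntegerVector locus,
                         IntegerVector allele, IntegerVector n_alleles,
                         int K, int burnin, int reps, int ll_every,
                         double lambda, double alpha_init, double alpha_sd,
                         double alpha_max, bool update_alpha, double seed) {
  const int n_copies = unit.size();
  const int n_loci = n_alleles.size();
  std::vector<int> off(n_loci + 1, 0);
  for (int l = 0; l < n_loci; ++l) off[l + 1] = off[l] + n_alleles[l];
  const int T = off[n_loci];  // total allele slots across loci

  Xoshiro rng(static_cast<uint64_t>(seed));

  // flat index of each copy's (locus, allele) slot; copies of the same unit
  // are kept adjacent so the unit's Q row stays hot in cache
  std::vector<int> ord(n_copies);
  for (int c = 0; c < n_copies; ++c) ord[c] = c;
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int a, int b) { return unit[a] < unit[b]; });
  std::vector<int> cunit(n_copies), cslot(n_copies);
  for (int i = 0; i < n_copies; ++i) {
    cunit[i] = unit[ord[i]];
    cslot[i] = off[locus[ord[i]]] + allele[ord[i]];
  }

  // slot-major layout: the K cluster values of one (locus, allele) slot are
  // contiguous, so a copy's categorical weights sit on one cache line
  std::vector<double> P(static_cast<size_t>(T) * K);
  std::vector<double> Q(static_cast<size_t>(n_units) * K,
                        1.0 / static_cast<double>(K));
  std::vector<double> cntP(static_cast<size_t>(T) * K);
  std::vector<double> cntQ(static_cast<size_t>(n_units) * K);
  std::vector<double> Qsum(static_cast<size_t>(n_units) * K, 0.0);
  std::vector<double> Psum(static_cast<size_t>(T) * K, 0.0);

  // initial P draw from the prior
  for (int k = 0; k < K; ++k)
    for (int l = 0; l < n_loci; ++l) {
      double s = 0.0;
      for (int a = 0; a < n_alleles[l]; ++a) {
        double g = clamp_pos(rng.gamma(lambda));
        P[static_cast<size_t>(off[l] + a) * K + k] = g;
        s += g;
      }
      for (int a = 0; a < n_alleles[l]; ++a)
        P[static_cast<size_t>(off[l] + a) * K + k] /= s;
    }

  double alpha = alpha_init;
  int n_accept = 0, n_prop = 0;
  std::vector<double> ll_rec;
  std::vector<double> alpha_rec;
  std::vector<double> probs(K);

  const int total_sweeps = burnin + reps;
  int n_kept = 0;
  double ll = 0.0;
  bool ll_finite = true;
  const int *cu = cunit.data();
  const int *cs = cslot.data();
  double *Pd = P.data();
  double *Qd = Q.data();
  double *cPd = cntP.data();
  double *cQd = cntQ.data();

  for (int sweep = 0; sweep < total_sweeps; ++sweep) {
    // --- Z | P, Q (counts only; Z itself need not be stored) ---
    std::fill(cntP.begin(), cntP.end(), 0.0);
    std::fill(cntQ.begin(), cntQ.end(), 0.0);
    for (int c = 0; c < n_copies; ++c) {
      const double *qrow = Qd + static_cast<size_t>(cu[c]) * K;
      const double *prow = Pd + static_cast<size_t>(cs[c]) * K;
      double tot = 0.0;
      for (int k = 0; k < K; ++k) {
        double w = qrow[k] * prow[k];
        probs[k] = w;
        tot += w;
      }
      int kc = K - 1;
      if (tot > 0.0) {
        double r = rng.unif() * tot;
        double acc = 0.0;
        for (int k = 0; k < K - 1; ++k) {
          acc += probs[k];
          if (r <= acc) { kc = k; break; }
        }
      } else {
        kc = static_cast<int>(rng.unif() * K);
        if (kc >= K) kc = K - 1;
      }
      cPd[static_cast<size_t>(cs[c]) * K + kc] += 1.0;
      cQd[static_cast<size_t>(cu[c]) * K + kc] += 1.0;
    }
    // --- P | Z ---
    for (int k = 0; k < K; ++k)
      for (int l = 0; l < n_loci; ++l) {
        double s = 0.0;
        for (int a = 0; a < n_alleles[l]; ++a) {
          size_t ix = static_cast<size_t>(off[l] + a) * K + k;
          double g = clamp_pos(rng.gamma(lambda + cntP[ix]));
          P[ix] = g; s += g;
        }
        for (int a = 0; a < n_alleles[l]; ++a)
          P[static_cast<size_t>(off[l] + a) * K + k] /= s;
      }
    // --- Q | Z, alpha ---
    double sum_log_q = 0.0;
    for (int u = 0; u < n_units; ++u) {
      double s = 0.0;
      for (int k = 0; k < K; ++k) {
        double g = clamp_pos(rng.gamma(alpha + cntQ[static_cast<size_t>(u) * K + k]));
        Q[static_cast<size_t>(u) * K + k] = g; s += g;
      }
      for (int k = 0; k < K; ++k) {
        double q = Q[static_cast<size_t>(u) * K + k] / s;
        q = clamp_pos(q);
        Q[static_cast<size_t>(u) * K + k] = q;
        sum_log_q += std::log(q);
      }
    }
    // --- alpha | Q (random-walk Metropolis, uniform prior on (0, alpha_max]) ---
    if (update_alpha && K > 1) {
      double prop = alpha + alpha_sd * rng.normal();
      ++n_prop;
      if (prop > 0.0 && prop <= alpha_max) {
        double lr = n_units * (std::lgamma(K * prop) - K * std::lgamma(prop)
                               - std::lgamma(K * alpha) + K * std::lgamma(alpha))
                    + (prop - alpha) * sum_log_q;
        if (lr >= 0.0 || std::log(rng.unif()) < lr) { alpha = prop; ++n_accept; }
      }
    }
    // --- accumulation and likelihood recording ---
    if (sweep >= burnin) {
      ++n_kept;
      for (size_t i = 0; i < Qsum.size(); ++i) Qsum[i] += Q[i];
      for (size_t i = 0; i < Psum.size(); ++i) Psum[i] += P[i];
      if ((sweep - burnin) % ll_every == 0) {
        ll = 0.0;
        for (int c = 0; c < n_copies; ++c) {
          const double *qrow = Qd + static_cast<size_t>(cu[c]) * K;
          const double *prow = Pd + static_cast<size_t>(cs[c]) * K;
          double m = 0.0;
          for (int k = 0; k < K; ++k) m += qrow[k] * prow[k];
          ll += std::log(clamp_pos(m));
        }
        if (!std::isfinite(ll)) ll_finite = false;
        ll_rec.push_back(ll);
        alpha_rec.push_back(alpha);
      }
    }
    if (sweep % 4096 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix Qmean(n_units, K);
  for (int u = 0; u < n_units; ++u)
    for (int k = 0; k < K; ++k)
      Qmean(u, k) = Qsum[static_cast<size_t>(u) * K + k] / n_kept;
  // renormalize posterior means defensively
  for (int u = 0; u < n_units; ++u) {
    double s = 0.0;
    for (int k = 0; k < K; ++k) s += Qmean(u, k);
    for (int k = 0; k < K; ++k) Qmean(u, k) /= s;
  }
  List Pmean(n_loci);
  for (int l = 0; l < n_loci; ++l) {
    NumericMatrix pm(K, n_alleles[l]);
    for (int k = 0; k < K; ++k) {
      double s = 0.0;
      for (int a = 0; a < n_alleles[l]; ++a)
        s += Psum[static_cast<size_t>(off[l] + a) * K + k];
      for (int a = 0; a < n_alleles[l]; ++a)
        pm(k, a) = Psum[static_cast<size_t>(off[l] + a) * K + k] / s;
    }
    Pmean[l] = pm;
  }

  return List::create(
      _["Q"] = Qmean, _["P"] = Pmean,
      _["loglik"] = NumericVector(ll_rec.begin(), ll_rec.end()),
      _["alpha_trace"] = NumericVector(alpha_rec.begin(), alpha_rec.end()),
      _["alpha_accept_rate"] = n_prop > 0 ? double(n_accept) / n_prop : NA_REAL,
      _["loglik_finite"] = ll_finite);
}

// Draw n cluster assignments for one allele copy with P, Q frozen, using the
// sampler's own categorical routine; exposed to let tests compare the
// empirical distribution against the analytic conditional q_k * p_k.
// [[Rcpp::export]]
IntegerVector sample_z_conditional_cpp(NumericVector q, NumericVector p,
                                       int n, double seed) {
  const int K = q.size();
  if (p.size() != K) stop("q and p must have equal length");
  Xoshiro rng(static_cast<uint64_t>(seed));
  std::vector<double> w(K);
  double tot = 0.0;
  for (int k = 0; k < K; ++k) { w[k] = q[k] * p[k]; tot += w[k]; }
  IntegerVector counts(K);
  for (int i = 0; i < n; ++i) {
    int kc = K - 1;
    double r = rng.unif() * tot;
    double acc = 0.0;
    for (int k = 0; k < K; ++k) {
      acc += w[k];
      if (r <= acc) { kc = k; break; }
    }
    counts[kc] += 1;
  }
  return counts;
}
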