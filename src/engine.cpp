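// Fixed-step spatial tau-leap core.
//
// Per step and subvolume every reaction channel fires Poisson(a*dt) times
// (firings clipped so no reactant goes negative; clips are counted), then
// diffusible species jump between adjacent subvolumes with per-molecule
// leave probability 1 - exp(-D*G_i*dt), split multinomially over the
// neighbors. Injection events add Poisson-distributed molecule counts at
// their scheduled rate; clamp events pin a species to a fixed
// per-subvolume count while active.
//
// Random numbers come from an explicitly seeded xoshiro256++ counter
// stream (one stream per run), so trajectories are bitwise reproducible
// for a given seed independent of R's global RNG state. Large-mean
// Poisson and large-N binomial draws use clamped normal approximations,
// which leave leap means exact and are accurate at the molecule counts
// where they engage.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
using namespace Rcpp;

namespace {

struct Rng {
  uint64_t s[4];
  explicit Rng(uint64_t seed) {
    // splitmix64 expansion of the seed
    uint64_t z = seed + 0x9E3779B97F4A7C15ULL;
    for (int i = 0; i < 4; ++i) {
      z += 0x9E3779B97F4A7C15ULL;
      uint64_t x = z;
      x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
      x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
      s[i] = x ^ (x >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double u01() {  // uniform in (0,1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  bool have_norm = false;
  double cached_norm = 0.0;
  inline double norm() {
    if (have_norm) { have_norm = false; return cached_norm; }
    double u1 = u01(), u2 = u01();
    double r = std::sqrt(-2.0 * std::log(u1)), a = 6.283185307179586 * u2;
    cached_norm = r * std::sin(a);
    have_norm = true;
    return r * std::cos(a);
  }
  inline int pois(double lam) {
    if (lam <= 0.0) return 0;
    if (lam < 30.0) {
      double u = u01(), term = std::exp(-lam), F = term;
      int n = 0;
      while (u > F && n < 500) { ++n; term *= lam / n; F += term; }
      return n;
    }
    double x = std::floor(lam + std::sqrt(lam) * norm() + 0.5);
    return x < 0 ? 0 : (int) x;
  }
  inline int binom(int n, double p) {
    if (n <= 0 || p <= 0.0) return 0;
    if (p >= 1.0) return n;
    if (n <= 16) {
      int k = 0;
      for (int i = 0; i < n; ++i) k += (u01() < p);
      return k;
    }
    double np = n * (double) p;
    if (p < 0.05 && np < 15.0) {
      int k = pois(np);
      return k > n ? n : k;
    }
    double q = 1.0 - p;
    if (q < 0.05 && n * q < 15.0) {
      int k = pois(n * q);
      return n - (k > n ? n : k);
    }
    double x = std::floor(np + std::sqrt(np * q) * norm() + 0.5);
    if (x < 0) x = 0;
    if (x > n) x = n;
    return (int) x;
  }
};

}  // namespace

// [[Rcpp::export(name = ".simCore")]]
List simCore(IntegerMatrix counts,      // nspec x nsub
             NumericVector conv,        // nM per molecule, per subvolume
             IntegerVector ch_np, IntegerVector ch_r1, IntegerVector ch_r2,
             NumericVector ch_k,
             IntegerVector st_ptr, IntegerVector st_sp, IntegerVector st_d,
             IntegerVector cn_ptr, IntegerVector cn_sp, IntegerVector cn_n,
             IntegerVector diff_sp, NumericVector diff_D,
             IntegerVector nb_ptr, IntegerVector nb_idx,
             NumericVector nb_g,        // A/(V_i*d) per directed edge (1/um^2)
             IntegerVector ev_kind, IntegerVector ev_sp,
             NumericVector ev_t0, NumericVector ev_t1,
             NumericVector ev_r0, NumericVector ev_tau,
             IntegerVector ev_ptr, IntegerVector ev_sub, NumericVector ev_w,
             double dt, int nsteps, int record_every,
             IntegerVector group, int ngroups, double seed) {
  const int nspec = counts.nrow(), nsub = counts.ncol();
  const int nchan = ch_np.size(), ndiff = diff_sp.size(), nev = ev_kind.size();
  int* X = INTEGER(counts);
  Rng rng((uint64_t) seed);

  // per-subvolume total jump-geometry and neighbor split fractions
  std::vector<double> Gtot(nsub, 0.0);
  for (int i = 0; i < nsub; ++i)
    for (int e = nb_ptr[i]; e < nb_ptr[i + 1]; ++e) Gtot[i] += nb_g[e];
  std::vector<double> frac(nb_g.size());
  for (int i = 0; i < nsub; ++i)
    for (int e = nb_ptr[i]; e < nb_ptr[i + 1]; ++e)
      frac[e] = Gtot[i] > 0 ? nb_g[e] / Gtot[i] : 0.0;
  // fast diffusers in small subvolumes get substeps so that the
  // per-substep leave probability stays moderate (multi-hop error small)
  double Gmax = 0.0;
  for (int i = 0; i < nsub; ++i) if (Gtot[i] > Gmax) Gmax = Gtot[i];
  std::vector<int> nsplit(ndiff, 1);
  std::vector<double> pleave((size_t) ndiff * nsub);
  for (int d = 0; d < ndiff; ++d) {
    nsplit[d] = (int) std::ceil(diff_D[d] * Gmax * dt / 0.25);
    if (nsplit[d] < 1) nsplit[d] = 1;
    const double sdt = dt / nsplit[d];
    for (int i = 0; i < nsub; ++i)
      pleave[(size_t) d * nsub + i] = 1.0 - std::exp(-diff_D[d] * Gtot[i] * sdt);
  }
  // per-channel per-subvolume rate constants (unit conversion baked in)
  std::vector<double> ks((size_t) nchan * nsub);
  for (int c = 0; c < nchan; ++c)
    for (int i = 0; i < nsub; ++i)
      ks[(size_t) c * nsub + i] = ch_np[c] == 2 ? ch_k[c] * conv[i] * dt
                                                : ch_k[c] * dt;

  const int nrec = nsteps / record_every + 1;
  NumericVector rec((size_t) ngroups * nspec * nrec);
  double* RR = REAL(rec);
  double corrections = 0.0;
  std::vector<int> tmp(nsub);
  std::vector<int> active;
  int next_ev = 0, irec = 0;

  auto record = [&](int slot) {
    double* base = RR + (size_t) slot * ngroups * nspec;
    for (int s = 0; s < nsub; ++s) {
      const int g = group[s];
      const int* col = X + (size_t) s * nspec;
      double* out = base + (size_t) g;
      for (int k = 0; k < nspec; ++k) out[(size_t) k * ngroups] += col[k];
    }
  };
  record(irec++);

  for (int step = 0; step < nsteps; ++step) {
    const double t = step * dt;
    while (next_ev < nev && ev_t0[next_ev] <= t + 1e-12) active.push_back(next_ev++);
    for (size_t a = 0; a < active.size();) {
      if (t >= ev_t1[active[a]] - 1e-12) {
        active[a] = active.back(); active.pop_back();
      } else ++a;
    }
    // injections
    for (size_t a = 0; a < active.size(); ++a) {
      const int e = active[a];
      if (ev_kind[e] != 0) continue;
      double rate = ev_r0[e];
      if (ev_tau[e] > 0) rate *= std::exp(-(t - ev_t0[e]) / ev_tau[e]);
      const int sp = ev_sp[e];
      for (int k = ev_ptr[e]; k < ev_ptr[e + 1]; ++k)
        X[(size_t) ev_sub[k] * nspec + sp] += rng.pois(rate * dt * ev_w[k]);
    }
    // reactions
    for (int s = 0; s < nsub; ++s) {
      int* col = X + (size_t) s * nspec;
      for (int c = 0; c < nchan; ++c) {
        const int n1 = col[ch_r1[c]];
        if (n1 == 0) continue;
        double a = ks[(size_t) c * nsub + s] * n1;
        if (ch_np[c] == 2) {
          const int n2 = col[ch_r2[c]];
          if (n2 == 0) continue;
          a *= (double) n2;
        }
        int nf = rng.pois(a);
        if (nf == 0) continue;
        for (int k = cn_ptr[c]; k < cn_ptr[c + 1]; ++k) {
          const int avail = col[cn_sp[k]] / cn_n[k];
          if (nf > avail) { corrections += nf - avail; nf = avail; }
        }
        if (nf == 0) continue;
        for (int k = st_ptr[c]; k < st_ptr[c + 1]; ++k)
          col[st_sp[k]] += st_d[k] * nf;
      }
    }
    // diffusion (draws from a per-species snapshot of the counts)
    for (int d = 0; d < ndiff; ++d) {
      const int sp = diff_sp[d];
      const double* pl = &pleave[(size_t) d * nsub];
      for (int sub = 0; sub < nsplit[d]; ++sub) {
        bool any = false;
        for (int i = 0; i < nsub; ++i) {
          tmp[i] = X[(size_t) i * nspec + sp];
          any = any || tmp[i];
        }
        if (!any) break;
        for (int i = 0; i < nsub; ++i) {
          const int N = tmp[i];
          if (N == 0 || pl[i] <= 0) continue;
          int L = rng.binom(N, pl[i]);
          if (L == 0) continue;
          X[(size_t) i * nspec + sp] -= L;
          double fr = 1.0;
          for (int e = nb_ptr[i]; e < nb_ptr[i + 1] && L > 0; ++e) {
            const double f = frac[e];
            int m = (e == nb_ptr[i + 1] - 1) ? L
              : rng.binom(L, f / fr > 1.0 ? 1.0 : f / fr);
            if (m > 0) {
              X[(size_t) nb_idx[e] * nspec + sp] += m;
              L -= m;
            }
            fr -= f;
          }
        }
      }
    }
    // clamps
    for (size_t a = 0; a < active.size(); ++a) {
      const int e = active[a];
      if (ev_kind[e] != 1) continue;
      const int sp = ev_sp[e];
      for (int k = ev_ptr[e]; k < ev_ptr[e + 1]; ++k)
        X[(size_t) ev_sub[k] * nspec + sp] = (int) ev_w[k];
    }
    if ((step + 1) % record_every == 0) record(irec++);
  }

  return List::create(_["rec"] = rec, _["final"] = counts,
                      _["nrec"] = irec, _["corrections"] = corrections);
}
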