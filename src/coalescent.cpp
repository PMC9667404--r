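// Structured-coalescent simulator for multi-deme demographic models with
// divergence events, deme size changes, and time-windowed migration.
//
// Time runs backward in generations before present.  Haploid coalescent:
// k lineages in a deme of size Ne coalesce at rate k(k-1)/(2*Ne) per
// generation.  Migration rows are already expressed backward in time
// (a lineage currently in deme `from` jumps to deme `to` at `rate` per
// generation while t is inside [t0, t1)).
//
// Three output modes:
//   0  expected SFS: accumulate branch lengths into joint-SFS cells
//      (cell index = sum of per-sample stride contributions, so merging
//      two lineages just adds their indices);
//   1  sampled SFS: one genealogy per locus, Poisson(theta * total branch
//      length) infinite-sites mutations dropped on branches, integer cells;
//   2  genotypes: as mode 1 but emits per-mutation 0/1 rows over samples
//      with distinct positions within the locus.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// xoshiro256** with splitmix64 seeding: cheap per-replicate construction
// and platform-independent streams (everything specified here, nothing
// implementation-defined).
struct Rng {
  uint64_t s[4];
  explicit Rng(uint64_t seed) {
    for (int i = 0; i < 4; ++i) { seed = splitmix64(seed); s[i] = seed; }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  uint64_t next() {
    const uint64_t result = rotl(s[1] * 5, 7) * 9;
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  double unif() {  // in (0, 1)
    return (static_cast<double>(next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  int unif_int(int n) {  // 0 .. n-1
    int k = static_cast<int>(unif() * n);
    return k >= n ? n - 1 : k;
  }
  // Knuth Poisson in chunks so exp(-mu) never underflows
  int rpois(double mu) {
    int total = 0;
    while (mu > 60.0) { total += rpois_small(60.0); mu -= 60.0; }
    return total + rpois_small(mu);
  }
  int rpois_small(double mu) {
    if (mu <= 0) return 0;
    double L = std::exp(-mu), p = 1.0;
    int k = 0;
    do { ++k; p *= unif(); } while (p > L);
    return k - 1;
  }
};

struct Branch { double len; int cell; int slot; };

constexpr double EPS = 1e-9;

}  // namespace

// [[Rcpp::export(name = ".coal_core")]]
List coal_core(NumericVector ne0,
               IntegerVector lin_deme,
               IntegerVector lin_cell,
               int ncells,
               NumericMatrix events,   // cols: time, type(0 merge a->b, 1 Ne[a]=x), a, b, x
               NumericMatrix mig,      // cols: from, to, rate, t0, t1  (backward time)
               int n_sims, int mode, double theta, int locus_len,
               double seed, int n_batches) {
  const int nl = lin_deme.size();
  const int nd = ne0.size();
  const int nev = events.nrow();
  const int nmig = mig.nrow();
  if (nl < 2) stop("need at least two sampled lineages");
  if (n_sims < 1) stop("n_sims must be >= 1");
  for (int i = 0; i < nev - 1; ++i)
    if (events(i, 0) > events(i + 1, 0) + EPS) stop("events must be sorted by time");

  // change points where rates can jump: event times + window boundaries
  std::vector<double> chg;
  for (int i = 0; i < nev; ++i) chg.push_back(events(i, 0));
  for (int j = 0; j < nmig; ++j) {
    if (R_finite(mig(j, 3))) chg.push_back(mig(j, 3));
    if (R_finite(mig(j, 4))) chg.push_back(mig(j, 4));
  }
  std::sort(chg.begin(), chg.end());
  chg.erase(std::unique(chg.begin(), chg.end()), chg.end());
  const int nchg = static_cast<int>(chg.size());

  // flat copies of the event/migration tables (hot loop avoids Rcpp matrix
  // element access)
  std::vector<double> ev_t(nev), ev_x(nev);
  std::vector<int> ev_type(nev), ev_a(nev), ev_b(nev);
  for (int i = 0; i < nev; ++i) {
    ev_t[i] = events(i, 0); ev_type[i] = static_cast<int>(events(i, 1));
    ev_a[i] = static_cast<int>(events(i, 2));
    ev_b[i] = static_cast<int>(events(i, 3)); ev_x[i] = events(i, 4);
  }
  std::vector<double> mg_rate(nmig), mg_t0(nmig), mg_t1(nmig);
  std::vector<int> mg_from(nmig), mg_to(nmig);
  for (int j = 0; j < nmig; ++j) {
    mg_from[j] = static_cast<int>(mig(j, 0)); mg_to[j] = static_cast<int>(mig(j, 1));
    mg_rate[j] = mig(j, 2); mg_t0[j] = mig(j, 3); mg_t1[j] = mig(j, 4);
  }

  const int cap = 2 * nl;  // total branches over one genealogy
  std::vector<double> Ne(nd), blen(cap), cum;
  std::vector<int> deme(cap), cell(cap), kcnt(nd), lv;
  lv.reserve(nl);
  std::vector<double> crate(nd), mrate(nmig);
  std::vector<std::vector<int>> smp;         // mode 2: sample sets per slot
  std::vector<Branch> branches;

  const bool want_batches = (mode == 0 && n_batches > 1);
  NumericVector sfs(mode == 2 ? 1 : ncells);
  NumericMatrix batches(want_batches ? n_batches : 1,
                        want_batches ? ncells : 1);
  double total_len_sum = 0.0;

  // mode 2 output buffers
  std::vector<int> out_locus, out_pos;
  std::vector<int> out_geno;  // row-flattened, nl columns

  for (int rep = 0; rep < n_sims; ++rep) {
    Rng rng(splitmix64(static_cast<uint64_t>(seed) * 0x9E3779B97F4A7C15ULL +
                       static_cast<uint64_t>(rep) + 1ULL));
    for (int d = 0; d < nd; ++d) { Ne[d] = ne0[d]; kcnt[d] = 0; }
    int nslots = nl;
    lv.clear();
    for (int i = 0; i < nl; ++i) {
      deme[i] = lin_deme[i]; cell[i] = lin_cell[i];
      blen[i] = 0.0; kcnt[deme[i]]++;
      lv.push_back(i);
    }
    if (mode == 2) {
      smp.assign(cap, {});
      for (int i = 0; i < nl; ++i) smp[i] = { i };
    }
    branches.clear();
    double t = 0.0, rep_len = 0.0;
    int ei = 0, ci = 0;
    const int batch = want_batches
      ? static_cast<int>((static_cast<long long>(rep) * n_batches) / n_sims) : 0;

    while (static_cast<int>(lv.size()) > 1) {
      // apply demographic events scheduled at (or before) current time
      while (ei < nev && ev_t[ei] <= t + EPS) {
        const int a = ev_a[ei];
        if (ev_type[ei] == 0) {
          const int b = ev_b[ei];
          if (kcnt[a] > 0) {
            for (int i : lv) if (deme[i] == a) deme[i] = b;
            kcnt[b] += kcnt[a]; kcnt[a] = 0;
          }
        } else {
          Ne[a] = ev_x[ei];
        }
        ++ei;
      }
      while (ci < nchg && chg[ci] <= t + EPS) ++ci;
      const double tc = (ci < nchg) ? chg[ci] : R_PosInf;

      double R = 0.0;
      for (int d = 0; d < nd; ++d) {
        crate[d] = (kcnt[d] > 1) ? kcnt[d] * (kcnt[d] - 1.0) / (2.0 * Ne[d]) : 0.0;
        R += crate[d];
      }
      for (int j = 0; j < nmig; ++j) {
        const bool active = (t >= mg_t0[j] - EPS) && (t < mg_t1[j] - EPS);
        mrate[j] = active ? kcnt[mg_from[j]] * mg_rate[j] : 0.0;
        R += mrate[j];
      }

      double step;
      bool hit_change;
      if (R > 0.0) {
        const double dt = -std::log(rng.unif()) / R;
        if (t + dt < tc) { step = dt; hit_change = false; }
        else { step = tc - t; hit_change = true; }
      } else {
        if (!R_finite(tc))
          stop("model leaves lineages that can never coalesce (invalid spec)");
        step = tc - t; hit_change = true;
      }

      // accrue branch time
      if (mode == 0) {
        if (want_batches) {
          for (int i : lv) { sfs[cell[i]] += step; batches(batch, cell[i]) += step; }
        } else {
          for (int i : lv) sfs[cell[i]] += step;
        }
      } else {
        for (int i : lv) blen[i] += step;
      }
      rep_len += lv.size() * step;
      t += step;
      if (hit_change) continue;

      double u = rng.unif() * R;
      int picked_deme = -1, mig_row = -1;
      for (int d = 0; d < nd; ++d) {
        if (u < crate[d]) { picked_deme = d; break; }
        u -= crate[d];
      }
      if (picked_deme < 0) {
        for (int j = 0; j < nmig; ++j) {
          if (u < mrate[j]) { mig_row = j; break; }
          u -= mrate[j];
        }
        if (mig_row < 0) mig_row = nmig - 1;  // guard against rounding
      }

      if (picked_deme >= 0) {
        // coalesce a uniform pair within picked_deme
        const int k = kcnt[picked_deme];
        int r1 = rng.unif_int(k), r2 = rng.unif_int(k - 1);
        if (r2 >= r1) ++r2;
        int p1 = -1, p2 = -1, seen = 0;
        for (size_t p = 0; p < lv.size() && (p1 < 0 || p2 < 0); ++p) {
          if (deme[lv[p]] == picked_deme) {
            if (seen == r1) p1 = static_cast<int>(p);
            if (seen == r2) p2 = static_cast<int>(p);
            ++seen;
          }
        }
        const int i1 = lv[p1], i2 = lv[p2];
        const int nw = nslots++;
        deme[nw] = picked_deme; cell[nw] = cell[i1] + cell[i2];
        blen[nw] = 0.0;
        if (mode != 0) {
          branches.push_back({ blen[i1], cell[i1], i1 });
          branches.push_back({ blen[i2], cell[i2], i2 });
        }
        if (mode == 2) {
          smp[nw].clear();
          smp[nw].insert(smp[nw].end(), smp[i1].begin(), smp[i1].end());
          smp[nw].insert(smp[nw].end(), smp[i2].begin(), smp[i2].end());
        }
        lv[p1] = nw;
        lv[p2] = lv.back(); lv.pop_back();
        kcnt[picked_deme]--;
      } else {
        // migrate a uniform lineage out of mig(from)
        const int from = mg_from[mig_row];
        const int to = mg_to[mig_row];
        int r = rng.unif_int(kcnt[from]);
        for (int i : lv) {
          if (deme[i] == from) {
            if (r == 0) { deme[i] = to; break; }
            --r;
          }
        }
        kcnt[from]--; kcnt[to]++;
      }
    }
    total_len_sum += rep_len;

    if (mode != 0 && theta > 0.0) {
      double T = 0.0;
      for (const Branch& b : branches) T += b.len;
      int nmut = rng.rpois(theta * T);
      if (mode == 2 && nmut > locus_len) nmut = locus_len;  // finite-sites guard
      if (nmut > 0) {
        cum.resize(branches.size());
        double acc = 0.0;
        for (size_t b = 0; b < branches.size(); ++b) {
          acc += branches[b].len; cum[b] = acc;
        }
        if (mode == 1) {
          for (int mN = 0; mN < nmut; ++mN) {
            const double x = rng.unif() * T;
            const size_t b = std::lower_bound(cum.begin(), cum.end(), x) - cum.begin();
            sfs[branches[std::min(b, branches.size() - 1)].cell] += 1.0;
          }
        } else {
          // distinct positions within the locus (infinite sites on a finite grid)
          std::vector<int> pos;
          pos.reserve(nmut);
          {
            std::vector<char> used(locus_len, 0);
            while (static_cast<int>(pos.size()) < nmut) {
              const int p = rng.unif_int(locus_len);
              if (!used[p]) { used[p] = 1; pos.push_back(p + 1); }
            }
            std::sort(pos.begin(), pos.end());
          }
          for (int mN = 0; mN < nmut; ++mN) {
            const double x = rng.unif() * T;
            size_t b = std::lower_bound(cum.begin(), cum.end(), x) - cum.begin();
            b = std::min(b, branches.size() - 1);
            out_locus.push_back(rep + 1);
            out_pos.push_back(pos[mN]);
            const size_t base = out_geno.size();
            out_geno.resize(base + nl, 0);
            for (int s : smp[branches[b].slot]) out_geno[base + s] = 1;
          }
        }
      }
    }
  }

  List out = List::create(
    _["mean_total_length"] = total_len_sum / n_sims,
    _["n_sims"] = n_sims);
  if (mode == 2) {
    const int nrow = static_cast<int>(out_locus.size());
    IntegerMatrix geno(nrow, nl);
    for (int r = 0; r < nrow; ++r)
      for (int c = 0; c < nl; ++c) geno(r, c) = out_geno[static_cast<size_t>(r) * nl + c];
    out["locus"] = wrap(out_locus);
    out["position"] = wrap(out_pos);
    out["geno"] = geno;
  } else {
    out["sfs"] = sfs;
    if (want_batches) out["batches"] = batches;
  }
  return out;
}
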