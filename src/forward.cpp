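// Forward Wright-Fisher simulator with purifying selection.
//
// Diploid, random mating, multiplicative fitness across sites with genotype
// fitnesses 1, 1 - s/2, 1 - s (semidominance). Finite sites: at most one
// segregating mutation per site; a new mutation hitting an occupied site is
// redrawn; back mutation is disallowed (fixed sites stay occupied).
// Exonic mutations draw s from a 4-class discrete DFE over 2*Nanc*s bins
// [0,1), [1,10), [10,100), [100, 2*Nanc); other sites are neutral.
// Burn-in of burnin_mult * Nanc generations precedes the forward epochs.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <unordered_set>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

struct Mut {
  int pos;
  float s;
  int cls;      // -1 neutral (non-exonic), 0..3 DFE class
  int gen;      // generation of origin (relative to end of burn-in)
};

struct Hap {
  std::vector<int> neu; // mutation ids, sorted by position
  std::vector<int> sel;
};

struct StepMap {
  std::vector<double> cum;   // cumulative rate mass per window
  std::vector<double> start; // window starts (bp)
  std::vector<double> rate;
  double total;
  void build(const NumericVector& breaks, const NumericVector& rates) {
    start.assign(breaks.begin(), breaks.end() - 1);
    rate.assign(rates.begin(), rates.end());
    cum.resize(rate.size());
    double acc = 0;
    for (size_t i = 0; i < rate.size(); ++i) {
      acc += rate[i] * (breaks[i + 1] - breaks[i]);
      cum[i] = acc;
    }
    total = acc;
  }
  // inverse-CDF draw of a position
  double draw(std::mt19937_64& rng) const {
    double u = std::uniform_real_distribution<double>(0, total)(rng);
    size_t w = std::lower_bound(cum.begin(), cum.end(), u) - cum.begin();
    double lo = w == 0 ? 0.0 : cum[w - 1];
    return start[w] + (u - lo) / rate[w];
  }
};

} // namespace

static inline bool in_intervals(const std::vector<int>& st,
                                const std::vector<int>& en, int pos) {
  // intervals sorted, disjoint; find last start <= pos
  size_t i = std::upper_bound(st.begin(), st.end(), pos) - st.begin();
  return i > 0 && pos < en[i - 1];
}

// copy elements of src with positions inside segments owned by this parent
// haplotype, given sorted crossover breakpoints and a starting source flag.
static void copy_segments(const std::vector<int>& src,
                          const std::vector<Mut>& reg,
                          const std::vector<int>& bp, bool take_first,
                          std::vector<int>& out) {
  size_t k = 0;
  bool take = take_first;
  for (int id : src) {
    int p = reg[id].pos;
    while (k < bp.size() && p >= bp[k]) { take = !take; ++k; }
    if (take) out.push_back(id);
  }
}

// [[Rcpp::export]]
List forward_wf_cpp(double L,
                    IntegerMatrix exons,        // k x 2, 0-based half-open
                    NumericVector mu_breaks, NumericVector mu_rates,
                    NumericVector rec_breaks, NumericVector rec_rates,
                    NumericVector f,            // DFE proportions, length 4
                    double nanc_bins,           // diploid N for 2Ns bins
                    bool class0_neutral,
                    int n_init,                 // diploid size during burn-in
                    double burnin_mult,
                    NumericMatrix epochs,       // rows: gens, Nstart, Nend, mode
                    int n_sample,
                    int seed,
                    int scan_every = 8,
                    Nullable<List> init_sites = R_NilValue) {
  if (n_init < 2) stop("population too small");
  std::mt19937_64 rng((uint64_t)seed * 6364136223846793005ULL + 1442695040888963407ULL);
  std::uniform_real_distribution<double> runif(0.0, 1.0);

  StepMap mu, rec;
  mu.build(mu_breaks, mu_rates);
  rec.build(rec_breaks, rec_rates);

  std::vector<int> ex_st, ex_en;
  for (int i = 0; i < exons.nrow(); ++i) {
    ex_st.push_back(exons(i, 0));
    ex_en.push_back(exons(i, 1));
  }

  const double bin_lo[4] = {0.0, 1.0, 10.0, 100.0};
  const double bin_hi[4] = {1.0, 10.0, 100.0, 2.0 * nanc_bins};
  double fcum[4];
  double acc = 0;
  for (int i = 0; i < 4; ++i) { acc += f[i]; fcum[i] = acc; }
  if (std::fabs(acc - 1.0) > 1e-9) stop("DFE proportions must sum to 1");

  std::vector<Mut> reg;
  std::unordered_set<int> occupied;
  std::vector<int> live;

  int N = n_init;
  std::vector<Hap> pop(2 * N), nxt;

  // optional standing variation (e.g. a neutral-coalescent equilibrium
  // sample) seeding the population before the burn-in; sites enter as
  // neutral standing variants
  if (init_sites.isNotNull()) {
    List is(init_sites);
    IntegerVector ipos = is["pos"];
    List icar = is["carriers"];
    for (int s = 0; s < ipos.size(); ++s) {
      Mut mm;
      mm.pos = ipos[s];
      mm.s = 0.0f;
      mm.cls = -1;
      mm.gen = 0;
      int id = (int)reg.size();
      reg.push_back(mm);
      occupied.insert(mm.pos);
      live.push_back(id);
      IntegerVector cv = icar[s];
      for (int h : cv) {
        if (h < 0 || h >= 2 * N) stop("init carrier index out of range");
        pop[h].neu.push_back(id);
      }
    }
    for (auto& h : pop)
      std::sort(h.neu.begin(), h.neu.end(),
                [&](int a, int b) { return reg[a].pos < reg[b].pos; });
  }

  // schedule: burn-in followed by forward epochs
  long burnin = (long)std::llround(burnin_mult * n_init);
  std::vector<long> ep_gens;
  std::vector<double> ep_n0, ep_n1;
  std::vector<int> ep_mode;
  long total_post = 0;
  for (int i = 0; i < epochs.nrow(); ++i) {
    ep_gens.push_back((long)std::llround(epochs(i, 0)));
    ep_n0.push_back(epochs(i, 1));
    ep_n1.push_back(epochs(i, 2));
    ep_mode.push_back((int)epochs(i, 3));
    total_post += ep_gens.back();
  }

  std::vector<double> w(N);
  std::vector<int> cnt;

  std::vector<std::pair<int, int>> fixations; // (mut id, generation found)

  auto pop_size_at = [&](long g_post) -> int {
    long off = 0;
    for (size_t i = 0; i < ep_gens.size(); ++i) {
      if (g_post < off + ep_gens[i]) {
        double frac = (double)(g_post - off + 1) / (double)ep_gens[i];
        if (ep_mode[i] == 0) return (int)std::llround(ep_n0[i]);
        double nn = ep_n0[i] * std::pow(ep_n1[i] / ep_n0[i], frac);
        return std::max(2, (int)std::llround(nn));
      }
      off += ep_gens[i];
    }
    return ep_gens.empty() ? n_init
                           : std::max(2, (int)std::llround(ep_n1.back()));
  };

  auto scan = [&](long gen_post, int Ncur) {
    cnt.assign(reg.size(), 0);
    for (auto& h : pop) {
      for (int id : h.neu) ++cnt[id];
      for (int id : h.sel) ++cnt[id];
    }
    std::vector<int> keep;
    std::vector<char> drop(reg.size(), 0);
    bool any_fixed = false;
    for (int id : live) {
      if (cnt[id] == 0) {
        occupied.erase(reg[id].pos); // site free again (allele lost)
      } else if (cnt[id] == 2 * Ncur) {
        fixations.push_back({id, (int)gen_post});
        drop[id] = 1;
        any_fixed = true; // stays occupied: no back mutation
      } else {
        keep.push_back(id);
      }
    }
    live.swap(keep);
    if (any_fixed) {
      for (auto& h : pop) {
        auto rm = [&](std::vector<int>& v) {
          v.erase(std::remove_if(v.begin(), v.end(),
                                 [&](int id) { return drop[id] == 1; }),
                  v.end());
        };
        rm(h.neu);
        rm(h.sel);
      }
    }
  };

  long total_gens = burnin + total_post;
  std::vector<int> bps;
  // Poisson draws by sequential inversion (exact; fast for small means),
  // falling back to the library sampler for large means
  std::poisson_distribution<int> rpois_rec(rec.total);
  std::poisson_distribution<int> rpois_mut(mu.total);
  const double p0_rec = std::exp(-rec.total);
  const double p0_mut = std::exp(-mu.total);
  auto rpois_small = [&](double lambda, double p0,
                         std::poisson_distribution<int>& fb) -> int {
    if (lambda > 12.0) return fb(rng);
    double u = runif(rng);
    int k = 0;
    double p = p0, cum = p0;
    while (u >= cum) {
      ++k;
      p *= lambda / k;
      cum += p;
      if (k > 200) break;
    }
    return k;
  };
  std::vector<double> wcum;
  for (long g = 0; g < total_gens; ++g) {
    long g_post = g - burnin; // >= 0 once past burn-in
    int Nnew = (g_post >= 0) ? pop_size_at(g_post) : n_init;

    // parent fitnesses
    w.assign(N, 1.0);
    bool any_sel = false;
    for (int i = 0; i < N; ++i) {
      const std::vector<int>& a = pop[2 * i].sel;
      const std::vector<int>& b = pop[2 * i + 1].sel;
      if (a.empty() && b.empty()) continue;
      any_sel = true;
      double wi = 1.0;
      size_t ia = 0, ib = 0;
      while (ia < a.size() || ib < b.size()) {
        int pa = ia < a.size() ? reg[a[ia]].pos : INT32_MAX;
        int pb = ib < b.size() ? reg[b[ib]].pos : INT32_MAX;
        if (pa == pb) { // homozygote (same id: one mutation per site)
          wi *= 1.0 - reg[a[ia]].s;
          ++ia; ++ib;
        } else if (pa < pb) {
          wi *= 1.0 - 0.5 * reg[a[ia]].s;
          ++ia;
        } else {
          wi *= 1.0 - 0.5 * reg[b[ib]].s;
          ++ib;
        }
      }
      if (wi <= 0.0) stop("non-positive genotype fitness (s >= 1?)");
      w[i] = wi;
    }

    if (any_sel) { // cumulative fitness for binary-search sampling
      wcum.resize(N);
      double acc2 = 0;
      for (int i = 0; i < N; ++i) { acc2 += w[i]; wcum[i] = acc2; }
    }
    std::uniform_int_distribution<int> upick(0, N - 1);
    auto pick_parent = [&]() -> int {
      if (!any_sel) return upick(rng);
      double u = std::uniform_real_distribution<double>(0, wcum[N - 1])(rng);
      return (int)(std::lower_bound(wcum.begin(), wcum.end(), u) -
                   wcum.begin());
    };

    if ((int)nxt.size() < 2 * Nnew) nxt.resize(2 * Nnew);
    for (int c = 0; c < Nnew; ++c) {
      for (int par = 0; par < 2; ++par) {
        int p = pick_parent();
        Hap& out = nxt[2 * c + par];
        out.neu.clear();
        out.sel.clear();
        const Hap& h1 = pop[2 * p];
        const Hap& h2 = pop[2 * p + 1];
        // crossovers
        int nx = rpois_small(rec.total, p0_rec, rpois_rec);
        bps.clear();
        for (int x = 0; x < nx; ++x) bps.push_back((int)rec.draw(rng));
        std::sort(bps.begin(), bps.end());
        bool first = runif(rng) < 0.5;
        out.neu.reserve(h1.neu.size() + h2.neu.size());
        out.sel.reserve(h1.sel.size() + h2.sel.size() + 1);
        if (bps.empty()) {
          const Hap& src = first ? h1 : h2;
          out.neu = src.neu;
          out.sel = src.sel;
        } else {
          std::vector<int> tmp;
          copy_segments(h1.neu, reg, bps, first, out.neu);
          copy_segments(h2.neu, reg, bps, !first, tmp);
          std::vector<int> merged;
          merged.reserve(out.neu.size() + tmp.size());
          std::merge(out.neu.begin(), out.neu.end(), tmp.begin(), tmp.end(),
                     std::back_inserter(merged),
                     [&](int a2, int b2) { return reg[a2].pos < reg[b2].pos; });
          out.neu.swap(merged);
          tmp.clear();
          std::vector<int> s1;
          copy_segments(h1.sel, reg, bps, first, s1);
          copy_segments(h2.sel, reg, bps, !first, tmp);
          out.sel.clear();
          std::merge(s1.begin(), s1.end(), tmp.begin(), tmp.end(),
                     std::back_inserter(out.sel),
                     [&](int a2, int b2) { return reg[a2].pos < reg[b2].pos; });
        }
        // new mutations
        int nm = rpois_small(mu.total, p0_mut, rpois_mut);
        for (int m = 0; m < nm; ++m) {
          int posn = -1;
          for (int tries = 0; tries < 200; ++tries) {
            int cand = (int)mu.draw(rng);
            if (!occupied.count(cand)) { posn = cand; break; }
          }
          if (posn < 0) continue; // saturated neighbourhood; skip
          Mut mm;
          mm.pos = posn;
          mm.gen = (int)std::max((long)0, g_post + 1);
          mm.cls = -1;
          mm.s = 0.0f;
          if (in_intervals(ex_st, ex_en, posn)) {
            double u = runif(rng);
            int cls = 0;
            while (cls < 3 && u > fcum[cls]) ++cls;
            mm.cls = cls;
            if (!(cls == 0 && class0_neutral)) {
              double tns = bin_lo[cls] +
                runif(rng) * (bin_hi[cls] - bin_lo[cls]);
              mm.s = (float)(tns / (2.0 * nanc_bins));
              if (mm.s >= 1.0f) stop("sampled s >= 1");
            }
          }
          int id = (int)reg.size();
          reg.push_back(mm);
          occupied.insert(posn);
          live.push_back(id);
          std::vector<int>& vec = (mm.cls > 0 || (mm.cls == 0 && mm.s > 0))
                                      ? out.sel : out.neu;
          auto it = std::upper_bound(vec.begin(), vec.end(), mm.pos,
                                     [&](int pv, int idv) { return pv < reg[idv].pos; });
          vec.insert(it, id);
        }
      }
    }
    pop.swap(nxt);
    N = Nnew;
    if (g % scan_every == scan_every - 1 || g == total_gens - 1)
      scan(std::max((long)0, g_post), N);
  }
  scan(total_post, N);

  // sample n_sample diploids without replacement
  if (n_sample > N) stop("sample larger than population");
  std::vector<int> idx(N);
  for (int i = 0; i < N; ++i) idx[i] = i;
  for (int i = 0; i < n_sample; ++i) {
    int j = i + std::uniform_int_distribution<int>(0, N - 1 - i)(rng);
    std::swap(idx[i], idx[j]);
  }
  int nh = 2 * n_sample;
  // tally derived counts within sample
  cnt.assign(reg.size(), 0);
  for (int i = 0; i < n_sample; ++i) {
    for (int hp = 0; hp < 2; ++hp) {
      const Hap& h = pop[2 * idx[i] + hp];
      for (int id : h.neu) ++cnt[id];
      for (int id : h.sel) ++cnt[id];
    }
  }
  std::vector<int> segsites;
  int n_mono_derived = 0;
  for (int id : live)
    if (cnt[id] > 0) {
      if (cnt[id] < nh) segsites.push_back(id);
      else ++n_mono_derived;
    }
  std::sort(segsites.begin(), segsites.end(),
            [&](int a, int b) { return reg[a].pos < reg[b].pos; });
  std::vector<int> col(reg.size(), -1);
  for (size_t s = 0; s < segsites.size(); ++s) col[segsites[s]] = (int)s;
  IntegerMatrix geno(nh, (int)segsites.size());
  for (int i = 0; i < n_sample; ++i)
    for (int hp = 0; hp < 2; ++hp) {
      const Hap& h = pop[2 * idx[i] + hp];
      int row = 2 * i + hp;
      for (int id : h.neu) if (col[id] >= 0) geno(row, col[id]) = 1;
      for (int id : h.sel) if (col[id] >= 0) geno(row, col[id]) = 1;
    }

  int S = (int)segsites.size();
  IntegerVector pos(S), cls(S), count(S);
  NumericVector sval(S);
  for (int s = 0; s < S; ++s) {
    pos[s] = reg[segsites[s]].pos;
    cls[s] = reg[segsites[s]].cls;
    sval[s] = reg[segsites[s]].s;
    count[s] = cnt[segsites[s]];
  }
  int nf = (int)fixations.size();
  IntegerVector fpos(nf), fgen(nf), fcls(nf);
  NumericVector fs(nf);
  for (int i = 0; i < nf; ++i) {
    fpos[i] = reg[fixations[i].first].pos;
    fgen[i] = fixations[i].second;
    fcls[i] = reg[fixations[i].first].cls;
    fs[i] = reg[fixations[i].first].s;
  }
  return List::create(
      _["pos"] = pos, _["s"] = sval, _["class"] = cls, _["count"] = count,
      _["geno"] = geno, _["n_mono_derived"] = n_mono_derived,
      _["fix_pos"] = fpos, _["fix_gen"] = fgen, _["fix_class"] = fcls,
      _["fix_s"] = fs, _["gens_post_burnin"] = (double)total_post,
      _["n_final"] = N);
}
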