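// Neutral coalescent engine under piecewise population-size histories.
//
// The sequence is split into independently simulated chunks (free
// recombination between chunks, none within); see the methods vignette for
// the scope of this approximation. Epochs are ordered backwards in time from
// the present. Each epoch row is (duration, N_recent, N_ancient, mode, jump):
//   mode 0 = constant size, 1 = exponential change (forward in time),
//   jump  > 0 with duration 0 = instantaneous burst of coalescent intensity
//           (in units of pairwise coalescent "omega", i.e. int dt/(2N)).
// All sizes are diploid; B multiplies every size (BGS rescaling).

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct Epoch {
  double dur;    // generations (can be Inf for the last epoch)
  double nrec;   // diploid size at the recent edge
  double nanc;   // diploid size at the ancient edge
  int mode;      // 0 constant, 1 exponential
  double jump;   // omega units, consumed instantaneously
};

struct DemogWalker {
  const std::vector<Epoch>& ep;
  size_t idx;     // current epoch
  double x;       // backward time within current epoch
  double t;       // absolute backward time (generations)
  double B;

  DemogWalker(const std::vector<Epoch>& e, double b)
    : ep(e), idx(0), x(0.0), t(0.0), B(b) {}

  // Advance until c * omega == target has been consumed; returns when the
  // coalescence happens (time() gives the absolute time).
  void consume(double c, double target) {
    while (true) {
      const Epoch& e = ep[idx];
      if (e.jump > 0.0 && e.dur <= 0.0) {
        double cap = c * (e.jump - x); // x reused as consumed omega in pulse
        if (target <= cap) { x += target / c; return; }
        target -= cap; ++idx; x = 0.0; continue;
      }
      if (e.mode == 0 || e.nrec == e.nanc) {
        double rate = c / (2.0 * B * e.nrec);          // per generation
        double need = target / rate;                   // generations
        double rem = e.dur - x;
        if (need <= rem) { x += need; t += need; return; }
        target -= rem * rate; t += rem; ++idx; x = 0.0; continue;
      }
      // exponential: N(x) = nrec * exp(-g x), g = log(nrec/nanc)/dur
      double g = std::log(e.nrec / e.nanc) / e.dur;
      double a = 1.0 / (2.0 * B * e.nrec);
      // omega(x1->x2) = a/g * (exp(g x2) - exp(g x1))
      double rem_omega = a / g * (std::exp(g * e.dur) - std::exp(g * x));
      double cap = c * rem_omega;
      if (target <= cap) {
        double x2 = std::log(std::exp(g * x) + g * target / (c * a)) / g;
        t += x2 - x; x = x2; return;
      }
      target -= cap; t += e.dur - x; ++idx; x = 0.0;
    }
  }
};

std::vector<Epoch> as_epochs(const NumericMatrix& m) {
  std::vector<Epoch> out;
  for (int i = 0; i < m.nrow(); ++i)
    out.push_back({m(i, 0), m(i, 1), m(i, 2), (int)m(i, 3), m(i, 4)});
  // guard: ensure final epoch is effectively open-ended
  if (out.empty()) stop("empty demography");
  return out;
}

} // namespace

// Simulate a single tree; fills branch length per subtended-leaf-count.
// lens[b-1] accumulates total branch length subtending exactly b leaves.
// If carriers != nullptr, also records per-branch leaf sets and lengths.
static void sim_tree(int n, const std::vector<Epoch>& ep, double B,
                     std::mt19937_64& rng, std::vector<double>& lens,
                     std::vector<std::vector<int>>* leafsets = nullptr,
                     std::vector<double>* leaflens = nullptr) {
  std::exponential_distribution<double> rexp(1.0);
  std::vector<int> size(n, 1);
  std::vector<double> birth(n, 0.0);
  std::vector<std::vector<int>> leaves;
  if (leafsets) {
    leaves.resize(n);
    for (int i = 0; i < n; ++i) leaves[i] = {i};
  }
  DemogWalker w(ep, B);
  int k = n;
  while (k > 1) {
    double c = 0.5 * k * (k - 1);
    w.consume(c, rexp(rng));
    double t = w.t;
    std::uniform_int_distribution<int> ui(0, k - 1);
    int i = ui(rng);
    int j = std::uniform_int_distribution<int>(0, k - 2)(rng);
    if (j >= i) ++j;
    if (i > j) std::swap(i, j);
    for (int idx2 : {i, j}) {
      double len = t - birth[idx2];
      lens[size[idx2] - 1] += len;
      if (leafsets) { leafsets->push_back(leaves[idx2]); leaflens->push_back(len); }
    }
    // merge j into i
    size[i] += size[j];
    birth[i] = t;
    if (leafsets) {
      leaves[i].insert(leaves[i].end(), leaves[j].begin(), leaves[j].end());
      leaves[j] = std::move(leaves[k - 1]);
    }
    size[j] = size[k - 1];
    birth[j] = birth[k - 1];
    --k;
  }
}

// [[Rcpp::export]]
List coalescent_engine_cpp(int n_hap, double L, double mu,
                           NumericMatrix epochs, double B,
                           double chunk_bp, int n_rep, int output,
                           int seed) {
  if (n_hap < 2) stop("n_hap must be >= 2");
  std::vector<Epoch> ep = as_epochs(epochs);
  std::mt19937_64 rng((uint64_t)seed * 2654435761u + 1u);
  int nchunk = (int)std::ceil(L / chunk_bp);

  if (output == 0) { // segregating-site counts per replicate
    NumericVector S(n_rep);
    std::vector<double> lens(n_hap);
    for (int r = 0; r < n_rep; ++r) {
      double s = 0.0;
      for (int ch = 0; ch < nchunk; ++ch) {
        double clen = std::min(chunk_bp, L - ch * chunk_bp);
        std::fill(lens.begin(), lens.end(), 0.0);
        sim_tree(n_hap, ep, B, rng, lens);
        double tot = 0.0;
        for (int b = 0; b < n_hap - 1; ++b) tot += lens[b];
        std::poisson_distribution<long> rpois(mu * clen * tot);
        s += (double)rpois(rng);
      }
      S[r] = s;
    }
    return List::create(_["S"] = S);
  }

  if (output == 1) { // SFS counts (n_rep x (n_hap-1))
    IntegerMatrix sfs(n_rep, n_hap - 1);
    std::vector<double> lens(n_hap), acc(n_hap);
    for (int r = 0; r < n_rep; ++r) {
      std::fill(acc.begin(), acc.end(), 0.0);
      for (int ch = 0; ch < nchunk; ++ch) {
        double clen = std::min(chunk_bp, L - ch * chunk_bp);
        std::fill(lens.begin(), lens.end(), 0.0);
        sim_tree(n_hap, ep, B, rng, lens);
        for (int b = 0; b < n_hap - 1; ++b) acc[b] += clen * lens[b];
      }
      for (int b = 0; b < n_hap - 1; ++b) {
        std::poisson_distribution<long> rpois(mu * acc[b]);
        sfs(r, b) = (int)rpois(rng);
      }
    }
    return List::create(_["sfs"] = sfs);
  }

  // output == 2: full site data for a single replicate (positions, carriers)
  std::vector<double> lens(n_hap);
  std::vector<std::vector<int>> leafsets;
  std::vector<double> leaflens;
  std::vector<double> pos;
  std::vector<std::vector<int>> carriers;
  for (int ch = 0; ch < nchunk; ++ch) {
    double clen = std::min(chunk_bp, L - ch * chunk_bp);
    double off = ch * chunk_bp;
    std::fill(lens.begin(), lens.end(), 0.0);
    leafsets.clear(); leaflens.clear();
    sim_tree(n_hap, ep, B, rng, lens, &leafsets, &leaflens);
    for (size_t e = 0; e < leafsets.size(); ++e) {
      std::poisson_distribution<int> rpois(mu * clen * leaflens[e]);
      int nm = rpois(rng);
      for (int m = 0; m < nm; ++m) {
        double p = off + std::uniform_real_distribution<double>(0, clen)(rng);
        pos.push_back(p);
        carriers.push_back(leafsets[e]);
      }
    }
  }
  // sort by position
  std::vector<size_t> ord(pos.size());
  for (size_t i = 0; i < ord.size(); ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](size_t a, size_t b) { return pos[a] < pos[b]; });
  NumericVector opos(pos.size());
  List ocar(pos.size());
  for (size_t i = 0; i < ord.size(); ++i) {
    opos[i] = std::floor(pos[ord[i]]);
    IntegerVector cv(carriers[ord[i]].begin(), carriers[ord[i]].end());
    ocar[i] = cv;
  }
  return List::create(_["pos"] = opos, _["carriers"] = ocar);
}
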