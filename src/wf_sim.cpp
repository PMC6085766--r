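// Forward Wright-Fisher simulator: one ancestral population evolved to
// mutation-drift equilibrium, split into three daughter populations, with an
// optional hard sweep (additive selection) in the first daughter.  Haplotypes
// are sparse sorted vectors of derived-allele positions on a discrete bp grid
// (infinite-sites: a position is never hit twice while segregating).
// Uses R's RNG throughout so set.seed() in R makes runs bit-reproducible.

#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <algorithm>
using namespace Rcpp;

typedef std::vector<int> Hap;
typedef std::vector<Hap> Pop; // 2N haplotypes; individual i = rows 2i, 2i+1

static inline int unif_pos(int L) {
  int x = 1 + (int)(unif_rand() * L);
  return x > L ? L : x;
}

static inline bool carries(const Hap &h, int pos) {
  return std::binary_search(h.begin(), h.end(), pos);
}

// One recombinant gamete from a diploid parent (haplotypes a, b).
static Hap make_gamete(const Hap &a, const Hap &b, double r_total, int L) {
  int k = (int)R::rpois(r_total);
  bool cur_is_a = unif_rand() < 0.5;
  if (k == 0) return cur_is_a ? a : b;
  std::vector<int> bps(k);
  for (int i = 0; i < k; i++) bps[i] = unif_pos(L);
  std::sort(bps.begin(), bps.end());
  Hap out;
  out.reserve(std::max(a.size(), b.size()) + 4);
  size_t ia = 0, ib = 0;
  int prev = 0;
  for (int s = 0; s <= k; s++) {
    int hi = (s < k) ? bps[s] : L;
    if (hi > prev) {
      if (cur_is_a) {
        while (ia < a.size() && a[ia] <= prev) ia++;
        while (ia < a.size() && a[ia] <= hi) out.push_back(a[ia++]);
      } else {
        while (ib < b.size() && b[ib] <= prev) ib++;
        while (ib < b.size() && b[ib] <= hi) out.push_back(b[ib++]);
      }
      prev = hi;
    }
    cur_is_a = !cur_is_a;
  }
  return out;
}

// Poisson(mu_total) new mutations; duplicate bp draws (infinite-sites
// collisions) are redrawn a few times, then discarded.
static void mutate(Hap &h, double mu_total, int L,
                   std::unordered_set<int> &used) {
  int m = (int)R::rpois(mu_total);
  for (int i = 0; i < m; i++) {
    int pos = 0;
    bool ok = false;
    for (int t = 0; t < 50; t++) {
      pos = unif_pos(L);
      if (!used.count(pos)) { ok = true; break; }
    }
    if (!ok) continue;
    used.insert(pos);
    h.insert(std::upper_bound(h.begin(), h.end(), pos), pos);
  }
}

static int count_allele(const Pop &pop, int pos) {
  int c = 0;
  for (const Hap &h : pop)
    if (carries(h, pos)) c++;
  return c;
}

// One non-overlapping WF generation. s > 0 applies additive selection on the
// allele at sweep_pos (fitness 1, 1+s, 1+2s).
static void next_generation(Pop &pop, double mu_total, double r_total, int L,
                            std::unordered_set<int> &used, double s,
                            int sweep_pos) {
  int H = (int)pop.size(), N = H / 2;
  std::vector<double> cum;
  double tot = 0.0;
  bool sel = (s > 0.0 && sweep_pos > 0);
  if (sel) {
    cum.resize(N);
    for (int i = 0; i < N; i++) {
      int g = (carries(pop[2 * i], sweep_pos) ? 1 : 0) +
              (carries(pop[2 * i + 1], sweep_pos) ? 1 : 0);
      tot += 1.0 + s * g;
      cum[i] = tot;
    }
  }
  Pop nxt;
  nxt.reserve(H);
  for (int i = 0; i < N; i++) {
    int pa, pb;
    if (sel) {
      double u = unif_rand() * tot;
      pa = (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
      u = unif_rand() * tot;
      pb = (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
    } else {
      pa = (int)(unif_rand() * N); if (pa >= N) pa = N - 1;
      pb = (int)(unif_rand() * N); if (pb >= N) pb = N - 1;
    }
    Hap g1 = make_gamete(pop[2 * pa], pop[2 * pa + 1], r_total, L);
    mutate(g1, mu_total, L, used);
    Hap g2 = make_gamete(pop[2 * pb], pop[2 * pb + 1], r_total, L);
    mutate(g2, mu_total, L, used);
    nxt.push_back(std::move(g1));
    nxt.push_back(std::move(g2));
  }
  pop.swap(nxt);
}

// Drop positions fixed in every haplotype (they become the new ancestral
// state) and rebuild `used` as the currently segregating set so lost
// positions can be reused by later mutations.
static void cleanup(Pop &pop, std::unordered_set<int> &used, int reserve_pos) {
  std::unordered_map<int, int> cnt;
  for (const Hap &h : pop)
    for (int p : h) cnt[p]++;
  int H = (int)pop.size();
  std::unordered_set<int> fixed;
  used.clear();
  for (const auto &kv : cnt) {
    if (kv.second == H) fixed.insert(kv.first);
    else used.insert(kv.first);
  }
  if (reserve_pos > 0) used.insert(reserve_pos);
  if (fixed.empty()) return;
  for (Hap &h : pop)
    h.erase(std::remove_if(h.begin(), h.end(),
                           [&](int p) { return fixed.count(p) > 0; }),
            h.end());
}

// [[Rcpp::export]]
List wf_simulate_cpp(int n_diploid, int L, double mu, double r, int burn_in,
                     int split_gens, double s, int sweep_pos,
                     int sweep_intro_gen, IntegerVector sample_sizes,
                     double sweep_min_freq, int max_retries) {
  double mu_total = mu * (double)L;
  double r_total = r * (double)L;
  int H = 2 * n_diploid;

  // Burn-in of the ancestral population from a monomorphic start.
  Pop anc(H);
  std::unordered_set<int> used;
  for (int g = 0; g < burn_in; g++) {
    next_generation(anc, mu_total, r_total, L, used, 0.0, 0);
    if ((g + 1) % 100 == 0) cleanup(anc, used, 0);
  }
  cleanup(anc, used, s > 0 ? sweep_pos : 0);
  if (s > 0) {
    // reserve the sweep site: clear any segregating neutral allele there
    for (Hap &h : anc)
      h.erase(std::remove(h.begin(), h.end(), sweep_pos), h.end());
  }

  // Split: three daughters start as copies of the ancestor.
  Pop popF = anc, pop1 = anc, pop2 = anc;
  anc.clear(); anc.shrink_to_fit();

  // Sweep in the focal daughter: neutral drift until sweep_intro_gen, then
  // a single copy of the sweep allele evolves under selection for the rest
  // of the epoch, conditioned on reaching sweep_min_freq by the end
  // (restart the selection phase on loss or shortfall).  Introducing the
  // allele late keeps the sweep recent at sampling time.
  int attempts = 0;
  double final_freq = 0.0;
  if (s > 0) {
    if (sweep_intro_gen < 0 || sweep_intro_gen >= split_gens)
      stop("sweep_intro_gen must lie in [0, split_gens)");
    for (int g = 0; g < sweep_intro_gen; g++)
      next_generation(popF, mu_total, r_total, L, used, 0.0, 0);
    int sel_gens = split_gens - sweep_intro_gen;
    Pop saved = popF;
    std::unordered_set<int> used_saved = used;
    bool ok = false;
    while (attempts < max_retries && !ok) {
      attempts++;
      popF = saved;
      used = used_saved;
      int h0 = (int)(unif_rand() * H); if (h0 >= H) h0 = H - 1;
      Hap &hh = popF[h0];
      hh.insert(std::upper_bound(hh.begin(), hh.end(), sweep_pos), sweep_pos);
      bool lost = false;
      for (int g = 0; g < sel_gens; g++) {
        next_generation(popF, mu_total, r_total, L, used, s, sweep_pos);
        if (count_allele(popF, sweep_pos) == 0) { lost = true; break; }
      }
      if (!lost) {
        final_freq = count_allele(popF, sweep_pos) / (double)H;
        if (final_freq >= sweep_min_freq) ok = true;
      }
    }
    if (!ok)
      stop("sweep allele failed to reach frequency %f within %d attempts; "
           "increase the selection coefficient s or split_time_gens",
           sweep_min_freq, max_retries);
  } else {
    for (int g = 0; g < split_gens; g++)
      next_generation(popF, mu_total, r_total, L, used, 0.0, 0);
  }
  for (int g = 0; g < split_gens; g++)
    next_generation(pop1, mu_total, r_total, L, used, 0.0, 0);
  for (int g = 0; g < split_gens; g++)
    next_generation(pop2, mu_total, r_total, L, used, 0.0, 0);

  // Sample the first n_i diploids of each population (exchangeable).
  std::vector<const Pop *> pops = {&popF, &pop1, &pop2};
  std::vector<Hap> sample;
  for (int p = 0; p < 3; p++) {
    int n = sample_sizes[p];
    if (2 * n > H) stop("sample size exceeds population size");
    for (int i = 0; i < 2 * n; i++) sample.push_back((*pops[p])[i]);
  }
  int Hs = (int)sample.size();

  // Positions polymorphic in the combined sample, ascending.
  std::unordered_map<int, int> cnt;
  for (const Hap &h : sample)
    for (int p : h) cnt[p]++;
  std::vector<int> keep;
  keep.reserve(cnt.size());
  for (const auto &kv : cnt)
    if (kv.second > 0 && kv.second < Hs) keep.push_back(kv.first);
  std::sort(keep.begin(), keep.end());
  int S = (int)keep.size();

  IntegerMatrix alleles(Hs, S);
  std::unordered_map<int, int> colof;
  for (int j = 0; j < S; j++) colof[keep[j]] = j;
  for (int i = 0; i < Hs; i++)
    for (int p : sample[i]) {
      auto it = colof.find(p);
      if (it != colof.end()) alleles(i, it->second) = 1;
    }

  return List::create(_["positions"] = IntegerVector(keep.begin(), keep.end()),
                      _["alleles"] = alleles,
                      _["sweep_freq"] = final_freq,
                      _["attempts"] = attempts);
}
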