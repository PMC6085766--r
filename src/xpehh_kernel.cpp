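// XP-EHH scan kernel.  For each core SNP, EHH is tracked outward in both
// directions for the focal population, the reference population, and the
// pooled sample; the walk stops at the first marker where the pooled EHH
// falls below the cutoff (that marker is included in the integral), giving
// both populations a shared truncation boundary.  EHH is unconditioned on
// the core allele: the identity partition starts trivial at the core
// (EHH(core) = 1) and is refined by flanking markers only.

#include <Rcpp.h>
using namespace Rcpp;

static inline double pair_hom(const std::vector<int> &sizes, int H) {
  double num = 0.0;
  for (int n : sizes) num += 0.5 * n * (n - 1);
  return num / (0.5 * H * (H - 1));
}

struct Partition {
  std::vector<int> cls; // class id per haplotype
  int ncls;
  explicit Partition(int H) : cls(H, 0), ncls(1) {}
  // refine by a 0/1 allele column; returns EHH after refinement
  template <typename Acc>
  double refine(const Acc &allele, int H) {
    std::vector<int> relab(2 * ncls, -1);
    int nn = 0;
    for (int i = 0; i < H; i++) {
      int key = cls[i] * 2 + allele(i);
      if (relab[key] < 0) relab[key] = nn++;
      cls[i] = relab[key];
    }
    ncls = nn;
    std::vector<int> sizes(nn, 0);
    for (int i = 0; i < H; i++) sizes[cls[i]]++;
    return pair_hom(sizes, H);
  }
};

// [[Rcpp::export(rng = false)]]
DataFrame xpehh_core_cpp(const IntegerMatrix &hapF, const IntegerMatrix &hapR,
                         const IntegerVector &positions, double cutoff) {
  int HF = hapF.nrow(), HR = hapR.nrow(), S = hapF.ncol();
  if (hapR.ncol() != S || positions.size() != S)
    stop("haplotype matrices and positions disagree on site count");
  NumericVector ihhF(S, NA_REAL), ihhR(S, NA_REAL);
  LogicalVector eligible(S), edge(S);

  for (int core = 0; core < S; core++) {
    int tot = 0;
    for (int i = 0; i < HF; i++) tot += hapF(i, core);
    for (int i = 0; i < HR; i++) tot += hapR(i, core);
    if (tot == 0 || tot == HF + HR) { eligible[core] = false; continue; }
    eligible[core] = true;

    double areaF = 0.0, areaR = 0.0;
    bool hit_edge = false;
    for (int dir = -1; dir <= 1; dir += 2) {
      Partition pF(HF), pR(HR), pC(HF + HR);
      double ehhF = 1.0, ehhR = 1.0;
      double prev_pos = positions[core];
      bool truncated = false;
      for (int j = core + dir; j >= 0 && j < S; j += dir) {
        double eF = pF.refine([&](int i) { return hapF(i, j); }, HF);
        double eR = pR.refine([&](int i) { return hapR(i, j); }, HR);
        double eC = pC.refine(
            [&](int i) { return i < HF ? hapF(i, j) : hapR(i - HF, j); },
            HF + HR);
        double w = std::abs(positions[j] - prev_pos);
        areaF += w * 0.5 * (ehhF + eF);
        areaR += w * 0.5 * (ehhR + eR);
        ehhF = eF;
        ehhR = eR;
        prev_pos = positions[j];
        if (eC < cutoff) { truncated = true; break; }
      }
      if (!truncated) { hit_edge = true; break; }
    }
    edge[core] = hit_edge;
    if (!hit_edge) { ihhF[core] = areaF; ihhR[core] = areaR; }
  }
  return DataFrame::create(_["pos"] = positions, _["ihh_focal"] = ihhF,
                           _["ihh_ref"] = ihhR, _["eligible"] = eligible,
                           _["edge"] = edge);
}
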