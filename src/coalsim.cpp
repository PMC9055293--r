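// Event-driven structured coalescent for two demes with piecewise-constant
// migration, infinite-sites mutation, no recombination.
//
// Time is in units of 4*N0 generations: pair coalescence rate within a deme
// of relative size x is 2/x, each lineage in the recipient deme jumps to the
// donor deme at the scaled rate 4*N0*m of the corresponding forward-time
// flow, and mutations fall as Poisson(theta * total branch length).
// Uses R's RNG throughout so set.seed() gives bit-identical output.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

struct Segment {
  double len;
  std::vector<int> tips;
};

inline double pair_rate(int k, double x) {
  return k < 2 ? 0.0 : (k * (k - 1)) / x; // C(k,2) * 2/x
}

} // namespace

// epochs: matrix with columns (t0, t1, bw12, bw21) tiling [0, tdiv];
// bw12 = backward jump rate deme1 -> deme2 (forward-time flow 2 -> 1),
// bw21 = backward jump rate deme2 -> deme1.
// [[Rcpp::export(name = ".sim_locus_cpp")]]
List sim_locus_cpp(int n1, int n2, double x1, double x2, double tdiv,
                   NumericMatrix epochs, double theta) {
  int n = n1 + n2;
  std::vector<int> deme;
  std::vector<double> len;
  std::vector<std::vector<int> > tips;
  deme.reserve(2 * n); len.reserve(2 * n); tips.reserve(2 * n);
  for (int i = 0; i < n; ++i) {
    deme.push_back(i < n1 ? 0 : 1);
    len.push_back(0.0);
    tips.push_back(std::vector<int>(1, i));
  }
  std::vector<Segment> frozen;
  frozen.reserve(2 * n);

  double t = 0.0;
  int ep = 0;
  const int nep = epochs.nrow();
  int k = n;

  while (k > 1) {
    bool merged = (t >= tdiv);
    double bw12 = 0.0, bw21 = 0.0, boundary = R_PosInf;
    if (!merged) {
      while (ep < nep - 1 && t >= epochs(ep, 1)) ++ep;
      bw12 = epochs(ep, 2);
      bw21 = epochs(ep, 3);
      boundary = epochs(ep, 1) < tdiv ? epochs(ep, 1) : tdiv;
    }
    int k1 = 0, k2 = 0;
    for (size_t i = 0; i < deme.size(); ++i) (deme[i] == 0 ? k1 : k2)++;
    double rc1, rc2, rm1, rm2;
    if (merged) {
      rc1 = pair_rate(k, 1.0); rc2 = 0.0; rm1 = rm2 = 0.0;
    } else {
      rc1 = pair_rate(k1, x1);
      rc2 = pair_rate(k2, x2);
      rm1 = k1 * bw12;
      rm2 = k2 * bw21;
    }
    double R = rc1 + rc2 + rm1 + rm2;

    double dt;
    bool hit_boundary;
    if (R <= 0.0) {
      // nothing can happen in this epoch (e.g. one lineage per deme, no
      // migration): slide to the next boundary
      dt = boundary - t;
      hit_boundary = true;
    } else {
      dt = R::exp_rand() / R;
      hit_boundary = (t + dt > boundary);
      if (hit_boundary) dt = boundary - t;
    }
    for (size_t i = 0; i < len.size(); ++i) len[i] += dt;
    t += dt;
    if (hit_boundary) continue;

    double u = unif_rand() * R;
    if (u < rc1 + rc2) {
      int d = (u < rc1) ? 0 : 1;
      if (merged) d = -1; // any deme label counts
      // pick an unordered pair uniformly within the deme
      std::vector<int> idx;
      for (size_t i = 0; i < deme.size(); ++i)
        if (d < 0 || deme[i] == d) idx.push_back((int)i);
      int kk = (int)idx.size();
      int a = (int)(unif_rand() * kk); if (a >= kk) a = kk - 1;
      int b = (int)(unif_rand() * (kk - 1)); if (b >= kk - 1) b = kk - 2;
      if (b >= a) ++b;
      int ia = idx[a], ib = idx[b];
      Segment sa; sa.len = len[ia]; sa.tips = tips[ia]; frozen.push_back(sa);
      Segment sb; sb.len = len[ib]; sb.tips = tips[ib]; frozen.push_back(sb);
      std::vector<int> merged_tips(tips[ia]);
      merged_tips.insert(merged_tips.end(), tips[ib].begin(), tips[ib].end());
      int parent_deme = (d < 0) ? 0 : d;
      // remove ib first (larger swap-safe removal), then ia
      int hi = ia > ib ? ia : ib, lo = ia > ib ? ib : ia;
      deme.erase(deme.begin() + hi); len.erase(len.begin() + hi); tips.erase(tips.begin() + hi);
      deme.erase(deme.begin() + lo); len.erase(len.begin() + lo); tips.erase(tips.begin() + lo);
      deme.push_back(parent_deme); len.push_back(0.0); tips.push_back(merged_tips);
      --k;
    } else {
      int d = (u < rc1 + rc2 + rm1) ? 0 : 1;
      std::vector<int> idx;
      for (size_t i = 0; i < deme.size(); ++i)
        if (deme[i] == d) idx.push_back((int)i);
      int a = (int)(unif_rand() * idx.size());
      if (a >= (int)idx.size()) a = (int)idx.size() - 1;
      deme[idx[a]] = 1 - d;
    }
  }

  double total = 0.0;
  for (size_t i = 0; i < frozen.size(); ++i) total += frozen[i].len;
  int nmut = (n > 1 && total > 0.0) ? (int)R::rpois(theta * total) : 0;

  IntegerMatrix haps(nmut, n);
  NumericVector pos(nmut);
  for (int m = 0; m < nmut; ++m) {
    double u = unif_rand() * total, acc = 0.0;
    size_t seg = 0;
    for (; seg < frozen.size(); ++seg) {
      acc += frozen[seg].len;
      if (u <= acc) break;
    }
    if (seg >= frozen.size()) seg = frozen.size() - 1;
    for (size_t j = 0; j < frozen[seg].tips.size(); ++j)
      haps(m, frozen[seg].tips[j]) = 1;
    pos[m] = unif_rand();
  }
  return List::create(_["haps"] = haps, _["positions"] = pos);
}
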