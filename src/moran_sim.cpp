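#include <Rcpp.h>
#include <vector>
#include "rng.h"

using namespace Rcpp;
using morancolonize::SubstreamRNG;

// Adjacency is passed in CSR form with 0-based node ids:
// off has length n+1, tgt[off[u]..off[u+1]-1] are u's out-neighbours.

// Modified Moran process at r -> infinity: each step picks a uniformly random
// node; a resident pick is an idle step, a mutant pick reproduces onto a
// uniform out-neighbour. Returns one row per replicate with columns
// (modified, classic, real). With skip_idle the geometric run of idle steps
// in the current state is drawn in one shot (distributionally identical;
// mutant picks are never skipped). Deterministic real time is modified/n by
// construction; sampled real time accrues an Exp(mean 1/|M|) draw per classic
// step.
// [[Rcpp::export]]
NumericMatrix cpp_sim_colonization(int n, IntegerVector off, IntegerVector tgt,
                                   IntegerVector init, int replicates,
                                   double seed, bool skip_idle,
                                   bool sampled_time) {
  NumericMatrix out(replicates, 3);
  std::vector<char> mut0(n, 0);
  for (int i = 0; i < init.size(); ++i) mut0[init[i]] = 1;

  for (int rep = 0; rep < replicates; ++rep) {
    SubstreamRNG rng((uint64_t)seed, (uint64_t)rep);
    std::vector<char> mut(mut0);
    std::vector<int> mlist;
    mlist.reserve(n);
    for (int v = 0; v < n; ++v)
      if (mut[v]) mlist.push_back(v);
    double modified = 0.0, classic = 0.0, rtime = 0.0;
    size_t m = mlist.size();

    while ((int)m < n) {
      int u;
      if (skip_idle) {
        double p = (double)m / (double)n;
        double k = std::floor(std::log(rng.unif_pos()) / std::log1p(-p));
        if (k < 0.0) k = 0.0;  // guard the u == 1 edge of the inversion
        modified += k + 1.0;
        u = mlist[rng.below((uint64_t)m)];
      } else {
        int x = (int)rng.below((uint64_t)n);
        modified += 1.0;
        if (!mut[x]) continue;
        u = x;
      }
      classic += 1.0;
      if (sampled_time) rtime += rng.exp_mean(1.0 / (double)m);
      int d = off[u + 1] - off[u];
      if (d > 0) {
        int w = tgt[off[u] + (int)rng.below((uint64_t)d)];
        if (!mut[w]) {
          mut[w] = 1;
          mlist.push_back(w);
          ++m;
        }
      }
    }
    out(rep, 0) = modified;
    out(rep, 1) = classic;
    out(rep, 2) = sampled_time ? rtime : modified / (double)n;
  }
  return out;
}

// Classic Moran Birth-death process: select a node proportional to fitness
// (mutants r, residents 1; r = Inf means only mutants are ever selected and
// total fitness is |M|), offspring replaces a uniform out-neighbour.
// Returns one row per replicate: (outcome, classic, real) with outcome
// 1 = fixed, 0 = extinct, -1 = truncated at max_steps.
// [[Rcpp::export]]
NumericMatrix cpp_sim_classic(int n, IntegerVector off, IntegerVector tgt,
                              IntegerVector init, double r, int replicates,
                              double seed, double max_steps) {
  NumericMatrix out(replicates, 3);
  const bool rinf = !R_finite(r);
  std::vector<char> mut0(n, 0);
  for (int i = 0; i < init.size(); ++i) mut0[init[i]] = 1;

  for (int rep = 0; rep < replicates; ++rep) {
    SubstreamRNG rng((uint64_t)seed, (uint64_t)rep);
    std::vector<char> mut(mut0);
    // membership lists with positional bookkeeping for O(1) moves
    std::vector<int> listM, listR;
    std::vector<int> where(n);
    listM.reserve(n);
    listR.reserve(n);
    for (int v = 0; v < n; ++v) {
      if (mut[v]) {
        where[v] = (int)listM.size();
        listM.push_back(v);
      } else {
        where[v] = (int)listR.size();
        listR.push_back(v);
      }
    }
    double classic = 0.0, rtime = 0.0;
    double outcome = -1.0;

    while (classic < max_steps) {
      size_t m = listM.size();
      if (m == 0) { outcome = 0.0; break; }
      if ((int)m == n) { outcome = 1.0; break; }
      double F = rinf ? (double)m : r * (double)m + (double)(n - (int)m);
      bool pick_mut;
      if (rinf) {
        pick_mut = true;
      } else {
        pick_mut = rng.unif_pos() <= r * (double)m / F;
      }
      int u = pick_mut ? listM[rng.below((uint64_t)m)]
                       : listR[rng.below((uint64_t)(n - (int)m))];
      classic += 1.0;
      rtime += 1.0 / F;
      int d = off[u + 1] - off[u];
      if (d == 0) continue;  // counted no-op: a sink was selected
      int w = tgt[off[u] + (int)rng.below((uint64_t)d)];
      if (mut[w] == mut[u]) continue;  // wasted reproduction, no state change
      if (mut[u]) {
        // w: resident -> mutant
        int iw = where[w];
        int last = listR.back();
        listR[iw] = last;
        where[last] = iw;
        listR.pop_back();
        where[w] = (int)listM.size();
        listM.push_back(w);
        mut[w] = 1;
      } else {
        // w: mutant -> resident
        int iw = where[w];
        int last = listM.back();
        listM[iw] = last;
        where[last] = iw;
        listM.pop_back();
        where[w] = (int)listR.size();
        listR.push_back(w);
        mut[w] = 0;
      }
    }
    out(rep, 0) = outcome;
    out(rep, 1) = classic;
    out(rep, 2) = rtime;
  }
  return out;
}
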