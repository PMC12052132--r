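#include <Rcpp.h>
#include <gmpxx.h>
#include <algorithm>
#include <sstream>
#include <string>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Exact rational arithmetic: GMP mpq_class. Reachable expected times carry
// denominators of hundreds of digits already at n = 10 (heterogeneous
// degrees compound multiplicatively through the stage recursion), so
// arbitrary precision is required, not just wide integers. mpq keeps every
// value canonical (reduced, positive denominator), which is what "bit-exact
// agreement" between the two solvers compares.
// ---------------------------------------------------------------------------

typedef mpq_class Rat;

static Rat rfrac(long long n, long long d) {
  Rat q((long)n, (long)d);
  q.canonicalize();
  return q;
}

static double rdouble(const Rat &a) { return a.get_d(); }

// "num/den" (or plain "num" for integers) in base 10
static std::string ratstr(const Rat &a) {
  std::ostringstream os;
  os << a;
  return os.str();
}

// ---------------------------------------------------------------------------
// Shared arithmetic shim so the two solver algorithms can be written once
// over doubles and once over exact rationals.
// ---------------------------------------------------------------------------

template <class T> struct Arith;

template <> struct Arith<double> {
  static double zero() { return 0.0; }
  static double frac(long long n, long long d) { return (double)n / (double)d; }
  static double add(double a, double b) { return a + b; }
  static double mul(double a, double b) { return a * b; }
  static double div(double a, double b) { return a / b; }
  static bool is_zero(double a) { return a == 0.0; }
};

template <> struct Arith<Rat> {
  static Rat zero() { return Rat(0); }
  static Rat frac(long long n, long long d) { return rfrac(n, d); }
  static Rat add(const Rat &a, const Rat &b) { return a + b; }
  static Rat mul(const Rat &a, const Rat &b) { return a * b; }
  static Rat div(const Rat &a, const Rat &b) { return a / b; }
  static bool is_zero(const Rat &a) { return a == 0; }
};

static inline int popcount64(uint64_t x) { return __builtin_popcountll(x); }

// Per-state stage quantities: gain rates q_w = sum_{u in M, w in N(u)} 1/deg(u)
// for each resident w reachable in one reproduction, and their total Q.
// The per-step leave probability is Q/n, so the expected modified steps spent
// in state M is n/Q, of which a fraction |M|/n are classic (mutant-pick)
// steps, i.e. |M|/Q.
template <class T>
static void gain_rates(int n, const int *off, const int *tgt, uint64_t mask,
                       std::vector<int> &gains, std::vector<T> &q) {
  gains.clear();
  std::vector<T> acc(n, Arith<T>::zero());
  std::vector<char> seen(n, 0);
  for (int u = 0; u < n; ++u) {
    if (!((mask >> u) & 1ULL)) continue;
    int d = off[u + 1] - off[u];
    if (d == 0) continue;
    T inv = Arith<T>::frac(1, d);
    for (int e = off[u]; e < off[u + 1]; ++e) {
      int w = tgt[e];
      if ((mask >> w) & 1ULL) continue;
      acc[w] = Arith<T>::add(acc[w], inv);
      if (!seen[w]) {
        seen[w] = 1;
        gains.push_back(w);
      }
    }
  }
  q.clear();
  for (size_t i = 0; i < gains.size(); ++i) q.push_back(acc[gains[i]]);
}

// ---------------------------------------------------------------------------
// Monotone-state dynamic program: memoized recursion over the mutant sets
// reachable from the initial state. The chain is monotone at r -> infinity
// (mutant sets only grow) so the state graph is acyclic and a single
// post-order pass suffices.
// ---------------------------------------------------------------------------

template <class T> struct DPVal {
  T mod, cls;
};

template <class T>
static DPVal<T> dp_solve(int n, const int *off, const int *tgt, uint64_t mask,
                         uint64_t full,
                         std::unordered_map<uint64_t, DPVal<T>> &memo,
                         double state_cap) {
  if (mask == full) {
    DPVal<T> z;
    z.mod = Arith<T>::zero();
    z.cls = Arith<T>::zero();
    return z;
  }
  typename std::unordered_map<uint64_t, DPVal<T>>::iterator it =
      memo.find(mask);
  if (it != memo.end()) return it->second;
  if ((double)memo.size() >= state_cap)
    stop("state cap exceeded: more than %.0f reachable mutant sets; raise "
         "stateCap or use a symmetry-reduced solver",
         state_cap);

  std::vector<int> gains;
  std::vector<T> q;
  gain_rates<T>(n, off, tgt, mask, gains, q);
  if (gains.empty())
    stop("internal error: non-absorbing state with no gain moves "
         "(initial set cannot reach all nodes?)");

  T Q = Arith<T>::zero();
  T smod = Arith<T>::zero();
  T scls = Arith<T>::zero();
  for (size_t i = 0; i < gains.size(); ++i) {
    Q = Arith<T>::add(Q, q[i]);
    DPVal<T> nxt = dp_solve<T>(n, off, tgt, mask | (1ULL << gains[i]), full,
                               memo, state_cap);
    smod = Arith<T>::add(smod, Arith<T>::mul(q[i], nxt.mod));
    scls = Arith<T>::add(scls, Arith<T>::mul(q[i], nxt.cls));
  }
  int m = popcount64(mask);
  DPVal<T> v;
  v.mod = Arith<T>::div(Arith<T>::add(Arith<T>::frac(n, 1), smod), Q);
  v.cls = Arith<T>::div(Arith<T>::add(Arith<T>::frac(m, 1), scls), Q);
  memo[mask] = v;
  return v;
}

static uint64_t init_mask(IntegerVector init) {
  uint64_t mask = 0;
  for (int i = 0; i < init.size(); ++i) mask |= 1ULL << init[i];
  return mask;
}

// [[Rcpp::export]]
List cpp_exact_dp(int n, IntegerVector off, IntegerVector tgt,
                  IntegerVector init, double state_cap, bool rational) {
  if (n > 64) stop("bitmask solvers require n <= 64");
  uint64_t full = (n == 64) ? ~0ULL : ((1ULL << n) - 1);
  uint64_t mask = init_mask(init);
  if (rational) {
    std::unordered_map<uint64_t, DPVal<Rat>> memo;
    DPVal<Rat> v = dp_solve<Rat>(n, off.begin(), tgt.begin(), mask, full, memo,
                                 state_cap);
    Rat real = v.mod / rfrac(n, 1);
    return List::create(
        _["modified"] = rdouble(v.mod), _["classic"] = rdouble(v.cls),
        _["real"] = rdouble(real), _["states"] = (double)memo.size(),
        _["exact"] = CharacterVector::create(ratstr(v.mod), ratstr(v.cls),
                                             ratstr(real)));
  } else {
    std::unordered_map<uint64_t, DPVal<double>> memo;
    DPVal<double> v = dp_solve<double>(n, off.begin(), tgt.begin(), mask, full,
                                       memo, state_cap);
    return List::create(_["modified"] = v.mod, _["classic"] = v.cls,
                        _["real"] = v.mod / (double)n,
                        _["states"] = (double)memo.size(),
                        _["exact"] = R_NilValue);
  }
}

// ---------------------------------------------------------------------------
// Brute-force oracle: a flat table over every one of the 2^n mutant sets that
// contain the initial set, filled in decreasing mask order (adding a node
// always increases the mask numerically, so all successors are ready).
// Deliberately enumeration-based and pruning-free, as an independent check on
// the memoized recursion.
// ---------------------------------------------------------------------------

template <class T>
static void brute_solve(int n, const int *off, const int *tgt, uint64_t imask,
                        std::vector<DPVal<T>> &table, double &states) {
  uint64_t full = (1ULL << n) - 1;
  table.assign((size_t)full + 1, DPVal<T>());
  table[full].mod = Arith<T>::zero();
  table[full].cls = Arith<T>::zero();
  states = 0;
  std::vector<int> gains;
  std::vector<T> q;
  for (uint64_t mask = full - 1;; --mask) {
    if ((mask & imask) == imask) {
      gain_rates<T>(n, off, tgt, mask, gains, q);
      if (gains.empty())
        stop("brute-force solver: state with no outgoing move; the initial "
             "set must reach every node");
      T Q = Arith<T>::zero();
      T smod = Arith<T>::zero();
      T scls = Arith<T>::zero();
      for (size_t i = 0; i < gains.size(); ++i) {
        Q = Arith<T>::add(Q, q[i]);
        const DPVal<T> &nxt = table[mask | (1ULL << gains[i])];
        smod = Arith<T>::add(smod, Arith<T>::mul(q[i], nxt.mod));
        scls = Arith<T>::add(scls, Arith<T>::mul(q[i], nxt.cls));
      }
      int m = popcount64(mask);
      table[mask].mod =
          Arith<T>::div(Arith<T>::add(Arith<T>::frac(n, 1), smod), Q);
      table[mask].cls =
          Arith<T>::div(Arith<T>::add(Arith<T>::frac(m, 1), scls), Q);
      states += 1;
    }
    if (mask == 0) break;
  }
}

// [[Rcpp::export]]
List cpp_exact_brute(int n, IntegerVector off, IntegerVector tgt,
                     IntegerVector init, bool rational) {
  if (n > 14) stop("brute-force subset solver requires n <= 14");
  uint64_t imask = init_mask(init);
  double states = 0;
  if (rational) {
    std::vector<DPVal<Rat>> table;
    brute_solve<Rat>(n, off.begin(), tgt.begin(), imask, table, states);
    const DPVal<Rat> &v = table[imask];
    Rat real = v.mod / rfrac(n, 1);
    return List::create(
        _["modified"] = rdouble(v.mod), _["classic"] = rdouble(v.cls),
        _["real"] = rdouble(real), _["states"] = states,
        _["exact"] = CharacterVector::create(ratstr(v.mod), ratstr(v.cls),
                                             ratstr(real)));
  } else {
    std::vector<DPVal<double>> table;
    brute_solve<double>(n, off.begin(), tgt.begin(), imask, table, states);
    const DPVal<double> &v = table[imask];
    return List::create(_["modified"] = v.mod, _["classic"] = v.cls,
                        _["real"] = v.mod / (double)n, _["states"] = states,
                        _["exact"] = R_NilValue);
  }
}
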