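#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Child-order search engine for backbone-tree layouts.
//
// Nodes are 0-based compact indices; `pre` lists them parents-first. Leaf
// y-coordinates equal their rank in the left-to-right traversal, so each
// subtree occupies a contiguous block of ranks whose size (`cnt`) does not
// depend on child order; a single parents-first sweep computes the block
// start of every node, and internal y follow either as means of children
// (mode 0) or as the closed-form mid-rank of the block (mode 1,
// descendant-leaf mean).

namespace {

struct Engine {
  int V;
  std::vector< std::vector<int> > kids;
  std::vector<int> cnt;
  std::vector<int> pre;
  std::vector<int> ea, eb;
  int mode;
  bool circular;
  double H;
  std::vector<double> start, y;

  double cost() {
    start[pre[0]] = 0.0;
    for (int idx = 0; idx < V; ++idx) {
      int v = pre[idx];
      double s = start[v];
      for (size_t j = 0; j < kids[v].size(); ++j) {
        int c = kids[v][j];
        start[c] = s;
        s += cnt[c];
      }
    }
    if (mode == 1) {
      for (int v = 0; v < V; ++v) y[v] = start[v] + (cnt[v] - 1) / 2.0;
    } else {
      for (int idx = V - 1; idx >= 0; --idx) {
        int v = pre[idx];
        if (kids[v].empty()) y[v] = start[v];
        else {
          double s = 0;
          for (size_t j = 0; j < kids[v].size(); ++j) s += y[kids[v][j]];
          y[v] = s / kids[v].size();
        }
      }
    }
    double tot = 0;
    for (size_t i = 0; i < ea.size(); ++i) {
      double d = std::fabs(y[ea[i]] - y[eb[i]]);
      if (circular && H - d < d) d = H - d;
      tot += d;
    }
    return tot;
  }
};

Engine make_engine(List children, IntegerVector cnt, IntegerVector pre,
                   IntegerMatrix redges, int mode, bool circular, double H) {
  Engine eng;
  eng.V = children.size();
  eng.kids.resize(eng.V);
  for (int v = 0; v < eng.V; ++v) {
    IntegerVector kv = children[v];
    eng.kids[v].assign(kv.begin(), kv.end());
    for (size_t j = 0; j < eng.kids[v].size(); ++j) eng.kids[v][j] -= 1;
  }
  eng.cnt.assign(cnt.begin(), cnt.end());
  eng.pre.assign(pre.begin(), pre.end());
  for (size_t j = 0; j < eng.pre.size(); ++j) eng.pre[j] -= 1;
  eng.ea.resize(redges.nrow());
  eng.eb.resize(redges.nrow());
  for (int i = 0; i < redges.nrow(); ++i) {
    eng.ea[i] = redges(i, 0) - 1;
    eng.eb[i] = redges(i, 1) - 1;
  }
  eng.mode = mode;
  eng.circular = circular;
  eng.H = H;
  eng.start.assign(eng.V, 0.0);
  eng.y.assign(eng.V, 0.0);
  return eng;
}

}  // namespace

// Evaluate the displacement of the current child orders.
// [[Rcpp::export]]
double eval_order_cost_cpp(List children, IntegerVector cnt,
                           IntegerVector pre, IntegerMatrix redges,
                           int mode, bool circular, double H) {
  Engine eng = make_engine(children, cnt, pre, redges, mode, circular, H);
  return eng.cost();
}

// Optimize the child order at `node` (1-based compact index), holding all
// other orders fixed. method 0 = exhaustive over all permutations (initial
// order kept on ties); method 1 = simulated annealing over pairwise swaps
// with Metropolis acceptance, returning the best order evaluated. Uses R's
// RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
List order_search_cpp(List children, IntegerVector cnt, IntegerVector pre,
                      int node, IntegerMatrix redges, int mode,
                      bool circular, double H, int method,
                      double t_start, double t_end, int iters_per_step,
                      double cooling) {
  Engine eng = make_engine(children, cnt, pre, redges, mode, circular, H);
  int v = node - 1;
  std::vector<int> init = eng.kids[v];
  int k = (int)init.size();
  std::vector<int> best = init;
  double cbest = eng.cost();

  if (method == 0) {
    std::vector<int> perm = init;
    std::sort(perm.begin(), perm.end());
    do {
      eng.kids[v] = perm;
      double c = eng.cost();
      if (c < cbest - 1e-12) { cbest = c; best = perm; }
    } while (std::next_permutation(perm.begin(), perm.end()));
  } else {
    std::vector<int> cur = init;
    eng.kids[v] = cur;
    double ccur = eng.cost();
    double T = t_start;
    while (T >= t_end) {
      for (int it = 0; it < iters_per_step; ++it) {
        int i = (int)(unif_rand() * k); if (i >= k) i = k - 1;
        int j = (int)(unif_rand() * (k - 1)); if (j >= k - 1) j = k - 2;
        if (j >= i) ++j;
        std::swap(cur[i], cur[j]);
        eng.kids[v] = cur;
        double c = eng.cost();
        if (c < cbest) { cbest = c; best = cur; }
        double d = c - ccur;
        if (d <= 0 || unif_rand() < std::exp(-d / T)) ccur = c;
        else std::swap(cur[i], cur[j]);  // reject: undo
      }
      T *= cooling;
    }
  }
  IntegerVector out(k);
  for (int i = 0; i < k; ++i) out[i] = best[i] + 1;
  return List::create(_["order"] = out, _["cost"] = cbest);
}

// Exhaustive joint search over the child permutations of TWO nodes,
// holding everything else fixed. Used as a refinement stage once
// single-node coordinate descent has converged: it realizes simultaneous
// reorders that no sequence of single-node moves can reach. The initial
// orders are kept on ties.
// [[Rcpp::export]]
List pair_search_cpp(List children, IntegerVector cnt, IntegerVector pre,
                     int node_a, int node_b, IntegerMatrix redges,
                     int mode, bool circular, double H) {
  Engine eng = make_engine(children, cnt, pre, redges, mode, circular, H);
  int a = node_a - 1, b = node_b - 1;
  std::vector<int> besta = eng.kids[a], bestb = eng.kids[b];
  double cbest = eng.cost();
  std::vector<int> pa = eng.kids[a];
  std::sort(pa.begin(), pa.end());
  do {
    eng.kids[a] = pa;
    std::vector<int> pb = eng.kids[b];
    std::sort(pb.begin(), pb.end());
    do {
      eng.kids[b] = pb;
      double c = eng.cost();
      if (c < cbest - 1e-12) { cbest = c; besta = pa; bestb = pb; }
    } while (std::next_permutation(pb.begin(), pb.end()));
  } while (std::next_permutation(pa.begin(), pa.end()));
  IntegerVector oa(besta.size()), ob(bestb.size());
  for (size_t i = 0; i < besta.size(); ++i) oa[i] = besta[i] + 1;
  for (size_t i = 0; i < bestb.size(); ++i) ob[i] = bestb[i] + 1;
  return List::create(_["order_a"] = oa, _["order_b"] = ob,
                      _["cost"] = cbest);
}
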