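// Random survival forest core: log-rank splitting on component activities,
// recursive tree growing, co-terminal-node proximity accumulation and
// per-tree feature usage. Trees see all samples (no bootstrap); each tree
// draws a fixed-size candidate feature subset via R's RNG so forests are
// reproducible from set.seed() on the R side.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

namespace {

struct SplitResult {
  bool found;
  int var;          // index into candidate list
  double cutpoint;
  double statistic;
  double p_adjusted;
};

// Two-sample log-rank statistic maximised over cutpoints of x within a node.
// idx: sample indices of the node. time/event: full vectors.
// Children must each keep >= min_node samples and >= min_events events.
// Returns (cutpoint, chi-square statistic) of the best admissible split.
bool best_split_one_var(const NumericVector& x, const NumericVector& time,
                        const IntegerVector& event,
                        const std::vector<int>& idx, int min_node,
                        int min_events, double& best_cut, double& best_stat,
                        int& n_eval) {
  const int n = (int)idx.size();
  // distinct event times within the node
  std::vector<double> etimes;
  etimes.reserve(n);
  for (int j = 0; j < n; ++j)
    if (event[idx[j]] == 1) etimes.push_back(time[idx[j]]);
  if (etimes.empty()) return false;
  std::sort(etimes.begin(), etimes.end());
  etimes.erase(std::unique(etimes.begin(), etimes.end()), etimes.end());
  const int m = (int)etimes.size();

  // per-sample: number of event times <= its own time (risk membership),
  // and, for events, the index of its event time
  std::vector<int> risk_upto(n), ev_at(n, -1);
  std::vector<int> n_ge(m, 0), d_all(m, 0);
  int total_events = 0;
  for (int j = 0; j < n; ++j) {
    double tj = time[idx[j]];
    int k = (int)(std::upper_bound(etimes.begin(), etimes.end(), tj) -
                  etimes.begin());
    risk_upto[j] = k;                 // at risk for event-time indices 0..k-1
    for (int e = 0; e < k; ++e) n_ge[e]++;
    if (event[idx[j]] == 1) {
      int e = (int)(std::lower_bound(etimes.begin(), etimes.end(), tj) -
                    etimes.begin());
      ev_at[j] = e;
      d_all[e]++;
      total_events++;
    }
  }
  if (total_events < 2 * min_events) return false;

  // order node samples by x
  std::vector<int> ord(n);
  for (int j = 0; j < n; ++j) ord[j] = j;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    return x[idx[a]] < x[idx[b]];
  });

  std::vector<int> n1_ge(m, 0), d1(m, 0);
  int n_left = 0, ev_left = 0;
  bool found = false;
  best_stat = 0.0;
  n_eval = 0;

  for (int r = 0; r < n - 1; ++r) {
    int j = ord[r];
    for (int e = 0; e < risk_upto[j]; ++e) n1_ge[e]++;
    if (ev_at[j] >= 0) { d1[ev_at[j]]++; ev_left++; }
    n_left++;
    double xl = x[idx[ord[r]]], xr = x[idx[ord[r + 1]]];
    if (xl == xr) continue;                       // not a boundary
    int n_right = n - n_left;
    int ev_right = total_events - ev_left;
    if (n_left < min_node || n_right < min_node) continue;
    if (ev_left < min_events || ev_right < min_events) continue;
    double O = 0.0, E = 0.0, V = 0.0;
    for (int e = 0; e < m; ++e) {
      int Ne = n_ge[e], De = d_all[e], N1 = n1_ge[e];
      if (Ne < 1 || De < 1) continue;
      double frac = (double)N1 / Ne;
      O += d1[e];
      E += De * frac;
      if (Ne > 1)
        V += De * frac * (1.0 - frac) * (double)(Ne - De) / (Ne - 1);
    }
    if (V <= 0.0) continue;
    n_eval++;
    double stat = (O - E) * (O - E) / V;
    if (stat > best_stat) {
      best_stat = stat;
      best_cut = 0.5 * (xl + xr);
      found = true;
    }
  }
  return found && best_stat > 0.0;
}

// Bonferroni-adjusted p of the cutpoint-maximised log-rank statistic
double adjusted_p(double stat, int n_eval) {
  double p = R::pchisq(stat, 1.0, 0, 0) * n_eval;
  return p > 1.0 ? 1.0 : p;
}

// A split is admitted only when significant at split_alpha after Bonferroni
// correction over the cutpoints evaluated; candidates compete on adjusted p
// (ties broken by raw statistic), so a node with no significant candidate
// stays terminal.
SplitResult best_split(const NumericMatrix& act, const NumericVector& time,
                       const IntegerVector& event, const std::vector<int>& idx,
                       const IntegerVector& cand, int min_node,
                       int min_events, double split_alpha) {
  SplitResult best{false, -1, 0.0, 0.0, 1.0};
  for (int v = 0; v < cand.size(); ++v) {
    NumericVector x = const_cast<NumericMatrix&>(act).row(cand[v]);
    double cut, stat;
    int n_eval;
    if (best_split_one_var(x, time, event, idx, min_node, min_events, cut,
                           stat, n_eval)) {
      double pa = adjusted_p(stat, n_eval);
      if (pa >= split_alpha) continue;
      if (!best.found || pa < best.p_adjusted ||
          (pa == best.p_adjusted && stat > best.statistic))
        best = {true, v, cut, stat, pa};
    }
  }
  return best;
}

struct TreeNode {
  int split_var;       // row index into activities, -1 for terminal
  double cutpoint;
  double statistic;
  int left, right;     // node indices, -1 for terminal
  std::vector<int> samples;
};

// grow one tree; returns terminal-node label per sample and fills node table
void grow_tree_impl(const NumericMatrix& act, const NumericVector& time,
                    const IntegerVector& event, const IntegerVector& cand,
                    int min_node, int min_events, double split_alpha,
                    std::vector<TreeNode>& nodes, std::vector<int>& terminal) {
  const int n = act.ncol();
  terminal.assign(n, -1);
  std::vector<int> all(n);
  for (int i = 0; i < n; ++i) all[i] = i;
  nodes.clear();
  nodes.push_back(TreeNode{-1, 0.0, 0.0, -1, -1, all});
  std::vector<int> open;
  open.push_back(0);
  while (!open.empty()) {
    int ni = open.back();
    open.pop_back();
    std::vector<int> idx = nodes[ni].samples;
    bool try_split = (int)idx.size() >= 2 * min_node;
    SplitResult sp{false, -1, 0.0, 0.0, 1.0};
    if (try_split)
      sp = best_split(act, time, event, idx, cand, min_node, min_events,
                      split_alpha);
    if (!sp.found) continue;       // stays terminal
    int var = cand[sp.var];
    std::vector<int> li, ri;
    for (int j : idx)
      (act(var, j) <= sp.cutpoint ? li : ri).push_back(j);
    nodes[ni].split_var = var;
    nodes[ni].cutpoint = sp.cutpoint;
    nodes[ni].statistic = sp.statistic;
    nodes[ni].samples.clear();
    int l = (int)nodes.size();
    nodes.push_back(TreeNode{-1, 0.0, 0.0, -1, -1, li});
    int r = (int)nodes.size();
    nodes.push_back(TreeNode{-1, 0.0, 0.0, -1, -1, ri});
    nodes[ni].left = l;
    nodes[ni].right = r;
    open.push_back(l);
    open.push_back(r);
  }
  for (size_t ni = 0; ni < nodes.size(); ++ni)
    if (nodes[ni].split_var == -1)
      for (int j : nodes[ni].samples) terminal[j] = (int)ni;
}

}  // namespace

// [[Rcpp::export(name = ".logrank_split_cpp")]]
List logrank_split_cpp(NumericVector x, NumericVector time,
                       IntegerVector event, int min_node, int min_events,
                       double split_alpha) {
  std::vector<int> idx(x.size());
  for (int i = 0; i < x.size(); ++i) idx[i] = i;
  double cut = NA_REAL, stat = 0.0;
  int n_eval = 0;
  bool found = ((int)idx.size() >= 2 * min_node) &&
               best_split_one_var(x, time, event, idx, min_node, min_events,
                                  cut, stat, n_eval);
  double pa = found ? adjusted_p(stat, n_eval) : 1.0;
  if (found && pa >= split_alpha) found = false;
  return List::create(_["found"] = found, _["cutpoint"] = cut,
                      _["statistic"] = stat, _["p_adjusted"] = pa);
}

// [[Rcpp::export(name = ".grow_tree_cpp")]]
List grow_tree_cpp(NumericMatrix act, NumericVector time, IntegerVector event,
                   IntegerVector candidates, int min_node, int min_events,
                   double split_alpha) {
  std::vector<TreeNode> nodes;
  std::vector<int> terminal;
  grow_tree_impl(act, time, event, candidates, min_node, min_events,
                 split_alpha, nodes, terminal);
  int nn = (int)nodes.size();
  IntegerVector split_var(nn), left(nn), right(nn);
  NumericVector cutpoint(nn), statistic(nn);
  for (int i = 0; i < nn; ++i) {
    split_var[i] = nodes[i].split_var < 0 ? NA_INTEGER : nodes[i].split_var + 1;
    cutpoint[i] = nodes[i].split_var < 0 ? NA_REAL : nodes[i].cutpoint;
    statistic[i] = nodes[i].split_var < 0 ? NA_REAL : nodes[i].statistic;
    left[i] = nodes[i].left < 0 ? NA_INTEGER : nodes[i].left + 1;
    right[i] = nodes[i].right < 0 ? NA_INTEGER : nodes[i].right + 1;
  }
  IntegerVector term(terminal.size());
  for (size_t i = 0; i < terminal.size(); ++i) term[i] = terminal[i] + 1;
  return List::create(_["split_var"] = split_var, _["cutpoint"] = cutpoint,
                      _["statistic"] = statistic, _["left"] = left,
                      _["right"] = right, _["terminal"] = term);
}

// [[Rcpp::export(name = ".grow_forest_cpp")]]
List grow_forest_cpp(NumericMatrix act, NumericVector time,
                     IntegerVector event, int n_trees, int mtry, int min_node,
                     int min_events, double split_alpha) {
  const int k = act.nrow(), n = act.ncol();
  NumericMatrix prox(n, n);
  IntegerMatrix used(k, n_trees), candidate(k, n_trees);
  RNGScope rng;  // candidate subsets from R's RNG: reproducible via set.seed
  std::vector<TreeNode> nodes;
  std::vector<int> terminal;
  for (int t = 0; t < n_trees; ++t) {
    // sample mtry distinct features (Fisher-Yates prefix)
    std::vector<int> pool(k);
    for (int i = 0; i < k; ++i) pool[i] = i;
    IntegerVector cand(mtry);
    for (int i = 0; i < mtry; ++i) {
      int j = i + (int)(unif_rand() * (k - i));
      if (j >= k) j = k - 1;
      std::swap(pool[i], pool[j]);
      cand[i] = pool[i];
      candidate(pool[i], t) = 1;
    }
    grow_tree_impl(act, time, event, cand, min_node, min_events, split_alpha,
                   nodes, terminal);
    for (size_t ni = 0; ni < nodes.size(); ++ni) {
      if (nodes[ni].split_var >= 0) used(nodes[ni].split_var, t) = 1;
      if (nodes[ni].split_var == -1) {
        const std::vector<int>& s = nodes[ni].samples;
        for (size_t a = 0; a < s.size(); ++a)
          for (size_t b = 0; b < s.size(); ++b) prox(s[a], s[b]) += 1.0;
      }
    }
  }
  return List::create(_["proximity"] = prox, _["used"] = used,
                      _["candidate"] = candidate);
}
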