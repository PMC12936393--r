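// Boosted regression trees for Bernoulli-deviance binary response with
// monotone constraints, bagging, best-first tree growth and out-of-bag
// bookkeeping. Trees are grown on the gradient residuals z = y - p with
// squared-error split gain; terminal values are one-step Newton updates
// sum(z)/sum(p(1-p)) shrunk by the learning rate. Deterministic given the
// seed (own xorshift RNG; no dependence on R's RNG stream).

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <limits>
#include <queue>
#include <vector>

using namespace Rcpp;

// --- small deterministic RNG (splitmix64 seeding + xorshift64*) ---------
struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) {
    s = seed + 0x9E3779B97F4A7C15ULL;
    s = (s ^ (s >> 30)) * 0xBF58476D1CE4E5B9ULL;
    s = (s ^ (s >> 27)) * 0x94D049BB133111EBULL;
    s = s ^ (s >> 31);
    if (s == 0) s = 0x106689D45497FDB5ULL;
  }
  uint64_t next() {
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    return s * 0x2545F4914F6CDD1DULL;
  }
  // uniform integer in [0, n)
  int below(int n) { return (int)(next() % (uint64_t)n); }
};

struct Node {
  int var = -1;           // split predictor, -1 for leaf
  double threshold = 0.0; // numeric split: left iff x < threshold
  uint32_t catmask = 0;   // categorical split: left iff bit(level) set
  int left = -1, right = -1;
  double value = 0.0;     // leaf value (Newton step, unshrunk)
  int majority = 0;       // 0 = unseen categorical codes go left, 1 = right
  int n_bag = 0;
  bool is_cat = false;
  // monotone-constraint bounds inherited down the tree; terminal Newton
  // values are clipped into [lo, hi] so constrained predictions stay
  // ordered across sibling subtrees, not just across one split
  double lo = -std::numeric_limits<double>::infinity();
  double hi = std::numeric_limits<double>::infinity();
};

struct Split {
  bool ok = false;
  int var = -1;
  double threshold = 0.0;
  uint32_t catmask = 0;
  double gain = 0.0;
  int majority = 0;
  bool is_cat = false;
  int mono = 0;      // constraint sign of the split variable
  double mid = 0.0;  // midpoint of the child Newton values (bound anchor)
};

struct XZW { double x, z, w; bool operator<(const XZW& o) const { return x < o.x; } };

// best split for the rows of one node
static Split best_split(const NumericMatrix& X, const std::vector<double>& z,
                        const std::vector<double>& w,
                        const std::vector<int>& rows,
                        const IntegerVector& monotone,
                        const IntegerVector& n_levels, int min_obs) {
  Split best;
  const int p = X.ncol();
  const int n = (int)rows.size();
  if (n < 2 * min_obs) return best;
  double S = 0.0, W = 0.0;
  for (int r : rows) { S += z[r]; W += w[r]; }
  const double base = S * S / n;

  std::vector<XZW> xv(n);
  for (int j = 0; j < p; ++j) {
    const int L = n_levels[j];
    if (L > 0 && L <= 8) {
      // exhaustive subset search over level bipartitions
      double lsum[8] = {0}; int lcnt[8] = {0};
      bool bad = false;
      for (int r : rows) {
        int c = (int)X(r, j);
        if (c < 0 || c >= L) { bad = true; break; }
        lsum[c] += z[r]; lcnt[c]++;
      }
      if (bad) continue;
      const uint32_t full = (1u << L) - 1u;
      for (uint32_t m = 1; m < full; ++m) {
        double SL = 0; int nL = 0;
        for (int c = 0; c < L; ++c) {
          if (m & (1u << c)) { SL += lsum[c]; nL += lcnt[c]; }
        }
        int nR = n - nL;
        if (nL < min_obs || nR < min_obs) continue;
        double SR = S - SL;
        double gain = SL * SL / nL + SR * SR / nR - base;
        if (gain > best.gain + 1e-12) {
          best.ok = true; best.var = j; best.catmask = m;
          best.gain = gain; best.is_cat = true;
          best.majority = (nL >= nR) ? 0 : 1;
          best.mono = 0; best.mid = 0.0;
        }
      }
    } else if (L > 8) {
      // order levels by within-node mean response, scan as ordered
      std::vector<double> lsum(L, 0.0); std::vector<int> lcnt(L, 0);
      for (int r : rows) {
        int c = (int)X(r, j);
        if (c >= 0 && c < L) { lsum[c] += z[r]; lcnt[c]++; }
      }
      std::vector<int> lv;
      for (int c = 0; c < L; ++c) if (lcnt[c] > 0) lv.push_back(c);
      if ((int)lv.size() < 2) continue;
      std::sort(lv.begin(), lv.end(), [&](int a, int b) {
        return lsum[a] / lcnt[a] < lsum[b] / lcnt[b];
      });
      double SL = 0; int nL = 0;
      uint32_t m = 0;
      for (size_t k = 0; k + 1 < lv.size(); ++k) {
        SL += lsum[lv[k]]; nL += lcnt[lv[k]];
        m |= (1u << lv[k]);
        int nR = n - nL;
        if (nL < min_obs || nR < min_obs) continue;
        double SR = S - SL;
        double gain = SL * SL / nL + SR * SR / nR - base;
        if (gain > best.gain + 1e-12) {
          best.ok = true; best.var = j; best.catmask = m;
          best.gain = gain; best.is_cat = true;
          best.majority = (nL >= nR) ? 0 : 1;
          best.mono = 0; best.mid = 0.0;
        }
      }
    } else {
      // numeric predictor
      for (int i = 0; i < n; ++i) {
        xv[i] = {X(rows[i], j), z[rows[i]], w[rows[i]]};
      }
      std::sort(xv.begin(), xv.end());
      if (xv.front().x == xv.back().x) continue;
      const int mono = monotone[j];
      double SL = 0.0, WL = 0.0;
      for (int i = 0; i + 1 < n; ++i) {
        SL += xv[i].z;
        WL += xv[i].w;
        if (xv[i].x == xv[i + 1].x) continue;
        int nL = i + 1, nR = n - nL;
        if (nL < min_obs || nR < min_obs) continue;
        double SR = S - SL;
        double vL = 0.0, vR = 0.0, mid = 0.0;
        if (mono != 0) {
          // reject splits whose child Newton values violate the sign
          double WR = W - WL;
          if (WL < 1e-12 || WR < 1e-12) continue;
          vL = SL / WL; vR = SR / WR;
          if ((vR - vL) * mono <= 0) continue;
          mid = 0.5 * (vL + vR);
        }
        double gain = SL * SL / nL + SR * SR / nR - base;
        if (gain > best.gain + 1e-12) {
          best.ok = true; best.var = j;
          best.threshold = 0.5 * (xv[i].x + xv[i + 1].x);
          best.gain = gain; best.is_cat = false;
          best.mono = mono; best.mid = mid;
        }
      }
    }
  }
  return best;
}

static int route(const Node& nd, double x) {
  if (nd.is_cat) {
    int c = (int)x;
    if (c < 0 || c > 31) return nd.majority ? nd.right : nd.left;
    uint32_t bit = 1u << c;
    // unseen level (bit beyond trained mask coverage) handled by majority
    return (nd.catmask & bit) ? nd.left : nd.right;
  }
  return (x < nd.threshold) ? nd.left : nd.right;
}

static int leaf_of(const std::vector<Node>& tree, const NumericMatrix& X,
                   int row) {
  int k = 0;
  while (tree[k].var >= 0) k = route(tree[k], X(row, tree[k].var));
  return k;
}

static double bern_nll2(double y, double F) {
  // -2 * loglik contribution, numerically stable
  double m = F > 0 ? F : 0.0;
  double log1pe = m + std::log(std::exp(-m) + std::exp(F - m));
  return -2.0 * (y * F - log1pe);
}

// [[Rcpp::export(name = ".brt_fit_cpp")]]
List brt_fit_cpp(NumericMatrix X, NumericVector y, IntegerVector monotone,
                 IntegerVector n_levels, int n_trees, double learning_rate,
                 int tree_complexity, double bag_fraction, int min_obs,
                 double seed) {
  const int n = X.nrow(), p = X.ncol();
  double ybar = 0;
  for (int i = 0; i < n; ++i) ybar += y[i];
  ybar /= n;
  const double F0 = std::log(ybar / (1.0 - ybar));
  std::vector<double> F(n, F0), z(n), w(n);
  std::vector<double> influence(p, 0.0);
  NumericVector oob_improve(n_trees), train_dev(n_trees);
  Rng rng((uint64_t)seed);
  const int n_bag = std::max(2, (int)std::floor(bag_fraction * n));
  std::vector<int> idx(n);
  List trees(n_trees);

  for (int t = 0; t < n_trees; ++t) {
    for (int i = 0; i < n; ++i) {
      double pr = 1.0 / (1.0 + std::exp(-F[i]));
      z[i] = y[i] - pr;
      w[i] = std::max(pr * (1.0 - pr), 1e-12);
    }
    // bag: partial Fisher-Yates, without replacement
    for (int i = 0; i < n; ++i) idx[i] = i;
    for (int i = 0; i < n_bag; ++i) {
      int j = i + rng.below(n - i);
      std::swap(idx[i], idx[j]);
    }
    std::vector<int> bag(idx.begin(), idx.begin() + n_bag);
    std::vector<char> inbag(n, 0);
    for (int r : bag) inbag[r] = 1;

    double oob_before = 0.0;
    for (int i = 0; i < n; ++i) if (!inbag[i]) oob_before += bern_nll2(y[i], F[i]);

    // best-first growth to at most tree_complexity splits
    std::vector<Node> tree(1);
    tree[0].n_bag = n_bag;
    std::vector<std::vector<int>> node_rows{bag};
    std::vector<double> node_gain(1, 0.0);
    struct Open { double gain; int node; Split sp; };
    auto cmp = [](const Open& a, const Open& b) { return a.gain < b.gain; };
    std::priority_queue<Open, std::vector<Open>, decltype(cmp)> pq(cmp);
    Split s0 = best_split(X, z, w, node_rows[0], monotone, n_levels, min_obs);
    if (s0.ok) pq.push({s0.gain, 0, s0});
    int n_splits = 0;
    while (!pq.empty() && n_splits < tree_complexity) {
      Open o = pq.top(); pq.pop();
      Node& nd = tree[o.node];
      nd.var = o.sp.var; nd.threshold = o.sp.threshold;
      nd.catmask = o.sp.catmask; nd.is_cat = o.sp.is_cat;
      nd.majority = o.sp.majority;
      int li = (int)tree.size(); tree.push_back(Node());
      int ri = (int)tree.size(); tree.push_back(Node());
      tree[o.node].left = li; tree[o.node].right = ri;
      std::vector<int> lr, rr;
      for (int r : node_rows[o.node]) {
        const Node& cur = tree[o.node];
        double xv = X(r, cur.var);
        bool goleft;
        if (cur.is_cat) {
          int c = (int)xv;
          goleft = (c >= 0 && c <= 31) && (cur.catmask & (1u << c));
        } else {
          goleft = xv < cur.threshold;
        }
        (goleft ? lr : rr).push_back(r);
      }
      tree[li].n_bag = (int)lr.size();
      tree[ri].n_bag = (int)rr.size();
      // children inherit the node's value bounds; a constrained split
      // tightens them around the child-Newton midpoint
      tree[li].lo = tree[o.node].lo; tree[li].hi = tree[o.node].hi;
      tree[ri].lo = tree[o.node].lo; tree[ri].hi = tree[o.node].hi;
      if (o.sp.mono == 1) {
        tree[li].hi = std::min(tree[li].hi, o.sp.mid);
        tree[ri].lo = std::max(tree[ri].lo, o.sp.mid);
      } else if (o.sp.mono == -1) {
        tree[li].lo = std::max(tree[li].lo, o.sp.mid);
        tree[ri].hi = std::min(tree[ri].hi, o.sp.mid);
      }
      node_rows.push_back(lr);
      node_rows.push_back(rr);
      node_gain.push_back(0.0);
      node_gain.push_back(0.0);
      node_gain[o.node] = o.sp.gain;
      influence[tree[o.node].var] += o.sp.gain;
      n_splits++;
      Split sl = best_split(X, z, w, lr, monotone, n_levels, min_obs);
      if (sl.ok) pq.push({sl.gain, li, sl});
      Split sr = best_split(X, z, w, rr, monotone, n_levels, min_obs);
      if (sr.ok) pq.push({sr.gain, ri, sr});
    }
    // terminal Newton values from the bag rows, clipped to the node's
    // monotone bounds
    for (size_t k = 0; k < tree.size(); ++k) {
      if (tree[k].var >= 0) continue;
      double sz = 0, sw = 0;
      for (int r : node_rows[k]) { sz += z[r]; sw += w[r]; }
      double v = (sw > 1e-12) ? sz / sw : 0.0;
      if (v < tree[k].lo) v = tree[k].lo;
      if (v > tree[k].hi) v = tree[k].hi;
      tree[k].value = v;
    }
    // update F on all rows
    for (int i = 0; i < n; ++i) {
      F[i] += learning_rate * tree[leaf_of(tree, X, i)].value;
    }
    double oob_after = 0.0, dev = 0.0;
    for (int i = 0; i < n; ++i) {
      double d = bern_nll2(y[i], F[i]);
      dev += d;
      if (!inbag[i]) oob_after += d;
    }
    oob_improve[t] = oob_before - oob_after;
    train_dev[t] = dev;

    NumericMatrix tm(tree.size(), 9);
    for (size_t k = 0; k < tree.size(); ++k) {
      tm(k, 0) = tree[k].var;
      tm(k, 1) = tree[k].threshold;
      tm(k, 2) = (double)tree[k].catmask;
      tm(k, 3) = tree[k].left;
      tm(k, 4) = tree[k].right;
      tm(k, 5) = tree[k].value;
      tm(k, 6) = tree[k].majority;
      tm(k, 7) = tree[k].n_bag;
      tm(k, 8) = node_gain[k];
    }
    trees[t] = tm;
  }
  return List::create(_["trees"] = trees, _["init"] = F0,
                      _["influence"] = NumericVector(influence.begin(), influence.end()),
                      _["oob_improve"] = oob_improve,
                      _["train_deviance"] = train_dev);
}

// walk one flattened tree for a row held in xrow
static inline double tree_value_raw(const NumericMatrix& tm,
                                    const std::vector<double>& xrow) {
  int k = 0;
  while ((int)tm(k, 0) >= 0) {
    int var = (int)tm(k, 0);
    double x = xrow[var];
    bool is_cat = ((uint32_t)tm(k, 2)) != 0u;
    bool goleft;
    if (is_cat) {
      int c = (int)x;
      uint32_t mask = (uint32_t)tm(k, 2);
      if (c < 0 || c > 31) goleft = (tm(k, 6) == 0);
      else goleft = (mask & (1u << c)) != 0;
    } else {
      goleft = x < tm(k, 1);
    }
    k = goleft ? (int)tm(k, 3) : (int)tm(k, 4);
  }
  return tm(k, 5);
}

// [[Rcpp::export(name = ".brt_predict_cpp")]]
NumericVector brt_predict_cpp(List trees, double init, NumericMatrix X,
                              double learning_rate, int n_trees) {
  const int n = X.nrow(), p = X.ncol();
  NumericVector F(n, init);
  std::vector<NumericMatrix> tl;
  tl.reserve(n_trees);
  for (int t = 0; t < n_trees; ++t) tl.push_back(as<NumericMatrix>(trees[t]));
  std::vector<double> xrow(p);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < p; ++j) xrow[j] = X(i, j);
    double f = 0.0;
    for (int t = 0; t < n_trees; ++t) f += tree_value_raw(tl[t], xrow);
    F[i] += learning_rate * f;
  }
  return F;
}

// Partial dependence by batched brute force: mean link-scale prediction
// over the supplied rows with column `var` overridden by each grid value.
// [[Rcpp::export(name = ".brt_pd_cpp")]]
NumericVector brt_pd_cpp(List trees, double init, NumericMatrix X, int var,
                         NumericVector grid, double learning_rate,
                         int n_trees) {
  const int n = X.nrow(), g = grid.size(), p = X.ncol();
  NumericVector out(g, 0.0);
  std::vector<NumericMatrix> tl;
  tl.reserve(n_trees);
  for (int t = 0; t < n_trees; ++t) tl.push_back(as<NumericMatrix>(trees[t]));
  std::vector<double> xrow(p);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < p; ++j) xrow[j] = X(i, j);
    for (int k = 0; k < g; ++k) {
      xrow[var] = grid[k];
      double F = init;
      for (int t = 0; t < n_trees; ++t) {
        F += learning_rate * tree_value_raw(tl[t], xrow);
      }
      out[k] += F;
    }
  }
  for (int k = 0; k < g; ++k) out[k] /= n;
  return out;
}

// Two-way partial dependence surface (link scale), rows overridden on both
// predictors for every grid pair.
// [[Rcpp::export(name = ".brt_pd2_cpp")]]
NumericMatrix brt_pd2_cpp(List trees, double init, NumericMatrix X, int var1,
                          int var2, NumericVector grid1, NumericVector grid2,
                          double learning_rate, int n_trees) {
  const int n = X.nrow(), g1 = grid1.size(), g2 = grid2.size(), p = X.ncol();
  NumericMatrix out(g1, g2);
  std::vector<NumericMatrix> tl;
  tl.reserve(n_trees);
  for (int t = 0; t < n_trees; ++t) tl.push_back(as<NumericMatrix>(trees[t]));
  std::vector<double> xrow(p);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < p; ++j) xrow[j] = X(i, j);
    for (int a = 0; a < g1; ++a) {
      xrow[var1] = grid1[a];
      for (int b = 0; b < g2; ++b) {
        xrow[var2] = grid2[b];
        double F = init;
        for (int t = 0; t < n_trees; ++t) {
          F += learning_rate * tree_value_raw(tl[t], xrow);
        }
        out(a, b) += F;
      }
    }
  }
  for (int a = 0; a < g1; ++a) for (int b = 0; b < g2; ++b) out(a, b) /= n;
  return out;
}
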