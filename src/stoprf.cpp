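// Tree-growing core for stopping-rule regression random forests.
//
// All randomness is driven by an internal splitmix64 stream so that fits are
// bit-identical for a given seed on every platform, independent of R's RNG.
// Feature subsampling at each node is keyed by the node's path from the root
// (not by expansion order), so tightening a halt threshold prunes the tree
// without resynchronising the random draws of surviving nodes.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <deque>
#include <algorithm>
#include <cmath>
#include <limits>

using namespace Rcpp;

namespace {

inline uint64_t splitmix64(uint64_t &state) {
  state += 0x9E3779B97F4A7C15ULL;
  uint64_t z = state;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

inline uint64_t mix64(uint64_t z) {
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Stream {
  uint64_t s;
  explicit Stream(uint64_t seed) : s(seed) {
    for (int i = 0; i < 4; ++i) splitmix64(s);
  }
  uint64_t u64() { return splitmix64(s); }
  int below(int n) { return static_cast<int>(u64() % static_cast<uint64_t>(n)); }
};

// Stopping configuration + full-training reference statistics, packed by the
// R side (see cfg_vector() in R/stopping.R).  Negative theta => disabled.
struct Config {
  double theta_var, theta_range, theta_icr;
  double icr_p;        // lower tail probability X/100
  int min_parent;      // <= 0 disabled
  int min_leaf;        // <= 1 is no constraint
  double tot_var, tot_range, tot_icr;
};

Config parse_config(const NumericVector &v) {
  Config c;
  c.theta_var   = v[0];
  c.theta_range = v[1];
  c.theta_icr   = v[2];
  c.icr_p       = v[3] / 100.0;
  c.min_parent  = static_cast<int>(v[4]);
  c.min_leaf    = std::max(1, static_cast<int>(v[5]));
  c.tot_var     = v[6];
  c.tot_range   = v[7];
  c.tot_icr     = v[8];
  return c;
}

// Linear-interpolation ("type 7") quantile of a sorted vector.
double quantile7(const std::vector<double> &x, double p) {
  const int n = static_cast<int>(x.size());
  if (n == 1) return x[0];
  const double h = (n - 1) * p;
  const int lo = static_cast<int>(std::floor(h));
  if (lo >= n - 1) return x[n - 1];
  return x[lo] + (h - lo) * (x[lo + 1] - x[lo]);
}

// Dispersion statistics of an outcome multiset.  The R side computes the
// full-training reference statistics through these same routines (via
// cpp_dispersion), so a node whose sample coincides with the reference set
// reproduces the reference value bit-for-bit and the non-strict <= halts it
// at theta = 1.
double disp_variance(const std::vector<double> &ys) {
  const int n = static_cast<int>(ys.size());
  double s = 0.0;
  for (double v : ys) s += v;
  const double m = s / n;
  double ss = 0.0;
  for (double v : ys) { const double d = v - m; ss += d * d; }
  return ss / n;
}

double disp_range(const std::vector<double> &ys) {
  double mn = ys[0], mx = ys[0];
  for (double v : ys) {
    if (v < mn) mn = v;
    if (v > mx) mx = v;
  }
  return mx - mn;
}

double disp_icr(std::vector<double> ys, double p) {
  std::sort(ys.begin(), ys.end());
  return quantile7(ys, 1.0 - p) - quantile7(ys, p);
}

// Any of the halt rules (parent size, variance, range, intercentile range)
// triggered for the node holding observations idx?
bool node_halts(const NumericVector &y, const std::vector<int> &idx,
                const Config &cfg) {
  const int n = static_cast<int>(idx.size());
  if (cfg.min_parent > 0 && n < cfg.min_parent) return true;
  if (cfg.theta_var < 0.0 && cfg.theta_range < 0.0 && cfg.theta_icr < 0.0)
    return false;
  std::vector<double> ys;
  ys.reserve(n);
  for (int i : idx) ys.push_back(y[i]);
  if (cfg.theta_range >= 0.0 &&
      disp_range(ys) <= cfg.theta_range * cfg.tot_range)
    return true;
  if (cfg.theta_var >= 0.0 && disp_variance(ys) <= cfg.theta_var * cfg.tot_var)
    return true;
  if (cfg.theta_icr >= 0.0 &&
      disp_icr(ys, cfg.icr_p) <= cfg.theta_icr * cfg.tot_icr)
    return true;
  return false;
}

struct SplitRes {
  int feat = -1;       // 1-based
  double thr = 0.0;
  int nl = 0, nr = 0;
};

// Exhaustive split search over the supplied candidate features (1-based,
// scanned in ascending order), thresholds at midpoints of adjacent distinct
// values.  Criterion: maximise sum_L^2/n_L + sum_R^2/n_R (equivalent to the
// SSE reduction since the parent term is constant).  A candidate replaces the
// incumbent only if it beats it by a relative tolerance, so exact ties keep
// the lowest feature index and smallest threshold regardless of round-off.
bool find_best_split(const NumericMatrix &X, const NumericVector &y,
                     const std::vector<int> &idx, const std::vector<int> &feats,
                     int min_leaf, SplitRes &out) {
  const int n = static_cast<int>(idx.size());
  if (n < 2 || 2 * min_leaf > n) return false;
  double best_crit = 0.0;
  bool found = false;
  std::vector<std::pair<double, double>> xy(n);
  for (int f : feats) {
    for (int i = 0; i < n; ++i)
      xy[i] = std::make_pair(X(idx[i], f - 1), y[idx[i]]);
    std::sort(xy.begin(), xy.end(),
              [](const std::pair<double, double> &a,
                 const std::pair<double, double> &b) { return a.first < b.first; });
    double total = 0.0;
    for (int i = 0; i < n; ++i) total += xy[i].second;
    double suml = 0.0;
    for (int i = 1; i < n; ++i) {
      suml += xy[i - 1].second;
      if (xy[i].first == xy[i - 1].first) continue;
      const int nl = i, nr = n - i;
      if (nl < min_leaf || nr < min_leaf) continue;
      const double sumr = total - suml;
      const double crit = suml * suml / nl + sumr * sumr / nr;
      if (!found) {
        found = true;
        best_crit = crit;
        out.feat = f;
        out.thr = 0.5 * (xy[i - 1].first + xy[i].first);
        out.nl = nl;
        out.nr = nr;
      } else {
        const double tol = 1e-9 * std::max(1.0, std::fabs(best_crit));
        if (crit > best_crit + tol) {
          best_crit = crit;
          out.feat = f;
          out.thr = 0.5 * (xy[i - 1].first + xy[i].first);
          out.nl = nl;
          out.nr = nr;
        }
      }
    }
  }
  return found;
}

struct Tree {
  std::vector<int> feature;      // 1-based split feature; 0 = leaf
  std::vector<double> threshold; // NA for leaves
  std::vector<int> left, right;  // 1-based node ids; 0 = none
  std::vector<int> nn;           // in-node sample size
  std::vector<double> value;     // in-node outcome mean

  int add_node(int n, double mean) {
    feature.push_back(0);
    threshold.push_back(NA_REAL);
    left.push_back(0);
    right.push_back(0);
    nn.push_back(n);
    value.push_back(mean);
    return static_cast<int>(feature.size()) - 1;
  }
};

struct Pending {
  int id;
  uint64_t key;           // path hash: stable across configs
  std::vector<int> idx;
};

// Breadth-first expansion; maxnodes caps the number of terminal nodes.
Tree grow(const NumericMatrix &X, const NumericVector &y,
          std::vector<int> root_idx, const Config &cfg, int mtry, int maxnodes,
          uint64_t node_stream_base) {
  Tree tr;
  const int p = X.ncol();
  double s0 = 0.0;
  for (int i : root_idx) s0 += y[i];
  const int root = tr.add_node(static_cast<int>(root_idx.size()),
                               s0 / root_idx.size());
  std::deque<Pending> q;
  q.push_back(Pending{root, 0x5851F42D4C957F2DULL, std::move(root_idx)});
  int n_terminal = 1;
  std::vector<int> featbuf(p);

  while (!q.empty()) {
    Pending node = std::move(q.front());
    q.pop_front();
    const std::vector<int> &idx = node.idx;
    const int n = static_cast<int>(idx.size());
    if (n < 2) continue;
    if (node_halts(y, idx, cfg)) continue;
    if (n_terminal + 1 > maxnodes) continue;

    // mtry features without replacement, drawn from the node-keyed stream,
    // then scanned in ascending index order for the deterministic tie-break.
    Stream rng(node_stream_base ^ node.key);
    for (int j = 0; j < p; ++j) featbuf[j] = j + 1;
    for (int j = 0; j < mtry; ++j) {
      const int k = j + rng.below(p - j);
      std::swap(featbuf[j], featbuf[k]);
    }
    std::vector<int> feats(featbuf.begin(), featbuf.begin() + mtry);
    std::sort(feats.begin(), feats.end());

    SplitRes sp;
    if (!find_best_split(X, y, idx, feats, cfg.min_leaf, sp)) continue;

    std::vector<int> li, ri;
    li.reserve(sp.nl);
    ri.reserve(sp.nr);
    double sl = 0.0, sr = 0.0;
    for (int i : idx) {
      if (X(i, sp.feat - 1) <= sp.thr) {
        li.push_back(i);
        sl += y[i];
      } else {
        ri.push_back(i);
        sr += y[i];
      }
    }
    const int lid = tr.add_node(static_cast<int>(li.size()), sl / li.size());
    const int rid = tr.add_node(static_cast<int>(ri.size()), sr / ri.size());
    tr.feature[node.id] = sp.feat;
    tr.threshold[node.id] = sp.thr;
    tr.left[node.id] = lid + 1;
    tr.right[node.id] = rid + 1;
    ++n_terminal;
    q.push_back(Pending{lid, mix64(node.key * 2u + 0u + 0x9E3779B97F4A7C15ULL),
                        std::move(li)});
    q.push_back(Pending{rid, mix64(node.key * 2u + 1u + 0x9E3779B97F4A7C15ULL),
                        std::move(ri)});
  }
  return tr;
}

List tree_to_list(const Tree &tr) {
  return List::create(_["feature"] = wrap(tr.feature),
                      _["threshold"] = wrap(tr.threshold),
                      _["left"] = wrap(tr.left),
                      _["right"] = wrap(tr.right),
                      _["n"] = wrap(tr.nn),
                      _["value"] = wrap(tr.value));
}

double predict_one(const IntegerVector &feature, const NumericVector &threshold,
                   const IntegerVector &left, const IntegerVector &right,
                   const NumericVector &value, const NumericMatrix &X, int row) {
  int cur = 0;
  while (feature[cur] != 0) {
    const double v = X(row, feature[cur] - 1);
    cur = (v <= threshold[cur]) ? left[cur] - 1 : right[cur] - 1;
  }
  return value[cur];
}

}  // namespace

// [[Rcpp::export]]
List cpp_grow_tree(NumericMatrix X, NumericVector y, NumericVector cfg,
                   int mtry, int maxnodes, double seed) {
  const Config c = parse_config(cfg);
  std::vector<int> idx(X.nrow());
  for (int i = 0; i < X.nrow(); ++i) idx[i] = i;
  const uint64_t base =
      mix64(static_cast<uint64_t>(static_cast<int64_t>(seed)) ^
            0xA0761D6478BD642FULL);
  return tree_to_list(grow(X, y, std::move(idx), c, mtry, maxnodes, base));
}

// [[Rcpp::export]]
List cpp_grow_forest(NumericMatrix X, NumericVector y, NumericVector cfg,
                     int mtry, int maxnodes, int ntree, double seed,
                     bool keep_inbag) {
  const Config c = parse_config(cfg);
  const int n = X.nrow();
  List trees(ntree);
  IntegerMatrix inbag;
  if (keep_inbag) inbag = IntegerMatrix(n, ntree);
  const uint64_t s0 = static_cast<uint64_t>(static_cast<int64_t>(seed));
  for (int b = 0; b < ntree; ++b) {
    Stream boot(s0 ^ (0xD1B54A32D192ED03ULL * static_cast<uint64_t>(b + 1)));
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = boot.below(n);
    if (keep_inbag)
      for (int i = 0; i < n; ++i) inbag(idx[i], b) += 1;
    const uint64_t base = boot.u64();
    trees[b] = tree_to_list(grow(X, y, std::move(idx), c, mtry, maxnodes, base));
  }
  if (keep_inbag) return List::create(_["trees"] = trees, _["inbag"] = inbag);
  return List::create(_["trees"] = trees, _["inbag"] = R_NilValue);
}

// [[Rcpp::export]]
NumericVector cpp_predict_tree(List tree, NumericMatrix X) {
  const IntegerVector feature = tree["feature"];
  const NumericVector threshold = tree["threshold"];
  const IntegerVector left = tree["left"];
  const IntegerVector right = tree["right"];
  const NumericVector value = tree["value"];
  const int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = predict_one(feature, threshold, left, right, value, X, i);
  return out;
}

// [[Rcpp::export]]
SEXP cpp_predict_forest(List trees, NumericMatrix X, bool all) {
  const int n = X.nrow();
  const int ntree = trees.size();
  if (all) {
    NumericMatrix out(n, ntree);
    for (int b = 0; b < ntree; ++b) {
      List tree = trees[b];
      const IntegerVector feature = tree["feature"];
      const NumericVector threshold = tree["threshold"];
      const IntegerVector left = tree["left"];
      const IntegerVector right = tree["right"];
      const NumericVector value = tree["value"];
      for (int i = 0; i < n; ++i)
        out(i, b) = predict_one(feature, threshold, left, right, value, X, i);
    }
    return out;
  }
  NumericVector acc(n);
  for (int b = 0; b < ntree; ++b) {
    List tree = trees[b];
    const IntegerVector feature = tree["feature"];
    const NumericVector threshold = tree["threshold"];
    const IntegerVector left = tree["left"];
    const IntegerVector right = tree["right"];
    const NumericVector value = tree["value"];
    for (int i = 0; i < n; ++i)
      acc[i] += predict_one(feature, threshold, left, right, value, X, i);
  }
  for (int i = 0; i < n; ++i) acc[i] /= ntree;
  return acc;
}

// [[Rcpp::export]]
List cpp_dispersion(NumericVector y, double icr_centile) {
  std::vector<double> ys(y.begin(), y.end());
  return List::create(_["variance"] = disp_variance(ys),
                      _["range"] = disp_range(ys),
                      _["icr"] = disp_icr(ys, icr_centile / 100.0));
}

// [[Rcpp::export]]
List cpp_best_split(NumericMatrix X, NumericVector y, IntegerVector features,
                    int min_leaf) {
  const int n = X.nrow();
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::vector<int> feats(features.begin(), features.end());
  std::sort(feats.begin(), feats.end());
  SplitRes sp;
  if (!find_best_split(X, y, idx, feats, std::max(1, min_leaf), sp))
    return List::create();
  // SSE reduction computed directly for the chosen split.
  double m = 0.0;
  for (int i = 0; i < n; ++i) m += y[i];
  m /= n;
  double sse_parent = 0.0;
  for (int i = 0; i < n; ++i) { const double d = y[i] - m; sse_parent += d * d; }
  double sl = 0.0, sr = 0.0;
  for (int i = 0; i < n; ++i)
    (X(i, sp.feat - 1) <= sp.thr ? sl : sr) += y[i];
  const double ml = sl / sp.nl, mr = sr / sp.nr;
  double sse_kids = 0.0;
  for (int i = 0; i < n; ++i) {
    const double mu = (X(i, sp.feat - 1) <= sp.thr) ? ml : mr;
    const double d = y[i] - mu;
    sse_kids += d * d;
  }
  const double red = std::max(0.0, sse_parent - sse_kids);
  return List::create(_["feature"] = sp.feat, _["threshold"] = sp.thr,
                      _["sse_reduction"] = red, _["left_n"] = sp.nl,
                      _["right_n"] = sp.nr);
}
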