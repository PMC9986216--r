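// Random forest internals: Gini-split probability trees with bootstrap and
// per-node feature subsampling. Columns arrive pre-quantized into bins
// (exact when a column has few distinct values, quantile bins otherwise),
// so split search is a counting scan rather than a sort. Uses R's RNG
// stream, so forests are reproducible under set.seed().

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

struct Node {
  int feature;      // -1 for leaf
  double threshold;
  int left, right;
  double prob;
};

struct Task {
  int node;
  std::vector<int> rows;
  int depth;
};

// sample `k` distinct values from 0..n-1 with R's RNG (partial Fisher-Yates)
void sample_features(int n, int k, std::vector<int>& pool) {
  for (int i = 0; i < n; ++i) pool[i] = i;
  for (int i = 0; i < k; ++i) {
    int j = i + (int)(unif_rand() * (n - i));
    if (j >= n) j = n - 1;
    std::swap(pool[i], pool[j]);
  }
}

}  // namespace

// codes: n x p integer matrix of 0-based bin indices per feature;
// thresholds[j]: numeric vector of candidate split values between
// consecutive bins of feature j (length nbins_j - 1)
// [[Rcpp::export]]
List forest_fit_cpp(IntegerMatrix codes, IntegerVector y, List thresholds,
                    int num_trees, int mtry, int max_depth, int min_node) {
  const int n = codes.nrow(), p = codes.ncol();
  std::vector<std::vector<double>> thr(p);
  int max_bins = 1;
  for (int j = 0; j < p; ++j) {
    NumericVector t = thresholds[j];
    thr[j] = std::vector<double>(t.begin(), t.end());
    if ((int)thr[j].size() + 1 > max_bins) max_bins = thr[j].size() + 1;
  }
  List trees(num_trees);
  std::vector<int> pool(p);
  std::vector<int> cnt(max_bins), cnt1(max_bins);

  for (int b = 0; b < num_trees; ++b) {
    std::vector<int> boot(n);
    for (int i = 0; i < n; ++i) {
      int j = (int)(unif_rand() * n);
      if (j >= n) j = n - 1;
      boot[i] = j;
    }
    std::vector<Node> nodes;
    std::vector<Task> stack;
    nodes.push_back(Node{-1, 0, -1, -1, 0});
    stack.push_back(Task{0, boot, 0});

    while (!stack.empty()) {
      Task t = std::move(stack.back());
      stack.pop_back();
      const int nt = t.rows.size();
      int tot1 = 0;
      for (int r : t.rows) tot1 += y[r];
      nodes[t.node].prob = (double)tot1 / nt;
      if (t.depth >= max_depth || nt < min_node || tot1 == 0 || tot1 == nt) continue;

      sample_features(p, mtry, pool);
      int best_feat = -1, best_bin = -1;
      double best_score = R_PosInf;
      for (int fi = 0; fi < mtry; ++fi) {
        const int j = pool[fi];
        const int nb = thr[j].size() + 1;
        if (nb < 2) continue;
        std::fill(cnt.begin(), cnt.begin() + nb, 0);
        std::fill(cnt1.begin(), cnt1.begin() + nb, 0);
        for (int r : t.rows) {
          const int c = codes(r, j);
          ++cnt[c];
          cnt1[c] += y[r];
        }
        int nl = 0, l1 = 0;
        for (int c = 0; c < nb - 1; ++c) {
          nl += cnt[c];
          l1 += cnt1[c];
          if (nl == 0) continue;
          const int nr = nt - nl;
          if (nr == 0) break;
          const int r1 = tot1 - l1;
          const double pl = (double)l1 / nl, pr = (double)r1 / nr;
          const double gini = nl * (1.0 - pl * pl - (1.0 - pl) * (1.0 - pl)) +
                              nr * (1.0 - pr * pr - (1.0 - pr) * (1.0 - pr));
          if (gini < best_score) {
            best_score = gini;
            best_feat = j;
            best_bin = c;
          }
        }
      }
      if (best_feat < 0) continue;
      std::vector<int> lrows, rrows;
      for (int r : t.rows) {
        if (codes(r, best_feat) <= best_bin) lrows.push_back(r); else rrows.push_back(r);
      }
      if (lrows.empty() || rrows.empty()) continue;
      const int li = nodes.size(), ri = nodes.size() + 1;
      nodes.push_back(Node{-1, 0, -1, -1, 0});
      nodes.push_back(Node{-1, 0, -1, -1, 0});
      nodes[t.node].feature = best_feat;
      nodes[t.node].threshold = thr[best_feat][best_bin];
      nodes[t.node].left = li;
      nodes[t.node].right = ri;
      stack.push_back(Task{li, std::move(lrows), t.depth + 1});
      stack.push_back(Task{ri, std::move(rrows), t.depth + 1});
    }

    const int m = nodes.size();
    IntegerVector feature(m), left(m), right(m);
    NumericVector threshold(m), prob(m);
    for (int i = 0; i < m; ++i) {
      feature[i] = nodes[i].feature;
      threshold[i] = nodes[i].threshold;
      left[i] = nodes[i].left;
      right[i] = nodes[i].right;
      prob[i] = nodes[i].prob;
    }
    trees[b] = List::create(_["feature"] = feature, _["threshold"] = threshold,
                            _["left"] = left, _["right"] = right, _["prob"] = prob);
  }
  return trees;
}

// [[Rcpp::export]]
NumericVector forest_predict_cpp(List trees, NumericMatrix X) {
  const int n = X.nrow(), B = trees.size();
  NumericVector out(n);
  for (int b = 0; b < B; ++b) {
    List tr = trees[b];
    IntegerVector feature = tr["feature"], left = tr["left"], right = tr["right"];
    NumericVector threshold = tr["threshold"], prob = tr["prob"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feature[node] >= 0) {
        node = (X(i, feature[node]) <= threshold[node]) ? left[node] : right[node];
      }
      out[i] += prob[node];
    }
  }
  return out / (double)B;
}
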