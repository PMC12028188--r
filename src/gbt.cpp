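// Compact gradient-boosted decision trees for binary classification with
// second-order (gradient/hessian) boosting, L1/L2 regularisation, row
// subsampling, optional positive-class weighting, and exact TreeSHAP
// attributions. Designed for small tabular clinical datasets (hundreds of
// rows, tens of features); split finding is exact greedy with per-node sorts.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

struct Node {
  int feature;       // -1 for leaf
  double threshold;  // go left when x < threshold
  int left, right;   // child indices, -1 for leaf
  double value;      // leaf weight (already scaled by eta)
  double cover;      // sum of hessians reaching the node
};

struct BuildCtx {
  const NumericMatrix* X;
  const std::vector<double>* g;
  const std::vector<double>* h;
  int max_depth;
  double lambda;     // L2
  double alpha;      // L1 (soft threshold on gradient sums)
  double eta;
  double min_child_weight;
  std::vector<Node> nodes;
};

inline double soft_threshold(double G, double alpha) {
  if (G > alpha) return G - alpha;
  if (G < -alpha) return G + alpha;
  return 0.0;
}

inline double node_score(double G, double H, double lambda, double alpha) {
  const double T = soft_threshold(G, alpha);
  return T * T / (H + lambda);
}

// Recursively grow one tree; rows holds indices of records at this node.
int build_node(BuildCtx& ctx, std::vector<int>& rows, int depth) {
  const NumericMatrix& X = *ctx.X;
  const std::vector<double>& g = *ctx.g;
  const std::vector<double>& h = *ctx.h;

  double G = 0.0, H = 0.0;
  for (int r : rows) { G += g[r]; H += h[r]; }

  const int me = (int)ctx.nodes.size();
  ctx.nodes.push_back(Node{-1, 0.0, -1, -1, 0.0, H});

  bool can_split = depth < ctx.max_depth && (int)rows.size() >= 2 &&
                   H >= 2.0 * ctx.min_child_weight;

  int best_f = -1;
  double best_gain = 1e-12, best_thr = 0.0;
  const double parent_score = node_score(G, H, ctx.lambda, ctx.alpha);

  if (can_split) {
    const int p = X.ncol();
    std::vector<std::pair<double, int> > vals(rows.size());
    for (int f = 0; f < p; ++f) {
      for (size_t i = 0; i < rows.size(); ++i)
        vals[i] = std::make_pair(X(rows[i], f), rows[i]);
      std::sort(vals.begin(), vals.end());
      double GL = 0.0, HL = 0.0;
      for (size_t i = 0; i + 1 < vals.size(); ++i) {
        GL += g[vals[i].second];
        HL += h[vals[i].second];
        if (vals[i + 1].first <= vals[i].first) continue;  // tied values
        const double HR = H - HL;
        if (HL < ctx.min_child_weight || HR < ctx.min_child_weight) continue;
        const double gain = 0.5 * (node_score(GL, HL, ctx.lambda, ctx.alpha) +
                                   node_score(G - GL, HR, ctx.lambda, ctx.alpha) -
                                   parent_score);
        if (gain > best_gain) {
          best_gain = gain;
          best_f = f;
          best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
        }
      }
    }
  }

  if (best_f < 0) {
    ctx.nodes[me].value = -ctx.eta * soft_threshold(G, ctx.alpha) / (H + ctx.lambda);
    return me;
  }

  std::vector<int> lrows, rrows;
  for (int r : rows) {
    if (X(r, best_f) < best_thr) lrows.push_back(r); else rrows.push_back(r);
  }
  ctx.nodes[me].feature = best_f;
  ctx.nodes[me].threshold = best_thr;
  const int li = build_node(ctx, lrows, depth + 1);
  ctx.nodes[me].left = li;
  const int ri = build_node(ctx, rrows, depth + 1);
  ctx.nodes[me].right = ri;
  return me;
}

inline double predict_tree(const NumericMatrix& tree, const NumericMatrix& X, int row) {
  int j = 0;
  while (tree(j, 0) >= 0) {
    j = (X(row, (int)tree(j, 0)) < tree(j, 1)) ? (int)tree(j, 2) : (int)tree(j, 3);
  }
  return tree(j, 4);
}

NumericMatrix pack_tree(const std::vector<Node>& nodes) {
  NumericMatrix m((int)nodes.size(), 6);
  for (size_t i = 0; i < nodes.size(); ++i) {
    m(i, 0) = nodes[i].feature;
    m(i, 1) = nodes[i].threshold;
    m(i, 2) = nodes[i].left;
    m(i, 3) = nodes[i].right;
    m(i, 4) = nodes[i].value;
    m(i, 5) = nodes[i].cover;
  }
  colnames(m) = CharacterVector::create("feature", "threshold", "left", "right",
                                        "value", "cover");
  return m;
}

inline double sigmoid(double z) { return 1.0 / (1.0 + std::exp(-z)); }

// ---- TreeSHAP (path-dependent expectations via node covers) -------------

struct PathElement {
  int d;
  double z;  // fraction of zero (unknown-feature) paths flowing through
  double o;  // fraction of one (known-feature) paths flowing through
  double w;  // permutation weight
};

void extend_path(PathElement* path, int depth, double pz, double po, int pi) {
  path[depth].d = pi;
  path[depth].z = pz;
  path[depth].o = po;
  path[depth].w = (depth == 0) ? 1.0 : 0.0;
  for (int i = depth - 1; i >= 0; --i) {
    path[i + 1].w += po * path[i].w * (i + 1) / (double)(depth + 1);
    path[i].w = pz * path[i].w * (depth - i) / (double)(depth + 1);
  }
}

void unwind_path(PathElement* path, int depth, int idx) {
  const double o = path[idx].o;
  const double z = path[idx].z;
  double n = path[depth].w;
  for (int i = depth - 1; i >= 0; --i) {
    if (o != 0.0) {
      const double t = path[i].w;
      path[i].w = n * (depth + 1) / ((i + 1) * o);
      n = t - path[i].w * z * (depth - i) / (double)(depth + 1);
    } else {
      path[i].w = path[i].w * (depth + 1) / (z * (depth - i));
    }
  }
  for (int i = idx; i < depth; ++i) {
    path[i].d = path[i + 1].d;
    path[i].z = path[i + 1].z;
    path[i].o = path[i + 1].o;
  }
}

double unwound_sum(const PathElement* path, int depth, int idx) {
  const double o = path[idx].o;
  const double z = path[idx].z;
  double n = path[depth].w;
  double total = 0.0;
  if (o != 0.0) {
    for (int i = depth - 1; i >= 0; --i) {
      const double t = n / ((i + 1) * o);
      total += t;
      n = path[i].w - t * z * (depth - i);
    }
  } else {
    for (int i = depth - 1; i >= 0; --i)
      total += path[i].w / (z * (depth - i));
  }
  return total * (depth + 1);
}

void shap_recurse(const NumericMatrix& tree, const NumericMatrix& X, int row,
                  double* phi, int node, PathElement* parent_path, int depth,
                  double pz, double po, int pi) {
  PathElement* path = parent_path + depth + 1;
  std::copy(parent_path, parent_path + depth + 1, path);
  extend_path(path, depth, pz, po, pi);

  const int f = (int)tree(node, 0);
  if (f < 0) {  // leaf
    const double v = tree(node, 4);
    for (int i = 1; i <= depth; ++i) {
      const double w = unwound_sum(path, depth, i);
      phi[path[i].d] += w * (path[i].o - path[i].z) * v;
    }
    return;
  }

  const int left = (int)tree(node, 2), right = (int)tree(node, 3);
  const int hot = (X(row, f) < tree(node, 1)) ? left : right;
  const int cold = (hot == left) ? right : left;
  const double cover = tree(node, 5);
  const double hot_z = tree(hot, 5) / cover;
  const double cold_z = tree(cold, 5) / cover;

  double iz = 1.0, io = 1.0;
  int k = 0;
  for (; k <= depth; ++k) if (path[k].d == f) break;
  if (k <= depth) {
    iz = path[k].z;
    io = path[k].o;
    unwind_path(path, depth, k);
    depth -= 1;
  }
  shap_recurse(tree, X, row, phi, hot, path, depth + 1, hot_z * iz, io, f);
  shap_recurse(tree, X, row, phi, cold, path, depth + 1, cold_z * iz, 0.0, f);
}

int tree_max_depth(const NumericMatrix& tree, int node, int depth) {
  if (tree(node, 0) < 0) return depth;
  return std::max(tree_max_depth(tree, (int)tree(node, 2), depth + 1),
                  tree_max_depth(tree, (int)tree(node, 3), depth + 1));
}

double tree_expected(const NumericMatrix& tree, int node) {
  if (tree(node, 0) < 0) return tree(node, 4);
  const int l = (int)tree(node, 2), r = (int)tree(node, 3);
  const double cover = tree(node, 5);
  return (tree(l, 5) * tree_expected(tree, l) +
          tree(r, 5) * tree_expected(tree, r)) / cover;
}

}  // namespace

// [[Rcpp::export]]
List cpp_gbt_train(NumericMatrix X, NumericVector y, int nrounds, int max_depth,
                   double eta, double subsample, double lambda, double alpha,
                   double pos_weight, double min_child_weight,
                   Nullable<NumericMatrix> Xval_, Nullable<NumericVector> yval_,
                   int patience) {
  const int n = X.nrow();
  std::vector<double> margin(n, 0.0), g(n), h(n);

  const bool has_val = Xval_.isNotNull();
  NumericMatrix Xval;
  NumericVector yval;
  std::vector<double> vmargin;
  if (has_val) {
    Xval = Xval_.get();
    yval = yval_.get();
    vmargin.assign(Xval.nrow(), 0.0);
  }

  List trees(nrounds);
  NumericVector val_loss(has_val ? nrounds : 0);
  double best_loss = R_PosInf;
  int best_iter = nrounds, stall = 0, done = 0;

  std::vector<int> perm(n);
  const int nsub = std::max(2, (int)std::floor(subsample * n));

  for (int it = 0; it < nrounds; ++it) {
    for (int i = 0; i < n; ++i) {
      const double p = sigmoid(margin[i]);
      const double w = (y[i] > 0.5) ? pos_weight : 1.0;
      g[i] = w * (p - y[i]);
      h[i] = std::max(w * p * (1.0 - p), 1e-16);
    }

    std::vector<int> rows;
    if (nsub < n) {
      for (int i = 0; i < n; ++i) perm[i] = i;
      for (int i = 0; i < nsub; ++i) {  // partial Fisher-Yates via R's RNG
        const int j = i + (int)std::floor(unif_rand() * (n - i));
        std::swap(perm[i], perm[std::min(j, n - 1)]);
      }
      rows.assign(perm.begin(), perm.begin() + nsub);
    } else {
      for (int i = 0; i < n; ++i) rows.push_back(i);
    }

    BuildCtx ctx;
    ctx.X = &X; ctx.g = &g; ctx.h = &h;
    ctx.max_depth = max_depth; ctx.lambda = lambda; ctx.alpha = alpha;
    ctx.eta = eta; ctx.min_child_weight = min_child_weight;
    build_node(ctx, rows, 0);
    NumericMatrix tm = pack_tree(ctx.nodes);
    trees[it] = tm;
    done = it + 1;

    for (int i = 0; i < n; ++i) margin[i] += predict_tree(tm, X, i);

    if (has_val) {
      double loss = 0.0;
      for (int i = 0; i < Xval.nrow(); ++i) {
        vmargin[i] += predict_tree(tm, Xval, i);
        const double p = std::min(std::max(sigmoid(vmargin[i]), 1e-12), 1.0 - 1e-12);
        loss += yval[i] > 0.5 ? -std::log(p) : -std::log(1.0 - p);
      }
      loss /= Xval.nrow();
      val_loss[it] = loss;
      if (loss < best_loss - 1e-9) {
        best_loss = loss;
        best_iter = it + 1;
        stall = 0;
      } else if (++stall >= patience && patience > 0) {
        break;
      }
    }
  }

  if (!has_val) best_iter = done;
  List kept(best_iter);
  for (int i = 0; i < best_iter; ++i) kept[i] = trees[i];

  return List::create(_["trees"] = kept,
                      _["best_iter"] = best_iter,
                      _["val_loss"] = has_val ? val_loss[Range(0, done - 1)]
                                              : NumericVector(0));
}

// [[Rcpp::export]]
NumericVector cpp_gbt_margin(List trees, NumericMatrix X) {
  const int n = X.nrow();
  NumericVector out(n);
  for (int t = 0; t < trees.size(); ++t) {
    NumericMatrix tm = trees[t];
    for (int i = 0; i < n; ++i) out[i] += predict_tree(tm, X, i);
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_gbt_shap(List trees, NumericMatrix X) {
  const int n = X.nrow(), p = X.ncol();
  NumericMatrix phi(n, p);
  double base = 0.0;
  for (int t = 0; t < trees.size(); ++t) {
    NumericMatrix tm = trees[t];
    base += tree_expected(tm, 0);
    const int md = tree_max_depth(tm, 0, 0);
    std::vector<PathElement> buf((md + 2) * (md + 3) / 2 + md + 2);
    for (int i = 0; i < n; ++i) {
      std::vector<double> prow(p, 0.0);
      shap_recurse(tm, X, i, prow.data(), 0, buf.data(), 0, 1.0, 1.0, -1);
      for (int j = 0; j < p; ++j) phi(i, j) += prow[j];
    }
  }
  phi.attr("base_value") = base;
  return phi;
}
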