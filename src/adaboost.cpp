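#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Weighted CART stumps/trees (Gini impurity, exhaustive split search on
// continuous features, midpoint thresholds) used as the AdaBoost weak
// learner. A tree is flattened into a nodes x 5 matrix with columns
// [feature (1-based, 0 = leaf), threshold, left, right, leaf value (+/-1)];
// child indices are 1-based row numbers.

struct TreeBuf {
    std::vector<double> feature, thresh, left, right, value;
    int add() {
        feature.push_back(0); thresh.push_back(0);
        left.push_back(0); right.push_back(0); value.push_back(0);
        return (int)feature.size() - 1;
    }
};

// returns node index
static int build_node(const NumericMatrix &X, const IntegerVector &y,
                      const std::vector<double> &w, std::vector<int> &idx,
                      int depth, int max_depth, TreeBuf &T)
{
    const int node = T.add();
    const int n = (int)idx.size();
    const int nf = X.ncol();

    double w0 = 0.0, w1 = 0.0;
    for (int k = 0; k < n; ++k) {
        if (y[idx[k]] == 1) w1 += w[idx[k]]; else w0 += w[idx[k]];
    }
    const double W = w0 + w1;
    const double leaf_val = (w1 >= w0) ? 1.0 : -1.0;
    const double parent_imp = W - (w0 * w0 + w1 * w1) / std::max(W, 1e-300);

    bool make_leaf = (depth >= max_depth) || (n < 2) ||
                     (w0 <= 0.0) || (w1 <= 0.0);

    int best_f = -1;
    double best_thr = 0.0, best_imp = parent_imp - 1e-12;
    if (!make_leaf) {
        std::vector<std::pair<double, int> > ord(n);
        for (int f = 0; f < nf; ++f) {
            for (int k = 0; k < n; ++k)
                ord[k] = std::make_pair(X(idx[k], f), idx[k]);
            std::sort(ord.begin(), ord.end());
            double l0 = 0.0, l1 = 0.0;
            for (int k = 0; k < n - 1; ++k) {
                if (y[ord[k].second] == 1) l1 += w[ord[k].second];
                else l0 += w[ord[k].second];
                if (ord[k + 1].first <= ord[k].first) continue;  // tie: no cut
                const double wl = l0 + l1, wr = W - wl;
                if (wl <= 0.0 || wr <= 0.0) continue;
                const double r0 = w0 - l0, r1 = w1 - l1;
                const double imp = (wl - (l0 * l0 + l1 * l1) / wl) +
                                   (wr - (r0 * r0 + r1 * r1) / wr);
                if (imp < best_imp) {
                    best_imp = imp;
                    best_f = f;
                    best_thr = 0.5 * (ord[k].first + ord[k + 1].first);
                }
            }
        }
        if (best_f < 0) make_leaf = true;
    }

    if (make_leaf) {
        T.feature[node] = 0;
        T.value[node] = leaf_val;
        return node;
    }

    std::vector<int> li, ri;
    li.reserve(n); ri.reserve(n);
    for (int k = 0; k < n; ++k) {
        if (X(idx[k], best_f) <= best_thr) li.push_back(idx[k]);
        else ri.push_back(idx[k]);
    }
    const int lnode = build_node(X, y, w, li, depth + 1, max_depth, T);
    const int rnode = build_node(X, y, w, ri, depth + 1, max_depth, T);
    T.feature[node] = best_f + 1;
    T.thresh[node] = best_thr;
    T.left[node] = lnode + 1;
    T.right[node] = rnode + 1;
    return node;
}

static NumericMatrix pack_tree(const TreeBuf &T)
{
    const int n = (int)T.feature.size();
    NumericMatrix M(n, 5);
    for (int i = 0; i < n; ++i) {
        M(i, 0) = T.feature[i]; M(i, 1) = T.thresh[i];
        M(i, 2) = T.left[i];    M(i, 3) = T.right[i];
        M(i, 4) = T.value[i];
    }
    return M;
}

static double predict_tree(const NumericMatrix &M, const NumericMatrix &X, int row)
{
    int node = 0;
    while ((int)M(node, 0) != 0) {
        const int f = (int)M(node, 0) - 1;
        node = (X(row, f) <= M(node, 1)) ? (int)M(node, 2) - 1
                                         : (int)M(node, 3) - 1;
    }
    return M(node, 4);
}

// Discrete AdaBoost (two-class SAMME) with weighted CART weak learners.
// y is 0/1 with 1 the positive class. Deterministic: no RNG involved.
// [[Rcpp::export(name = ".adaboost_fit_cpp")]]
List adaboost_fit_cpp(NumericMatrix X, IntegerVector y, int max_depth,
                      int n_estimators, double learning_rate)
{
    const int n = X.nrow();
    if (n < 1) stop("empty training set");
    bool has0 = false, has1 = false;
    for (int i = 0; i < n; ++i) { if (y[i] == 1) has1 = true; else has0 = true; }
    if (!has0 || !has1) stop("single-class training set");

    std::vector<double> w(n, 1.0 / n);
    std::vector<int> all(n);
    for (int i = 0; i < n; ++i) all[i] = i;

    List trees(n_estimators);
    NumericVector alpha(n_estimators);
    std::vector<double> h(n);
    int m_used = 0;

    for (int m = 0; m < n_estimators; ++m) {
        TreeBuf T;
        std::vector<int> idx(all);
        build_node(X, y, w, idx, 0, max_depth, T);
        NumericMatrix Tm = pack_tree(T);

        double err = 0.0, wsum = 0.0;
        for (int i = 0; i < n; ++i) {
            h[i] = predict_tree(Tm, X, i);
            const double yi = (y[i] == 1) ? 1.0 : -1.0;
            wsum += w[i];
            if (h[i] != yi) err += w[i];
        }
        err /= wsum;

        if (err >= 0.5) {
            // weak learner no better than chance: keep a first member with a
            // negligible weight so the ensemble is defined, then stop
            if (m_used == 0) { trees[m_used] = Tm; alpha[m_used] = 1e-10; ++m_used; }
            break;
        }
        const double e = std::max(err, 1e-12);
        const double a = learning_rate * std::log((1.0 - e) / e);
        trees[m_used] = Tm;
        alpha[m_used] = a;
        ++m_used;
        if (err <= 1e-12) break;  // perfect member dominates; done

        double z = 0.0;
        for (int i = 0; i < n; ++i) {
            const double yi = (y[i] == 1) ? 1.0 : -1.0;
            if (h[i] != yi) w[i] *= std::exp(a);
            z += w[i];
        }
        for (int i = 0; i < n; ++i) w[i] /= z;
    }

    List out_trees(m_used);
    NumericVector out_alpha(m_used);
    for (int m = 0; m < m_used; ++m) { out_trees[m] = trees[m]; out_alpha[m] = alpha[m]; }
    return List::create(_["trees"] = out_trees, _["alpha"] = out_alpha);
}

// Normalized weighted vote margin in [-1, 1]; positive favors class 1.
// [[Rcpp::export(name = ".adaboost_score_cpp")]]
NumericVector adaboost_score_cpp(List model, NumericMatrix X)
{
    List trees = model["trees"];
    NumericVector alpha = model["alpha"];
    const int M = trees.size(), n = X.nrow();
    double asum = 0.0;
    for (int m = 0; m < M; ++m) asum += alpha[m];
    NumericVector s(n);
    for (int m = 0; m < M; ++m) {
        NumericMatrix Tm = trees[m];
        for (int i = 0; i < n; ++i) s[i] += alpha[m] * predict_tree(Tm, X, i);
    }
    if (asum > 0) for (int i = 0; i < n; ++i) s[i] /= asum;
    return s;
}
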