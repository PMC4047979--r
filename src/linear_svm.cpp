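#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Dual coordinate descent for the L1-loss (hinge) linear SVM
//
//   min_w 0.5 ||w||^2 + C sum_i max(0, 1 - y_i w.x_i)
//
// following Hsieh et al. (2008). The intercept is handled through an
// augmented constant feature of value 1, so w has length d + 1 and the
// decision rule is g(x) = w[0..d-1].x + w[d]. Coordinates are visited in a
// random order re-drawn each epoch (essential for fast convergence on the
// spatially correlated features typical of smoothed volumes); the shuffle
// uses a private xorshift generator with a fixed seed, so the solver stays
// fully deterministic and independent of R's RNG state.
//
// X is stored row-major here (one contiguous block per sample) because the
// inner loop streams over one sample's features at a time.

static inline unsigned int xorshift32(unsigned int &s) {
    s ^= s << 13; s ^= s >> 17; s ^= s << 5;
    return s;
}

static void dcd_train(const std::vector<double> &X, int n, int d,
                      const int *y, double C, double eps, int max_epochs,
                      std::vector<double> &w) {
    std::fill(w.begin(), w.end(), 0.0);
    std::vector<double> alpha(n, 0.0);
    std::vector<double> qii(n);
    std::vector<int> order(n);
    unsigned int rng = 88172645u;  // fixed: deterministic solver
    for (int i = 0; i < n; ++i) {
        order[i] = i;
        const double *xi = &X[(size_t)i * d];
        double s = 1.0;  // intercept feature contributes 1
        for (int j = 0; j < d; ++j) s += xi[j] * xi[j];
        qii[i] = s;
    }
    // active-set shrinking as in liblinear: bounded variables whose
    // gradients point firmly outward are dropped from the sweep until the
    // remaining set converges, then everything is checked once more
    int active = n;
    const double inf = std::numeric_limits<double>::infinity();
    double pgmax_old = inf, pgmin_old = -inf;
    for (int epoch = 0; epoch < max_epochs; ++epoch) {
        double pgmax_new = -inf, pgmin_new = inf;
        for (int i = active - 1; i > 0; --i) {
            int j = (int)(xorshift32(rng) % (unsigned int)(i + 1));
            std::swap(order[i], order[j]);
        }
        for (int t = 0; t < active; ++t) {
            const int i = order[t];
            const double *xi = &X[(size_t)i * d];
            double g = w[d];
            for (int j = 0; j < d; ++j) g += w[j] * xi[j];
            g = g * y[i] - 1.0;  // gradient of dual objective wrt alpha_i
            double pg = 0.0;     // projected gradient
            if (alpha[i] <= 0.0) {
                if (g > pgmax_old) {  // shrink: firmly at lower bound
                    --active;
                    std::swap(order[t], order[active]);
                    --t;
                    continue;
                }
                if (g < 0.0) pg = g;
            } else if (alpha[i] >= C) {
                if (g < pgmin_old) {  // shrink: firmly at upper bound
                    --active;
                    std::swap(order[t], order[active]);
                    --t;
                    continue;
                }
                if (g > 0.0) pg = g;
            } else {
                pg = g;
            }
            if (pg > pgmax_new) pgmax_new = pg;
            if (pg < pgmin_new) pgmin_new = pg;
            if (std::fabs(pg) > 1e-12) {
                double a_old = alpha[i];
                double a_new = a_old - g / qii[i];
                if (a_new < 0.0) a_new = 0.0;
                if (a_new > C) a_new = C;
                alpha[i] = a_new;
                double delta = (a_new - a_old) * y[i];
                for (int j = 0; j < d; ++j) w[j] += delta * xi[j];
                w[d] += delta;
            }
        }
        if (pgmax_new - pgmin_new <= eps) {
            if (active == n) break;
            active = n;  // unshrink and verify over the full set
            pgmax_old = inf;
            pgmin_old = -inf;
            continue;
        }
        pgmax_old = pgmax_new > 0.0 ? pgmax_new : inf;
        pgmin_old = pgmin_new < 0.0 ? pgmin_new : -inf;
    }
}

// copy selected rows of an R column-major matrix into a row-major block,
// centring each column on its mean over those rows. Centring makes the
// fitted rule invariant to global feature shifts (the intercept absorbs
// them exactly) and conditions the dual problem: gray-matter features sit
// around a common baseline, which would otherwise dominate every inner
// product. Column means are returned so predictions can be made in the
// original coordinates.
static void copy_rows_centered(const NumericMatrix &X,
                               const std::vector<int> &rows,
                               std::vector<double> &out,
                               std::vector<double> &mu) {
    const int d = X.ncol();
    const size_t nr = rows.size();
    out.resize(nr * d);
    mu.assign(d, 0.0);
    for (size_t r = 0; r < nr; ++r)
        for (int j = 0; j < d; ++j)
            mu[j] += X(rows[r], j);
    for (int j = 0; j < d; ++j) mu[j] /= (double)nr;
    for (size_t r = 0; r < nr; ++r)
        for (int j = 0; j < d; ++j)
            out[r * d + j] = X(rows[r], j) - mu[j];
}

// fold the training-mean offset into the intercept: g(x) = w.(x - mu) + b
// becomes w.x + (b - w.mu)
static double absorb_mu(const std::vector<double> &w, int d,
                        const std::vector<double> &mu) {
    double off = w[d];
    for (int j = 0; j < d; ++j) off -= w[j] * mu[j];
    return off;
}

// [[Rcpp::export(name = ".svm_train_cpp")]]
List svm_train_cpp(NumericMatrix X, IntegerVector y, double C,
                   double eps, int max_epochs) {
    const int n = X.nrow(), d = X.ncol();
    std::vector<int> rows(n);
    for (int i = 0; i < n; ++i) rows[i] = i;
    std::vector<double> Xr, mu;
    copy_rows_centered(X, rows, Xr, mu);
    std::vector<double> w(d + 1);
    dcd_train(Xr, n, d, &y[0], C, eps, max_epochs, w);
    NumericVector wv(d);
    for (int j = 0; j < d; ++j) wv[j] = w[j];
    return List::create(_["w"] = wv, _["w0"] = absorb_mu(w, d, mu));
}

// [[Rcpp::export(name = ".svm_decision_cpp")]]
NumericVector svm_decision_cpp(NumericMatrix X, NumericVector w, double w0) {
    const int n = X.nrow(), d = X.ncol();
    NumericVector out(n);
    for (int i = 0; i < n; ++i) {
        double g = w0;
        for (int j = 0; j < d; ++j) g += w[j] * X(i, j);
        out[i] = g;
    }
    return out;
}

// Pooled k-fold CV predictions for one label vector on a fixed fold
// partition. fold is 1-based fold id per row. Returns predicted labels
// (+1/-1) per row. A single-class training fold predicts that class.
// [[Rcpp::export(name = ".svm_cv_predict_cpp")]]
IntegerVector svm_cv_predict_cpp(NumericMatrix X, IntegerVector y,
                                 IntegerVector fold, double C, double eps,
                                 int max_epochs) {
    const int n = X.nrow(), d = X.ncol();
    int k = 0;
    for (int i = 0; i < n; ++i) if (fold[i] > k) k = fold[i];
    IntegerVector pred(n);
    std::vector<double> Xtr, mu, w((size_t)d + 1);
    std::vector<int> ytr, tr, te;
    for (int f = 1; f <= k; ++f) {
        tr.clear(); te.clear(); ytr.clear();
        for (int i = 0; i < n; ++i) (fold[i] == f ? te : tr).push_back(i);
        if (te.empty()) continue;
        int pos = 0, neg = 0;
        for (size_t r = 0; r < tr.size(); ++r) {
            ytr.push_back(y[tr[r]]);
            if (y[tr[r]] > 0) ++pos; else ++neg;
        }
        if (pos == 0 || neg == 0) {
            int cls = pos == 0 ? -1 : 1;
            for (size_t r = 0; r < te.size(); ++r) pred[te[r]] = cls;
            continue;
        }
        copy_rows_centered(X, tr, Xtr, mu);
        dcd_train(Xtr, (int)tr.size(), d, ytr.data(), C, eps, max_epochs, w);
        const double off = absorb_mu(w, d, mu);
        for (size_t r = 0; r < te.size(); ++r) {
            double g = off;
            for (int j = 0; j < d; ++j) g += w[j] * X(te[r], j);
            pred[te[r]] = g > 0 ? 1 : -1;
        }
    }
    return pred;
}

// Batched pooled CV accuracy over many label vectors (columns of Y,
// typically label permutations), each with its own fold partition (matching
// column of F): every column re-runs the identical procedure — stratified
// folds included — on its labels. Returns pooled accuracy per column.
// [[Rcpp::export(name = ".svm_cv_accuracy_batch_cpp")]]
NumericVector svm_cv_accuracy_batch_cpp(NumericMatrix X, IntegerMatrix Y,
                                        IntegerMatrix F, double C,
                                        double eps, int max_epochs) {
    const int n = X.nrow(), d = X.ncol(), m = Y.ncol();
    if (F.nrow() != n || F.ncol() != m)
        stop("fold matrix must match the label matrix");
    std::vector<int> correct(m, 0);
    std::vector<double> Xtr, mu, w((size_t)d + 1);
    std::vector<int> ytr, tr, te;
    for (int c = 0; c < m; ++c) {
        int k = 0;
        for (int i = 0; i < n; ++i) if (F(i, c) > k) k = F(i, c);
        for (int f = 1; f <= k; ++f) {
            tr.clear(); te.clear(); ytr.clear();
            for (int i = 0; i < n; ++i) (F(i, c) == f ? te : tr).push_back(i);
            if (te.empty()) continue;
            int pos = 0, neg = 0;
            for (size_t r = 0; r < tr.size(); ++r) {
                int yy = Y(tr[r], c);
                ytr.push_back(yy);
                if (yy > 0) ++pos; else ++neg;
            }
            if (pos == 0 || neg == 0) {
                int cls = pos == 0 ? -1 : 1;
                for (size_t r = 0; r < te.size(); ++r)
                    if (Y(te[r], c) == cls) ++correct[c];
                continue;
            }
            copy_rows_centered(X, tr, Xtr, mu);
            dcd_train(Xtr, (int)tr.size(), d, ytr.data(), C, eps,
                      max_epochs, w);
            const double off = absorb_mu(w, d, mu);
            for (size_t r = 0; r < te.size(); ++r) {
                double g = off;
                for (int j = 0; j < d; ++j) g += w[j] * X(te[r], j);
                int p = g > 0 ? 1 : -1;
                if (p == Y(te[r], c)) ++correct[c];
            }
        }
        Rcpp::checkUserInterrupt();
    }
    NumericVector acc(m);
    for (int c = 0; c < m; ++c) acc[c] = (double)correct[c] / n;
    return acc;
}
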