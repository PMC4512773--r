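#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Plug-in mutual information (bits) between two integer-coded vectors whose
// symbols have already been mapped to 0..(kx-1) / 0..(ky-1).
static double mi_counts(const int* x, const int* y, int n, int kx, int ky) {
    std::vector<int> joint(kx * ky, 0), mx(kx, 0), my(ky, 0);
    for (int i = 0; i < n; ++i) {
        joint[x[i] * ky + y[i]]++;
        mx[x[i]]++;
        my[y[i]]++;
    }
    const double dn = static_cast<double>(n);
    double mi = 0.0;
    for (int a = 0; a < kx; ++a) {
        if (!mx[a]) continue;
        for (int b = 0; b < ky; ++b) {
            int c = joint[a * ky + b];
            if (!c) continue;
            double pab = c / dn;
            mi += pab * std::log2(c * dn /
                  (static_cast<double>(mx[a]) * static_cast<double>(my[b])));
        }
    }
    return mi > 0.0 ? mi : 0.0;
}

// codes: n_samples x n_features integer matrix, each column one feature,
// symbols in 0..(k_codes-1). labels: length n, symbols in 0..(k_lab-1).
// [[Rcpp::export(name = ".mrmr_mid_cpp")]]
List mrmr_mid_cpp(IntegerMatrix codes, IntegerVector labels, int k,
                  int k_codes, int k_lab, double eps = 1e-9) {
    const int n = codes.nrow(), f = codes.ncol();
    if (labels.size() != n) stop("labels length must match sample count");
    if (k < 1 || k > f) stop("k out of range");

    std::vector<double> relevance(f);
    for (int j = 0; j < f; ++j) {
        relevance[j] = mi_counts(&codes(0, j), &labels[0], n, k_codes, k_lab);
    }

    std::vector<bool> selected(f, false);
    std::vector<double> redsum(f, 0.0); // sum of MI(candidate, selected)
    IntegerVector order(k);
    NumericVector score(k), rel_out(k);

    for (int step = 0; step < k; ++step) {
        int best = -1;
        double best_obj = 0.0, best_rel = 0.0;
        for (int j = 0; j < f; ++j) {
            if (selected[j]) continue;
            double obj = (step == 0)
                ? relevance[j]
                : relevance[j] - redsum[j] / static_cast<double>(step);
            if (best < 0 || obj > best_obj + eps ||
                (obj > best_obj - eps && relevance[j] > best_rel + eps)) {
                best = j;
                best_obj = obj;
                best_rel = relevance[j];
            }
        }
        selected[best] = true;
        order[step] = best + 1; // 1-based for R
        score[step] = best_obj;
        rel_out[step] = relevance[best];
        if (step + 1 < k) {
            for (int j = 0; j < f; ++j) {
                if (selected[j]) continue;
                redsum[j] += mi_counts(&codes(0, j), &codes(0, best),
                                       n, k_codes, k_codes);
            }
        }
    }
    return List::create(_["order"] = order, _["score"] = score,
                        _["relevance"] = rel_out);
}

// [[Rcpp::export(name = ".mi_pair_cpp")]]
double mi_pair_cpp(IntegerVector x, IntegerVector y, int kx, int ky) {
    if (x.size() != y.size()) stop("length mismatch");
    return mi_counts(&x[0], &y[0], x.size(), kx, ky);
}
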