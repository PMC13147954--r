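#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Exact brute-force k-nearest neighbours within one FOV.
// `rank` is a permutation rank used for deterministic tie-breaking
// (typically the rank of cell_id within the FOV); ties in distance are
// resolved toward the smaller rank.
// Returns local (1-based) neighbour indices and Euclidean distances,
// each an n x min(k, n-1) matrix, rows sorted by (distance, rank).
// [[Rcpp::export(name = ".knn_brute_cpp")]]
List knn_brute_cpp(NumericVector x, NumericVector y, int k, IntegerVector rank) {
    const int n = x.size();
    if (n < 2) stop("need at least 2 cells for a neighbour search");
    const int kk = std::min(k, n - 1);

    IntegerMatrix idx(n, kk);
    NumericMatrix dst(n, kk);

    std::vector<std::pair<double, int> > cand(n - 1);
    for (int i = 0; i < n; ++i) {
        int m = 0;
        for (int j = 0; j < n; ++j) {
            if (j == i) continue;
            double dx = x[j] - x[i], dy = y[j] - y[i];
            cand[m++] = std::make_pair(dx * dx + dy * dy, j);
        }
        std::partial_sort(cand.begin(), cand.begin() + kk, cand.end(),
            [&rank](const std::pair<double, int>& a, const std::pair<double, int>& b) {
                if (a.first != b.first) return a.first < b.first;
                return rank[a.second] < rank[b.second];
            });
        for (int q = 0; q < kk; ++q) {
            idx(i, q) = cand[q].second + 1;
            dst(i, q) = std::sqrt(cand[q].first);
        }
    }
    return List::create(_["idx"] = idx, _["dist"] = dst);
}
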