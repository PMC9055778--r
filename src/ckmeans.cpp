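#include <Rcpp.h>
using namespace Rcpp;

// Exact optimal univariate k-means by dynamic programming over the sorted
// data. Clusters of an optimal solution are contiguous intervals of the
// sorted values, so minimising within-cluster sum of squares reduces to an
// optimal segmentation problem solved in O(k n^2) with prefix sums.
//
// cost(j, i): within-SS of x[j..i] (0-based, inclusive), computed from
// prefix sums of x and x^2 in a numerically careful centred form.

static inline double seg_cost(const std::vector<long double>& s1,
                              const std::vector<long double>& s2,
                              int j, int i) {
    long double n = i - j + 1;
    long double sum = s1[i + 1] - s1[j];
    long double ss = s2[i + 1] - s2[j];
    long double c = ss - sum * sum / n;
    return c > 0 ? (double)c : 0.0;
}

// [[Rcpp::export(name = ".ckmeans_dp")]]
List ckmeans_dp(NumericVector x, int k) {
    int n = x.size();
    if (k < 1 || k > n) stop("k must satisfy 1 <= k <= length(x)");

    // sort, remembering original order
    IntegerVector ord(n);
    for (int i = 0; i < n; ++i) ord[i] = i;
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return x[a] < x[b]; });
    std::vector<double> xs(n);
    for (int i = 0; i < n; ++i) xs[i] = x[ord[i]];

    std::vector<long double> s1(n + 1, 0.0L), s2(n + 1, 0.0L);
    for (int i = 0; i < n; ++i) {
        s1[i + 1] = s1[i] + xs[i];
        s2[i + 1] = s2[i] + (long double)xs[i] * xs[i];
    }

    // D[q][i]: min cost of clustering xs[0..i] into q+1 clusters
    // B[q][i]: start index of the last cluster in that optimum
    std::vector<std::vector<double>> D(k, std::vector<double>(n));
    std::vector<std::vector<int>> B(k, std::vector<int>(n));
    for (int i = 0; i < n; ++i) {
        D[0][i] = seg_cost(s1, s2, 0, i);
        B[0][i] = 0;
    }
    for (int q = 1; q < k; ++q) {
        for (int i = q; i < n; ++i) {
            double best = R_PosInf;
            int bestj = q;
            for (int j = q; j <= i; ++j) {
                double c = D[q - 1][j - 1] + seg_cost(s1, s2, j, i);
                if (c < best) { best = c; bestj = j; }
            }
            D[q][i] = best;
            B[q][i] = bestj;
        }
    }

    // backtrack cluster boundaries
    std::vector<int> starts(k);
    int i = n - 1;
    for (int q = k - 1; q >= 0; --q) {
        starts[q] = B[q][i];
        i = starts[q] - 1;
    }

    IntegerVector assign(n);
    NumericVector centers(k), sizes(k);
    for (int q = 0; q < k; ++q) {
        int a = starts[q];
        int b = (q == k - 1) ? n - 1 : starts[q + 1] - 1;
        long double sum = s1[b + 1] - s1[a];
        centers[q] = (double)(sum / (b - a + 1));
        sizes[q] = b - a + 1;
        for (int t = a; t <= b; ++t) assign[ord[t]] = q + 1;
    }

    return List::create(_["assignments"] = assign,
                        _["centroids"] = centers,
                        _["sizes"] = sizes,
                        _["withinss"] = D[k - 1][n - 1]);
}
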