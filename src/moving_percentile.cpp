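#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Type-7 (R default) quantile of a sorted vector.
static double quantile7(const std::vector<double>& w, double p) {
    const int m = static_cast<int>(w.size());
    if (m == 1) return w[0];
    double h = (m - 1) * p;
    int lo = static_cast<int>(std::floor(h));
    if (lo >= m - 1) return w[m - 1];
    return w[lo] + (h - lo) * (w[lo + 1] - w[lo]);
}

// Moving windowed percentile with truncated (not padded) edge windows.
// Window at sample i covers [i - half, i + half] clipped to the trace.
// Maintains the window as a sorted vector; O(n * w) worst case but with
// memmove-level constants, fast for the 180-s windows used here.
// [[Rcpp::export(name = ".moving_percentile_cpp")]]
NumericVector moving_percentile_cpp(NumericVector x, int half, double p) {
    const int n = x.size();
    NumericVector out(n);
    if (n == 0) return out;
    std::vector<double> win;
    win.reserve(2 * half + 2);
    int lo = 0, hi = -1;  // current inclusive window bounds
    for (int i = 0; i < n; ++i) {
        int new_lo = std::max(0, i - half);
        int new_hi = std::min(n - 1, i + half);
        while (hi < new_hi) {
            ++hi;
            win.insert(std::lower_bound(win.begin(), win.end(), x[hi]), x[hi]);
        }
        while (lo < new_lo) {
            win.erase(std::lower_bound(win.begin(), win.end(), x[lo]));
            ++lo;
        }
        out[i] = quantile7(win, p);
    }
    return out;
}
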