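#include <Rcpp.h>
using namespace Rcpp;

// Scale-local clearance pruning of skeleton vertices: vertex v is dropped
// iff some vertex u with clearance(u) >= clearance(v) / ratio lies within
// 2 * clearance(u) of v. Equivalent in spirit to pruning at ratio x the
// local maximum clearance, but insensitive to width variation along a
// component (tapering vessels), unlike a component-global threshold.

// [[Rcpp::export(name = ".prune_dominated_cpp")]]
LogicalVector prune_dominated_cpp(NumericVector u, NumericVector v,
                                  NumericVector clr, double ratio) {
    int n = u.size();
    LogicalVector drop(n);
    if (ratio <= 0) return drop;
    for (int i = 0; i < n; ++i) {
        double need = clr[i] / ratio;
        for (int j = 0; j < n; ++j) {
            if (clr[j] < need || j == i) continue;
            double dx = u[j] - u[i], dy = v[j] - v[i];
            double w = 2.0 * clr[j];
            if (dx * dx + dy * dy <= w * w) { drop[i] = true; break; }
        }
    }
    return drop;
}
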