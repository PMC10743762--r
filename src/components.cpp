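#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 8-connected component labelling of a binary 2D mask (BFS flood fill).
// Returns an integer matrix: 0 = background, 1..k = component id.

// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerMatrix label_components_cpp(IntegerMatrix mask) {
    int nr = mask.nrow(), nc = mask.ncol();
    IntegerMatrix lab(nr, nc);
    std::vector<int> stack;
    int next = 0;
    for (int j = 0; j < nc; ++j) {
        for (int i = 0; i < nr; ++i) {
            if (mask(i, j) == 0 || lab(i, j) != 0) continue;
            ++next;
            stack.clear();
            stack.push_back(i + j * nr);
            lab(i, j) = next;
            while (!stack.empty()) {
                int idx = stack.back(); stack.pop_back();
                int ci = idx % nr, cj = idx / nr;
                for (int dj = -1; dj <= 1; ++dj) {
                    for (int di = -1; di <= 1; ++di) {
                        if (di == 0 && dj == 0) continue;
                        int ni = ci + di, nj = cj + dj;
                        if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
                        if (mask(ni, nj) != 0 && lab(ni, nj) == 0) {
                            lab(ni, nj) = next;
                            stack.push_back(ni + nj * nr);
                        }
                    }
                }
            }
        }
    }
    return lab;
}
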