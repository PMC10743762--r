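#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Union-of-spheres rasterization: a voxel is foreground iff its center lies
// within (closed inequality) distance r_p of at least one centerline point p.
// Voxel centers are at origin + index * h, indices 0-based.

// [[Rcpp::export(name = ".voxelize_spheres_cpp")]]
IntegerVector voxelize_spheres_cpp(NumericMatrix pts, NumericVector origin,
                                   double h, IntegerVector dims) {
    int nx = dims[0], ny = dims[1], nz = dims[2];
    double ox = origin[0], oy = origin[1], oz = origin[2];
    R_xlen_t total = (R_xlen_t)nx * ny * nz;
    IntegerVector grid(total);   // zero-initialized
    int n = pts.nrow();
    for (int p = 0; p < n; ++p) {
        double x = pts(p, 0), y = pts(p, 1), z = pts(p, 2), r = pts(p, 3);
        double r2 = r * r;
        int i0 = (int)std::ceil((x - r - ox) / h - 1e-9);
        int i1 = (int)std::floor((x + r - ox) / h + 1e-9);
        int j0 = (int)std::ceil((y - r - oy) / h - 1e-9);
        int j1 = (int)std::floor((y + r - oy) / h + 1e-9);
        int k0 = (int)std::ceil((z - r - oz) / h - 1e-9);
        int k1 = (int)std::floor((z + r - oz) / h + 1e-9);
        if (i0 < 0) i0 = 0; if (i1 >= nx) i1 = nx - 1;
        if (j0 < 0) j0 = 0; if (j1 >= ny) j1 = ny - 1;
        if (k0 < 0) k0 = 0; if (k1 >= nz) k1 = nz - 1;
        for (int k = k0; k <= k1; ++k) {
            double dz = (oz + k * h) - z;
            double dz2 = dz * dz;
            if (dz2 > r2) continue;
            for (int j = j0; j <= j1; ++j) {
                double dy = (oy + j * h) - y;
                double dyz2 = dy * dy + dz2;
                if (dyz2 > r2) continue;
                R_xlen_t base = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx;
                for (int i = i0; i <= i1; ++i) {
                    double dx = (ox + i * h) - x;
                    if (dx * dx + dyz2 <= r2) grid[base + i] = 1;
                }
            }
        }
    }
    return grid;
}
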