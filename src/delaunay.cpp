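#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>
using namespace Rcpp;

// Bowyer-Watson incremental Delaunay triangulation of 2D point sites.
// Returns one row per finite triangle: circumcenter (u, v) and circumradius,
// i.e. the interior/exterior Voronoi vertices of the site set together with
// their clearance (distance to the nearest site, by the empty-circle
// property). Callers are expected to pass slightly jittered sites so that
// exactly cocircular configurations do not arise.

struct Tri {
    int a, b, c;     // site indices (>= n are super-triangle vertices)
    double cx, cy;   // circumcenter
    double r2;       // squared circumradius
    bool alive;
};

static inline bool circumcircle(double ax, double ay, double bx, double by,
                                double cx, double cy,
                                double &ux, double &uy, double &r2) {
    double d = 2.0 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by));
    if (std::fabs(d) < 1e-12) return false;
    double a2 = ax * ax + ay * ay;
    double b2 = bx * bx + by * by;
    double c2 = cx * cx + cy * cy;
    ux = (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d;
    uy = (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d;
    double dx = ax - ux, dy = ay - uy;
    r2 = dx * dx + dy * dy;
    return true;
}

// [[Rcpp::export(name = ".delaunay_vertices_cpp")]]
NumericMatrix delaunay_vertices_cpp(NumericVector x, NumericVector y) {
    int n = x.size();
    if (n < 3) return NumericMatrix(0, 3);

    std::vector<double> px(n + 3), py(n + 3);
    for (int i = 0; i < n; ++i) { px[i] = x[i]; py[i] = y[i]; }

    double xmin = px[0], xmax = px[0], ymin = py[0], ymax = py[0];
    for (int i = 1; i < n; ++i) {
        if (px[i] < xmin) xmin = px[i];
        if (px[i] > xmax) xmax = px[i];
        if (py[i] < ymin) ymin = py[i];
        if (py[i] > ymax) ymax = py[i];
    }
    double dmax = std::max(xmax - xmin, ymax - ymin);
    if (dmax <= 0) dmax = 1.0;
    double midx = 0.5 * (xmin + xmax), midy = 0.5 * (ymin + ymax);
    double M = 100.0 * dmax;
    // super-triangle enclosing all sites
    px[n]     = midx - 2.0 * M; py[n]     = midy - M;
    px[n + 1] = midx + 2.0 * M; py[n + 1] = midy - M;
    px[n + 2] = midx;           py[n + 2] = midy + 2.0 * M;

    std::vector<Tri> tris;
    tris.reserve(4 * n);
    {
        Tri t; t.a = n; t.b = n + 1; t.c = n + 2; t.alive = true;
        if (!circumcircle(px[t.a], py[t.a], px[t.b], py[t.b], px[t.c], py[t.c],
                          t.cx, t.cy, t.r2)) {
            t.cx = midx; t.cy = midy; t.r2 = R_PosInf;
        }
        tris.push_back(t);
    }

    std::vector<int> bad;
    typedef std::pair<int, int> Edge;
    std::map<Edge, int> edgeCount;

    for (int p = 0; p < n; ++p) {
        bad.clear();
        edgeCount.clear();
        double qx = px[p], qy = py[p];
        for (size_t t = 0; t < tris.size(); ++t) {
            if (!tris[t].alive) continue;
            double dx = qx - tris[t].cx, dy = qy - tris[t].cy;
            if (dx * dx + dy * dy <= tris[t].r2) bad.push_back((int)t);
        }
        for (size_t b = 0; b < bad.size(); ++b) {
            Tri &t = tris[bad[b]];
            t.alive = false;
            int v[3] = { t.a, t.b, t.c };
            for (int e = 0; e < 3; ++e) {
                int u1 = v[e], u2 = v[(e + 1) % 3];
                Edge key = u1 < u2 ? Edge(u1, u2) : Edge(u2, u1);
                edgeCount[key] += 1;
            }
        }
        // boundary of the cavity: edges used exactly once
        for (std::map<Edge, int>::iterator it = edgeCount.begin();
             it != edgeCount.end(); ++it) {
            if (it->second != 1) continue;
            Tri t;
            t.a = it->first.first; t.b = it->first.second; t.c = p;
            t.alive = true;
            if (!circumcircle(px[t.a], py[t.a], px[t.b], py[t.b],
                              px[t.c], py[t.c], t.cx, t.cy, t.r2)) {
                // nearly collinear: give it an all-covering circle so it is
                // destroyed by any subsequent insertion, and skip on output
                t.cx = qx; t.cy = qy; t.r2 = R_PosInf;
            }
            tris.push_back(t);
        }
    }

    int m = 0;
    for (size_t t = 0; t < tris.size(); ++t)
        if (tris[t].alive && tris[t].a < n && tris[t].b < n && tris[t].c < n &&
            R_finite(tris[t].r2))
            ++m;
    NumericMatrix out(m, 4);
    int k = 0;
    for (size_t t = 0; t < tris.size(); ++t) {
        if (!(tris[t].alive && tris[t].a < n && tris[t].b < n &&
              tris[t].c < n && R_finite(tris[t].r2)))
            continue;
        out(k, 0) = tris[t].cx;
        out(k, 1) = tris[t].cy;
        out(k, 2) = std::sqrt(tris[t].r2);
        // separation angle: widest angle subtended at the circumcenter by a
        // pair of the triangle's sites (large on the medial axis, small for
        // vertices generated by near-collinear samples of one boundary arc)
        int v[3] = { tris[t].a, tris[t].b, tris[t].c };
        double ang = 0.0;
        for (int e1 = 0; e1 < 3; ++e1) {
            for (int e2 = e1 + 1; e2 < 3; ++e2) {
                double ux = px[v[e1]] - tris[t].cx, uy = py[v[e1]] - tris[t].cy;
                double wx = px[v[e2]] - tris[t].cx, wy = py[v[e2]] - tris[t].cy;
                double nu = std::sqrt(ux * ux + uy * uy);
                double nw = std::sqrt(wx * wx + wy * wy);
                if (nu <= 0 || nw <= 0) continue;
                double c = (ux * wx + uy * wy) / (nu * nw);
                if (c > 1.0) c = 1.0;
                if (c < -1.0) c = -1.0;
                double a = std::acos(c);
                if (a > ang) ang = a;
            }
        }
        out(k, 3) = ang * (180.0 / M_PI);
        ++k;
    }
    colnames(out) = CharacterVector::create("u", "v", "clearance", "sepAngle");
    return out;
}
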