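#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Siddon traversal of a square pixel grid centred on the origin.
// Grid: n x n pixels of size px, physical extent [-n*px/2, n*px/2]^2.
// Pixel (ix, iy), 0-based: x in [-half + ix*px, -half + (ix+1)*px), same for y.
// emit(ix, iy, len) is called once per crossed pixel with the intersection
// length in mm.  Forward and adjoint use this identical enumeration, so the
// operator pair is exactly adjoint.
template <typename F>
static inline void traverse_ray(double x0, double y0, double x1, double y1,
                                int n, double px, F&& emit) {
    const double half = 0.5 * n * px;
    const double dx = x1 - x0, dy = y1 - y0;
    const double L = std::sqrt(dx * dx + dy * dy);
    if (L <= 0.0) return;
    const double inf = std::numeric_limits<double>::infinity();

    double tmin = 0.0, tmax = 1.0;
    if (std::fabs(dx) > 1e-14) {
        double t1 = (-half - x0) / dx, t2 = (half - x0) / dx;
        if (t1 > t2) std::swap(t1, t2);
        if (t1 > tmin) tmin = t1;
        if (t2 < tmax) tmax = t2;
    } else if (x0 <= -half || x0 >= half) {
        return;
    }
    if (std::fabs(dy) > 1e-14) {
        double t1 = (-half - y0) / dy, t2 = (half - y0) / dy;
        if (t1 > t2) std::swap(t1, t2);
        if (t1 > tmin) tmin = t1;
        if (t2 < tmax) tmax = t2;
    } else if (y0 <= -half || y0 >= half) {
        return;
    }
    if (tmin >= tmax) return;

    // entry cell (nudge inward to dodge the boundary)
    const double teps = 1e-12;
    double xe = x0 + (tmin + teps) * dx;
    double ye = y0 + (tmin + teps) * dy;
    int ix = (int)std::floor((xe + half) / px);
    int iy = (int)std::floor((ye + half) / px);
    if (ix < 0) ix = 0; if (ix > n - 1) ix = n - 1;
    if (iy < 0) iy = 0; if (iy > n - 1) iy = n - 1;

    const int stepx = (dx > 0) - (dx < 0);
    const int stepy = (dy > 0) - (dy < 0);
    const double dtx = (stepx != 0) ? px / std::fabs(dx) : inf;
    const double dty = (stepy != 0) ? px / std::fabs(dy) : inf;
    double tx = inf, ty = inf;
    if (stepx != 0) {
        double xplane = -half + (ix + (stepx > 0 ? 1 : 0)) * px;
        tx = (xplane - x0) / dx;
    }
    if (stepy != 0) {
        double yplane = -half + (iy + (stepy > 0 ? 1 : 0)) * px;
        ty = (yplane - y0) / dy;
    }

    double tcur = tmin;
    while (tcur < tmax - 1e-13) {
        double tnext = tx < ty ? tx : ty;
        if (tnext > tmax) tnext = tmax;
        double len = (tnext - tcur) * L;
        if (len > 0.0) emit(ix, iy, len);
        if (tnext >= tmax) break;
        if (tx <= ty) { ix += stepx; tx += dtx; }
        else          { iy += stepy; ty += dty; }
        if (ix < 0 || ix >= n || iy < 0 || iy >= n) break;
        tcur = tnext;
    }
}

// views: V x 6 matrix, columns (src_x, src_y, cen_x, cen_y, v_x, v_y):
// source point, detector-array centre, detector direction unit vector (mm).
// vidx: 1-based indices of the views to process.
static inline void ray_endpoints(const NumericMatrix& views, int v, int e,
                                 int nd, double sd,
                                 double& x0, double& y0, double& x1, double& y1) {
    const double off = (e - 0.5 * (nd - 1)) * sd;
    x0 = views(v, 0);
    y0 = views(v, 1);
    x1 = views(v, 2) + off * views(v, 4);
    y1 = views(v, 3) + off * views(v, 5);
}

// [[Rcpp::export]]
NumericMatrix cpp_forward_project(NumericMatrix img, NumericMatrix views,
                                  IntegerVector vidx, int nd, double sd,
                                  double px) {
    const int n = img.nrow();
    const int V = vidx.size();
    NumericMatrix sino(V, nd);
    for (int vi = 0; vi < V; ++vi) {
        const int v = vidx[vi] - 1;
        for (int e = 0; e < nd; ++e) {
            double x0, y0, x1, y1, acc = 0.0;
            ray_endpoints(views, v, e, nd, sd, x0, y0, x1, y1);
            traverse_ray(x0, y0, x1, y1, n, px,
                         [&](int ix, int iy, double len) {
                             acc += len * img(ix, iy);
                         });
            sino(vi, e) = acc;
        }
    }
    return sino;
}

// [[Rcpp::export]]
NumericMatrix cpp_back_project(NumericMatrix sino, NumericMatrix views,
                               IntegerVector vidx, int nd, double sd,
                               int n, double px) {
    const int V = vidx.size();
    NumericMatrix img(n, n);
    for (int vi = 0; vi < V; ++vi) {
        const int v = vidx[vi] - 1;
        for (int e = 0; e < nd; ++e) {
            const double g = sino(vi, e);
            if (g == 0.0) continue;
            double x0, y0, x1, y1;
            ray_endpoints(views, v, e, nd, sd, x0, y0, x1, y1);
            traverse_ray(x0, y0, x1, y1, n, px,
                         [&](int ix, int iy, double len) {
                             img(ix, iy) += len * g;
                         });
        }
    }
    return img;
}

// Full simultaneous-update SART iteration in one pass: each sweep traverses
// every ray once, reusing the cell weights for both the residual dot product
// and the normalized scatter.  row_sums/col_sums come from
// normalization_sums(); rays with zero row sum and pixels with zero column
// sum are excluded, matching the update formula's a_i+ != 0, a_+j != 0.
// Returns the final image and the residual-norm history (entry k is
// ||A f^(k-1) - b|| over included rays; the last entry is the final
// residual).
// [[Rcpp::export]]
List cpp_sart_sweeps(NumericMatrix img0, NumericMatrix sino,
                     NumericMatrix views, IntegerVector vidx, int nd,
                     double sd, double px, int n_sweeps, double beta,
                     NumericMatrix row_sums, NumericMatrix col_sums,
                     bool nonneg) {
    const int n = img0.nrow();
    const int V = vidx.size();
    NumericMatrix f(clone(img0));
    NumericMatrix upd(n, n);
    NumericVector residuals(n_sweeps + 1);
    std::vector<int> cix; cix.reserve(4 * n);
    std::vector<double> clen; clen.reserve(4 * n);
    double* fp = f.begin();
    double* up = upd.begin();

    for (int sweep = 0; sweep <= n_sweeps; ++sweep) {
        const bool last = (sweep == n_sweeps);
        std::fill(upd.begin(), upd.end(), 0.0);
        double rss = 0.0;
        for (int vi = 0; vi < V; ++vi) {
            const int v = vidx[vi] - 1;
            for (int e = 0; e < nd; ++e) {
                const double rs = row_sums(vi, e);
                if (rs <= 0.0) continue;
                double x0, y0, x1, y1;
                ray_endpoints(views, v, e, nd, sd, x0, y0, x1, y1);
                cix.clear(); clen.clear();
                double dot = 0.0;
                traverse_ray(x0, y0, x1, y1, n, px,
                             [&](int ix, int iy, double len) {
                                 const int p = ix + n * iy;
                                 cix.push_back(p);
                                 clen.push_back(len);
                                 dot += len * fp[p];
                             });
                const double r = sino(vi, e) - dot;
                rss += r * r;
                if (last) continue;
                const double w = r / rs;
                for (size_t t = 0; t < cix.size(); ++t)
                    up[cix[t]] += clen[t] * w;
            }
        }
        residuals[sweep] = std::sqrt(rss);
        if (last) break;
        for (int p = 0; p < n * n; ++p) {
            const double cs = col_sums[p];
            if (cs > 0.0) {
                fp[p] += beta * up[p] / cs;
                if (nonneg && fp[p] < 0.0) fp[p] = 0.0;
            }
        }
    }
    return List::create(Rcpp::Named("image") = f,
                        Rcpp::Named("residuals") = residuals);
}
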