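#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Regularised Biot-Savart induction of a set of polyline filaments.
//
// pts:       n x 3 query points (m)
// verts:     total_vertices x 3 filament vertices, filaments concatenated
// v_first:   0-based index of the first vertex of each filament
// v_count:   number of vertices of each filament (segments = count - 1)
// gamma:     circulation of each filament (m^2/s, right-hand rule along order)
// core:      Lamb-Oseen core radius r_c of each filament (m)
//
// Each segment contributes the classical straight-segment kernel multiplied by
// the Lamb-Oseen regularisation (1 - exp(-d^2/r_c^2)), d the perpendicular
// distance to the segment's supporting line. The factor removes the line
// singularity and reproduces the Lamb-Oseen tangential profile for straight
// filaments.
// [[Rcpp::export(name = ".bs_induced")]]
NumericMatrix bs_induced(NumericMatrix pts, NumericMatrix verts,
                         IntegerVector v_first, IntegerVector v_count,
                         NumericVector gamma, NumericVector core) {
  const int np = pts.nrow();
  const int nf = gamma.size();
  NumericMatrix out(np, 3);
  std::vector<double> px(np), py(np), pz(np);
  for (int p = 0; p < np; ++p) {
    px[p] = pts(p, 0); py[p] = pts(p, 1); pz[p] = pts(p, 2);
  }
  for (int f = 0; f < nf; ++f) {
    const double g4pi = gamma[f] / (4.0 * M_PI);
    const double rc2 = core[f] * core[f];
    const int v0 = v_first[f];
    const int nseg = v_count[f] - 1;
    for (int s = 0; s < nseg; ++s) {
      const double ax = verts(v0 + s, 0), ay = verts(v0 + s, 1), az = verts(v0 + s, 2);
      const double bx = verts(v0 + s + 1, 0), by = verts(v0 + s + 1, 1), bz = verts(v0 + s + 1, 2);
      const double sx = bx - ax, sy = by - ay, sz = bz - az;
      const double L2 = sx * sx + sy * sy + sz * sz;
      if (L2 < 1e-24) continue;  // degenerate segment
      for (int p = 0; p < np; ++p) {
        const double r1x = px[p] - ax, r1y = py[p] - ay, r1z = pz[p] - az;
        const double r2x = px[p] - bx, r2y = py[p] - by, r2z = pz[p] - bz;
        const double cx = r1y * r2z - r1z * r2y;
        const double cy = r1z * r2x - r1x * r2z;
        const double cz = r1x * r2y - r1y * r2x;
        const double c2 = cx * cx + cy * cy + cz * cz;
        if (c2 < 1e-24 * L2) continue;  // on the supporting line
        const double n1 = std::sqrt(r1x * r1x + r1y * r1y + r1z * r1z);
        const double n2 = std::sqrt(r2x * r2x + r2y * r2y + r2z * r2z);
        const double dot = r1x * r2x + r1y * r2y + r1z * r2z;
        const double denom = n1 * n2 * (n1 * n2 + dot);
        if (denom < 1e-30) continue;
        const double d2 = c2 / L2;  // squared distance to the line
        const double reg = (d2 > 30.0 * rc2) ? 1.0 : 1.0 - std::exp(-d2 / rc2);
        const double k = g4pi * (n1 + n2) / denom * reg;
        out(p, 0) += k * cx;
        out(p, 1) += k * cy;
        out(p, 2) += k * cz;
      }
    }
  }
  return out;
}

// Per-cell 3x3-neighbourhood (centre excluded) median of the valid
// neighbours plus the median absolute residual about it (the robust scale of
// the normalised median test; insensitive to outliers among the neighbours
// themselves). Cells with no valid neighbour get NA. Used by the outlier
// detector and by median replacement.
// [[Rcpp::export(name = ".nbr_stats")]]
List nbr_stats(NumericMatrix x, LogicalMatrix mask) {
  const int nr = x.nrow(), nc = x.ncol();
  NumericMatrix med(nr, nc), scl(nr, nc);
  IntegerMatrix nv(nr, nc);
  double buf[8];
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int n = 0;
      for (int dj = -1; dj <= 1; ++dj) {
        for (int di = -1; di <= 1; ++di) {
          if (di == 0 && dj == 0) continue;
          const int ii = i + di, jj = j + dj;
          if (ii < 0 || jj < 0 || ii >= nr || jj >= nc) continue;
          if (mask(ii, jj) != TRUE) continue;
          buf[n++] = x(ii, jj);
        }
      }
      nv(i, j) = n;
      if (n == 0) {
        med(i, j) = NA_REAL;
        scl(i, j) = NA_REAL;
        continue;
      }
      std::sort(buf, buf + n);
      const double m = (n % 2) ? buf[n / 2] : 0.5 * (buf[n / 2 - 1] + buf[n / 2]);
      for (int t = 0; t < n; ++t) buf[t] = std::fabs(buf[t] - m);
      std::sort(buf, buf + n);
      med(i, j) = m;
      scl(i, j) = (n % 2) ? buf[n / 2] : 0.5 * (buf[n / 2 - 1] + buf[n / 2]);
    }
  }
  return List::create(_["med"] = med, _["scale"] = scl, _["n"] = nv);
}

// 26-connected component labelling of a 3D logical mask (flood fill).
// Returns an integer array of labels (0 = background) with attribute "ncomp".
// [[Rcpp::export(name = ".label3d")]]
IntegerVector label3d(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = mask.size();
  IntegerVector lab(n, 0);
  std::vector<int> stack;
  int cur = 0;
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        const int id0 = i + nx * (j + ny * k);
        if (mask[id0] != TRUE || lab[id0]) continue;
        ++cur;
        lab[id0] = cur;
        stack.push_back(id0);
        while (!stack.empty()) {
          const int id = stack.back();
          stack.pop_back();
          const int ci = id % nx, cj = (id / nx) % ny, ck = id / (nx * ny);
          for (int dk = -1; dk <= 1; ++dk) {
            for (int dj = -1; dj <= 1; ++dj) {
              for (int di = -1; di <= 1; ++di) {
                if (di == 0 && dj == 0 && dk == 0) continue;
                const int ii = ci + di, jj = cj + dj, kk = ck + dk;
                if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
                const int id2 = ii + nx * (jj + ny * kk);
                if (mask[id2] == TRUE && !lab[id2]) {
                  lab[id2] = cur;
                  stack.push_back(id2);
                }
              }
            }
          }
        }
      }
    }
  }
  lab.attr("dim") = dims;
  lab.attr("ncomp") = cur;
  return lab;
}
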