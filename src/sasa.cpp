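#include <Rcpp.h>
using namespace Rcpp;

// Shrake-Rupley solvent-accessible surface area with a deterministic
// golden-section spiral point set.  radii are the atomic radii (probe not
// yet added).  Returns the per-atom accessible area in Angstrom^2.
// [[Rcpp::export(name = ".sasa_cpp")]]
NumericVector sasa_cpp(NumericMatrix coords, NumericVector radii,
                       double probe, int n_points) {
  const int n = coords.nrow();
  NumericVector out(n);
  std::vector<double> R(n);
  for (int i = 0; i < n; ++i) R[i] = radii[i] + probe;

  // golden spiral on the unit sphere
  std::vector<double> px(n_points), py(n_points), pz(n_points);
  const double ga = M_PI * (3.0 - std::sqrt(5.0));
  for (int k = 0; k < n_points; ++k) {
    double z = 1.0 - (2.0 * k + 1.0) / n_points;
    double s = std::sqrt(std::max(0.0, 1.0 - z * z));
    double phi = (k + 1.0) * ga;
    px[k] = std::cos(phi) * s;
    py[k] = std::sin(phi) * s;
    pz[k] = z;
  }

  std::vector<double> cx(n), cy(n), cz(n);
  for (int i = 0; i < n; ++i) {
    cx[i] = coords(i, 0); cy[i] = coords(i, 1); cz[i] = coords(i, 2);
  }
  std::vector<std::pair<double, int> > nb;
  nb.reserve(128);
  std::vector<double> qx(n_points), qy(n_points), qz(n_points);
  for (int i = 0; i < n; ++i) {
    // deterministic per-atom rotation of the point set decorrelates the
    // quadrature error across atoms, so totals converge much faster
    const double a = ga * (i + 1), b = 2.0 * ga * (i + 1);
    const double ca = std::cos(a), sa = std::sin(a);
    const double cb = std::cos(b), sb = std::sin(b);
    for (int k = 0; k < n_points; ++k) {
      const double x1 = ca * px[k] - sa * py[k];
      const double y1 = sa * px[k] + ca * py[k];
      const double z1 = pz[k];
      qx[k] = x1;
      qy[k] = cb * y1 - sb * z1;
      qz[k] = sb * y1 + cb * z1;
    }
    nb.clear();
    const double xi = cx[i], yi = cy[i], zi = cz[i];
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double dx = cx[j] - xi, dy = cy[j] - yi, dz = cz[j] - zi;
      const double lim = R[i] + R[j];
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < lim * lim - 1e-12) nb.push_back(std::make_pair(d2, j));
    }
    // closest neighbors first: buried points reject almost immediately
    std::sort(nb.begin(), nb.end());
    int acc = 0;
    for (int k = 0; k < n_points; ++k) {
      const double sx = xi + R[i] * qx[k], sy = yi + R[i] * qy[k],
                   sz = zi + R[i] * qz[k];
      bool free_pt = true;
      for (size_t m = 0; m < nb.size(); ++m) {
        const int j = nb[m].second;
        const double dx = sx - cx[j], dy = sy - cy[j], dz = sz - cz[j];
        if (dx * dx + dy * dy + dz * dz < R[j] * R[j] - 1e-12) {
          free_pt = false;
          break;
        }
      }
      if (free_pt) ++acc;
    }
    out[i] = 4.0 * M_PI * R[i] * R[i] * acc / n_points;
  }
  return out;
}
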