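#include <Rcpp.h>
using namespace Rcpp;

// Shrake-Rupley solvent-accessible surface area on a deterministic
// golden-spiral point set. For each atom, test points on the expanded
// sphere (radius + probe) are discarded when they fall inside any
// neighbouring expanded sphere; the surviving fraction times the sphere
// area is the atom's SASA.
// [[Rcpp::export(name = ".sasa_cpp")]]
NumericVector sasa_cpp(NumericMatrix xyz, NumericVector radius,
                       double probe, int n_points) {
  const int n = xyz.nrow();
  NumericVector out(n);
  if (n == 0) return out;

  // golden-spiral unit sphere points
  std::vector<double> px(n_points), py(n_points), pz(n_points);
  const double golden = M_PI * (3.0 - std::sqrt(5.0));
  for (int k = 0; k < n_points; ++k) {
    double zk = 1.0 - 2.0 * (k + 0.5) / n_points;
    double rk = std::sqrt(std::max(0.0, 1.0 - zk * zk));
    double th = golden * k;
    px[k] = rk * std::cos(th);
    py[k] = rk * std::sin(th);
    pz[k] = zk;
  }

  std::vector<double> R(n);
  for (int i = 0; i < n; ++i) R[i] = radius[i] + probe;

  std::vector<int> nb;
  for (int i = 0; i < n; ++i) {
    nb.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = xyz(j, 0) - xyz(i, 0);
      double dy = xyz(j, 1) - xyz(i, 1);
      double dz = xyz(j, 2) - xyz(i, 2);
      double cut = R[i] + R[j];
      if (dx * dx + dy * dy + dz * dz < cut * cut) nb.push_back(j);
    }
    int acc = 0;
    for (int k = 0; k < n_points; ++k) {
      double qx = xyz(i, 0) + R[i] * px[k];
      double qy = xyz(i, 1) + R[i] * py[k];
      double qz = xyz(i, 2) + R[i] * pz[k];
      bool buried = false;
      for (size_t m = 0; m < nb.size(); ++m) {
        int j = nb[m];
        double dx = qx - xyz(j, 0);
        double dy = qy - xyz(j, 1);
        double dz = qz - xyz(j, 2);
        double d2 = dx * dx + dy * dy + dz * dz;
        double R2 = R[j] * R[j];
        // strict burial, with a deterministic tie rule so that a point
        // exactly on a neighbour's surface (coincident duplicate atoms)
        // is assigned to the lower-index atom only
        if (d2 < R2 * (1.0 - 1e-12) ||
            (d2 < R2 * (1.0 + 1e-12) && j < i)) { buried = true; break; }
      }
      if (!buried) ++acc;
    }
    out[i] = 4.0 * M_PI * R[i] * R[i] * acc / n_points;
  }
  return out;
}
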