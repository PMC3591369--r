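#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Deterministic quasi-uniform points on the unit sphere (Fibonacci lattice).
static std::vector<double> fibonacci_sphere(int n) {
  std::vector<double> pts(3 * n);
  const double ga = M_PI * (3.0 - std::sqrt(5.0)); // golden angle
  for (int k = 0; k < n; ++k) {
    double z = 1.0 - (2.0 * k + 1.0) / n;
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    double th = ga * k;
    pts[3 * k]     = r * std::cos(th);
    pts[3 * k + 1] = r * std::sin(th);
    pts[3 * k + 2] = z;
  }
  return pts;
}

// Shrake-Rupley solvent accessible surface area, one value per atom (A^2).
// xyz: n x 3 heavy-atom coordinates, rad: vdW radii, probe in A,
// npts: sample points per atom.
// [[Rcpp::export]]
NumericVector sasa_shrake_rupley(NumericMatrix xyz, NumericVector rad,
                                 double probe, int npts) {
  int n = xyz.nrow();
  NumericVector out(n);
  if (n == 0) return out;
  std::vector<double> sph = fibonacci_sphere(npts);
  double rmax = 0.0;
  for (int i = 0; i < n; ++i) rmax = std::max(rmax, rad[i]);

  for (int i = 0; i < n; ++i) {
    double ri = rad[i] + probe;
    double xi = xyz(i, 0), yi = xyz(i, 1), zi = xyz(i, 2);
    // neighbours whose expanded sphere can occlude atom i's test sphere
    std::vector<int> nb;
    double reach = ri + rmax + probe;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = xyz(j, 0) - xi, dy = xyz(j, 1) - yi, dz = xyz(j, 2) - zi;
      if (dx * dx + dy * dy + dz * dz < reach * reach) nb.push_back(j);
    }
    int acc = 0;
    for (int k = 0; k < npts; ++k) {
      double px = xi + ri * sph[3 * k];
      double py = yi + ri * sph[3 * k + 1];
      double pz = zi + ri * sph[3 * k + 2];
      bool free_pt = true;
      for (size_t m = 0; m < nb.size(); ++m) {
        int j = nb[m];
        double rj = rad[j] + probe;
        double dx = px - xyz(j, 0), dy = py - xyz(j, 1), dz = pz - xyz(j, 2);
        if (dx * dx + dy * dy + dz * dz < rj * rj) { free_pt = false; break; }
      }
      if (free_pt) ++acc;
    }
    out[i] = 4.0 * M_PI * ri * ri * ((double) acc / npts);
  }
  return out;
}

// Protrusion index cx per atom: (V_empty / V_atoms) inside a sphere of
// radius R centred on the atom, volumes estimated on a uniform voxel grid
// of the given spacing centred on the atom.  V_atoms is the union volume
// of all heavy-atom spheres (including atom i) clipped to the R-sphere.
// Voxels are weighted with a linear antialiasing ramp one voxel wide at
// every sphere boundary, which removes the lattice-alignment bias of hard
// in/out counting on atom-sized spheres.
// [[Rcpp::export]]
NumericVector cx_protrusion(NumericMatrix xyz, NumericVector rad,
                            double R, double spacing) {
  int n = xyz.nrow();
  NumericVector out(n);
  if (n == 0) return out;
  int half = (int) std::floor(R / spacing) + 2;
  int dim = 2 * half + 1;
  size_t ncell = (size_t) dim * dim * dim;
  double rmax = 0.0;
  for (int i = 0; i < n; ++i) rmax = std::max(rmax, rad[i]);

  // membership weight of every cube voxel in the R-ball (grid centred on
  // the query atom), plus the reference sphere volume
  std::vector<double> gw(ncell, 0.0);
  double v_sphere = 0.0;
  for (int a = -half; a <= half; ++a)
    for (int b = -half; b <= half; ++b)
      for (int c = -half; c <= half; ++c) {
        double x = a * spacing, y = b * spacing, z = c * spacing;
        double d = std::sqrt(x * x + y * y + z * z);
        double w = (R - d) / spacing + 0.5;
        if (w <= 0.0) continue;
        if (w > 1.0) w = 1.0;
        gw[((size_t)(a + half) * dim + (b + half)) * dim + (c + half)] = w;
        v_sphere += w;
      }

  std::vector<double> wa(ncell);  // union membership, reused per atom
  for (int i = 0; i < n; ++i) {
    double xi = xyz(i, 0), yi = xyz(i, 1), zi = xyz(i, 2);
    std::fill(wa.begin(), wa.end(), 0.0);
    double reach = R + rmax + spacing;
    // scatter every neighbour sphere into the voxel cube
    for (int j = 0; j < n; ++j) {
      double ox = xyz(j, 0) - xi, oy = xyz(j, 1) - yi, oz = xyz(j, 2) - zi;
      if (ox * ox + oy * oy + oz * oz >= reach * reach) continue;
      double rj = rad[j];
      double rr = rj + spacing;
      int alo = std::max(-half, (int) std::floor((ox - rr) / spacing));
      int ahi = std::min(half, (int) std::ceil((ox + rr) / spacing));
      int blo = std::max(-half, (int) std::floor((oy - rr) / spacing));
      int bhi = std::min(half, (int) std::ceil((oy + rr) / spacing));
      int clo = std::max(-half, (int) std::floor((oz - rr) / spacing));
      int chi = std::min(half, (int) std::ceil((oz + rr) / spacing));
      for (int a = alo; a <= ahi; ++a) {
        double dx = a * spacing - ox;
        for (int b = blo; b <= bhi; ++b) {
          double dy = b * spacing - oy;
          size_t base = ((size_t)(a + half) * dim + (b + half)) * dim + half;
          for (int c = clo; c <= chi; ++c) {
            double dz = c * spacing - oz;
            double d = std::sqrt(dx * dx + dy * dy + dz * dz);
            double w = (rj - d) / spacing + 0.5;
            if (w <= 0.0) continue;
            if (w > 1.0) w = 1.0;
            size_t idx = base + c;
            if (w > wa[idx]) wa[idx] = w;
          }
        }
      }
    }
    double occ = 0.0;
    for (size_t g = 0; g < ncell; ++g)
      if (wa[g] > 0.0 && gw[g] > 0.0) occ += std::min(wa[g], gw[g]);
    out[i] = (v_sphere - occ) / occ;
  }
  return out;
}

// Minimum pairwise distance between two heavy-atom coordinate sets.
// [[Rcpp::export]]
double min_pair_distance(NumericMatrix a, NumericMatrix b) {
  double best = R_PosInf;
  for (int i = 0; i < a.nrow(); ++i)
    for (int j = 0; j < b.nrow(); ++j) {
      double dx = a(i, 0) - b(j, 0), dy = a(i, 1) - b(j, 1),
             dz = a(i, 2) - b(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
  return std::sqrt(best);
}

// True iff any inter-set atom pair is closer than the sum of its radii
// (strict inequality).
// [[Rcpp::export]]
bool any_vdw_clash(NumericMatrix a, NumericVector ra,
                   NumericMatrix b, NumericVector rb) {
  for (int i = 0; i < a.nrow(); ++i)
    for (int j = 0; j < b.nrow(); ++j) {
      double dx = a(i, 0) - b(j, 0), dy = a(i, 1) - b(j, 1),
             dz = a(i, 2) - b(j, 2);
      double s = ra[i] + rb[j];
      if (dx * dx + dy * dy + dz * dz < s * s) return true;
    }
  return false;
}

// Number of atoms of b within `cutoff` of each atom of a (inclusive bound).
// [[Rcpp::export]]
IntegerVector count_within(NumericMatrix a, NumericMatrix b, double cutoff) {
  IntegerVector out(a.nrow());
  double c2 = cutoff * cutoff;
  for (int i = 0; i < a.nrow(); ++i) {
    int k = 0;
    for (int j = 0; j < b.nrow(); ++j) {
      double dx = a(i, 0) - b(j, 0), dy = a(i, 1) - b(j, 1),
             dz = a(i, 2) - b(j, 2);
      if (dx * dx + dy * dy + dz * dz <= c2) ++k;
    }
    out[i] = k;
  }
  return out;
}
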