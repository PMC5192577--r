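#include <Rcpp.h>
#include <unordered_set>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Single-bead Metropolis dynamics of a chain on the cubic lattice with
// 26-neighbour connectivity. A move displaces one bead to one of its 26
// surrounding sites; it is accepted iff the site is empty (when
// self-avoidance is on), every bond incident to the bead (chain bonds and
// loop-closure bonds) stays within the 26-neighbourhood, and, for beads
// under spherical confinement, the bead stays inside its sphere. The
// proposal is symmetric, so the dynamics satisfy detailed balance with
// respect to the uniform measure on valid conformations.

static inline int64_t pack(int x, int y, int z) {
  const int64_t C = 1 << 20;
  return (((int64_t)(x + C)) << 42) | (((int64_t)(y + C)) << 21) |
         ((int64_t)(z + C));
}

static inline bool adjacent(int ax, int ay, int az, int bx, int by, int bz) {
  int dx = ax - bx, dy = ay - by, dz = az - bz;
  if (dx == 0 && dy == 0 && dz == 0) return false;
  return dx >= -1 && dx <= 1 && dy >= -1 && dy <= 1 && dz >= -1 && dz <= 1;
}

// In addition to single-bead moves, a tail-regrowth move resamples one
// chain bond (uniformly among the 26 offsets) at a cut position where no
// loop-closure bond and no confinement sphere spans the cut, rigidly
// translating the downstream part of the chain. The proposal is symmetric
// and greatly accelerates the relaxation of long linear stretches.

// [[Rcpp::export]]
List cpp_mc_run(IntegerMatrix coords, IntegerMatrix edges, double n_moves,
                bool self_avoiding, IntegerVector conf_group,
                NumericMatrix conf_center, NumericVector conf_radius,
                IntegerVector cut_candidates, double p_tail) {
  int n = coords.nrow();
  std::vector<int> X(n), Y(n), Z(n);
  for (int i = 0; i < n; ++i) {
    X[i] = coords(i, 0); Y[i] = coords(i, 1); Z[i] = coords(i, 2);
  }
  // adjacency lists of bonded partners
  std::vector<std::vector<int>> nb(n);
  for (int e = 0; e < edges.nrow(); ++e) {
    int a = edges(e, 0), b = edges(e, 1);
    nb[a].push_back(b);
    nb[b].push_back(a);
  }
  std::unordered_set<int64_t> occ;
  if (self_avoiding) {
    occ.reserve(2 * n);
    for (int i = 0; i < n; ++i) occ.insert(pack(X[i], Y[i], Z[i]));
    if ((int)occ.size() != n) stop("initial conformation has site collisions");
  }
  // 26 neighbour offsets
  int OX[26], OY[26], OZ[26], m = 0;
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        OX[m] = dx; OY[m] = dy; OZ[m] = dz; ++m;
      }
  RNGScope scope;
  double accepted = 0, attempted = 0;
  int64_t total = (int64_t)n_moves;
  int n_cuts = cut_candidates.size();
  for (int64_t step = 0; step < total; ++step) {
    if (n_cuts > 0 && unif_rand() < p_tail) {
      // tail-regrowth move: resample the bond after bead `c`
      ++attempted;
      int c = cut_candidates[(int)(unif_rand() * n_cuts) % n_cuts];
      int o = (int)(unif_rand() * 26);
      if (o >= 26) o = 25;
      int dx = X[c] + OX[o] - X[c + 1], dy = Y[c] + OY[o] - Y[c + 1],
          dz = Z[c] + OZ[o] - Z[c + 1];
      if (dx == 0 && dy == 0 && dz == 0) continue;
      bool ok = true;
      if (self_avoiding) {
        // head occupancy = all sites minus the tail's current sites
        for (int j = c + 1; j < n; ++j)
          occ.erase(pack(X[j], Y[j], Z[j]));
        for (int j = c + 1; j < n && ok; ++j)
          if (occ.count(pack(X[j] + dx, Y[j] + dy, Z[j] + dz))) ok = false;
        if (!ok) {  // restore
          for (int j = c + 1; j < n; ++j)
            occ.insert(pack(X[j], Y[j], Z[j]));
          continue;
        }
      }
      for (int j = c + 1; j < n; ++j) {
        X[j] += dx; Y[j] += dy; Z[j] += dz;
        if (self_avoiding) occ.insert(pack(X[j], Y[j], Z[j]));
      }
      ++accepted;
      continue;
    }
    int i = (int)(unif_rand() * n);
    if (i >= n) i = n - 1;
    int o = (int)(unif_rand() * 26);
    if (o >= 26) o = 25;
    ++attempted;
    int nx = X[i] + OX[o], ny = Y[i] + OY[o], nz = Z[i] + OZ[o];
    bool ok = true;
    for (size_t k = 0; k < nb[i].size() && ok; ++k) {
      int j = nb[i][k];
      if (!adjacent(nx, ny, nz, X[j], Y[j], Z[j])) ok = false;
    }
    if (ok && conf_group[i] >= 0) {
      int g = conf_group[i];
      double ddx = nx - conf_center(g, 0), ddy = ny - conf_center(g, 1),
             ddz = nz - conf_center(g, 2);
      double r = conf_radius[g];
      if (ddx * ddx + ddy * ddy + ddz * ddz > r * r) ok = false;
    }
    if (ok && self_avoiding) {
      if (occ.count(pack(nx, ny, nz))) ok = false;
    }
    if (!ok) continue;
    if (self_avoiding) {
      occ.erase(pack(X[i], Y[i], Z[i]));
      occ.insert(pack(nx, ny, nz));
    }
    X[i] = nx; Y[i] = ny; Z[i] = nz;
    ++accepted;
  }
  IntegerMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = X[i]; out(i, 1) = Y[i]; out(i, 2) = Z[i];
  }
  return List::create(_["coords"] = out, _["accepted"] = accepted,
                      _["attempted"] = attempted);
}

// Count, per genomic bin pair, the number of conformations in which any
// bead pair of the two bins lies within the capture radius (Euclidean, in
// lattice units). `bin` is a 0-based bin index per bead.
// [[Rcpp::export]]
IntegerMatrix cpp_contact_counts(List conformations, IntegerVector bin,
                                 int n_bins, double capture_radius) {
  int n = bin.size();
  double r2 = capture_radius * capture_radius;
  IntegerMatrix counts(n_bins, n_bins);
  std::vector<char> hit((size_t)n_bins * n_bins);
  for (int c = 0; c < conformations.size(); ++c) {
    IntegerMatrix xyz = conformations[c];
    if (xyz.nrow() != n) stop("bead/bin length mismatch");
    std::fill(hit.begin(), hit.end(), 0);
    for (int i = 0; i < n; ++i) {
      for (int j = i; j < n; ++j) {
        double dx = xyz(i, 0) - xyz(j, 0), dy = xyz(i, 1) - xyz(j, 1),
               dz = xyz(i, 2) - xyz(j, 2);
        if (dx * dx + dy * dy + dz * dz <= r2) {
          hit[(size_t)bin[i] * n_bins + bin[j]] = 1;
          hit[(size_t)bin[j] * n_bins + bin[i]] = 1;
        }
      }
    }
    for (int a = 0; a < n_bins; ++a)
      for (int b = 0; b < n_bins; ++b)
        counts(a, b) += hit[(size_t)a * n_bins + b];
  }
  return counts;
}
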