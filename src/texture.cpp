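// Sliding-window GLCM texture-map engine and small image utilities.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
using namespace Rcpp;

// Nine Haralick features of a normalised symmetric GLCM held in `p`
// (ng x ng, column-major). Order: energy, entropy, sum average,
// correlation, IDMN, contrast, cluster shade, cluster prominence,
// Haralick correlation.
static void glcm_features(const std::vector<double>& p, int ng, double* out) {
  std::vector<double> px(ng, 0.0), py(ng, 0.0);
  double energy = 0.0, entropy = 0.0;
  for (int j = 0; j < ng; ++j) {
    for (int i = 0; i < ng; ++i) {
      double v = p[i + j * ng];
      energy += v * v;
      if (v > 0.0) entropy -= v * std::log2(v);
      px[i] += v;
      py[j] += v;
    }
  }
  double mux = 0.0, muy = 0.0;
  for (int i = 0; i < ng; ++i) {
    mux += (i + 1) * px[i];
    muy += (i + 1) * py[i];
  }
  double sx2 = 0.0, sy2 = 0.0;
  for (int i = 0; i < ng; ++i) {
    sx2 += (i + 1 - mux) * (i + 1 - mux) * px[i];
    sy2 += (i + 1 - muy) * (i + 1 - muy) * py[i];
  }
  double sxsy = std::sqrt(sx2) * std::sqrt(sy2);
  double sumavg = 0.0, corr = 0.0, idmn = 0.0, contrast = 0.0;
  double shade = 0.0, prom = 0.0, hsum = 0.0;
  for (int j = 0; j < ng; ++j) {
    for (int i = 0; i < ng; ++i) {
      double v = p[i + j * ng];
      if (v == 0.0) continue;
      double ii = i + 1, jj = j + 1;
      sumavg += (ii + jj) * v;
      corr += (ii - mux) * (jj - muy) * v;
      double dn = (ii - jj) / ng;
      idmn += v / (1.0 + dn * dn);
      contrast += (ii - jj) * (ii - jj) * v;
      double c = ii + jj - mux - muy;
      shade += c * c * c * v;
      prom += c * c * c * c * v;
      hsum += ii * jj * v;
    }
  }
  out[0] = energy;
  out[1] = entropy;
  out[2] = sumavg;
  out[3] = (sxsy > 1e-12) ? corr / sxsy : 0.0;
  out[4] = idmn;
  out[5] = contrast;
  out[6] = shade;
  out[7] = prom;
  out[8] = (sxsy > 1e-12) ? (hsum - mux * muy) / sxsy : 0.0;
}

// Per-voxel sliding-window texture maps.
// levels: 3D integer array (0 = unquantised/outside), target: logical array
// of voxels to evaluate, window: odd in-plane size, offsets: n x 2 (di, dj).
// Returns features (n_target x 9) and a valid flag per target voxel.
// [[Rcpp::export]]
List cpp_texture_maps(IntegerVector levels, LogicalVector target,
                      int window, IntegerMatrix offsets, int ng) {
  IntegerVector dims = levels.attr("dim");
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int hw = window / 2;
  std::vector<int> tx, ty, tz;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i)
        if (target[i + j * nx + k * nx * ny]) {
          tx.push_back(i); ty.push_back(j); tz.push_back(k);
        }
  int n = tx.size();
  NumericMatrix feats(n, 9);
  LogicalVector valid(n);
  IntegerVector idx(n);
  std::vector<double> counts(ng * ng), p(ng * ng);
  int noff = offsets.nrow();
  for (int t = 0; t < n; ++t) {
    int ci = tx[t], cj = ty[t], ck = tz[t];
    idx[t] = ci + cj * nx + ck * nx * ny + 1;  // 1-based linear index
    int i0 = std::max(0, ci - hw), i1 = std::min(nx - 1, ci + hw);
    int j0 = std::max(0, cj - hw), j1 = std::min(ny - 1, cj + hw);
    std::fill(counts.begin(), counts.end(), 0.0);
    double total = 0.0;
    const int base = ck * nx * ny;
    for (int o = 0; o < noff; ++o) {
      int di = offsets(o, 0), dj = offsets(o, 1);
      for (int j = j0; j <= j1; ++j) {
        int j2 = j + dj;
        if (j2 < j0 || j2 > j1) continue;
        for (int i = i0; i <= i1; ++i) {
          int i2 = i + di;
          if (i2 < i0 || i2 > i1) continue;
          int la = levels[i + j * nx + base];
          int lb = levels[i2 + j2 * nx + base];
          if (la > 0 && lb > 0) {
            counts[(la - 1) + (lb - 1) * ng] += 1.0;
            counts[(lb - 1) + (la - 1) * ng] += 1.0;
            total += 2.0;
          }
        }
      }
    }
    if (total == 0.0) {
      valid[t] = false;
      for (int f = 0; f < 9; ++f) feats(t, f) = NA_REAL;
      continue;
    }
    for (int c = 0; c < ng * ng; ++c) p[c] = counts[c] / total;
    double out[9];
    glcm_features(p, ng, out);
    for (int f = 0; f < 9; ++f) feats(t, f) = out[f];
    valid[t] = true;
  }
  return List::create(_["features"] = feats, _["valid"] = valid,
                      _["idx"] = idx);
}

// 6-connected component labelling of a binary 3D array.
// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerVector mask) {
  IntegerVector dims = mask.attr("dim");
  int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector lab(mask.size());
  lab.attr("dim") = dims;
  int next = 0;
  std::queue<int> q;
  const int dx[6] = {1, -1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, 1, -1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, 1, -1};
  for (int s = 0; s < mask.size(); ++s) {
    if (mask[s] == 0 || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    q.push(s);
    while (!q.empty()) {
      int cur = q.front(); q.pop();
      int i = cur % nx, j = (cur / nx) % ny, k = cur / (nx * ny);
      for (int d = 0; d < 6; ++d) {
        int i2 = i + dx[d], j2 = j + dy[d], k2 = k + dz[d];
        if (i2 < 0 || i2 >= nx || j2 < 0 || j2 >= ny || k2 < 0 || k2 >= nz)
          continue;
        int s2 = i2 + j2 * nx + k2 * nx * ny;
        if (mask[s2] != 0 && lab[s2] == 0) {
          lab[s2] = next;
          q.push(s2);
        }
      }
    }
  }
  return lab;
}
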