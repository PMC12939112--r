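#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Index helpers for column-major 3D arrays (R layout).
static inline R_xlen_t idx3(int i, int j, int k, int nx, int ny) {
  return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * (R_xlen_t)k);
}

// Reflect index into [0, n-1].
static inline int reflect(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// Separable Gaussian blur; sigma given per axis in voxel units.
// [[Rcpp::export]]
NumericVector cpp_gauss_blur3(NumericVector vol, IntegerVector dim,
                              NumericVector sigma_vox) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector cur = clone(vol);
  NumericVector nxt(vol.size());
  int n_ax[3] = {nx, ny, nz};
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma_vox[ax];
    if (s <= 1e-8) continue;
    int half = std::max(1, (int)std::ceil(3.0 * s));
    std::vector<double> ker(2 * half + 1);
    double sum = 0.0;
    for (int t = -half; t <= half; ++t) {
      ker[t + half] = std::exp(-0.5 * t * t / (s * s));
      sum += ker[t + half];
    }
    for (double &v : ker) v /= sum;
    int n = n_ax[ax];
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          double acc = 0.0;
          for (int t = -half; t <= half; ++t) {
            int ii = i, jj = j, kk = k;
            if (ax == 0) ii = reflect(i + t, n);
            else if (ax == 1) jj = reflect(j + t, n);
            else kk = reflect(k + t, n);
            acc += ker[t + half] * cur[idx3(ii, jj, kk, nx, ny)];
          }
          nxt[idx3(i, j, k, nx, ny)] = acc;
        }
    std::swap(cur, nxt);
  }
  cur.attr("dim") = dim;
  return cur;
}

// Eigenvalues of a symmetric 3x3 matrix (analytic, ascending by value).
static void sym3_eigenvalues(double a11, double a22, double a33,
                             double a12, double a13, double a23,
                             double ev[3]) {
  double p1 = a12 * a12 + a13 * a13 + a23 * a23;
  if (p1 < 1e-30) {
    ev[0] = a11; ev[1] = a22; ev[2] = a33;
  } else {
    double q = (a11 + a22 + a33) / 3.0;
    double b11 = a11 - q, b22 = a22 - q, b33 = a33 - q;
    double p2 = b11 * b11 + b22 * b22 + b33 * b33 + 2.0 * p1;
    double p = std::sqrt(p2 / 6.0);
    // r = det(B/p)/2, clamped for acos
    double c11 = b11 / p, c22 = b22 / p, c33 = b33 / p;
    double c12 = a12 / p, c13 = a13 / p, c23 = a23 / p;
    double detB = c11 * (c22 * c33 - c23 * c23)
                - c12 * (c12 * c33 - c23 * c13)
                + c13 * (c12 * c23 - c22 * c13);
    double r = detB / 2.0;
    r = std::max(-1.0, std::min(1.0, r));
    double phi = std::acos(r) / 3.0;
    ev[2] = q + 2.0 * p * std::cos(phi);
    ev[0] = q + 2.0 * p * std::cos(phi + 2.0 * M_PI / 3.0);
    ev[1] = 3.0 * q - ev[0] - ev[2];
  }
  if (ev[0] > ev[1]) std::swap(ev[0], ev[1]);
  if (ev[1] > ev[2]) std::swap(ev[1], ev[2]);
  if (ev[0] > ev[1]) std::swap(ev[0], ev[1]);
}

// Eigenvector for eigenvalue lam of symmetric 3x3 via cross products.
static void sym3_eigenvector(double a11, double a22, double a33,
                             double a12, double a13, double a23,
                             double lam, double v[3]) {
  double r0[3] = {a11 - lam, a12, a13};
  double r1[3] = {a12, a22 - lam, a23};
  double r2[3] = {a13, a23, a33 - lam};
  double c01[3] = {r0[1] * r1[2] - r0[2] * r1[1],
                   r0[2] * r1[0] - r0[0] * r1[2],
                   r0[0] * r1[1] - r0[1] * r1[0]};
  double c02[3] = {r0[1] * r2[2] - r0[2] * r2[1],
                   r0[2] * r2[0] - r0[0] * r2[2],
                   r0[0] * r2[1] - r0[1] * r2[0]};
  double c12[3] = {r1[1] * r2[2] - r1[2] * r2[1],
                   r1[2] * r2[0] - r1[0] * r2[2],
                   r1[0] * r2[1] - r1[1] * r2[0]};
  double n01 = c01[0]*c01[0] + c01[1]*c01[1] + c01[2]*c01[2];
  double n02 = c02[0]*c02[0] + c02[1]*c02[1] + c02[2]*c02[2];
  double n12 = c12[0]*c12[0] + c12[1]*c12[1] + c12[2]*c12[2];
  double *best = c01; double nb = n01;
  if (n02 > nb) { best = c02; nb = n02; }
  if (n12 > nb) { best = c12; nb = n12; }
  if (nb < 1e-30) { v[0] = 0; v[1] = 0; v[2] = 1; return; }
  double inv = 1.0 / std::sqrt(nb);
  v[0] = best[0] * inv; v[1] = best[1] * inv; v[2] = best[2] * inv;
}

// Frangi bright-tube vesselness from Hessian components, plus the tube
// axis (eigenvector of the smallest-magnitude eigenvalue).
// [[Rcpp::export]]
List cpp_frangi(NumericVector hxx, NumericVector hyy, NumericVector hzz,
                NumericVector hxy, NumericVector hxz, NumericVector hyz,
                double alpha, double beta, double cpar) {
  R_xlen_t n = hxx.size();
  NumericVector resp(n), ox(n), oy(n), oz(n);
  double c2 = 2.0 * cpar * cpar;
  double a2 = 2.0 * alpha * alpha;
  double b2 = 2.0 * beta * beta;
  for (R_xlen_t v = 0; v < n; ++v) {
    double ev[3];
    sym3_eigenvalues(hxx[v], hyy[v], hzz[v], hxy[v], hxz[v], hyz[v], ev);
    // sort by |lambda|: l1 smallest magnitude
    double l[3] = {ev[0], ev[1], ev[2]};
    // simple |.| insertion sort of 3
    if (std::fabs(l[0]) > std::fabs(l[1])) std::swap(l[0], l[1]);
    if (std::fabs(l[1]) > std::fabs(l[2])) std::swap(l[1], l[2]);
    if (std::fabs(l[0]) > std::fabs(l[1])) std::swap(l[0], l[1]);
    double l1 = l[0], l2 = l[1], l3 = l[2];
    if (l2 >= 0.0 || l3 >= 0.0) { resp[v] = 0.0; continue; } // dark or plate-up
    double Ra = std::fabs(l2) / std::fabs(l3);
    double Rb = std::fabs(l1) / std::sqrt(std::fabs(l2 * l3));
    double S2 = l1 * l1 + l2 * l2 + l3 * l3;
    double val = (1.0 - std::exp(-(Ra * Ra) / a2))
               * std::exp(-(Rb * Rb) / b2)
               * (1.0 - std::exp(-S2 / c2));
    resp[v] = val;
    if (val > 0.0) {
      double vec[3];
      sym3_eigenvector(hxx[v], hyy[v], hzz[v], hxy[v], hxz[v], hyz[v], l1, vec);
      ox[v] = vec[0]; oy[v] = vec[1]; oz[v] = vec[2];
    }
  }
  return List::create(_["response"] = resp, _["ox"] = ox,
                      _["oy"] = oy, _["oz"] = oz);
}

// Connected-component labeling (6- or 26-connectivity), BFS.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = mask.size();
  IntegerVector lab(n, 0);
  std::vector<std::array<int,3>> nbr;
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        if (di == 0 && dj == 0 && dk == 0) continue;
        int man = std::abs(di) + std::abs(dj) + std::abs(dk);
        if (connectivity == 6 && man != 1) continue;
        nbr.push_back({di, dj, dk});
      }
  int next_lab = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next_lab;
    lab[s] = next_lab;
    q.push(s);
    while (!q.empty()) {
      R_xlen_t cur = q.front(); q.pop();
      int i = cur % nx, j = (cur / nx) % ny, k = cur / ((R_xlen_t)nx * ny);
      for (auto &d : nbr) {
        int ii = i + d[0], jj = j + d[1], kk = k + d[2];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
          continue;
        R_xlen_t t = idx3(ii, jj, kk, nx, ny);
        if (mask[t] && lab[t] == 0) { lab[t] = next_lab; q.push(t); }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// BFS region growing from a seed with per-wave leakage guard: if one wave
// multiplies the accumulated volume by more than leak_factor (after a
// burn-in), growth stops and leaked = TRUE.
// [[Rcpp::export]]
List cpp_region_grow(LogicalVector mask, IntegerVector dim, int seed0,
                     double leak_factor, int burn_in) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = mask.size();
  LogicalVector out(n, false);
  bool leaked = false;
  if (seed0 < 0 || seed0 >= n || !mask[seed0]) {
    out.attr("dim") = dim;
    return List::create(_["region"] = out, _["leaked"] = false,
                        _["n_voxels"] = 0);
  }
  std::vector<R_xlen_t> frontier = {(R_xlen_t)seed0};
  out[seed0] = true;
  R_xlen_t total = 1;
  int wave = 0;
  const int d6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  while (!frontier.empty()) {
    ++wave;
    std::vector<R_xlen_t> nextf;
    for (R_xlen_t cur : frontier) {
      int i = cur % nx, j = (cur / nx) % ny, k = cur / ((R_xlen_t)nx * ny);
      for (auto &d : d6) {
        int ii = i + d[0], jj = j + d[1], kk = k + d[2];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
          continue;
        R_xlen_t t = idx3(ii, jj, kk, nx, ny);
        if (mask[t] && !out[t]) { out[t] = true; nextf.push_back(t); }
      }
    }
    if (wave > burn_in && total > 0 &&
        (double)(total + (R_xlen_t)nextf.size()) > leak_factor * (double)total) {
      leaked = true;
      for (R_xlen_t t : nextf) out[t] = false;
      break;
    }
    total += nextf.size();
    frontier.swap(nextf);
  }
  out.attr("dim") = dim;
  return List::create(_["region"] = out, _["leaked"] = leaked,
                      _["n_voxels"] = (double)total);
}

// Binary dilation (or erosion via complement outside) with an ellipsoidal
// structuring element given by per-axis radius in voxels.
// [[Rcpp::export]]
LogicalVector cpp_binary_dilate(LogicalVector mask, IntegerVector dim,
                                NumericVector rad_vox) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int rx = (int)std::floor(rad_vox[0]), ry = (int)std::floor(rad_vox[1]),
      rz = (int)std::floor(rad_vox[2]);
  std::vector<std::array<int,3>> se;
  for (int dk = -rz; dk <= rz; ++dk)
    for (int dj = -ry; dj <= ry; ++dj)
      for (int di = -rx; di <= rx; ++di) {
        double q = 0.0;
        if (rad_vox[0] > 0) q += (double)di * di / (rad_vox[0] * rad_vox[0]);
        else if (di != 0) continue;
        if (rad_vox[1] > 0) q += (double)dj * dj / (rad_vox[1] * rad_vox[1]);
        else if (dj != 0) continue;
        if (rad_vox[2] > 0) q += (double)dk * dk / (rad_vox[2] * rad_vox[2]);
        else if (dk != 0) continue;
        if (q <= 1.0 + 1e-9) se.push_back({di, dj, dk});
      }
  LogicalVector out(mask.size(), false);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        if (!mask[idx3(i, j, k, nx, ny)]) continue;
        for (auto &d : se) {
          int ii = i + d[0], jj = j + d[1], kk = k + d[2];
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
            continue;
          out[idx3(ii, jj, kk, nx, ny)] = true;
        }
      }
  out.attr("dim") = dim;
  return out;
}

// 26-neighbourhood local maxima of a scalar field above a threshold.
// [[Rcpp::export]]
LogicalVector cpp_local_maxima(NumericVector f, IntegerVector dim,
                               double thresh) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  LogicalVector out(f.size(), false);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double v = f[idx3(i, j, k, nx, ny)];
        if (v < thresh) continue;
        bool is_max = true;
        for (int dk = -1; dk <= 1 && is_max; ++dk)
          for (int dj = -1; dj <= 1 && is_max; ++dj)
            for (int di = -1; di <= 1 && is_max; ++di) {
              if (di == 0 && dj == 0 && dk == 0) continue;
              int ii = i + di, jj = j + dj, kk = k + dk;
              if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
                continue;
              if (f[idx3(ii, jj, kk, nx, ny)] > v) is_max = false;
            }
        if (is_max) out[idx3(i, j, k, nx, ny)] = true;
      }
  out.attr("dim") = dim;
  return out;
}

// Paint a tube of varying radius along a polyline into a volume.
// points: m x 3 world mm; radii length m; value replaces voxel if the voxel
// centre lies within the local radius (hard profile with 1-voxel smooth rim
// handled on the R side via supersampling not needed for phantoms).
// [[Rcpp::export]]
void cpp_paint_tube(NumericVector vol, IntegerVector dim,
                    NumericVector spacing, NumericVector origin,
                    NumericMatrix points, NumericVector radii,
                    double value) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int m = points.nrow();
  for (int s = 0; s + 1 < m; ++s) {
    double p0[3] = {points(s,0), points(s,1), points(s,2)};
    double p1[3] = {points(s+1,0), points(s+1,1), points(s+1,2)};
    double r = std::max(radii[s], radii[s+1]);
    double lo[3], hi[3];
    for (int a = 0; a < 3; ++a) {
      lo[a] = std::min(p0[a], p1[a]) - r - spacing[a];
      hi[a] = std::max(p0[a], p1[a]) + r + spacing[a];
    }
    int i0 = std::max(0, (int)std::floor((lo[0] - origin[0]) / spacing[0]));
    int i1 = std::min(nx - 1, (int)std::ceil((hi[0] - origin[0]) / spacing[0]));
    int j0 = std::max(0, (int)std::floor((lo[1] - origin[1]) / spacing[1]));
    int j1 = std::min(ny - 1, (int)std::ceil((hi[1] - origin[1]) / spacing[1]));
    int k0 = std::max(0, (int)std::floor((lo[2] - origin[2]) / spacing[2]));
    int k1 = std::min(nz - 1, (int)std::ceil((hi[2] - origin[2]) / spacing[2]));
    double d[3] = {p1[0]-p0[0], p1[1]-p0[1], p1[2]-p0[2]};
    double len2 = d[0]*d[0] + d[1]*d[1] + d[2]*d[2];
    for (int k = k0; k <= k1; ++k)
      for (int j = j0; j <= j1; ++j)
        for (int i = i0; i <= i1; ++i) {
          double w[3] = {origin[0] + i * spacing[0],
                         origin[1] + j * spacing[1],
                         origin[2] + k * spacing[2]};
          double t = 0.0;
          if (len2 > 1e-20) {
            t = ((w[0]-p0[0])*d[0] + (w[1]-p0[1])*d[1] + (w[2]-p0[2])*d[2]) / len2;
            t = std::max(0.0, std::min(1.0, t));
          }
          double rloc = radii[s] + t * (radii[s+1] - radii[s]);
          double dx = w[0] - (p0[0] + t * d[0]);
          double dy = w[1] - (p0[1] + t * d[1]);
          double dz = w[2] - (p0[2] + t * d[2]);
          if (dx*dx + dy*dy + dz*dz <= rloc * rloc)
            vol[idx3(i, j, k, nx, ny)] = value;
        }
  }
}

// ---- artery/vein integer program ----
// Objective (maximize): sum_{u<v} W(u,v) * [x_u != x_v]
//                     + sum_u (ua[u] * x_u + uv[u] * (1 - x_u)),  x_u in {0,1}
// x = 1 means artery.

static double av_objective(const std::vector<int> &x, const NumericMatrix &W,
                           const NumericVector &ua, const NumericVector &uv) {
  int n = x.size();
  double obj = 0.0;
  for (int u = 0; u < n; ++u) {
    obj += x[u] ? ua[u] : uv[u];
    for (int v = u + 1; v < n; ++v)
      if (x[u] != x[v]) obj += W(u, v);
  }
  return obj;
}

// Plain exhaustive enumeration (oracle path; first-found optimum in the
// branch order: unit 0 tries prefer0 first, later units try artery first).
// [[Rcpp::export]]
List cpp_av_enumerate(NumericMatrix W, NumericVector ua, NumericVector uv,
                      int prefer0) {
  int n = ua.size();
  if (n > 26) stop("enumeration limited to 26 units");
  std::vector<int> x(n), best(n);
  double best_obj = -1e300;
  long m = 1L << n;
  for (long code = 0; code < m; ++code) {
    for (int u = 0; u < n; ++u) {
      // unit 0 is the most significant digit so ties resolve in the same
      // order as the branch-and-bound's depth-first exploration
      int bit = (code >> (n - 1 - u)) & 1L;
      int first = (u == 0) ? prefer0 : 1;
      x[u] = bit ? (1 - first) : first;
    }
    double obj = av_objective(x, W, ua, uv);
    if (obj > best_obj + 1e-12) { best_obj = obj; best = x; }
  }
  return List::create(_["labels"] = IntegerVector(best.begin(), best.end()),
                      _["objective"] = best_obj);
}

// Depth-first branch and bound with an optimistic bound on the remaining
// units (each undecided unit takes its better unary plus all its undecided
// and cut-able pairwise weight). Deterministic: explores unit 0's preferred
// label first, artery first for the rest, keeps the first incumbent at any
// given objective (strict improvement required).
struct AvBB {
  const NumericMatrix &W;
  const NumericVector &ua, &uv;
  int n, prefer0;
  std::vector<int> x, best;
  double best_obj;
  std::vector<double> opt_tail; // optimistic value of units >= u
  AvBB(const NumericMatrix &W_, const NumericVector &ua_,
       const NumericVector &uv_, int prefer0_)
    : W(W_), ua(ua_), uv(uv_), n(ua_.size()), prefer0(prefer0_),
      x(n, 0), best(n, 0), best_obj(-1e300), opt_tail(n + 1, 0.0) {
    for (int u = n - 1; u >= 0; --u) {
      double m = std::max(ua[u], uv[u]);
      double wsum = 0.0;
      for (int v = 0; v < n; ++v) if (v != u) wsum += W(std::min(u,v), std::max(u,v));
      opt_tail[u] = opt_tail[u + 1] + m + wsum; // pairwise counted twice max; still a valid upper add-on
    }
  }
  void rec(int u, double acc) {
    if (u == n) {
      if (acc > best_obj + 1e-12) { best_obj = acc; best = x; }
      return;
    }
    if (acc + opt_tail[u] <= best_obj + 1e-12) return;
    int first = (u == 0) ? prefer0 : 1;
    for (int trial = 0; trial < 2; ++trial) {
      int lab = trial == 0 ? first : 1 - first;
      x[u] = lab;
      double add = lab ? ua[u] : uv[u];
      for (int v = 0; v < u; ++v)
        if (x[v] != lab) add += W(std::min(u,v), std::max(u,v));
      rec(u + 1, acc + add);
    }
  }
};

// [[Rcpp::export]]
List cpp_av_branch_bound(NumericMatrix W, NumericVector ua, NumericVector uv,
                         int prefer0) {
  AvBB bb(W, ua, uv, prefer0);
  bb.rec(0, 0.0);
  return List::create(
    _["labels"] = IntegerVector(bb.best.begin(), bb.best.end()),
    _["objective"] = bb.best_obj);
}

// Greedy + local-flip fallback for large problems.
// [[Rcpp::export]]
List cpp_av_greedy(NumericMatrix W, NumericVector ua, NumericVector uv,
                   int prefer0, int max_sweeps) {
  int n = ua.size();
  std::vector<int> x(n);
  for (int u = 0; u < n; ++u) x[u] = (u == 0) ? prefer0 : (ua[u] >= uv[u] ? 1 : 0);
  bool improved = true;
  int sweep = 0;
  while (improved && sweep < max_sweeps) {
    improved = false; ++sweep;
    for (int u = 0; u < n; ++u) {
      double gain = (x[u] ? uv[u] - ua[u] : ua[u] - uv[u]);
      for (int v = 0; v < n; ++v) {
        if (v == u) continue;
        double w = W(std::min(u,v), std::max(u,v));
        gain += (x[u] != x[v]) ? -w : w; // flipping toggles the cut state
      }
      if (gain > 1e-12) { x[u] = 1 - x[u]; improved = true; }
    }
  }
  return List::create(_["labels"] = IntegerVector(x.begin(), x.end()),
                      _["objective"] = av_objective(x, W, ua, uv));
}
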