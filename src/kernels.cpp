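#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Squared Euclidean distance transform (Felzenszwalb & Huttenlocher),
// separable, spacing-aware. Distances are between voxel centers, in mm^2.
// Foreground voxels with no background anywhere get BIG (caller maps to Inf).
// ---------------------------------------------------------------------------

static const double BIG = 1e30;

static void dt1d(std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &z,
                 int n, double h) {
  int k = 0;
  v[0] = 0;
  z[0] = -BIG;
  z[1] = BIG;
  for (int q = 1; q < n; q++) {
    double fq = f[q] + (q * h) * (q * h);
    double s = 0.0;
    bool dominated = false;
    while (true) {
      int p = v[k];
      s = (fq - (f[p] + (p * h) * (p * h))) / (2.0 * h * (q - p));
      if (s <= z[k]) {
        if (k == 0) {  // parabola q undercuts the whole envelope
          dominated = true;
          break;
        }
        k--;
      } else {
        break;
      }
    }
    if (dominated) {
      v[0] = q;
      z[1] = BIG;
      continue;
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = BIG;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q * h) k++;
    double dx = (q - v[k]) * h;
    d[q] = dx * dx + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dim,
                         NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++) out[i] = mask[i] ? BIG : 0.0;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++) {
      R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
      for (int i = 0; i < nx; i++) f[i] = out[base + i];
      dt1d(f, d, v, z, nx, spacing[0]);
      for (int i = 0; i < nx; i++) out[base + i] = d[i];
    }
  // pass along y
  for (int k = 0; k < nz; k++)
    for (int i = 0; i < nx; i++) {
      R_xlen_t base = i + (R_xlen_t)nx * ny * k;
      for (int j = 0; j < ny; j++) f[j] = out[base + (R_xlen_t)nx * j];
      dt1d(f, d, v, z, ny, spacing[1]);
      for (int j = 0; j < ny; j++) out[base + (R_xlen_t)nx * j] = d[j];
    }
  // pass along z
  for (int j = 0; j < ny; j++)
    for (int i = 0; i < nx; i++) {
      R_xlen_t base = i + (R_xlen_t)nx * j;
      R_xlen_t stride = (R_xlen_t)nx * ny;
      for (int k = 0; k < nz; k++) f[k] = out[base + stride * k];
      dt1d(f, d, v, z, nz, spacing[2]);
      for (int k = 0; k < nz; k++) out[base + stride * k] = d[k];
    }
  return out;
}

// ---------------------------------------------------------------------------
// Local thickness by sphere painting. d2 is the squared distance map of the
// mask (cpp_edt_sq). Centers are processed in order of decreasing d2 (ties
// broken by linear index); a center c paints 2*sqrt(d2[c]) into every
// foreground voxel whose center-to-center distance satisfies dist^2 <= d2[c]
// and whose current value is smaller. Exactly the exhaustive definition.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_local_thickness(NumericVector d2, IntegerVector dim,
                                  NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double hx = spacing[0], hy = spacing[1], hz = spacing[2];
  NumericVector out(n);

  std::vector<R_xlen_t> fg;
  fg.reserve(1024);
  for (R_xlen_t i = 0; i < n; i++)
    if (d2[i] > 0) fg.push_back(i);

  std::stable_sort(fg.begin(), fg.end(), [&](R_xlen_t a, R_xlen_t b) {
    return d2[a] > d2[b];
  });

  for (size_t s = 0; s < fg.size(); s++) {
    R_xlen_t c = fg[s];
    double r2 = d2[c];
    double val = 2.0 * std::sqrt(r2);
    int cx = (int)(c % nx);
    int cy = (int)((c / nx) % ny);
    int cz = (int)(c / ((R_xlen_t)nx * ny));
    double r = std::sqrt(r2);
    int rx = (int)std::floor(r / hx), ry = (int)std::floor(r / hy),
        rz = (int)std::floor(r / hz);
    int x0 = std::max(0, cx - rx), x1 = std::min(nx - 1, cx + rx);
    int y0 = std::max(0, cy - ry), y1 = std::min(ny - 1, cy + ry);
    int z0 = std::max(0, cz - rz), z1 = std::min(nz - 1, cz + rz);
    for (int z = z0; z <= z1; z++) {
      double tz = (z - cz) * hz;
      tz *= tz;
      for (int y = y0; y <= y1; y++) {
        double ty = (y - cy) * hy;
        ty *= ty;
        R_xlen_t base = (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
        for (int x = x0; x <= x1; x++) {
          double tx = (x - cx) * hx;
          tx *= tx;
          double dist2 = (tx + ty) + tz;
          R_xlen_t p = base + x;
          if (dist2 <= r2 && d2[p] > 0 && out[p] < val) out[p] = val;
        }
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Topology-preserving 3D curve thinning.
// A voxel is deletable when it is a border point in the current direction,
// not a curve endpoint (>=2 foreground 26-neighbors), and a simple point in
// the sense of Bertrand & Malandain: exactly one 26-connected foreground
// component in the punctured 3x3x3 neighborhood, and exactly one 6-connected
// background component within the 18-neighborhood that touches a face
// neighbor. Six directional sub-iterations (U,D,N,S,E,W order), sequential
// deletion with recheck, repeated to convergence. Deterministic.
// ---------------------------------------------------------------------------

static int off27[27][3];
static bool adj26[27][27];
static bool adj6[27][27];
static bool inN18[27];
static bool faceNb[27];
static bool tables_ready = false;

static void init_tables() {
  if (tables_ready) return;
  int t = 0;
  for (int dz = -1; dz <= 1; dz++)
    for (int dy = -1; dy <= 1; dy++)
      for (int dx = -1; dx <= 1; dx++) {
        off27[t][0] = dx;
        off27[t][1] = dy;
        off27[t][2] = dz;
        int l1 = std::abs(dx) + std::abs(dy) + std::abs(dz);
        inN18[t] = (l1 >= 1 && l1 <= 2);
        faceNb[t] = (l1 == 1);
        t++;
      }
  for (int a = 0; a < 27; a++)
    for (int b = 0; b < 27; b++) {
      int dx = std::abs(off27[a][0] - off27[b][0]);
      int dy = std::abs(off27[a][1] - off27[b][1]);
      int dz = std::abs(off27[a][2] - off27[b][2]);
      adj26[a][b] = (a != b) && dx <= 1 && dy <= 1 && dz <= 1;
      adj6[a][b] = (dx + dy + dz == 1);
    }
  tables_ready = true;
}

// neighborhood nb[27] of foreground flags (center index 13)
static bool is_simple(const bool nb[27]) {
  // condition A: one 26-component of foreground in punctured neighborhood
  int comp = 0;
  bool seen[27] = {false};
  int stack[27];
  for (int i = 0; i < 27; i++) {
    if (i == 13 || !nb[i] || seen[i]) continue;
    comp++;
    if (comp > 1) return false;
    int sp = 0;
    stack[sp++] = i;
    seen[i] = true;
    while (sp) {
      int cur = stack[--sp];
      for (int j = 0; j < 27; j++)
        if (j != 13 && nb[j] && !seen[j] && adj26[cur][j]) {
          seen[j] = true;
          stack[sp++] = j;
        }
    }
  }
  if (comp != 1) return false;
  // condition B: one 6-component of background in N18 touching a face neighbor
  comp = 0;
  bool seenb[27] = {false};
  for (int i = 0; i < 27; i++) {
    if (!inN18[i] || nb[i] || seenb[i]) continue;
    int sp = 0;
    stack[sp++] = i;
    seenb[i] = true;
    bool touches = faceNb[i];
    while (sp) {
      int cur = stack[--sp];
      for (int j = 0; j < 27; j++)
        if (inN18[j] && !nb[j] && !seenb[j] && adj6[cur][j]) {
          seenb[j] = true;
          if (faceNb[j]) touches = true;
          stack[sp++] = j;
        }
    }
    if (touches) {
      comp++;
      if (comp > 1) return false;
    }
  }
  return comp == 1;
}

// [[Rcpp::export]]
LogicalVector cpp_skeletonize(LogicalVector mask, IntegerVector dim) {
  init_tables();
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int px = nx + 2, py = ny + 2, pz = nz + 2;
  std::vector<unsigned char> img((size_t)px * py * pz, 0);
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++)
        img[(size_t)(i + 1) + (size_t)px * ((j + 1) + (size_t)py * (k + 1))] =
            mask[(R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] ? 1 : 0;

  auto at = [&](int x, int y, int z) -> unsigned char & {
    return img[(size_t)x + (size_t)px * ((size_t)y + (size_t)py * z)];
  };
  auto gather = [&](int x, int y, int z, bool nb[27]) {
    int t = 0;
    for (int dz = -1; dz <= 1; dz++)
      for (int dy = -1; dy <= 1; dy++)
        for (int dx = -1; dx <= 1; dx++)
          nb[t++] = at(x + dx, y + dy, z + dz) != 0;
  };
  auto n26count = [&](const bool nb[27]) {
    int c = 0;
    for (int i = 0; i < 27; i++)
      if (i != 13 && nb[i]) c++;
    return c;
  };

  // direction offsets: U(+z), D(-z), N(+y), S(-y), E(+x), W(-x)
  const int dirs[6][3] = {{0, 0, 1}, {0, 0, -1}, {0, 1, 0},
                          {0, -1, 0}, {1, 0, 0}, {-1, 0, 0}};

  std::vector<size_t> cand;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; d++) {
      cand.clear();
      for (int z = 1; z <= nz; z++)
        for (int y = 1; y <= ny; y++)
          for (int x = 1; x <= nx; x++) {
            if (!at(x, y, z)) continue;
            if (at(x + dirs[d][0], y + dirs[d][1], z + dirs[d][2])) continue;
            bool nb[27];
            gather(x, y, z, nb);
            int cnt = n26count(nb);
            if (cnt < 2) continue;  // endpoint or isolated: keep
            if (is_simple(nb))
              cand.push_back((size_t)x + (size_t)px * ((size_t)y + (size_t)py * z));
          }
      for (size_t idx : cand) {
        int x = (int)(idx % px);
        int y = (int)((idx / px) % py);
        int z = (int)(idx / ((size_t)px * py));
        bool nb[27];
        gather(x, y, z, nb);
        int cnt = n26count(nb);
        if (cnt < 2) continue;
        if (!is_simple(nb)) continue;
        img[idx] = 0;
        changed = true;
      }
    }
  }

  LogicalVector out((R_xlen_t)nx * ny * nz);
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++)
        out[(R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] =
            at(i + 1, j + 1, k + 1) != 0;
  return out;
}

// ---------------------------------------------------------------------------
// Paint a tube (capsule around a polyline) into an integer label volume.
// Voxel centers are at origin + (index + 0.5) * spacing (0-based indices).
// Only empty (0) voxels are painted, so caller-controlled paint order is the
// overlap policy. Membership: squared distance to the polyline <= r^2.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
void cpp_paint_tube(IntegerVector labels, IntegerVector dim,
                    NumericVector spacing, NumericVector origin,
                    NumericMatrix pts, double radius, int label) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double r2 = radius * radius;
  const int nseg = pts.nrow() - 1;
  for (int s = 0; s < std::max(nseg, 1); s++) {
    double ax = pts(s, 0), ay = pts(s, 1), az = pts(s, 2);
    int e = (nseg >= 1) ? s + 1 : s;
    double bx = pts(e, 0), by = pts(e, 1), bz = pts(e, 2);
    double lo[3] = {std::min(ax, bx) - radius, std::min(ay, by) - radius,
                    std::min(az, bz) - radius};
    double hi[3] = {std::max(ax, bx) + radius, std::max(ay, by) + radius,
                    std::max(az, bz) + radius};
    int i0[3], i1[3];
    const int dmax[3] = {nx, ny, nz};
    for (int a = 0; a < 3; a++) {
      i0[a] = std::max(0, (int)std::floor((lo[a] - origin[a]) / spacing[a] - 0.5));
      i1[a] = std::min(dmax[a] - 1,
                       (int)std::ceil((hi[a] - origin[a]) / spacing[a] - 0.5));
    }
    double ux = bx - ax, uy = by - ay, uz = bz - az;
    double L2 = ux * ux + uy * uy + uz * uz;
    for (int z = i0[2]; z <= i1[2]; z++) {
      double pz_ = origin[2] + (z + 0.5) * spacing[2];
      for (int y = i0[1]; y <= i1[1]; y++) {
        double py_ = origin[1] + (y + 0.5) * spacing[1];
        R_xlen_t base = (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
        for (int x = i0[0]; x <= i1[0]; x++) {
          R_xlen_t p = base + x;
          if (labels[p] != 0) continue;
          double px_ = origin[0] + (x + 0.5) * spacing[0];
          double wx = px_ - ax, wy = py_ - ay, wz = pz_ - az;
          double t = 0.0;
          if (L2 > 0) {
            t = (wx * ux + wy * uy + wz * uz) / L2;
            t = std::max(0.0, std::min(1.0, t));
          }
          double dx = wx - t * ux, dy = wy - t * uy, dz = wz - t * uz;
          if (dx * dx + dy * dy + dz * dz <= r2) labels[p] = label;
        }
      }
    }
  }
}

// ---------------------------------------------------------------------------
// Exact two-sided permutation p-value for the Spearman rank correlation
// (n <= 10): enumerate distinct arrangements of the y ranks and count those
// with |rho| >= |rho_obs| (within fp tolerance).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
double cpp_spearman_exact_p(NumericVector rx, NumericVector ry) {
  int n = rx.size();
  std::vector<double> y(ry.begin(), ry.end());
  std::sort(y.begin(), y.end());

  double mx = 0, my = 0;
  for (int i = 0; i < n; i++) {
    mx += rx[i];
    my += ry[i];
  }
  mx /= n;
  my /= n;
  double sxx = 0, syy = 0, sxy = 0;
  for (int i = 0; i < n; i++) {
    sxx += (rx[i] - mx) * (rx[i] - mx);
    syy += (ry[i] - my) * (ry[i] - my);
    sxy += (rx[i] - mx) * (ry[i] - my);
  }
  double denom = std::sqrt(sxx * syy);
  double robs = std::fabs(sxy / denom);

  double count = 0, total = 0;
  do {
    double s = 0;
    for (int i = 0; i < n; i++) s += (rx[i] - mx) * (y[i] - my);
    if (std::fabs(s / denom) >= robs - 1e-12) count += 1;
    total += 1;
  } while (std::next_permutation(y.begin(), y.end()));
  return count / total;
}
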