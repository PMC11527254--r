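#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Flat index helpers for column-major 3D arrays (R layout).
static inline R_xlen_t idx3(int x, int y, int z, int nx, int ny) {
  return (R_xlen_t)x + (R_xlen_t)nx * ((R_xlen_t)y + (R_xlen_t)ny * z);
}

// 3D connected-component labelling by flood fill.
// mask: logical vector (length nx*ny*nz), connectivity in {6, 18, 26}.
// Returns integer labels in first-found order; 0 = background.
// [[Rcpp::export]]
IntegerVector cc_label_cpp(LogicalVector mask, IntegerVector dim, int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");
  std::vector<int> ox, oy, oz;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int man = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (man == 0) continue;
        if ((connectivity == 6 && man > 1) || (connectivity == 18 && man > 2))
          continue;
        ox.push_back(dx); oy.push_back(dy); oz.push_back(dz);
      }
  const int nn = (int)ox.size();
  IntegerVector lab(mask.size(), 0);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t i = idx3(x, y, z, nx, ny);
        if (!mask[i] || lab[i] != 0) continue;
        ++next;
        lab[i] = next;
        stack.clear();
        stack.push_back(i);
        while (!stack.empty()) {
          R_xlen_t cur = stack.back(); stack.pop_back();
          int cz = (int)(cur / ((R_xlen_t)nx * ny));
          R_xlen_t rem = cur - (R_xlen_t)cz * nx * ny;
          int cy = (int)(rem / nx);
          int cx = (int)(rem - (R_xlen_t)cy * nx);
          for (int k = 0; k < nn; ++k) {
            int qx = cx + ox[k], qy = cy + oy[k], qz = cz + oz[k];
            if (qx < 0 || qy < 0 || qz < 0 || qx >= nx || qy >= ny || qz >= nz)
              continue;
            R_xlen_t q = idx3(qx, qy, qz, nx, ny);
            if (mask[q] && lab[q] == 0) { lab[q] = next; stack.push_back(q); }
          }
        }
      }
  return lab;
}

// sliding-window extremum (window [i-w, i+w], clipped at the borders) via a
// monotonic deque; minimize=true gives the running min, else max
static void slide_extremum(const double* in, double* out, int n, int w,
                           bool minimize) {
  std::vector<int> dq(n);
  int head = 0, tail = 0, next_push = 0;  // dq[head..tail): candidate indices
  for (int i = 0; i < n; ++i) {
    int hi = std::min(i + w, n - 1);
    for (; next_push <= hi; ++next_push) {
      double v = in[next_push];
      while (tail > head &&
             (minimize ? in[dq[tail - 1]] >= v : in[dq[tail - 1]] <= v))
        --tail;
      dq[tail++] = next_push;
    }
    while (head < tail && dq[head] < i - w) ++head;
    out[i] = in[dq[head]];
  }
}

// Grayscale opening (erosion then dilation) with a flat disk of given pixel
// radius, applied independently to each z-slice. Out-of-bounds pixels are
// ignored (treated as +Inf for erosion, -Inf for dilation), so a flat slice
// is reproduced exactly. The disk is decomposed into horizontal runs: for
// each row offset dy the run half-width is floor(sqrt(r^2-dy^2)); each
// distinct half-width is handled by one 1D sliding-extremum pass.
// [[Rcpp::export]]
NumericVector open_disk_cpp(NumericVector vol, IntegerVector dim, int radius) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  if (radius < 1) stop("radius must be >= 1");
  std::vector<int> halfw(radius + 1);
  for (int dy = 0; dy <= radius; ++dy)
    halfw[dy] = (int)std::floor(std::sqrt((double)radius * radius - (double)dy * dy));
  std::vector<int> widths(halfw);  // distinct run half-widths
  std::sort(widths.begin(), widths.end());
  widths.erase(std::unique(widths.begin(), widths.end()), widths.end());
  const size_t np = (size_t)nx * ny;
  NumericVector out(vol.size());
  // rowfilt[w-index] holds the slice row-filtered with half-width w
  std::vector<std::vector<double>> rowfilt(widths.size(),
                                           std::vector<double>(np));
  std::vector<double> stage(np);

  auto pass = [&](const double* src, double* dst, bool minimize) {
    // 1) row filtering for each distinct half-width
    for (size_t wi = 0; wi < widths.size(); ++wi)
      for (int y = 0; y < ny; ++y)
        slide_extremum(src + (size_t)nx * y,
                       rowfilt[wi].data() + (size_t)nx * y, nx, widths[wi],
                       minimize);
    // 2) combine across row offsets dy with the matching run width
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        double m = minimize ? R_PosInf : R_NegInf;
        for (int dy = -radius; dy <= radius; ++dy) {
          int qy = y + dy;
          if (qy < 0 || qy >= ny) continue;
          int w = halfw[std::abs(dy)];
          size_t wi = std::lower_bound(widths.begin(), widths.end(), w) -
                      widths.begin();
          double v = rowfilt[wi][(size_t)x + (size_t)nx * qy];
          if (minimize ? (v < m) : (v > m)) m = v;
        }
        dst[(size_t)x + (size_t)nx * y] = m;
      }
  };

  std::vector<double> slice(np), eroded(np);
  for (int z = 0; z < nz; ++z) {
    const R_xlen_t base = (R_xlen_t)np * z;
    for (size_t i = 0; i < np; ++i) slice[i] = vol[base + i];
    pass(slice.data(), eroded.data(), true);
    pass(eroded.data(), stage.data(), false);
    for (size_t i = 0; i < np; ++i) out[base + i] = stage[i];
  }
  return out;
}

// Random walks with momentum from a source region into a target region,
// marking 1-voxel-wide curvilinear fiber paths until `budget` voxels inside
// the target are fiber-marked. Uses R's RNG so results are reproducible
// under set.seed(). Indices in src_idx are 1-based; masks are full-lattice.
// [[Rcpp::export]]
LogicalVector fiber_walk_cpp(LogicalVector fiber, IntegerVector dim,
                             IntegerVector src_idx, LogicalVector tgt,
                             LogicalVector brain, int budget,
                             double persistence, int max_steps,
                             int max_walks, NumericVector tgt_centroid) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  if (budget <= 0 || src_idx.size() == 0) return fiber;
  int hit = 0;
  for (R_xlen_t i = 0; i < fiber.size(); ++i)
    if (fiber[i] && tgt[i]) ++hit;
  double tc[3] = {tgt_centroid[0], tgt_centroid[1], tgt_centroid[2]};
  for (int walk = 0; walk < max_walks && hit < budget; ++walk) {
    R_xlen_t s0 = src_idx[(int)(unif_rand() * src_idx.size())] - 1;
    double pos[3];
    pos[2] = (double)(s0 / ((R_xlen_t)nx * ny));
    R_xlen_t rem = s0 - (R_xlen_t)pos[2] * nx * ny;
    pos[1] = (double)(rem / nx);
    pos[0] = (double)(rem - (R_xlen_t)pos[1] * nx);
    double dir[3], nrm = 0;
    for (int a = 0; a < 3; ++a) { dir[a] = tc[a] - pos[a]; nrm += dir[a] * dir[a]; }
    nrm = std::sqrt(std::max(nrm, 1e-18));
    for (int a = 0; a < 3; ++a) dir[a] /= nrm;
    for (int step = 0; step < max_steps && hit < budget; ++step) {
      double rnd[3], rn = 0;
      for (int a = 0; a < 3; ++a) { rnd[a] = norm_rand(); rn += rnd[a] * rnd[a]; }
      rn = std::sqrt(std::max(rn, 1e-18));
      for (int a = 0; a < 3; ++a) rnd[a] /= rn;
      double pull[3], pn = 0;
      for (int a = 0; a < 3; ++a) { pull[a] = tc[a] - pos[a]; pn += pull[a] * pull[a]; }
      pn = std::sqrt(std::max(pn, 1e-18));
      for (int a = 0; a < 3; ++a) pull[a] /= pn;
      double dn = 0;
      bool in_tgt_prev = false;
      {
        int vx = (int)std::lround(pos[0]), vy = (int)std::lround(pos[1]),
            vz = (int)std::lround(pos[2]);
        if (vx >= 0 && vy >= 0 && vz >= 0 && vx < nx && vy < ny && vz < nz)
          in_tgt_prev = tgt[idx3(vx, vy, vz, nx, ny)];
      }
      for (int a = 0; a < 3; ++a) {
        // inside the target wander freely; outside, drift toward it
        double steer = in_tgt_prev ? rnd[a] : (0.5 * rnd[a] + 0.5 * pull[a]);
        dir[a] = persistence * dir[a] + (1 - persistence) * steer;
        dn += dir[a] * dir[a];
      }
      dn = std::sqrt(std::max(dn, 1e-18));
      for (int a = 0; a < 3; ++a) { dir[a] /= dn; pos[a] += dir[a]; }
      int vx = (int)std::lround(pos[0]), vy = (int)std::lround(pos[1]),
          vz = (int)std::lround(pos[2]);
      if (vx < 0 || vy < 0 || vz < 0 || vx >= nx || vy >= ny || vz >= nz) break;
      R_xlen_t vi = idx3(vx, vy, vz, nx, ny);
      if (!brain[vi]) break;
      if (!fiber[vi]) {
        fiber[vi] = true;
        if (tgt[vi]) ++hit;
      }
    }
  }
  return fiber;
}

// 1D convolution along one axis (0=x, 1=y, 2=z) with zero padding.
// kernel has odd length; its centre aligns with the output voxel.
// [[Rcpp::export]]
NumericVector convolve_axis_cpp(NumericVector vol, IntegerVector dim,
                                NumericVector kernel, int axis) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int kl = kernel.size();
  if (kl % 2 == 0) stop("kernel length must be odd");
  const int kr = kl / 2;
  NumericVector out(vol.size());
  const int n[3] = {nx, ny, nz};
  const int na = n[axis];
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int pos[3] = {x, y, z};
        double acc = 0.0;
        for (int k = -kr; k <= kr; ++k) {
          int p = pos[axis] + k;
          if (p < 0 || p >= na) continue;
          int q[3] = {x, y, z};
          q[axis] = p;
          acc += kernel[k + kr] * vol[idx3(q[0], q[1], q[2], nx, ny)];
        }
        out[idx3(x, y, z, nx, ny)] = acc;
      }
  return out;
}

// Resample src onto a target lattice. For each 0-based target index v the
// continuous 0-based source index is s = M %*% v + off (M column-major 3x3).
// nearest=1 rounds to the nearest voxel; otherwise trilinear interpolation.
// Out-of-bounds samples are 0.
// [[Rcpp::export]]
NumericVector affine_resample_cpp(NumericVector src, IntegerVector sdim,
                                  NumericVector M, NumericVector off,
                                  IntegerVector tdim, int nearest) {
  const int sx = sdim[0], sy = sdim[1], sz = sdim[2];
  const int tx = tdim[0], ty = tdim[1], tz = tdim[2];
  NumericVector out((R_xlen_t)tx * ty * tz);
  for (int z = 0; z < tz; ++z)
    for (int y = 0; y < ty; ++y)
      for (int x = 0; x < tx; ++x) {
        double u = M[0] * x + M[3] * y + M[6] * z + off[0];
        double v = M[1] * x + M[4] * y + M[7] * z + off[1];
        double w = M[2] * x + M[5] * y + M[8] * z + off[2];
        double val = 0.0;
        if (nearest) {
          int iu = (int)std::lround(u), iv = (int)std::lround(v), iw = (int)std::lround(w);
          if (iu >= 0 && iv >= 0 && iw >= 0 && iu < sx && iv < sy && iw < sz)
            val = src[idx3(iu, iv, iw, sx, sy)];
        } else {
          int fu = (int)std::floor(u), fv = (int)std::floor(v), fw = (int)std::floor(w);
          double du = u - fu, dv = v - fv, dw = w - fw;
          for (int a = 0; a <= 1; ++a)
            for (int b = 0; b <= 1; ++b)
              for (int c = 0; c <= 1; ++c) {
                int qx = fu + a, qy = fv + b, qz = fw + c;
                double wt = (a ? du : 1 - du) * (b ? dv : 1 - dv) * (c ? dw : 1 - dw);
                if (wt == 0.0) continue;
                double s = 0.0;
                if (qx >= 0 && qy >= 0 && qz >= 0 && qx < sx && qy < sy && qz < sz)
                  s = src[idx3(qx, qy, qz, sx, sy)];
                val += wt * s;
              }
        }
        out[idx3(x, y, z, tx, ty)] = val;
      }
  return out;
}
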