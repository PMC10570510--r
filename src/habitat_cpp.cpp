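#include <Rcpp.h>
#include <cmath>
#include <queue>
#include <vector>
using namespace Rcpp;

// SLIC oversegmentation of a single axial slice restricted to a mask.
// feats: nx x ny x nc array flattened column-major (values expected in [0,1]);
// mask:  nx x ny logical; nCenters: target superpixel count;
// compactness m weights the spatial term: D^2 = dc^2 + m^2 * (ds/S)^2.
// Fully deterministic: grid initialisation, fixed iteration count, scan-order
// tie-breaking.  Returns integer labels, 0 outside the mask, 1..S inside.
// [[Rcpp::export]]
IntegerMatrix cpp_slic_slice(NumericVector feats, LogicalMatrix mask,
                             int nCenters, double compactness, int maxIter) {
  IntegerVector dims = feats.attr("dim");
  const int nx = dims[0], ny = dims[1], nc = dims[2];
  IntegerMatrix labels(nx, ny);

  std::vector<int> mx, my;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i)
      if (mask(i, j)) { mx.push_back(i); my.push_back(j); }
  const int nmask = (int)mx.size();
  if (nmask == 0) return labels;
  if (nCenters < 1) nCenters = 1;
  if (nCenters > nmask) nCenters = nmask;

  const double S = std::max(1.0, std::sqrt((double)nmask / (double)nCenters));
  const double m = compactness;

  // grid-initialised centers, snapped into the mask
  std::vector<double> cx, cy;
  std::vector<std::vector<double> > cf;
  int x0 = nx, x1 = -1, y0 = ny, y1 = -1;
  for (int p = 0; p < nmask; ++p) {
    if (mx[p] < x0) x0 = mx[p];
    if (mx[p] > x1) x1 = mx[p];
    if (my[p] < y0) y0 = my[p];
    if (my[p] > y1) y1 = my[p];
  }
  for (double gy = y0 + S / 2.0; gy <= y1 + S / 2.0; gy += S) {
    for (double gx = x0 + S / 2.0; gx <= x1 + S / 2.0; gx += S) {
      // nearest mask pixel within a window of S around the grid point
      int best = -1; double bestd = R_PosInf;
      int lx0 = std::max(0, (int)std::floor(gx - S)),
          lx1 = std::min(nx - 1, (int)std::ceil(gx + S)),
          ly0 = std::max(0, (int)std::floor(gy - S)),
          ly1 = std::min(ny - 1, (int)std::ceil(gy + S));
      for (int j = ly0; j <= ly1; ++j)
        for (int i = lx0; i <= lx1; ++i)
          if (mask(i, j)) {
            double d = (i - gx) * (i - gx) + (j - gy) * (j - gy);
            if (d < bestd) { bestd = d; best = i + j * nx; }
          }
      if (best >= 0) {
        int bi = best % nx, bj = best / nx;
        bool dup = false;
        for (size_t k = 0; k < cx.size(); ++k)
          if ((int)cx[k] == bi && (int)cy[k] == bj) { dup = true; break; }
        if (!dup) {
          cx.push_back(bi); cy.push_back(bj);
          std::vector<double> f(nc);
          for (int c = 0; c < nc; ++c) f[c] = feats[bi + bj * nx + c * nx * ny];
          cf.push_back(f);
        }
      }
    }
  }
  if (cx.empty()) { // tiny mask: single center at first mask pixel
    cx.push_back(mx[0]); cy.push_back(my[0]);
    std::vector<double> f(nc);
    for (int c = 0; c < nc; ++c) f[c] = feats[mx[0] + my[0] * nx + c * nx * ny];
    cf.push_back(f);
  }
  int K = (int)cx.size();

  std::vector<int> assign(nmask, -1);
  std::vector<int> pixIndex(nx * ny, -1);
  for (int p = 0; p < nmask; ++p) pixIndex[mx[p] + my[p] * nx] = p;

  for (int iter = 0; iter < maxIter; ++iter) {
    std::vector<double> bestD(nmask, R_PosInf);
    for (int k = 0; k < K; ++k) {
      int lx0 = std::max(0, (int)std::floor(cx[k] - 2 * S)),
          lx1 = std::min(nx - 1, (int)std::ceil(cx[k] + 2 * S)),
          ly0 = std::max(0, (int)std::floor(cy[k] - 2 * S)),
          ly1 = std::min(ny - 1, (int)std::ceil(cy[k] + 2 * S));
      for (int j = ly0; j <= ly1; ++j)
        for (int i = lx0; i <= lx1; ++i) {
          int p = pixIndex[i + j * nx];
          if (p < 0) continue;
          double dc2 = 0.0;
          for (int c = 0; c < nc; ++c) {
            double d = feats[i + j * nx + c * nx * ny] - cf[k][c];
            dc2 += d * d;
          }
          double dsx = i - cx[k], dsy = j - cy[k];
          double D = dc2 + m * m * (dsx * dsx + dsy * dsy) / (S * S);
          if (D < bestD[p]) { bestD[p] = D; assign[p] = k; }
        }
    }
    // orphans outside every 2S window: nearest center spatially
    for (int p = 0; p < nmask; ++p)
      if (assign[p] < 0) {
        double bd = R_PosInf; int bk = 0;
        for (int k = 0; k < K; ++k) {
          double d = (mx[p] - cx[k]) * (mx[p] - cx[k]) +
                     (my[p] - cy[k]) * (my[p] - cy[k]);
          if (d < bd) { bd = d; bk = k; }
        }
        assign[p] = bk;
      }
    // update centers
    std::vector<double> sx(K, 0.0), sy(K, 0.0);
    std::vector<int> cnt(K, 0);
    std::vector<std::vector<double> > sf(K, std::vector<double>(nc, 0.0));
    for (int p = 0; p < nmask; ++p) {
      int k = assign[p];
      sx[k] += mx[p]; sy[k] += my[p]; ++cnt[k];
      for (int c = 0; c < nc; ++c)
        sf[k][c] += feats[mx[p] + my[p] * nx + c * nx * ny];
    }
    for (int k = 0; k < K; ++k)
      if (cnt[k] > 0) {
        cx[k] = sx[k] / cnt[k]; cy[k] = sy[k] / cnt[k];
        for (int c = 0; c < nc; ++c) cf[k][c] = sf[k][c] / cnt[k];
      }
  }

  // connectivity enforcement: 4-connected components; components smaller than
  // minSize are merged into the first adjacent larger component encountered.
  std::vector<int> comp(nmask, -1);
  int nComp = 0;
  std::vector<int> compSize, compLabel;
  const int dxs[4] = { 1, -1, 0, 0 }, dys[4] = { 0, 0, 1, -1 };
  for (int p = 0; p < nmask; ++p) {
    if (comp[p] >= 0) continue;
    std::queue<int> q; q.push(p); comp[p] = nComp;
    int sz = 0;
    while (!q.empty()) {
      int u = q.front(); q.pop(); ++sz;
      int ux = mx[u], uy = my[u];
      for (int d = 0; d < 4; ++d) {
        int vx = ux + dxs[d], vy = uy + dys[d];
        if (vx < 0 || vx >= nx || vy < 0 || vy >= ny) continue;
        int v = pixIndex[vx + vy * nx];
        if (v < 0 || comp[v] >= 0 || assign[v] != assign[u]) continue;
        comp[v] = nComp; q.push(v);
      }
    }
    compSize.push_back(sz);
    compLabel.push_back(assign[p]);
    ++nComp;
  }
  int minSize = std::max(1, (int)(S * S / 2.0));
  // per-component mean feature vector for colour-aware fragment merging
  std::vector<std::vector<double> > compMean(nComp, std::vector<double>(nc, 0.0));
  for (int p = 0; p < nmask; ++p)
    for (int c = 0; c < nc; ++c)
      compMean[comp[p]][c] += feats[mx[p] + my[p] * nx + c * nx * ny];
  for (int cpt = 0; cpt < nComp; ++cpt)
    for (int c = 0; c < nc; ++c) compMean[cpt][c] /= compSize[cpt];
  std::vector<int> remap(nComp);
  for (int c = 0; c < nComp; ++c) remap[c] = c;
  for (int p = 0; p < nmask; ++p) {
    int c = comp[p];
    if (remap[c] != c || compSize[c] >= minSize) continue;
    // merge the fragment into the adjacent big component closest in colour
    int bestC = -1; double bestD = R_PosInf;
    for (int q = 0; q < nmask; ++q) {
      if (comp[q] != c) continue;
      for (int d = 0; d < 4; ++d) {
        int vx = mx[q] + dxs[d], vy = my[q] + dys[d];
        if (vx < 0 || vx >= nx || vy < 0 || vy >= ny) continue;
        int v = pixIndex[vx + vy * nx];
        if (v < 0) continue;
        int cv = comp[v];
        while (remap[cv] != cv) cv = remap[cv];
        if (cv == c || compSize[cv] < minSize) continue;
        double dd = 0.0;
        for (int ch = 0; ch < nc; ++ch) {
          double df = compMean[c][ch] - compMean[cv][ch];
          dd += df * df;
        }
        if (dd < bestD) { bestD = dd; bestC = cv; }
      }
    }
    if (bestC >= 0) remap[c] = bestC;
  }
  // resolve chains; components that found no big neighbour keep themselves
  for (int c = 0; c < nComp; ++c) {
    int r = c;
    while (remap[r] != r) r = remap[r];
    remap[c] = r;
  }
  // contiguous final labels in scan order
  std::vector<int> finalLab(nComp, 0);
  int next = 0;
  for (int p = 0; p < nmask; ++p) {
    int r = remap[comp[p]];
    if (finalLab[r] == 0) finalLab[r] = ++next;
    labels(mx[p], my[p]) = finalLab[r];
  }
  return labels;
}

// Local Shannon entropy (bits) of the intensity histogram in a disk
// neighbourhood, one axial slice.  img in [0,1]; neighbourhood is
// {(dx,dy): dx^2+dy^2 <= radius^2} clipped at the slice border and,
// when a mask is supplied, restricted to in-mask pixels (texture of the
// lung ROI must not be polluted by the chest-wall edge).  Masked-out
// pixels get entropy 0.
// [[Rcpp::export]]
NumericMatrix cpp_local_entropy(NumericMatrix img, double radius, int nbins,
                                Nullable<LogicalMatrix> maskOpt = R_NilValue) {
  const int nx = img.nrow(), ny = img.ncol();
  const bool hasMask = maskOpt.isNotNull();
  LogicalMatrix mask = hasMask ? LogicalMatrix(maskOpt)
                               : LogicalMatrix(0, 0);
  const int r = (int)std::floor(radius);
  NumericMatrix out(nx, ny);
  // precompute offsets
  std::vector<int> ox, oy;
  for (int dy = -r; dy <= r; ++dy)
    for (int dx = -r; dx <= r; ++dx)
      if (dx * dx + dy * dy <= radius * radius) { ox.push_back(dx); oy.push_back(dy); }
  const int noff = (int)ox.size();
  // bin image
  IntegerMatrix bin(nx, ny);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      int b = (int)std::floor(img(i, j) * nbins);
      if (b >= nbins) b = nbins - 1;
      if (b < 0) b = 0;
      bin(i, j) = b;
    }
  std::vector<int> hist(nbins);
  const double log2e = 1.0 / std::log(2.0);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      if (hasMask && !mask(i, j)) { out(i, j) = 0.0; continue; }
      std::fill(hist.begin(), hist.end(), 0);
      int n = 0;
      for (int o = 0; o < noff; ++o) {
        int x = i + ox[o], y = j + oy[o];
        if (x < 0 || x >= nx || y < 0 || y >= ny) continue;
        if (hasMask && !mask(x, y)) continue;
        ++hist[bin(x, y)]; ++n;
      }
      if (n == 0) { out(i, j) = 0.0; continue; }
      double H = 0.0;
      for (int b = 0; b < nbins; ++b)
        if (hist[b] > 0) {
          double p = (double)hist[b] / n;
          H -= p * std::log(p) * log2e;
        }
      out(i, j) = H;
    }
  return out;
}

// 6-connected component labelling of a 3-D binary mask.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask) {
  IntegerVector dims = mask.attr("dim");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector lab(mask.size());
  lab.attr("dim") = dims;
  int nextLab = 0;
  const int dxs[6] = { 1, -1, 0, 0, 0, 0 };
  const int dys[6] = { 0, 0, 1, -1, 0, 0 };
  const int dzs[6] = { 0, 0, 0, 0, 1, -1 };
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int idx = x + y * nx + z * nx * ny;
        if (!mask[idx] || lab[idx] != 0) continue;
        ++nextLab;
        std::queue<int> q; q.push(idx); lab[idx] = nextLab;
        while (!q.empty()) {
          int u = q.front(); q.pop();
          int ux = u % nx, uy = (u / nx) % ny, uz = u / (nx * ny);
          for (int d = 0; d < 6; ++d) {
            int vx = ux + dxs[d], vy = uy + dys[d], vz = uz + dzs[d];
            if (vx < 0 || vx >= nx || vy < 0 || vy >= ny || vz < 0 || vz >= nz)
              continue;
            int v = vx + vy * nx + vz * nx * ny;
            if (mask[v] && lab[v] == 0) { lab[v] = nextLab; q.push(v); }
          }
        }
      }
  return lab;
}
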