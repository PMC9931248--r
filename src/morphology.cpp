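#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// 8-neighbour offsets, clockwise from north (Zhang-Suen P2..P9)
static const int DR[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
static const int DC[8] = {0, 1, 1, 1, 0, -1, -1, -1};

static inline bool inb(int r, int c, int H, int W) {
  return r >= 0 && c >= 0 && r < H && c < W;
}

// [[Rcpp::export]]
IntegerMatrix cpp_label8(const IntegerMatrix& mask) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<int> stack;
  for (int c0 = 0; c0 < W; ++c0) {
    for (int r0 = 0; r0 < H; ++r0) {
      if (mask(r0, c0) == 0 || lab(r0, c0) != 0) continue;
      ++next;
      stack.push_back(r0 + H * c0);
      lab(r0, c0) = next;
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int r = p % H, c = p / H;
        for (int k = 0; k < 8; ++k) {
          int rr = r + DR[k], cc = c + DC[k];
          if (inb(rr, cc, H, W) && mask(rr, cc) != 0 && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            stack.push_back(rr + H * cc);
          }
        }
      }
    }
  }
  return lab;
}

// count of set 8-neighbours for every pixel of a binary mask
// [[Rcpp::export]]
IntegerMatrix cpp_neighbor_count(const IntegerMatrix& mask) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix out(H, W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      int n = 0;
      for (int k = 0; k < 8; ++k) {
        int rr = r + DR[k], cc = c + DC[k];
        if (inb(rr, cc, H, W) && mask(rr, cc) != 0) ++n;
      }
      out(r, c) = n;
    }
  return out;
}

static void neighbours(const IntegerMatrix& m, int r, int c, int* p) {
  int H = m.nrow(), W = m.ncol();
  for (int k = 0; k < 8; ++k) {
    int rr = r + DR[k], cc = c + DC[k];
    p[k] = (inb(rr, cc, H, W) && m(rr, cc) != 0) ? 1 : 0;
  }
}

// Topology-preserving thinning (Zhang-Suen) with optional endpoint
// re-extension: after convergence each skeleton endpoint is walked outward
// along its terminal direction while still inside the source mask, undoing
// the end-shortening inherent to iterative thinning of blunt-ended tubes.
// [[Rcpp::export]]
IntegerMatrix cpp_thin(const IntegerMatrix& mask, bool extend_ends = true) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix sk(H, W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) sk(r, c) = mask(r, c) != 0 ? 1 : 0;

  int p[8];
  bool changed = true;
  std::vector<int> kill;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int c = 0; c < W; ++c)
        for (int r = 0; r < H; ++r) {
          if (sk(r, c) == 0) continue;
          neighbours(sk, r, c, p);
          int B = 0, A = 0;
          for (int k = 0; k < 8; ++k) {
            B += p[k];
            if (p[k] == 0 && p[(k + 1) % 8] == 1) ++A;
          }
          if (B < 2 || B > 6 || A != 1) continue;
          // p[0]=N, p[2]=E, p[4]=S, p[6]=W
          bool cond;
          if (pass == 0)
            cond = (p[0] * p[2] * p[4] == 0) && (p[2] * p[4] * p[6] == 0);
          else
            cond = (p[0] * p[2] * p[6] == 0) && (p[0] * p[4] * p[6] == 0);
          if (cond) kill.push_back(r + H * c);
        }
      if (!kill.empty()) changed = true;
      for (size_t i = 0; i < kill.size(); ++i)
        sk(kill[i] % H, kill[i] / H) = 0;
    }
  }

  if (extend_ends) {
    std::vector<int> ends;
    for (int c = 0; c < W; ++c)
      for (int r = 0; r < H; ++r) {
        if (sk(r, c) == 0) continue;
        neighbours(sk, r, c, p);
        int B = 0, kn = -1;
        for (int k = 0; k < 8; ++k) if (p[k]) { ++B; kn = k; }
        if (B == 1) ends.push_back((r + H * c) * 8 + kn);
      }
    for (size_t i = 0; i < ends.size(); ++i) {
      int kn = ends[i] % 8, pos = ends[i] / 8;
      int r = pos % H, c = pos / H;
      int dr = -DR[kn], dc = -DC[kn]; // away from the single neighbour
      int rr = r + dr, cc = c + dc;
      while (inb(rr, cc, H, W) && mask(rr, cc) != 0 && sk(rr, cc) == 0) {
        sk(rr, cc) = 1;
        rr += dr; cc += dc;
      }
    }
  }
  return sk;
}

// stamp discs of per-point radius along a polyline into a copy of mask,
// writing `value`; used to rasterize vessel tubes
// [[Rcpp::export]]
IntegerMatrix cpp_stamp_tube(const IntegerMatrix& mask, const NumericVector& rows,
                             const NumericVector& cols, const NumericVector& radius,
                             int value) {
  IntegerMatrix out = clone(mask);
  int H = out.nrow(), W = out.ncol();
  for (int i = 0; i < rows.size(); ++i) {
    double cr = rows[i], cc = cols[i], rad = radius[i];
    if (rad <= 0) continue;
    int r0 = (int)std::floor(cr - rad), r1 = (int)std::ceil(cr + rad);
    int c0 = (int)std::floor(cc - rad), c1 = (int)std::ceil(cc + rad);
    for (int c = std::max(0, c0); c <= std::min(W - 1, c1); ++c)
      for (int r = std::max(0, r0); r <= std::min(H - 1, r1); ++r) {
        double dr = r - cr, dc = c - cc;
        if (dr * dr + dc * dc <= rad * rad) out(r, c) = value;
      }
  }
  return out;
}

// multi-source BFS over a mask: every mask pixel gets the label of the
// nearest (geodesic) seed pixel; pixels off the mask stay 0
// [[Rcpp::export]]
IntegerMatrix cpp_nearest_label_bfs(const IntegerMatrix& mask, const IntegerMatrix& seeds) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::queue<int> q;
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r)
      if (seeds(r, c) > 0 && mask(r, c) != 0) {
        lab(r, c) = seeds(r, c);
        q.push(r + H * c);
      }
  while (!q.empty()) {
    int pos = q.front(); q.pop();
    int r = pos % H, c = pos / H;
    for (int k = 0; k < 8; ++k) {
      int rr = r + DR[k], cc = c + DC[k];
      if (inb(rr, cc, H, W) && mask(rr, cc) != 0 && lab(rr, cc) == 0) {
        lab(rr, cc) = lab(r, c);
        q.push(rr + H * cc);
      }
    }
  }
  return lab;
}

// artery pixels (code 1) having at least one vein pixel (code 2) among
// their 8-neighbours
// [[Rcpp::export]]
IntegerMatrix cpp_contact_pixels(const IntegerMatrix& av) {
  int H = av.nrow(), W = av.ncol();
  IntegerMatrix out(H, W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      if (av(r, c) != 1) continue;
      for (int k = 0; k < 8; ++k) {
        int rr = r + DR[k], cc = c + DC[k];
        if (inb(rr, cc, H, W) && av(rr, cc) == 2) { out(r, c) = 1; break; }
      }
    }
  return out;
}
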