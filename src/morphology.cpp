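#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Neighborhood offsets for 4- or 8-connectivity, as (drow, dcol) pairs.
static void neighbor_offsets(int connectivity, std::vector<int>& dr,
                             std::vector<int>& dc) {
  dr.assign({-1, 1, 0, 0});
  dc.assign({0, 0, -1, 1});
  if (connectivity == 8) {
    dr.insert(dr.end(), {-1, -1, 1, 1});
    dc.insert(dc.end(), {-1, 1, -1, 1});
  }
}

// Grayscale morphological reconstruction by dilation of `seed` under `mask`
// (seed <= mask pointwise), i.e. the fixpoint of geodesic dilation
//   seed <- pmin(dilate(seed), mask).
// Hybrid sequential algorithm: one forward raster sweep, one backward sweep
// that also seeds a FIFO queue, then queue-driven propagation (Vincent 1993).
// [[Rcpp::export]]
NumericMatrix reconstruct_dilate_cpp(NumericMatrix seed, NumericMatrix mask,
                                     int connectivity) {
  int nr = seed.nrow(), nc = seed.ncol();
  if (mask.nrow() != nr || mask.ncol() != nc)
    stop("seed and mask dimensions differ");
  NumericMatrix J(clone(seed));
  for (int i = 0; i < nr * nc; ++i)
    if (J[i] > mask[i]) stop("seed exceeds mask");

  bool diag = (connectivity == 8);
  // forward sweep: causal neighbors N+ = up, left (and two upper diagonals)
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double v = J(r, c);
      if (r > 0 && J(r - 1, c) > v) v = J(r - 1, c);
      if (c > 0 && J(r, c - 1) > v) v = J(r, c - 1);
      if (diag) {
        if (r > 0 && c > 0 && J(r - 1, c - 1) > v) v = J(r - 1, c - 1);
        if (r < nr - 1 && c > 0 && J(r + 1, c - 1) > v) v = J(r + 1, c - 1);
      }
      J(r, c) = std::min(v, mask(r, c));
    }
  }
  // backward sweep + queue initialization
  std::queue<std::pair<int, int> > fifo;
  for (int c = nc - 1; c >= 0; --c) {
    for (int r = nr - 1; r >= 0; --r) {
      double v = J(r, c);
      if (r < nr - 1 && J(r + 1, c) > v) v = J(r + 1, c);
      if (c < nc - 1 && J(r, c + 1) > v) v = J(r, c + 1);
      if (diag) {
        if (r < nr - 1 && c < nc - 1 && J(r + 1, c + 1) > v) v = J(r + 1, c + 1);
        if (r > 0 && c < nc - 1 && J(r - 1, c + 1) > v) v = J(r - 1, c + 1);
      }
      v = std::min(v, mask(r, c));
      J(r, c) = v;
      // enqueue if some anti-causal neighbor could still be raised
      bool push = false;
      if (r < nr - 1 && J(r + 1, c) < v && J(r + 1, c) < mask(r + 1, c)) push = true;
      if (!push && c < nc - 1 && J(r, c + 1) < v && J(r, c + 1) < mask(r, c + 1)) push = true;
      if (!push && diag) {
        if (r < nr - 1 && c < nc - 1 && J(r + 1, c + 1) < v &&
            J(r + 1, c + 1) < mask(r + 1, c + 1)) push = true;
        if (!push && r > 0 && c < nc - 1 && J(r - 1, c + 1) < v &&
            J(r - 1, c + 1) < mask(r - 1, c + 1)) push = true;
      }
      if (push) fifo.push(std::make_pair(r, c));
    }
  }
  std::vector<int> dr, dc;
  neighbor_offsets(connectivity, dr, dc);
  while (!fifo.empty()) {
    int r = fifo.front().first, c = fifo.front().second;
    fifo.pop();
    double v = J(r, c);
    for (size_t k = 0; k < dr.size(); ++k) {
      int rr = r + dr[k], cc = c + dc[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      if (J(rr, cc) < v && mask(rr, cc) != J(rr, cc)) {
        double nv = std::min(v, mask(rr, cc));
        if (nv > J(rr, cc)) {
          J(rr, cc) = nv;
          fifo.push(std::make_pair(rr, cc));
        }
      }
    }
  }
  return J;
}

// Regional maxima: a pixel is 1 iff its constant-intensity connected plateau
// has no exterior neighbor with a strictly greater value.
// [[Rcpp::export]]
LogicalMatrix regional_maxima_cpp(NumericMatrix img, int connectivity) {
  int nr = img.nrow(), nc = img.ncol();
  std::vector<int> dr, dc;
  neighbor_offsets(connectivity, dr, dc);
  LogicalMatrix out(nr, nc);
  std::vector<char> visited(nr * nc, 0);
  std::vector<int> plateau;
  std::queue<int> q;
  for (int c0 = 0; c0 < nc; ++c0) {
    for (int r0 = 0; r0 < nr; ++r0) {
      int idx0 = c0 * nr + r0;
      if (visited[idx0]) continue;
      double level = img[idx0];
      bool is_max = true;
      plateau.clear();
      visited[idx0] = 1;
      q.push(idx0);
      while (!q.empty()) {
        int idx = q.front();
        q.pop();
        plateau.push_back(idx);
        int r = idx % nr, c = idx / nr;
        for (size_t k = 0; k < dr.size(); ++k) {
          int rr = r + dr[k], cc = c + dc[k];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          int nidx = cc * nr + rr;
          double nv = img[nidx];
          if (nv > level) is_max = false;
          else if (nv == level && !visited[nidx]) {
            visited[nidx] = 1;
            q.push(nidx);
          }
        }
      }
      if (is_max)
        for (size_t k = 0; k < plateau.size(); ++k) out[plateau[k]] = true;
    }
  }
  return out;
}

// Connected-component labeling of a binary image; labels 1..n, background 0.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask, int connectivity) {
  int nr = mask.nrow(), nc = mask.ncol();
  std::vector<int> dr, dc;
  neighbor_offsets(connectivity, dr, dc);
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::queue<int> q;
  for (int c0 = 0; c0 < nc; ++c0) {
    for (int r0 = 0; r0 < nr; ++r0) {
      int idx0 = c0 * nr + r0;
      if (!mask[idx0] || lab[idx0]) continue;
      lab[idx0] = ++next;
      q.push(idx0);
      while (!q.empty()) {
        int idx = q.front();
        q.pop();
        int r = idx % nr, c = idx / nr;
        for (size_t k = 0; k < dr.size(); ++k) {
          int rr = r + dr[k], cc = c + dc[k];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          int nidx = cc * nr + rr;
          if (mask[nidx] && !lab[nidx]) {
            lab[nidx] = next;
            q.push(nidx);
          }
        }
      }
    }
  }
  return lab;
}
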