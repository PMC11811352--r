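#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Spoke-kernel filtering of one 2D slice.
//
// slice: integer 0/1 matrix. The kernel arrives flattened:
//   ends:  ndiam x 4 matrix of (row, col) offsets of the two endpoints of
//          each diameter, relative to the kernel center;
//   trav:  ntot x 2 matrix of traversing-pixel offsets, all diameters
//          concatenated;
//   start: (ndiam + 1) vector of 0-based offsets into trav.
//
// The kernel center visits every foreground pixel.  For a diameter whose
// BOTH translated endpoints fall on background or outside the image, all of
// its translated traversing pixels are marked for removal.  The removal set
// is applied once, after the full scan, so preservation by one diameter
// never overrides removal by another.
// [[Rcpp::export]]
IntegerMatrix spoke_filter_slice_cpp(const IntegerMatrix& slice,
                                     const IntegerMatrix& ends,
                                     const IntegerMatrix& trav,
                                     const IntegerVector& start) {
  const int nr = slice.nrow(), nc = slice.ncol();
  const int nd = ends.nrow();
  std::vector<char> remove(static_cast<size_t>(nr) * nc, 0);
  const int* sl = INTEGER(slice);

  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (sl[r + static_cast<size_t>(c) * nr] == 0) continue;
      for (int d = 0; d < nd; ++d) {
        int r1 = r + ends(d, 0), c1 = c + ends(d, 1);
        if (r1 >= 0 && r1 < nr && c1 >= 0 && c1 < nc &&
            sl[r1 + static_cast<size_t>(c1) * nr] != 0) continue;
        int r2 = r + ends(d, 2), c2 = c + ends(d, 3);
        if (r2 >= 0 && r2 < nr && c2 >= 0 && c2 < nc &&
            sl[r2 + static_cast<size_t>(c2) * nr] != 0) continue;
        for (int k = start[d]; k < start[d + 1]; ++k) {
          int rr = r + trav(k, 0), cc = c + trav(k, 1);
          if (rr >= 0 && rr < nr && cc >= 0 && cc < nc)
            remove[rr + static_cast<size_t>(cc) * nr] = 1;
        }
      }
    }
  }

  IntegerMatrix out(nr, nc);
  int* o = INTEGER(out);
  for (size_t i = 0; i < remove.size(); ++i)
    o[i] = (sl[i] != 0 && !remove[i]) ? 1 : 0;
  return out;
}

// Connected-component labelling of a 3D 0/1 array under 26-connectivity.
// Returns the label array (0 = background) and per-label voxel counts.
// [[Rcpp::export]]
List label_components_cpp(const IntegerVector& vox, const IntegerVector& dims) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const size_t n = static_cast<size_t>(n1) * n2 * n3;
  const int* v = INTEGER(vox);
  IntegerVector labels(n, 0);
  int* lab = INTEGER(labels);
  std::vector<double> counts;
  std::vector<size_t> stack;
  int next_label = 0;

  for (size_t s = 0; s < n; ++s) {
    if (v[s] == 0 || lab[s] != 0) continue;
    ++next_label;
    double cnt = 0;
    stack.clear();
    stack.push_back(s);
    lab[s] = next_label;
    while (!stack.empty()) {
      size_t cur = stack.back();
      stack.pop_back();
      ++cnt;
      int i = static_cast<int>(cur % n1);
      int j = static_cast<int>((cur / n1) % n2);
      int k = static_cast<int>(cur / (static_cast<size_t>(n1) * n2));
      for (int dk = -1; dk <= 1; ++dk) {
        int kk = k + dk;
        if (kk < 0 || kk >= n3) continue;
        for (int dj = -1; dj <= 1; ++dj) {
          int jj = j + dj;
          if (jj < 0 || jj >= n2) continue;
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0 && dk == 0) continue;
            int ii = i + di;
            if (ii < 0 || ii >= n1) continue;
            size_t nb = ii + static_cast<size_t>(jj) * n1 +
                        static_cast<size_t>(kk) * n1 * n2;
            if (v[nb] != 0 && lab[nb] == 0) {
              lab[nb] = next_label;
              stack.push_back(nb);
            }
          }
        }
      }
    }
    counts.push_back(cnt);
  }

  labels.attr("dim") = dims;
  return List::create(_["labels"] = labels, _["counts"] = wrap(counts));
}

// k-means++ seeding (Arthur & Vassilvitskii 2007) on an n x d point matrix,
// using R's RNG so results are reproducible under set.seed().  Returns a
// k x d matrix of initial centers (rows of x).
// [[Rcpp::export]]
NumericMatrix kmeanspp_init_cpp(const NumericMatrix& x, const int k) {
  const int n = x.nrow(), d = x.ncol();
  NumericMatrix centers(k, d);
  std::vector<double> d2(n);
  int i0 = static_cast<int>(unif_rand() * n);
  if (i0 >= n) i0 = n - 1;
  for (int j = 0; j < d; ++j) centers(0, j) = x(i0, j);
  for (int i = 0; i < n; ++i) {
    double s = 0;
    for (int j = 0; j < d; ++j) {
      double t = x(i, j) - centers(0, j);
      s += t * t;
    }
    d2[i] = s;
  }
  for (int c = 1; c < k; ++c) {
    double tot = 0;
    for (int i = 0; i < n; ++i) tot += d2[i];
    int pick;
    if (tot <= 0) {
      pick = static_cast<int>(unif_rand() * n);
      if (pick >= n) pick = n - 1;
    } else {
      double u = unif_rand() * tot, acc = 0;
      pick = n - 1;
      for (int i = 0; i < n; ++i) {
        acc += d2[i];
        if (acc >= u) { pick = i; break; }
      }
    }
    for (int j = 0; j < d; ++j) centers(c, j) = x(pick, j);
    for (int i = 0; i < n; ++i) {
      double s = 0;
      for (int j = 0; j < d; ++j) {
        double t = x(i, j) - centers(c, j);
        s += t * t;
      }
      if (s < d2[i]) d2[i] = s;
    }
  }
  return centers;
}
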