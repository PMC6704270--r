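#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Prominence-based local-maxima detection ("noise tolerance" semantics of the
// classic Find Maxima tool): sweep pixels in decreasing intensity order,
// growing components with a union-find. When a component is absorbed into a
// higher one at level v, its prominence is peak - v; it is reported as a
// maximum iff prominence > tol. Components that survive to the end are
// measured against the global minimum. Summit plateaus report their centroid.

static int find_root(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

// [[Rcpp::export(name = ".find_maxima_cpp")]]
NumericMatrix find_maxima_cpp(NumericMatrix img, double tol) {
  const int nr = img.nrow(), nc = img.ncol(), n = nr * nc;
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  const double* v = img.begin();  // column-major: idx = col * nr + row
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int a, int b) { return v[a] > v[b]; });

  std::vector<int> parent(n, -1);
  std::vector<double> peak(n), sx(n), sy(n);
  std::vector<int> npk(n);
  std::vector<char> plateau(n), processed(n, 0);

  std::vector<double> out_x, out_y, out_v;
  const double vmin = *std::min_element(v, v + n);

  for (int k = 0; k < n; ++k) {
    const int p = ord[k];
    const int row = p % nr, col = p / nr;
    const double vp = v[p];

    int roots[8];
    int nroots = 0;
    for (int dc = -1; dc <= 1; ++dc) {
      for (int dr = -1; dr <= 1; ++dr) {
        if (dr == 0 && dc == 0) continue;
        const int r2 = row + dr, c2 = col + dc;
        if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
        const int q = c2 * nr + r2;
        if (!processed[q]) continue;
        int rt = find_root(parent, q);
        bool seen = false;
        for (int j = 0; j < nroots; ++j) if (roots[j] == rt) { seen = true; break; }
        if (!seen) roots[nroots++] = rt;
      }
    }

    if (nroots == 0) {
      parent[p] = p;
      peak[p] = vp; sx[p] = col; sy[p] = row; npk[p] = 1; plateau[p] = 1;
    } else {
      // main component: highest peak; ties -> smallest root index (stable)
      int main = roots[0];
      for (int j = 1; j < nroots; ++j) {
        if (peak[roots[j]] > peak[main] ||
            (peak[roots[j]] == peak[main] && roots[j] < main)) main = roots[j];
      }
      for (int j = 0; j < nroots; ++j) {
        const int r = roots[j];
        if (r == main) continue;
        const double prom = peak[r] - vp;
        if (prom > tol) {
          out_x.push_back(sx[r] / npk[r]);
          out_y.push_back(sy[r] / npk[r]);
          out_v.push_back(peak[r]);
        } else if (prom == 0 && plateau[r] && plateau[main] && peak[main] == vp) {
          // two summit plateaus of equal height joined at their own level:
          // one plateau, pool the centroid accumulators
          sx[main] += sx[r]; sy[main] += sy[r]; npk[main] += npk[r];
        }
        parent[r] = main;
        if (peak[r] != peak[main] || vp < peak[main]) {
          // absorbed material below the summit: no longer a pure plateau
          if (vp < peak[main]) plateau[main] = 0;
        }
      }
      parent[p] = main;
      if (vp == peak[main] && plateau[main]) {
        sx[main] += col; sy[main] += row; npk[main] += 1;
      } else if (vp < peak[main]) {
        plateau[main] = 0;
      }
    }
    processed[p] = 1;
  }

  // survivors: prominence relative to the global minimum
  for (int i = 0; i < n; ++i) {
    if (parent[i] == i && peak[i] - vmin > tol) {
      out_x.push_back(sx[i] / npk[i]);
      out_y.push_back(sy[i] / npk[i]);
      out_v.push_back(peak[i]);
    }
  }

  NumericMatrix res(out_x.size(), 3);
  for (size_t i = 0; i < out_x.size(); ++i) {
    res(i, 0) = out_x[i];
    res(i, 1) = out_y[i];
    res(i, 2) = out_v[i];
  }
  colnames(res) = CharacterVector::create("x", "y", "value");
  return res;
}
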