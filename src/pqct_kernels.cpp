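// Low-level voxel kernels: connected-component labelling, seeded flood fill,
// one-step binary dilation/erosion, and batched symmetric 3x3 eigensolves for
// the Hessian vesselness filter. Arrays are column-major with dim
// (slice, row, col); connectivity is 6 (faces) or 26 (faces+edges+corners).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct Grid {
  int n1, n2, n3;
  Grid(const IntegerVector &dim) : n1(dim[0]), n2(dim[1]), n3(dim[2]) {}
  inline int idx(int i, int j, int k) const { return i + n1 * (j + n2 * k); }
};

// neighbour offsets for the requested connectivity
static std::vector<std::array<int, 3>> neighbours(int connectivity) {
  std::vector<std::array<int, 3>> off;
  for (int di = -1; di <= 1; ++di)
    for (int dj = -1; dj <= 1; ++dj)
      for (int dk = -1; dk <= 1; ++dk) {
        if (di == 0 && dj == 0 && dk == 0) continue;
        int manh = std::abs(di) + std::abs(dj) + std::abs(dk);
        if (connectivity == 6 && manh != 1) continue;
        off.push_back({di, dj, dk});
      }
  return off;
}

} // namespace

// [[Rcpp::export(name = ".cc_label_3d")]]
IntegerVector cc_label_3d(LogicalVector mask, IntegerVector dim,
                          int connectivity) {
  Grid g(dim);
  const int n = mask.size();
  IntegerVector lab(n, 0);
  lab.attr("dim") = dim;
  std::vector<std::array<int, 3>> off = neighbours(connectivity);
  std::vector<int> stack;
  int next = 0;
  for (int k = 0; k < g.n3; ++k)
    for (int j = 0; j < g.n2; ++j)
      for (int i = 0; i < g.n1; ++i) {
        int v = g.idx(i, j, k);
        if (!mask[v] || lab[v]) continue;
        ++next;
        lab[v] = next;
        stack.clear();
        stack.push_back(v);
        while (!stack.empty()) {
          int cur = stack.back();
          stack.pop_back();
          int ci = cur % g.n1, rest = cur / g.n1;
          int cj = rest % g.n2, ck = rest / g.n2;
          for (const auto &o : off) {
            int ni = ci + o[0], nj = cj + o[1], nk = ck + o[2];
            if (ni < 0 || nj < 0 || nk < 0 || ni >= g.n1 || nj >= g.n2 ||
                nk >= g.n3)
              continue;
            int nv = g.idx(ni, nj, nk);
            if (mask[nv] && !lab[nv]) {
              lab[nv] = next;
              stack.push_back(nv);
            }
          }
        }
      }
  lab.attr("n_components") = next;
  return lab;
}

// [[Rcpp::export(name = ".flood_fill_3d")]]
LogicalVector flood_fill_3d(LogicalVector mask, IntegerVector dim,
                            int seed0, int connectivity) {
  Grid g(dim);
  LogicalVector out(mask.size(), false);
  out.attr("dim") = dim;
  if (seed0 < 0 || seed0 >= mask.size() || !mask[seed0]) return out;
  std::vector<std::array<int, 3>> off = neighbours(connectivity);
  std::vector<int> stack;
  out[seed0] = true;
  stack.push_back(seed0);
  while (!stack.empty()) {
    int cur = stack.back();
    stack.pop_back();
    int ci = cur % g.n1, rest = cur / g.n1;
    int cj = rest % g.n2, ck = rest / g.n2;
    for (const auto &o : off) {
      int ni = ci + o[0], nj = cj + o[1], nk = ck + o[2];
      if (ni < 0 || nj < 0 || nk < 0 || ni >= g.n1 || nj >= g.n2 ||
          nk >= g.n3)
        continue;
      int nv = g.idx(ni, nj, nk);
      if (mask[nv] && !out[nv]) {
        out[nv] = true;
        stack.push_back(nv);
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".binary_dilate_3d")]]
LogicalVector binary_dilate_3d(LogicalVector mask, IntegerVector dim,
                               int connectivity) {
  Grid g(dim);
  LogicalVector out = clone(mask);
  out.attr("dim") = dim;
  std::vector<std::array<int, 3>> off = neighbours(connectivity);
  for (int k = 0; k < g.n3; ++k)
    for (int j = 0; j < g.n2; ++j)
      for (int i = 0; i < g.n1; ++i) {
        int v = g.idx(i, j, k);
        if (!mask[v]) continue;
        for (const auto &o : off) {
          int ni = i + o[0], nj = j + o[1], nk = k + o[2];
          if (ni < 0 || nj < 0 || nk < 0 || ni >= g.n1 || nj >= g.n2 ||
              nk >= g.n3)
            continue;
          out[g.idx(ni, nj, nk)] = true;
        }
      }
  return out;
}

// [[Rcpp::export(name = ".binary_erode_3d")]]
LogicalVector binary_erode_3d(LogicalVector mask, IntegerVector dim,
                              int connectivity) {
  Grid g(dim);
  LogicalVector out = clone(mask);
  out.attr("dim") = dim;
  std::vector<std::array<int, 3>> off = neighbours(connectivity);
  for (int k = 0; k < g.n3; ++k)
    for (int j = 0; j < g.n2; ++j)
      for (int i = 0; i < g.n1; ++i) {
        int v = g.idx(i, j, k);
        if (!mask[v]) continue;
        bool keep = true;
        for (const auto &o : off) {
          int ni = i + o[0], nj = j + o[1], nk = k + o[2];
          // voxels at the volume border keep their value (reflective support)
          if (ni < 0 || nj < 0 || nk < 0 || ni >= g.n1 || nj >= g.n2 ||
              nk >= g.n3)
            continue;
          if (!mask[g.idx(ni, nj, nk)]) {
            keep = false;
            break;
          }
        }
        out[v] = keep;
      }
  return out;
}

// Eigenvalues of symmetric 3x3 Hessians, one per row of the six unique
// entries; returned sorted by increasing |lambda| (Frangi convention
// |l1| <= |l2| <= |l3|).
// [[Rcpp::export(name = ".hessian_eigvals")]]
NumericMatrix hessian_eigvals(NumericVector h11, NumericVector h22,
                              NumericVector h33, NumericVector h12,
                              NumericVector h13, NumericVector h23) {
  const int n = h11.size();
  NumericMatrix out(n, 3);
  arma::mat33 H;
  arma::vec3 ev;
  for (int i = 0; i < n; ++i) {
    H(0, 0) = h11[i]; H(1, 1) = h22[i]; H(2, 2) = h33[i];
    H(0, 1) = H(1, 0) = h12[i];
    H(0, 2) = H(2, 0) = h13[i];
    H(1, 2) = H(2, 1) = h23[i];
    arma::eig_sym(ev, H);
    // eig_sym sorts ascending by value; re-sort by magnitude
    std::array<double, 3> l = {ev[0], ev[1], ev[2]};
    std::sort(l.begin(), l.end(), [](double a, double b) {
      return std::abs(a) < std::abs(b);
    });
    out(i, 0) = l[0];
    out(i, 1) = l[1];
    out(i, 2) = l[2];
  }
  return out;
}
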