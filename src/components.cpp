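#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labelling of a 3D logical volume (column-major, dims =
// c(nx, ny, nz)). connectivity is 6 (face adjacency) or 26. A 2D mask can be
// passed as a single-slice volume; 26-connectivity then reduces to in-plane
// 8-connectivity. Labels are positive integers in scan order; background is 0.
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector vol, IntegerVector dims,
                                   int connectivity = 6) {
  if (dims.size() != 3) stop("dims must have length 3");
  const R_xlen_t nx = dims[0], ny = dims[1], nz = dims[2];
  if (nx * ny * nz != vol.size()) stop("dims do not match volume length");
  if (connectivity != 6 && connectivity != 26) stop("connectivity must be 6 or 26");

  IntegerVector labels(vol.size(), 0);

  // neighbour offsets
  std::vector<int> dx, dy, dz;
  if (connectivity == 6) {
    int ox[] = {1, -1, 0, 0, 0, 0};
    int oy[] = {0, 0, 1, -1, 0, 0};
    int oz[] = {0, 0, 0, 0, 1, -1};
    dx.assign(ox, ox + 6); dy.assign(oy, oy + 6); dz.assign(oz, oz + 6);
  } else {
    for (int a = -1; a <= 1; ++a)
      for (int b = -1; b <= 1; ++b)
        for (int c = -1; c <= 1; ++c) {
          if (a == 0 && b == 0 && c == 0) continue;
          dx.push_back(a); dy.push_back(b); dz.push_back(c);
        }
  }
  const int ndir = (int) dx.size();

  int current = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t idx = 0; idx < vol.size(); ++idx) {
    if (!vol[idx] || labels[idx] != 0) continue;
    ++current;
    labels[idx] = current;
    stack.clear();
    stack.push_back(idx);
    while (!stack.empty()) {
      R_xlen_t p = stack.back();
      stack.pop_back();
      R_xlen_t z = p / (nx * ny);
      R_xlen_t rem = p % (nx * ny);
      R_xlen_t y = rem / nx;
      R_xlen_t x = rem % nx;
      for (int d = 0; d < ndir; ++d) {
        R_xlen_t xx = x + dx[d], yy = y + dy[d], zz = z + dz[d];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
        R_xlen_t q = xx + nx * (yy + ny * zz);
        if (vol[q] && labels[q] == 0) {
          labels[q] = current;
          stack.push_back(q);
        }
      }
    }
  }
  return labels;
}
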