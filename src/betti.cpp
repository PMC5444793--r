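#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Iterative flood fill labelling of a logical matrix. connectivity is 4 or 8.
// Labels are 1..n in scan order; background cells get 0.
static int label_fill(const LogicalMatrix& m, IntegerMatrix& lab, int connectivity) {
  const int nr = m.nrow(), nc = m.ncol();
  const int dr4[] = {-1, 1, 0, 0};
  const int dc4[] = {0, 0, -1, 1};
  const int dr8[] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int* dr = (connectivity == 8) ? dr8 : dr4;
  const int* dc = (connectivity == 8) ? dc8 : dc4;
  const int nd = (connectivity == 8) ? 8 : 4;

  int next = 0;
  std::vector<int> stack;
  stack.reserve(256);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!m(i, j) || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      stack.push_back(i + j * nr);
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int ci = idx % nr, cj = idx / nr;
        for (int k = 0; k < nd; ++k) {
          int ni = ci + dr[k], nj = cj + dc[k];
          if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
          if (m(ni, nj) && lab(ni, nj) == 0) {
            lab(ni, nj) = next;
            stack.push_back(ni + nj * nr);
          }
        }
      }
    }
  }
  return next;
}

// [[Rcpp::export]]
List label_components_cpp(LogicalMatrix m, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  IntegerMatrix lab(m.nrow(), m.ncol());
  int n = label_fill(m, lab, connectivity);
  return List::create(_["labels"] = lab, _["n"] = n);
}

// Betti numbers of a binary image under the standard dual pairing:
// b0 = number of 8-connected foreground components;
// b1 = number of 4-connected background components touching no image border.
// [[Rcpp::export]]
IntegerVector betti_cpp(LogicalMatrix laa) {
  const int nr = laa.nrow(), nc = laa.ncol();
  IntegerMatrix lab(nr, nc);
  int b0 = label_fill(laa, lab, 8);

  LogicalMatrix comp(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      comp(i, j) = !laa(i, j);
  IntegerMatrix clab(nr, nc);
  int ncomp = label_fill(comp, clab, 4);

  std::vector<char> border(ncomp + 1, 0);
  for (int j = 0; j < nc; ++j) {
    if (nr > 0) {
      if (clab(0, j)) border[clab(0, j)] = 1;
      if (clab(nr - 1, j)) border[clab(nr - 1, j)] = 1;
    }
  }
  for (int i = 0; i < nr; ++i) {
    if (nc > 0) {
      if (clab(i, 0)) border[clab(i, 0)] = 1;
      if (clab(i, nc - 1)) border[clab(i, nc - 1)] = 1;
    }
  }
  int b1 = 0;
  for (int k = 1; k <= ncomp; ++k)
    if (!border[k]) ++b1;
  return IntegerVector::create(b0, b1);
}
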