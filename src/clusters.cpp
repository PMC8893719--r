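#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 4-connected components of same-sign supra-threshold cells in an
// nf x nt t-value grid. NA cells never join a cluster.

static void flood(const double *t, int nf, int nt, double thresh,
                  std::vector<int> &labels, int start, int lab, int sgn,
                  double &mass) {
  std::vector<int> stack;
  stack.push_back(start);
  labels[start] = lab;
  while (!stack.empty()) {
    int c = stack.back();
    stack.pop_back();
    mass += t[c];
    int fi = c % nf, ti = c / nf;
    const int nb[4][2] = {{-1, 0}, {1, 0}, {0, -1}, {0, 1}};
    for (int k = 0; k < 4; ++k) {
      int f2 = fi + nb[k][0], t2 = ti + nb[k][1];
      if (f2 < 0 || f2 >= nf || t2 < 0 || t2 >= nt) continue;
      int c2 = f2 + t2 * nf;
      if (labels[c2] != 0) continue;
      double v = t[c2];
      if (ISNAN(v)) continue;
      if ((sgn > 0 && v > thresh) || (sgn < 0 && v < -thresh)) {
        labels[c2] = lab;
        stack.push_back(c2);
      }
    }
  }
}

// [[Rcpp::export]]
List cluster_label_cpp(NumericMatrix tmat, double thresh) {
  int nf = tmat.nrow(), nt = tmat.ncol(), ncell = nf * nt;
  std::vector<int> labels(ncell, 0);
  std::vector<double> masses;
  std::vector<int> signs;
  const double *t = REAL(tmat);
  int lab = 0;
  for (int c = 0; c < ncell; ++c) {
    if (labels[c] != 0) continue;
    double v = t[c];
    if (ISNAN(v) || (v <= thresh && v >= -thresh)) continue;
    int sgn = v > 0 ? 1 : -1;
    double mass = 0.0;
    ++lab;
    flood(t, nf, nt, thresh, labels, c, lab, sgn, mass);
    masses.push_back(mass);
    signs.push_back(sgn);
  }
  IntegerMatrix lmat(nf, nt);
  for (int c = 0; c < ncell; ++c) lmat[c] = labels[c];
  return List::create(_["labels"] = lmat,
                      _["mass"] = NumericVector(masses.begin(), masses.end()),
                      _["sign"] = IntegerVector(signs.begin(), signs.end()));
}

// Max |cluster mass| per permutation replicate; tperm is nperm x (nf*nt)
// with cells in column-major (frequency-fastest) order.
// [[Rcpp::export]]
NumericVector max_cluster_mass_cpp(NumericMatrix tperm, int nf, int nt,
                                   double thresh) {
  int nperm = tperm.nrow(), ncell = nf * nt;
  if (tperm.ncol() != ncell) stop("tperm has %d columns, expected %d",
                                  tperm.ncol(), ncell);
  NumericVector out(nperm);
  std::vector<double> row(ncell);
  std::vector<int> labels(ncell);
  for (int p = 0; p < nperm; ++p) {
    for (int c = 0; c < ncell; ++c) row[c] = tperm(p, c);
    std::fill(labels.begin(), labels.end(), 0);
    double best = 0.0;
    int lab = 0;
    for (int c = 0; c < ncell; ++c) {
      if (labels[c] != 0) continue;
      double v = row[c];
      if (ISNAN(v) || (v <= thresh && v >= -thresh)) continue;
      double mass = 0.0;
      flood(row.data(), nf, nt, thresh, labels, c, ++lab,
            v > 0 ? 1 : -1, mass);
      if (std::fabs(mass) > best) best = std::fabs(mass);
    }
    out[p] = best;
  }
  return out;
}
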