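#include <Rcpp.h>
using namespace Rcpp;

// Raw k-mer kernel between two integer-encoded sequences (1-based residue
// indices). K(a,b) = sum over k in [kmin, kmax], over all k-mer start pairs,
// of the product of per-position base similarities mhat(x_i, y_i). Because
// every k-mer pair of length k extends one of length k-1, the sum over all
// window lengths along each diagonal is accumulated with a running product.
static double kernel_raw(const IntegerVector& a, const IntegerVector& b,
                         const NumericMatrix& mhat, int kmin, int kmax) {
  const int la = a.size(), lb = b.size();
  double total = 0.0;
  for (int i = 0; i < la; ++i) {
    for (int j = 0; j < lb; ++j) {
      const int maxk = std::min(kmax, std::min(la - i, lb - j));
      double prod = 1.0;
      for (int t = 0; t < maxk; ++t) {
        prod *= mhat(a[i + t] - 1, b[j + t] - 1);
        if (t + 1 >= kmin) total += prod;
      }
    }
  }
  return total;
}

// [[Rcpp::export(name = ".kernel_raw_cpp")]]
double kernel_raw_cpp(IntegerVector a, IntegerVector b, NumericMatrix mhat,
                      int kmin, int kmax) {
  return kernel_raw(a, b, mhat, kmin, kmax);
}

// Normalized kernel matrix between two sets of integer-encoded sequences:
// K(a,b) / sqrt(K(a,a) K(b,b)). Self-kernels are computed once per set.
// [[Rcpp::export(name = ".kernel_cross_cpp")]]
NumericMatrix kernel_cross_cpp(List avec, List bvec, NumericMatrix mhat,
                               int kmin, int kmax) {
  const int na = avec.size(), nb = bvec.size();
  std::vector<IntegerVector> as(na), bs(nb);
  std::vector<double> sa(na), sb(nb);
  for (int i = 0; i < na; ++i) {
    as[i] = avec[i];
    sa[i] = kernel_raw(as[i], as[i], mhat, kmin, kmax);
  }
  for (int j = 0; j < nb; ++j) {
    bs[j] = bvec[j];
    sb[j] = kernel_raw(bs[j], bs[j], mhat, kmin, kmax);
  }
  NumericMatrix out(na, nb);
  for (int i = 0; i < na; ++i)
    for (int j = 0; j < nb; ++j)
      out(i, j) = kernel_raw(as[i], bs[j], mhat, kmin, kmax) /
                  std::sqrt(sa[i] * sb[j]);
  return out;
}
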