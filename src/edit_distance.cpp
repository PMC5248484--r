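#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Weighted edit-distance dynamic programming.
//
// T[p,0] = p * w_del, T[0,q] = q * w_ins; interior cells take the minimum of
// the deletion, insertion and (mis)match branches.  When restrict_match is
// true the match branch is only available for symbols in {A,C,G,T}; ambiguous
// symbols (IUPAC codes kept under the "as-mismatch" policy) then never match,
// not even themselves.

static inline bool is_acgt(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

static double ed_core(const std::string& x, const std::string& y,
                      double w_ins, double w_del, double w_sub, double w_mat,
                      bool restrict_match) {
  const size_t n = x.size(), m = y.size();
  std::vector<double> prev(m + 1), cur(m + 1);
  for (size_t j = 0; j <= m; ++j) prev[j] = j * w_ins;
  for (size_t i = 1; i <= n; ++i) {
    cur[0] = i * w_del;
    const char xi = x[i - 1];
    const bool xi_ok = !restrict_match || is_acgt(xi);
    for (size_t j = 1; j <= m; ++j) {
      const bool match = xi_ok && xi == y[j - 1];
      double best = prev[j - 1] + (match ? w_mat : w_sub);
      const double del = prev[j] + w_del;
      if (del < best) best = del;
      const double ins = cur[j - 1] + w_ins;
      if (ins < best) best = ins;
      cur[j] = best;
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// [[Rcpp::export]]
double ed_distance_cpp(std::string x, std::string y,
                       double w_ins, double w_del, double w_sub, double w_mat,
                       bool restrict_match = false) {
  return ed_core(x, y, w_ins, w_del, w_sub, w_mat, restrict_match);
}

// [[Rcpp::export]]
NumericMatrix ed_table_cpp(std::string x, std::string y,
                           double w_ins, double w_del, double w_sub,
                           double w_mat, bool restrict_match = false) {
  const size_t n = x.size(), m = y.size();
  NumericMatrix T(n + 1, m + 1);
  for (size_t j = 0; j <= m; ++j) T(0, j) = j * w_ins;
  for (size_t i = 1; i <= n; ++i) {
    T(i, 0) = i * w_del;
    const char xi = x[i - 1];
    const bool xi_ok = !restrict_match || is_acgt(xi);
    for (size_t j = 1; j <= m; ++j) {
      const bool match = xi_ok && xi == y[j - 1];
      double best = T(i - 1, j - 1) + (match ? w_mat : w_sub);
      const double del = T(i - 1, j) + w_del;
      if (del < best) best = del;
      const double ins = T(i, j - 1) + w_ins;
      if (ins < best) best = ins;
      T(i, j) = best;
    }
  }
  return T;
}

// Pairwise matrix over the upper triangle, mirrored; optionally divided by
// max(|x|, |y|) (the normalized edit distance).
// [[Rcpp::export]]
NumericMatrix ed_distmat_cpp(CharacterVector seqs,
                             double w_ins, double w_del, double w_sub,
                             double w_mat, bool normalize = true,
                             bool restrict_match = false) {
  const int n = seqs.size();
  std::vector<std::string> s(n);
  for (int i = 0; i < n; ++i) s[i] = as<std::string>(seqs[i]);
  NumericMatrix M(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double d = ed_core(s[i], s[j], w_ins, w_del, w_sub, w_mat,
                         restrict_match);
      if (normalize) {
        const double denom = std::max(s[i].size(), s[j].size());
        if (denom == 0) stop("both sequences empty: normalized distance undefined");
        d /= denom;
      }
      M(i, j) = d;
      M(j, i) = d;
    }
  }
  return M;
}
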