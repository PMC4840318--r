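#include <Rcpp.h>
#include <algorithm>
#include <string>
#include <vector>

using namespace Rcpp;

// Weighted Levenshtein distance: substitutions cost `sub`, insertions and
// deletions cost `indel`. Standard O(nm) dynamic programme, two rolling rows.
static double wlev(const std::string& a, const std::string& b,
                   double sub, double indel) {
  const size_t n = a.size(), m = b.size();
  std::vector<double> prev(m + 1), cur(m + 1);
  for (size_t j = 0; j <= m; ++j) prev[j] = j * indel;
  for (size_t i = 1; i <= n; ++i) {
    cur[0] = i * indel;
    for (size_t j = 1; j <= m; ++j) {
      double best = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0.0 : sub);
      best = std::min(best, prev[j] + indel);
      best = std::min(best, cur[j - 1] + indel);
      cur[j] = best;
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// Gapless (Hamming-style) distance for equal-length strings.
static double gapless(const std::string& a, const std::string& b, double sub) {
  double d = 0.0;
  for (size_t i = 0; i < a.size(); ++i)
    if (a[i] != b[i]) d += sub;
  return d;
}

// Size of the intersection of two sorted, duplicate-free integer vectors.
static int sorted_intersection_size(const IntegerVector& x,
                                    const IntegerVector& y) {
  int i = 0, j = 0, count = 0;
  const int nx = x.size(), ny = y.size();
  while (i < nx && j < ny) {
    if (x[i] < y[j]) ++i;
    else if (x[i] > y[j]) ++j;
    else { ++count; ++i; ++j; }
  }
  return count;
}

// [[Rcpp::export(name = ".wlev_cpp")]]
double wlev_cpp(std::string s1, std::string s2, double sub_cost,
                double indel_cost) {
  return wlev(s1, s2, sub_cost, indel_cost);
}

// Condensed (lower-triangle, column-major as in stats::dist) vector of
// antibody-specific pairwise scores. Inputs are parallel per-record vectors:
// cdr3 strings, integer codes for V family / V gene / J gene, and a list of
// sorted integer-encoded substitution keys per record.
// [[Rcpp::export(name = ".condensed_scores_cpp")]]
NumericVector condensed_scores_cpp(CharacterVector cdr3,
                                   IntegerVector v_family,
                                   IntegerVector v_gene,
                                   IntegerVector j_gene,
                                   List mutations,
                                   double sub_cost, double indel_cost,
                                   double v_penalty, double j_penalty,
                                   double shared_mut_bonus,
                                   double clamp_floor,
                                   bool family_prescreen,
                                   double sentinel) {
  const int n = cdr3.size();
  std::vector<std::string> seqs(n);
  for (int i = 0; i < n; ++i) seqs[i] = as<std::string>(cdr3[i]);
  std::vector<IntegerVector> muts(n);
  for (int i = 0; i < n; ++i) muts[i] = mutations[i];

  const R_xlen_t npairs = (R_xlen_t)n * (n - 1) / 2;
  NumericVector out(npairs);
  R_xlen_t k = 0;
  for (int i = 0; i < n - 1; ++i) {
    const std::string& a = seqs[i];
    for (int j = i + 1; j < n; ++j, ++k) {
      if (family_prescreen && v_family[i] != v_family[j]) {
        out[k] = sentinel;
        continue;
      }
      const std::string& b = seqs[j];
      double d = (a.size() == b.size())
        ? gapless(a, b, sub_cost)
        : wlev(a, b, sub_cost, indel_cost);
      if (v_gene[i] != v_gene[j]) d += v_penalty;
      if (j_gene[i] != j_gene[j]) d += j_penalty;
      int shared = sorted_intersection_size(muts[i], muts[j]);
      d -= shared_mut_bonus * shared;
      if (d < clamp_floor) d = clamp_floor;
      double len = std::min(a.size(), b.size());
      out[k] = d / len;
    }
  }
  return out;
}
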