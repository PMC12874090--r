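#include <Rcpp.h>
#include <cstring>
#include <limits>
using namespace Rcpp;

// Residue indexing shared with R: "ACDEFGHIKLMNPQRSTVWY" -> 0..19, 'X' -> 20.
static const char *ALPHA = "ACDEFGHIKLMNPQRSTVWYX";

static inline int res_index(char c) {
  const char *p = std::strchr(ALPHA, c);
  if (p == nullptr) return -1;
  return (int)(p - ALPHA);
}

static std::vector<int> encode(const std::string &s, const char *label) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    int k = res_index(s[i]);
    if (k < 0)
      stop("unknown residue '%c' in sequence %s", s[i], label);
    v[i] = k;
  }
  return v;
}

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// Affine-gap Needleman-Wunsch, end gaps penalized. A gap of length k costs
// gap_open + (k-1) * gap_extend (both <= 0). Three-state DP:
//   M  - a[i] aligned to b[j]
//   Ga - gap in b (consumes a; "up")
//   Gb - gap in a (consumes b; "left")
// Traceback tie-break: M > Ga > Gb, fixed for determinism.
// [[Rcpp::export]]
List cpp_global_align(std::string a, std::string b, NumericMatrix smat,
                      double gap_open, double gap_extend, bool traceback) {
  if (a.empty() || b.empty())
    stop("empty sequence in global alignment");
  std::vector<int> ea = encode(a, "a"), eb = encode(b, "b");
  const int n = (int)ea.size(), m = (int)eb.size();

  std::vector<double> M((n + 1) * (m + 1), NEG_INF);
  std::vector<double> Ga((n + 1) * (m + 1), NEG_INF);
  std::vector<double> Gb((n + 1) * (m + 1), NEG_INF);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) Ga[at(i, 0)] = gap_open + (i - 1) * gap_extend;
  for (int j = 1; j <= m; ++j) Gb[at(0, j)] = gap_open + (j - 1) * gap_extend;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double diag = std::max(M[at(i - 1, j - 1)],
                    std::max(Ga[at(i - 1, j - 1)], Gb[at(i - 1, j - 1)]));
      M[at(i, j)] = diag + smat(ea[i - 1], eb[j - 1]);
      Ga[at(i, j)] = std::max(M[at(i - 1, j)] + gap_open,
                     std::max(Ga[at(i - 1, j)] + gap_extend,
                              Gb[at(i - 1, j)] + gap_open));
      Gb[at(i, j)] = std::max(M[at(i, j - 1)] + gap_open,
                     std::max(Ga[at(i, j - 1)] + gap_open,
                              Gb[at(i, j - 1)] + gap_extend));
    }
  }

  double sM = M[at(n, m)], sGa = Ga[at(n, m)], sGb = Gb[at(n, m)];
  double score = std::max(sM, std::max(sGa, sGb));

  if (!traceback)
    return List::create(_["score"] = score);

  // state codes: 0 = M, 1 = Ga, 2 = Gb; preference M > Ga > Gb
  std::string ra, rb;
  ra.reserve(n + m); rb.reserve(n + m);
  int i = n, j = m;
  int state = (sM >= sGa && sM >= sGb) ? 0 : (sGa >= sGb ? 1 : 2);
  int n_ident = 0;
  while (i > 0 || j > 0) {
    if (state == 0) {
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      if (a[i - 1] == b[j - 1] && a[i - 1] != 'X') ++n_ident;
      --i; --j;
      if (i == 0 && j == 0) break;
      double pM = M[at(i, j)], pGa = Ga[at(i, j)], pGb = Gb[at(i, j)];
      if (pM >= pGa && pM >= pGb) state = 0;
      else if (pGa >= pGb) state = 1;
      else state = 2;
    } else if (state == 1) {
      ra.push_back(a[i - 1]); rb.push_back('-');
      double here = Ga[at(i, j)];
      --i;
      if (i == 0 && j == 0) break;
      if (M[at(i, j)] + gap_open == here) state = 0;
      else if (Ga[at(i, j)] + gap_extend == here) state = 1;
      else state = 2;
    } else {
      ra.push_back('-'); rb.push_back(b[j - 1]);
      double here = Gb[at(i, j)];
      --j;
      if (i == 0 && j == 0) break;
      if (M[at(i, j)] + gap_open == here) state = 0;
      else if (Ga[at(i, j)] + gap_open == here) state = 1;
      else state = 2;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());

  return List::create(_["aligned_a"] = ra, _["aligned_b"] = rb,
                      _["score"] = score, _["n_identical"] = n_ident);
}

// Score-only alignment of one query against many references.
// [[Rcpp::export]]
NumericVector cpp_align_scores(std::string query, CharacterVector refs,
                               NumericMatrix smat, double gap_open,
                               double gap_extend) {
  int nr = refs.size();
  NumericVector out(nr);
  for (int r = 0; r < nr; ++r) {
    List res = cpp_global_align(query, as<std::string>(refs[r]), smat,
                                gap_open, gap_extend, false);
    out[r] = as<double>(res["score"]);
  }
  return out;
}
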