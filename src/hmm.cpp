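#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline double lse(double a, double b) {
  if (a == NEG_INF) return b;
  if (b == NEG_INF) return a;
  double m = a > b ? a : b;
  return m + std::log1p(std::exp(-(std::fabs(a - b))));
}

// Global-in-model profile HMM scoring (Plan7-lite: match/insert/delete, no
// D<->I transitions, single pass B -> 1..L -> E).
//
// Arguments, all on natural-log scale:
//   mlo: L x 21 match emission log-odds (log e_i(x)/bg(x)); column 21 is 'X'
//        and must be 0 (background-equivalent).
//   ilo: length-21 insert emission log-odds, ilo[20] == 0.
//   tr : (L+1) x 7 transition log-probabilities out of position i = 0..L with
//        columns MM, MI, MD, IM, II, DM, DD. Row 0 is the begin state (B acts
//        as M0; B->I0 uses column MI, I0 self-loop column II at row 0, etc.).
//        At row L the M/I/D -> E probabilities sit in MM, IM, DM and
//        MD/DD are -Inf.
//   seq: residues encoded 0..20.
// Returns c(viterbi, forward) log-odds in nats.
// [[Rcpp::export]]
NumericVector cpp_profile_score(NumericMatrix mlo, NumericVector ilo,
                                NumericMatrix tr, IntegerVector seq,
                                bool do_forward) {
  const int L = mlo.nrow();
  const int n = seq.size();
  if (n < 1) stop("empty sequence");

  // DP over profile positions i = 0..L and sequence prefix j = 0..n.
  // Row-major vectors indexed [i][j].
  auto at = [n](int i, int j) { return i * (n + 1) + j; };
  std::vector<double> VM((L + 1) * (n + 1), NEG_INF), VI = VM, VD = VM;
  std::vector<double> FM, FI, FD;
  if (do_forward) { FM = VM; FI = VM; FD = VM; }

  VM[at(0, 0)] = 0.0; // begin state, nothing emitted
  if (do_forward) FM[at(0, 0)] = 0.0;

  const int cMM = 0, cMI = 1, cMD = 2, cIM = 3, cII = 4, cDM = 5, cDD = 6;

  for (int i = 0; i <= L; ++i) {
    for (int j = 0; j <= n; ++j) {
      if (i == 0 && j == 0) continue;
      // insert state I_i emits seq[j-1]
      if (j > 0) {
        double e = ilo[seq[j - 1]];
        double v = std::max(VM[at(i, j - 1)] + tr(i, cMI),
                            VI[at(i, j - 1)] + tr(i, cII));
        VI[at(i, j)] = e + v;
        if (do_forward)
          FI[at(i, j)] = e + lse(FM[at(i, j - 1)] + tr(i, cMI),
                                 FI[at(i, j - 1)] + tr(i, cII));
      }
      if (i > 0) {
        // match state M_i emits seq[j-1]
        if (j > 0) {
          double e = mlo(i - 1, seq[j - 1]);
          double v = std::max(VM[at(i - 1, j - 1)] + tr(i - 1, cMM),
                     std::max(VI[at(i - 1, j - 1)] + tr(i - 1, cIM),
                              VD[at(i - 1, j - 1)] + tr(i - 1, cDM)));
          VM[at(i, j)] = e + v;
          if (do_forward)
            FM[at(i, j)] = e + lse(FM[at(i - 1, j - 1)] + tr(i - 1, cMM),
                               lse(FI[at(i - 1, j - 1)] + tr(i - 1, cIM),
                                   FD[at(i - 1, j - 1)] + tr(i - 1, cDM)));
        }
        // delete state D_i emits nothing
        double v = std::max(VM[at(i - 1, j)] + tr(i - 1, cMD),
                            VD[at(i - 1, j)] + tr(i - 1, cDD));
        VD[at(i, j)] = v;
        if (do_forward)
          FD[at(i, j)] = lse(FM[at(i - 1, j)] + tr(i - 1, cMD),
                             FD[at(i - 1, j)] + tr(i - 1, cDD));
      }
    }
  }

  double vit = std::max(VM[at(L, n)] + tr(L, cMM),
               std::max(VI[at(L, n)] + tr(L, cIM),
                        VD[at(L, n)] + tr(L, cDM)));
  double fwd = NA_REAL;
  if (do_forward)
    fwd = lse(FM[at(L, n)] + tr(L, cMM),
          lse(FI[at(L, n)] + tr(L, cIM),
              FD[at(L, n)] + tr(L, cDM)));
  return NumericVector::create(_["viterbi"] = vit, _["forward"] = fwd);
}

// Viterbi-only batch scoring of many encoded sequences against one profile.
// Rolling two-row DP with raw pointers; emissions are repacked row-major
// per match state so the inner loop stays in cache.
// [[Rcpp::export]]
NumericVector cpp_profile_score_many(NumericMatrix mlo, NumericVector ilo,
                                     NumericMatrix tr, List seqs) {
  const int L = mlo.nrow();
  const int ns = seqs.size();
  NumericVector out(ns);

  // repack: em[i * 21 + x] for match state i+1; transitions per row
  std::vector<double> em((size_t)L * 21);
  for (int i = 0; i < L; ++i)
    for (int x = 0; x < 21; ++x) em[(size_t)i * 21 + x] = mlo(i, x);
  std::vector<double> tMM(L + 1), tMI(L + 1), tMD(L + 1), tIM(L + 1),
      tII(L + 1), tDM(L + 1), tDD(L + 1);
  for (int i = 0; i <= L; ++i) {
    tMM[i] = tr(i, 0); tMI[i] = tr(i, 1); tMD[i] = tr(i, 2);
    tIM[i] = tr(i, 3); tII[i] = tr(i, 4); tDM[i] = tr(i, 5);
    tDD[i] = tr(i, 6);
  }
  std::vector<double> il(21);
  for (int x = 0; x < 21; ++x) il[x] = ilo[x];

  for (int k = 0; k < ns; ++k) {
    IntegerVector sv = seqs[k];
    const int n = sv.size();
    if (n < 1) stop("empty sequence");
    std::vector<int> s(n);
    for (int j = 0; j < n; ++j) s[j] = sv[j];

    std::vector<double> pM(n + 1, NEG_INF), pI(n + 1, NEG_INF),
        pD(n + 1, NEG_INF), cM(n + 1), cI(n + 1), cD(n + 1);
    // row i = 0 (begin): M0 at j=0 is 0; I0 run along j
    pM[0] = 0.0;
    {
      const double mi = tMI[0], ii = tII[0];
      for (int j = 1; j <= n; ++j) {
        double v = std::max(pM[j - 1] + mi, pI[j - 1] + ii);
        pI[j] = il[s[j - 1]] + v;
      }
    }
    for (int i = 1; i <= L; ++i) {
      const double *emi = &em[(size_t)(i - 1) * 21];
      const double mm = tMM[i - 1], im = tIM[i - 1], dm = tDM[i - 1];
      const double md = tMD[i - 1], dd = tDD[i - 1];
      const double mi = tMI[i], ii = tII[i];
      cM[0] = NEG_INF; cI[0] = NEG_INF;
      cD[0] = std::max(pM[0] + md, pD[0] + dd);
      for (int j = 1; j <= n; ++j) {
        double vm = std::max(pM[j - 1] + mm,
                    std::max(pI[j - 1] + im, pD[j - 1] + dm));
        vm += emi[s[j - 1]];
        double vd = std::max(pM[j] + md, pD[j] + dd);
        double vi = std::max(cM[j - 1] + mi, cI[j - 1] + ii);
        vi += il[s[j - 1]];
        cM[j] = vm; cD[j] = vd; cI[j] = vi;
      }
      std::swap(pM, cM); std::swap(pI, cI); std::swap(pD, cD);
    }
    out[k] = std::max(pM[n] + tMM[L],
             std::max(pI[n] + tIM[L], pD[n] + tDM[L]));
  }
  return out;
}
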