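#include <Rcpp.h>
using namespace Rcpp;

// Information-content weighted cross-likelihood between two motif profiles.
// Each profile is a pair of 4 x L matrices: f (smoothed column frequencies)
// and A (log-odds PWM with each column scaled by that column's information
// content).  The score of one aligned column pair (i, j) is
//   0.5 * ( sum_b A1(b,i) f2(b,j) + sum_b f1(b,i) A2(b,j) )
// and the raw score of an alignment is the sum over its column pairs
// divided by min(L1, L2) — i.e. the per-column mean scaled by alignment
// coverage of the shorter motif, so a short chance overlap cannot score as
// well as a full-length match.  raw_max scans every ungapped offset with
// overlap >= min_overlap and returns the maximum.  Strand handling
// (reverse-complement profiles) and self-normalization live in the R
// callers.

static double raw_max_one(const NumericMatrix& f1, const NumericMatrix& A1,
                          const NumericMatrix& f2, const NumericMatrix& A2,
                          int min_overlap) {
  const int L1 = f1.ncol(), L2 = f2.ncol();
  const int Lmin = std::min(L1, L2);
  double best = R_NegInf;
  // offset o: column i of motif 1 pairs with column i - o of motif 2
  for (int o = -(L2 - min_overlap); o <= L1 - min_overlap; ++o) {
    int lo = std::max(0, o);
    int hi = std::min(L1, L2 + o);  // exclusive
    int len = hi - lo;
    if (len < min_overlap) continue;
    double s = 0.0;
    for (int i = lo; i < hi; ++i) {
      int j = i - o;
      double t = 0.0;
      for (int b = 0; b < 4; ++b)
        t += A1(b, i) * f2(b, j) + f1(b, i) * A2(b, j);
      s += 0.5 * t;
    }
    double m = s / Lmin;
    if (m > best) best = m;
  }
  return best;
}

// [[Rcpp::export]]
double spic_raw_max(NumericMatrix f1, NumericMatrix A1,
                    NumericMatrix f2, NumericMatrix A2,
                    int min_overlap) {
  return raw_max_one(f1, A1, f2, A2, min_overlap);
}

static double normalize_score(double raw, double self1, double self2) {
  if (!(self1 > 0.0) || !(self2 > 0.0)) return 0.0;
  double s = raw / std::sqrt(self1 * self2);
  if (s > 1.0) s = 1.0;
  if (s < 0.0) s = 0.0;  // clip to [-1,1] then floor at 0
  return s;
}

// Scores of the motifs in `rows` (1-based indices) against every other
// motif.  fl/Al are the forward profiles, frl/Arl the reverse-complement
// profiles, selfraw the per-motif raw self-similarity maxima.
// [[Rcpp::export]]
NumericMatrix spic_score_rows(IntegerVector rows, List fl, List Al,
                              List frl, List Arl, NumericVector selfraw,
                              int min_overlap) {
  const int n = fl.size();
  const int nr = rows.size();
  NumericMatrix out(nr, n);
  for (int r = 0; r < nr; ++r) {
    int i = rows[r] - 1;
    NumericMatrix fi = fl[i], Ai = Al[i];
    for (int j = 0; j < n; ++j) {
      if (j == i) { out(r, j) = 1.0; continue; }
      NumericMatrix fj = fl[j], Aj = Al[j];
      NumericMatrix fjr = frl[j], Ajr = Arl[j];
      double raw = raw_max_one(fi, Ai, fj, Aj, min_overlap);
      double rawr = raw_max_one(fi, Ai, fjr, Ajr, min_overlap);
      if (rawr > raw) raw = rawr;
      out(r, j) = normalize_score(raw, selfraw[i], selfraw[j]);
    }
  }
  return out;
}
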