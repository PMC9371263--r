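// Affine-gap global alignment with free end gaps (Gotoh / overlap dialect).
//
// Library sequences are unaligned fragments of very different lengths
// (COI fragments down to ~245 bp against ~650 bp exemplars), so every
// pairwise comparison is aligned here before p-distances are taken.
// End gaps are free: a short fragment nested inside a longer sequence
// pays nothing for the unmatched overhangs.
//
// Gap cost model: a run of L gap characters costs gap_open + (L-1) *
// gap_extend, except runs touching either end of the alignment, which
// are free. Tie-breaking is deterministic: diagonal (match/mismatch)
// is preferred over a gap in A (A paired against '-'), which is
// preferred over a gap in B.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>

using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// state codes for traceback
enum State { SM = 0, SX = 1, SY = 2 }; // SX: gap in A (consumes B), SY: gap in B

// [[Rcpp::export(name = ".nw_affine")]]
List nw_affine(std::string a, std::string b,
               double match, double mismatch,
               double gap_open, double gap_extend) {
  const int n = (int)a.size(), m = (int)b.size();
  if (n == 0 || m == 0) stop("sequences must be non-empty");

  // score matrices, (n+1) x (m+1), flattened
  std::vector<double> M((n + 1) * (m + 1), NEG_INF);
  std::vector<double> X((n + 1) * (m + 1), NEG_INF);
  std::vector<double> Y((n + 1) * (m + 1), NEG_INF);
  // predecessor state of each cell, per state
  std::vector<signed char> pM((n + 1) * (m + 1), -1);
  std::vector<signed char> pX((n + 1) * (m + 1), -1);
  std::vector<signed char> pY((n + 1) * (m + 1), -1);

  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  M[at(0, 0)] = 0.0;
  // free leading gaps: skip a prefix of B (gap in A) or of A (gap in B)
  for (int j = 1; j <= m; ++j) { X[at(0, j)] = 0.0; pX[at(0, j)] = SX; }
  for (int i = 1; i <= n; ++i) { Y[at(i, 0)] = 0.0; pY[at(i, 0)] = SY; }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      // M: a[i] ~ b[j]; prefer M > X > Y on ties
      {
        double m0 = M[at(i - 1, j - 1)], x0 = X[at(i - 1, j - 1)],
               y0 = Y[at(i - 1, j - 1)];
        double best = m0; signed char st = SM;
        if (x0 > best) { best = x0; st = SX; }
        if (y0 > best) { best = y0; st = SY; }
        if (best > NEG_INF) { M[at(i, j)] = best + s; pM[at(i, j)] = st; }
      }
      // X: gap in A at column (i, j), consumes b[j]
      {
        double mo = M[at(i, j - 1)] == NEG_INF ? NEG_INF : M[at(i, j - 1)] + gap_open;
        double xe = X[at(i, j - 1)] == NEG_INF ? NEG_INF : X[at(i, j - 1)] + gap_extend;
        double yo = Y[at(i, j - 1)] == NEG_INF ? NEG_INF : Y[at(i, j - 1)] + gap_open;
        double best = mo; signed char st = SM;
        if (xe > best) { best = xe; st = SX; }
        if (yo > best) { best = yo; st = SY; }
        if (best > NEG_INF) { X[at(i, j)] = best; pX[at(i, j)] = st; }
      }
      // Y: gap in B at (i, j), consumes a[i]
      {
        double mo = M[at(i - 1, j)] == NEG_INF ? NEG_INF : M[at(i - 1, j)] + gap_open;
        double xo = X[at(i - 1, j)] == NEG_INF ? NEG_INF : X[at(i - 1, j)] + gap_open;
        double ye = Y[at(i - 1, j)] == NEG_INF ? NEG_INF : Y[at(i - 1, j)] + gap_extend;
        double best = mo; signed char st = SM;
        if (xo > best) { best = xo; st = SX; }
        if (ye > best) { best = ye; st = SY; }
        if (best > NEG_INF) { Y[at(i, j)] = best; pY[at(i, j)] = st; }
      }
    }
  }

  // termination: free trailing gaps -- best over last row / last column,
  // preferring (n, m), then larger i on the last column, then larger j on
  // the last row; within a cell prefer M > X > Y. Strict '>' keeps the
  // first-encountered (preferred) optimum.
  double best = NEG_INF; int bi = n, bj = m; signed char bst = SM;
  auto consider = [&](int i, int j) {
    double v[3] = { M[at(i, j)], X[at(i, j)], Y[at(i, j)] };
    for (int s = 0; s < 3; ++s)
      if (v[s] > best) { best = v[s]; bi = i; bj = j; bst = (signed char)s; }
  };
  consider(n, m);
  for (int i = n - 1; i >= 0; --i) consider(i, m);
  for (int j = m - 1; j >= 0; --j) consider(n, j);
  if (best == NEG_INF) stop("alignment failed");

  // traceback
  std::string ra, rb;
  // trailing free gaps
  for (int i = n; i > bi; --i) { ra.push_back(a[i - 1]); rb.push_back('-'); }
  for (int j = m; j > bj; --j) { ra.push_back('-'); rb.push_back(b[j - 1]); }
  int i = bi, j = bj; signed char st = bst;
  while (i > 0 || j > 0) {
    if (st == SM) {
      signed char prev = pM[at(i, j)];
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      --i; --j; st = prev;
    } else if (st == SX) {
      signed char prev = pX[at(i, j)];
      ra.push_back('-'); rb.push_back(b[j - 1]);
      --j; st = prev;
    } else {
      signed char prev = pY[at(i, j)];
      ra.push_back(a[i - 1]); rb.push_back('-');
      --i; st = prev;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());

  return List::create(_["aligned_a"] = ra, _["aligned_b"] = rb,
                      _["score"] = best);
}

// p-distance with pairwise deletion over two equal-length aligned strings.
// Sites where either sequence is a gap or not in {A,C,G,T} are dropped
// from numerator and denominator.
// [[Rcpp::export(name = ".p_distance_aligned")]]
List p_distance_aligned(std::string a, std::string b) {
  if (a.size() != b.size()) stop("aligned sequences must have equal length");
  long sites = 0, diff = 0;
  for (size_t k = 0; k < a.size(); ++k) {
    char ca = a[k], cb = b[k];
    bool oka = (ca == 'A' || ca == 'C' || ca == 'G' || ca == 'T');
    bool okb = (cb == 'A' || cb == 'C' || cb == 'G' || cb == 'T');
    if (oka && okb) { ++sites; if (ca != cb) ++diff; }
  }
  double d = (sites == 0) ? NA_REAL : (double)diff / (double)sites;
  return List::create(_["distance"] = d, _["sites"] = (double)sites);
}

// count of shared k-mers between a reference k-mer set and a query; used
// for strand normalization (11-mer matching of both query orientations).
// [[Rcpp::export(name = ".shared_kmers")]]
int shared_kmers(std::string ref, std::string query, int k) {
  if ((int)ref.size() < k || (int)query.size() < k) return 0;
  std::vector<std::string> kms;
  kms.reserve(ref.size() - k + 1);
  for (size_t i = 0; i + k <= ref.size(); ++i) kms.push_back(ref.substr(i, k));
  std::sort(kms.begin(), kms.end());
  int cnt = 0;
  for (size_t i = 0; i + k <= query.size(); ++i)
    if (std::binary_search(kms.begin(), kms.end(), query.substr(i, k))) ++cnt;
  return cnt;
}
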