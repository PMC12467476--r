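// Hot loops for the scrambled-null analyzers: interval census / entropy,
// blockiness, and homopeptide content. Residue codes are 0..19 for the 20
// standard amino acids and 20 for X (excluded from all statistics but
// occupying sequence positions).

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static const int NAA = 20;

// ---- interval census ------------------------------------------------------

// counts indexed by (x * 20 + z) * (deltaMax + 1) + delta; `touched`
// collects the indices that became non-zero so callers can iterate and
// reset sparsely (the census buffer is reused across scrambles)
static void censusFill(const int* codes, int L, int deltaMax,
                       const std::vector<bool>& ok, std::vector<int>& cnt,
                       std::vector<int>& touched) {
  for (size_t q = 0; q < touched.size(); ++q) cnt[touched[q]] = 0;
  touched.clear();
  const int D = deltaMax + 1;
  for (int i = 0; i < L; ++i) {
    int x = codes[i];
    if (x >= NAA || !ok[x]) continue;
    int jmax = std::min(L - 1, i + deltaMax + 1);
    int base = x * NAA;
    for (int j = i + 1; j <= jmax; ++j) {
      int z = codes[j];
      if (z >= NAA || !ok[z]) continue;
      int idx = (base + z) * D + (j - i - 1);
      if (cnt[idx]++ == 0) touched.push_back(idx);
    }
  }
}

static std::vector<bool> occOk(const int* codes, int L, int minOcc) {
  std::vector<int> tot(NAA + 1, 0);
  for (int i = 0; i < L; ++i) tot[codes[i]]++;
  std::vector<bool> ok(NAA);
  for (int a = 0; a < NAA; ++a) ok[a] = tot[a] >= minOcc;
  return ok;
}

// IE (bits) overall and for the same-/different-residue subsets, each
// renormalized within its subset; NA for an empty subset. Only the
// `touched` (non-zero) census slots are visited.
static void entropyTriple(const std::vector<int>& cnt,
                          const std::vector<int>& touched, int deltaMax,
                          double* out) {
  const int D = deltaMax + 1;
  double totAll = 0, totSame = 0, totDiff = 0;
  for (size_t q = 0; q < touched.size(); ++q) {
    int idx = touched[q];
    int pair = idx / D;
    bool same = (pair / NAA) == (pair % NAA);
    totAll += cnt[idx];
    (same ? totSame : totDiff) += cnt[idx];
  }
  double hAll = 0, hSame = 0, hDiff = 0;
  for (size_t q = 0; q < touched.size(); ++q) {
    int idx = touched[q];
    int pair = idx / D;
    bool same = (pair / NAA) == (pair % NAA);
    double c = cnt[idx];
    hAll -= (c / totAll) * std::log2(c / totAll);
    if (same) hSame -= (c / totSame) * std::log2(c / totSame);
    else hDiff -= (c / totDiff) * std::log2(c / totDiff);
  }
  out[0] = totAll > 0 ? hAll : NA_REAL;
  out[1] = totSame > 0 ? hSame : NA_REAL;
  out[2] = totDiff > 0 ? hDiff : NA_REAL;
}

// [[Rcpp::export]]
List cpp_census(IntegerVector codes, int deltaMax, int minOcc) {
  int L = codes.size();
  std::vector<bool> ok = occOk(codes.begin(), L, minOcc);
  std::vector<int> cnt((size_t)NAA * NAA * (deltaMax + 1), 0);
  std::vector<int> touched;
  censusFill(codes.begin(), L, deltaMax, ok, cnt, touched);
  std::sort(touched.begin(), touched.end());
  const int D = deltaMax + 1;
  std::vector<int> xs, zs, ds, cs;
  for (size_t q = 0; q < touched.size(); ++q) {
    size_t idx = touched[q];
    int pair = (int)(idx / D);
    xs.push_back(pair / NAA);
    zs.push_back(pair % NAA);
    ds.push_back((int)(idx % D));
    cs.push_back(cnt[idx]);
  }
  return List::create(_["x"] = wrap(xs), _["z"] = wrap(zs),
                      _["delta"] = wrap(ds), _["count"] = wrap(cs));
}

// Observed census + IE triples for nSamples composition-preserving
// scrambles (R RNG), plus per-observed-type counts of scrambles whose
// count reached the observed count (for one-sided enrichment p-values).
// [[Rcpp::export]]
List cpp_assess_ie(IntegerVector codes, int nSamples, int deltaMax,
                   int minOcc) {
  int L = codes.size();
  std::vector<bool> ok = occOk(codes.begin(), L, minOcc);
  size_t nIdx = (size_t)NAA * NAA * (deltaMax + 1);
  std::vector<int> cnt(nIdx, 0);
  std::vector<int> touched;
  censusFill(codes.begin(), L, deltaMax, ok, cnt, touched);
  std::sort(touched.begin(), touched.end());
  std::vector<size_t> obsIdx;
  std::vector<int> obsCnt;
  for (size_t q = 0; q < touched.size(); ++q)
    { obsIdx.push_back(touched[q]); obsCnt.push_back(cnt[touched[q]]); }
  NumericMatrix ieNull(nSamples, 3);
  IntegerVector exceed(obsIdx.size(), 0);
  std::vector<int> perm(codes.begin(), codes.end());
  std::vector<int> buf(nIdx, 0);
  std::vector<int> bufTouched;
  double trip[3];
  for (int srep = 0; srep < nSamples; ++srep) {
    // Fisher-Yates with R's RNG
    for (int i = L - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(perm[i], perm[j]);
    }
    censusFill(perm.data(), L, deltaMax, ok, buf, bufTouched);
    entropyTriple(buf, bufTouched, deltaMax, trip);
    ieNull(srep, 0) = trip[0] == trip[0] ? trip[0] : NA_REAL;
    ieNull(srep, 1) = trip[1];
    ieNull(srep, 2) = trip[2];
    for (size_t q = 0; q < obsIdx.size(); ++q)
      if (buf[obsIdx[q]] >= obsCnt[q]) exceed[q]++;
  }
  return List::create(_["ie_null"] = ieNull, _["exceed"] = exceed);
}

// ---- blockiness -----------------------------------------------------------

// Nearest same-type and different-type distances per position; positions
// holding X or a singleton type are dropped from both sums. X counts as a
// 21st (different) type for neighbours' dmin_diff. One-sided minima at the
// termini are accepted.
static bool blockinessSums(const int* codes, int L, double* num,
                           double* den, double* numA, double* denA) {
  const int BIG = 1 << 29;
  std::vector<int> tot(NAA + 1, 0);
  for (int i = 0; i < L; ++i) tot[codes[i]]++;
  std::vector<int> dsame(L, BIG), ddiff(L, BIG);
  std::vector<int> last(NAA + 1, -1);
  std::vector<int> prevDiff(L, -1), nextDiff(L, -1);
  // left-to-right pass: nearest previous same-type and different-type
  for (int i = 0; i < L; ++i) {
    int c = codes[i];
    if (last[c] >= 0) dsame[i] = i - last[c];
    if (i > 0)
      prevDiff[i] = (codes[i - 1] != c) ? (i - 1) : prevDiff[i - 1];
    if (prevDiff[i] >= 0) ddiff[i] = i - prevDiff[i];
    last[c] = i;
  }
  // right-to-left pass: nearest next same-type and different-type
  std::fill(last.begin(), last.end(), -1);
  for (int i = L - 1; i >= 0; --i) {
    int c = codes[i];
    if (last[c] >= 0 && last[c] - i < dsame[i]) dsame[i] = last[c] - i;
    if (i < L - 1)
      nextDiff[i] = (codes[i + 1] != c) ? (i + 1) : nextDiff[i + 1];
    if (nextDiff[i] >= 0 && nextDiff[i] - i < ddiff[i])
      ddiff[i] = nextDiff[i] - i;
    last[c] = i;
  }
  *num = 0; *den = 0;
  for (int a = 0; a < NAA; ++a) { numA[a] = 0; denA[a] = 0; }
  bool any = false;
  for (int i = 0; i < L; ++i) {
    int c = codes[i];
    if (c >= NAA) continue;            // X excluded from both sums
    if (tot[c] < 2) continue;          // singleton type: drop both terms
    if (dsame[i] >= BIG || ddiff[i] >= BIG) continue;
    *num += ddiff[i];
    *den += dsame[i];
    numA[c] += ddiff[i];
    denA[c] += dsame[i];
    any = true;
  }
  return any && *den > 0;
}

// [[Rcpp::export]]
List cpp_blockiness(IntegerVector codes) {
  int L = codes.size();
  double num, den;
  NumericVector numA(NAA), denA(NAA);
  bool defined = blockinessSums(codes.begin(), L, &num, &den,
                                numA.begin(), denA.begin());
  IntegerVector counts(NAA);
  for (int i = 0; i < L; ++i)
    if (codes[i] < NAA) counts[codes[i]]++;
  return List::create(_["defined"] = defined, _["num"] = num,
                      _["den"] = den, _["num_a"] = numA, _["den_a"] = denA,
                      _["counts"] = counts);
}

// B over nSamples scrambles (R RNG).
// [[Rcpp::export]]
NumericVector cpp_blockiness_null(IntegerVector codes, int nSamples) {
  int L = codes.size();
  std::vector<int> perm(codes.begin(), codes.end());
  NumericVector out(nSamples);
  double num, den;
  std::vector<double> numA(NAA), denA(NAA);
  for (int srep = 0; srep < nSamples; ++srep) {
    for (int i = L - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(perm[i], perm[j]);
    }
    bool defined = blockinessSums(perm.data(), L, &num, &den,
                                  numA.data(), denA.data());
    out[srep] = defined ? num / den : NA_REAL;
  }
  return out;
}

// ---- homopeptide content --------------------------------------------------

static int hpepOf(const int* codes, int L, int minLen) {
  int total = 0, runLen = 1;
  for (int i = 1; i <= L; ++i) {
    if (i < L && codes[i] == codes[i - 1]) { runLen++; continue; }
    if (runLen >= minLen && codes[i - 1] < NAA) total += runLen;
    runLen = 1;
  }
  return total;
}

// hpep over nSamples scrambles (R RNG).
// [[Rcpp::export]]
IntegerVector cpp_hpep_null(IntegerVector codes, int nSamples, int minLen) {
  int L = codes.size();
  std::vector<int> perm(codes.begin(), codes.end());
  IntegerVector out(nSamples);
  for (int srep = 0; srep < nSamples; ++srep) {
    for (int i = L - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(perm[i], perm[j]);
    }
    out[srep] = hpepOf(perm.data(), L, minLen);
  }
  return out;
}
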