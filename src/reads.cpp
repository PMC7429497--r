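// Hot-path helpers: read assembly from lookup tables and one-pass
// extraction of the per-read fields used by the filtering cascade.
// Semantics mirror the exported R stage functions exactly (equivalence is
// asserted in the test suite).

#include <Rcpp.h>
#include <cstring>
#include <string>

using namespace Rcpp;

static inline int baseDigit(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default: return -1;
  }
}

// out[i] = ta[ia[i]] + tb[ib[i]] + tc[ic[i]]  (1-based indices)
// [[Rcpp::export(name = ".cppJoin3")]]
CharacterVector cppJoin3(CharacterVector ta, IntegerVector ia,
                         CharacterVector tb, IntegerVector ib,
                         CharacterVector tc, IntegerVector ic) {
  R_xlen_t n = ia.size();
  if (ib.size() != n || ic.size() != n) stop("index vectors must match");
  CharacterVector out(n);
  std::string buf;
  for (R_xlen_t i = 0; i < n; ++i) {
    SEXP a = ta[ia[i] - 1], b = tb[ib[i] - 1], c = tc[ic[i] - 1];
    buf.clear();
    buf.append(CHAR(a), LENGTH(a));
    buf.append(CHAR(b), LENGTH(b));
    buf.append(CHAR(c), LENGTH(c));
    out[i] = Rf_mkCharLenCE(buf.data(), (int)buf.size(), CE_NATIVE);
  }
  return out;
}

// out[i] = ta[ia[i]] + fill
// [[Rcpp::export(name = ".cppJoin1c")]]
CharacterVector cppJoin1c(CharacterVector ta, IntegerVector ia,
                          std::string fill) {
  R_xlen_t n = ia.size();
  CharacterVector out(n);
  std::string buf;
  for (R_xlen_t i = 0; i < n; ++i) {
    SEXP a = ta[ia[i] - 1];
    buf.clear();
    buf.append(CHAR(a), LENGTH(a));
    buf.append(fill);
    out[i] = Rf_mkCharLenCE(buf.data(), (int)buf.size(), CE_NATIVE);
  }
  return out;
}

// Per-read fields of the filtering cascade, one pass over the bytes:
//   keyCode  - base-4 code of read1[1..15] as sequenced (NA if non-ACGT)
//   m15code  - code of the RNA-sense 15mer (revcomp of read1[1..15])
//   hasN     - non-ACGT base within read1[1..15]
//   structOK - read1[16] == 'C' and read1[17..18] in {AA, CA, CC}
//   extraC   - 0/1/2 per the 17..18 whitelist (NA otherwise)
//   polyaOK  - >= minFrac * window of the window bases starting at the
//              first tail A (position 17 + extraC) are 'A'
//   umiCode  - code of read2[1..umiLen] (NA if non-ACGT)
// [[Rcpp::export(name = ".cppReadFields")]]
List cppReadFields(CharacterVector r1, CharacterVector r2, int umiLen,
                   int window, double minFrac) {
  R_xlen_t n = r1.size();
  if (r2.size() != n) stop("mismatched record counts");
  NumericVector key(n), m15(n), umi(n);
  LogicalVector hasN(n), structOK(n), polyaOK(n);
  IntegerVector extraC(n);
  const double top15 = 1073741823.0;  // 4^15 - 1
  static const double pw[15] = {
    268435456.0, 67108864.0, 16777216.0, 4194304.0, 1048576.0, 262144.0,
    65536.0, 16384.0, 4096.0, 1024.0, 256.0, 64.0, 16.0, 4.0, 1.0};
  for (R_xlen_t i = 0; i < n; ++i) {
    SEXP s1 = r1[i];
    if (s1 == NA_STRING || LENGTH(s1) < 18 + window)
      stop("read too short: structural filter needs length >= %d at record %td",
           18 + window, (ptrdiff_t)(i + 1));
    const char* s = CHAR(s1);
    double k = 0.0, rsum = 0.0;
    bool bad = false;
    for (int j = 0; j < 15; ++j) {
      int d = baseDigit(s[j]);
      if (d < 0) { bad = true; break; }
      k += d * pw[j];
      rsum += d * pw[14 - j];
    }
    hasN[i] = bad;
    key[i] = bad ? NA_REAL : k;
    m15[i] = bad ? NA_REAL : (top15 - rsum);

    int extra = -1;
    if (s[16] == 'A' && s[17] == 'A') extra = 0;
    else if (s[16] == 'C' && s[17] == 'A') extra = 1;
    else if (s[16] == 'C' && s[17] == 'C') extra = 2;
    extraC[i] = extra < 0 ? NA_INTEGER : extra;
    bool sok = (s[15] == 'C') && extra >= 0;
    structOK[i] = sok;
    bool pok = false;
    if (extra >= 0) {
      int p = 16 + extra;  // 0-based index of position 17 + extra
      int cnt = 0;
      for (int j = p; j < p + window; ++j) cnt += (s[j] == 'A');
      pok = (double)cnt >= minFrac * window;
    }
    polyaOK[i] = pok;

    SEXP s2 = r2[i];
    if (s2 == NA_STRING || LENGTH(s2) < umiLen)
      stop("read2 shorter than the UMI at record %td", (ptrdiff_t)(i + 1));
    const char* t = CHAR(s2);
    double u = 0.0;
    bool ubad = false;
    for (int j = 0; j < umiLen; ++j) {
      int d = baseDigit(t[j]);
      if (d < 0) { ubad = true; break; }
      u = u * 4.0 + d;
    }
    umi[i] = ubad ? NA_REAL : u;
  }
  return List::create(_["keyCode"] = key, _["m15code"] = m15,
                      _["hasN"] = hasN, _["structOK"] = structOK,
                      _["polyaOK"] = polyaOK, _["extraC"] = extraC,
                      _["umiCode"] = umi);
}

// Streaming simulate+filter kernel: assembles each Read1/UMI in a local
// buffer from the lookup tables, applies pre-drawn substitution events
// (sorted by read index; at most one event per base), and computes the same
// per-read fields as cppReadFields - without materializing R strings. All
// randomness is drawn in R; this function is deterministic given its inputs.
// [[Rcpp::export(name = ".cppSimFields")]]
List cppSimFields(CharacterVector rc8, IntegerVector t8,
                  CharacterVector rc7, IntegerVector m7,
                  CharacterVector sfx, IntegerVector extraIdx,
                  CharacterVector umitab, IntegerVector umiIdx,
                  IntegerVector ev1r, IntegerVector ev1p, IntegerVector ev1s,
                  IntegerVector ev2r, IntegerVector ev2p, IntegerVector ev2s,
                  int umiLen, int window, double minFrac, int read1Len) {
  R_xlen_t n = t8.size();
  NumericVector key(n), m15(n), umi(n);
  LogicalVector hasN(n), structOK(n), polyaOK(n);
  IntegerVector extraC(n);
  static const char BASES[4] = {'A', 'C', 'G', 'T'};
  const double top15 = 1073741823.0;  // 4^15 - 1
  static const double pw[15] = {
    268435456.0, 67108864.0, 16777216.0, 4194304.0, 1048576.0, 262144.0,
    65536.0, 16384.0, 4096.0, 1024.0, 256.0, 64.0, 16.0, 4.0, 1.0};
  std::string buf(read1Len, 'A');
  std::string ubuf(umiLen, 'A');
  R_xlen_t e1 = 0, e2 = 0, ne1 = ev1r.size(), ne2 = ev2r.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    SEXP a = rc8[t8[i] - 1], b = rc7[m7[i] - 1], c = sfx[extraIdx[i] - 1];
    if (LENGTH(a) + LENGTH(b) + LENGTH(c) != read1Len)
      stop("read pieces do not add up to read1Len");
    std::memcpy(&buf[0], CHAR(a), LENGTH(a));
    std::memcpy(&buf[LENGTH(a)], CHAR(b), LENGTH(b));
    std::memcpy(&buf[LENGTH(a) + LENGTH(b)], CHAR(c), LENGTH(c));
    while (e1 < ne1 && ev1r[e1] == i + 1) {
      int p = ev1p[e1] - 1;
      buf[p] = BASES[(baseDigit(buf[p]) + ev1s[e1]) % 4];
      ++e1;
    }
    double k = 0.0, rsum = 0.0;
    for (int j = 0; j < 15; ++j) {
      int d = baseDigit(buf[j]);
      k += d * pw[j];
      rsum += d * pw[14 - j];
    }
    hasN[i] = false;
    key[i] = k;
    m15[i] = top15 - rsum;

    int extra = -1;
    if (buf[16] == 'A' && buf[17] == 'A') extra = 0;
    else if (buf[16] == 'C' && buf[17] == 'A') extra = 1;
    else if (buf[16] == 'C' && buf[17] == 'C') extra = 2;
    extraC[i] = extra < 0 ? NA_INTEGER : extra;
    structOK[i] = (buf[15] == 'C') && extra >= 0;
    bool pok = false;
    if (extra >= 0) {
      int p = 16 + extra;
      int cnt = 0;
      for (int j = p; j < p + window; ++j) cnt += (buf[j] == 'A');
      pok = (double)cnt >= minFrac * window;
    }
    polyaOK[i] = pok;

    SEXP us = umitab[umiIdx[i] - 1];
    std::memcpy(&ubuf[0], CHAR(us), umiLen);
    while (e2 < ne2 && ev2r[e2] == i + 1) {
      int p = ev2p[e2] - 1;
      if (p < umiLen)
        ubuf[p] = BASES[(baseDigit(ubuf[p]) + ev2s[e2]) % 4];
      ++e2;
    }
    double u = 0.0;
    for (int j = 0; j < umiLen; ++j) u = u * 4.0 + baseDigit(ubuf[j]);
    umi[i] = u;
  }
  return List::create(_["keyCode"] = key, _["m15code"] = m15,
                      _["hasN"] = hasN, _["structOK"] = structOK,
                      _["polyaOK"] = polyaOK, _["extraC"] = extraC,
                      _["umiCode"] = umi);
}

// sense 15mer codes of the first 15 bases (NA where non-ACGT)
// [[Rcpp::export(name = ".cppEncode15")]]
NumericVector cppEncode15(CharacterVector x) {
  R_xlen_t n = x.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    SEXP s1 = x[i];
    if (s1 == NA_STRING || LENGTH(s1) < 15) { out[i] = NA_REAL; continue; }
    const char* s = CHAR(s1);
    double k = 0.0;
    bool bad = false;
    for (int j = 0; j < 15; ++j) {
      int d = baseDigit(s[j]);
      if (d < 0) { bad = true; break; }
      k = k * 4.0 + d;
    }
    out[i] = bad ? NA_REAL : k;
  }
  return out;
}
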