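// MinHash over 32-bit shingle hashes with d universal-hash permutations
// h_i(x) = ((a_i * x + b_i) mod p) mod m,  p = 2^61 - 1, m = 2^32 - 1.
// Products reach 2^64, so intermediates use unsigned 128-bit integers; the
// whole path is exact integer arithmetic. Hash values travel to/from R as
// doubles (every value < 2^53, exactly representable).
#include <Rcpp.h>
#include <cstdint>

static const uint64_t MERSENNE_P = (1ULL << 61) - 1;
static const uint64_t MAX_HASH_M = (1ULL << 32) - 1;

//' @noRd
// [[Rcpp::export(name = "cpp_minhash")]]
Rcpp::NumericVector cpp_minhash(Rcpp::NumericVector hashes,
                                Rcpp::NumericVector a,
                                Rcpp::NumericVector b) {
  const R_xlen_t d = a.size(), nh = hashes.size();
  if (b.size() != d) Rcpp::stop("seed vectors a and b differ in length");
  if (nh == 0) Rcpp::stop("cannot MinHash an empty hash set");
  Rcpp::NumericVector out(d);
  std::vector<uint64_t> hv(nh);
  for (R_xlen_t j = 0; j < nh; ++j) hv[j] = static_cast<uint64_t>(hashes[j]);
  for (R_xlen_t i = 0; i < d; ++i) {
    const unsigned __int128 ai = static_cast<uint64_t>(a[i]);
    const uint64_t bi = static_cast<uint64_t>(b[i]);
    uint64_t best = UINT64_MAX;
    for (R_xlen_t j = 0; j < nh; ++j) {
      unsigned __int128 v = ai * hv[j] + bi;
      uint64_t r = static_cast<uint64_t>(v % MERSENNE_P) % MAX_HASH_M;
      if (r < best) best = r;
    }
    out[i] = static_cast<double>(best);
  }
  return out;
}

//' @noRd
// [[Rcpp::export(name = "cpp_match_counts")]]
Rcpp::IntegerVector cpp_match_counts(Rcpp::NumericMatrix fps,
                                     Rcpp::NumericVector q) {
  // per-row count of components equal to the query fingerprint
  const int n = fps.nrow(), d = fps.ncol();
  if (q.size() != d) Rcpp::stop("query dimension mismatch");
  Rcpp::IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int m = 0;
    for (int j = 0; j < d; ++j)
      if (fps(i, j) == q[j]) ++m;
    out[i] = m;
  }
  return out;
}

//' @noRd
// [[Rcpp::export(name = "cpp_nn_best")]]
Rcpp::IntegerMatrix cpp_nn_best(Rcpp::NumericMatrix fps) {
  // For each row, the other row with the highest number of matching
  // components (ties -> lowest row index). Column 1: 1-based index of the
  // nearest neighbor, column 2: match count.
  const int n = fps.nrow(), d = fps.ncol();
  if (n < 2) Rcpp::stop("need at least 2 fingerprints");
  Rcpp::IntegerMatrix out(n, 2);
  std::vector<int> bestIdx(n, -1), bestMatch(n, -1);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      int m = 0;
      for (int k = 0; k < d; ++k)
        if (fps(i, k) == fps(j, k)) ++m;
      if (m > bestMatch[i]) { bestMatch[i] = m; bestIdx[i] = j; }
      if (m > bestMatch[j]) { bestMatch[j] = m; bestIdx[j] = i; }
    }
    Rcpp::checkUserInterrupt();
  }
  for (int i = 0; i < n; ++i) {
    out(i, 0) = bestIdx[i] + 1;
    out(i, 1) = bestMatch[i];
  }
  return out;
}
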