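// SHA-1 (FIPS 180-1) with truncation of the digest to its first 32-bit word.
// Shingle hashing needs a stable, well-distributed "unique mapping" from
// byte-strings to 32-bit integers that is identical across platforms; the
// implementation is pinned by the standard "abc" test vector in the suite.
#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <string>

namespace {

inline uint32_t rol32(uint32_t x, int s) {
  return (x << s) | (x >> (32 - s));
}

// Returns the full 160-bit digest in h[5]; message is arbitrary bytes.
void sha1_digest(const unsigned char *msg, size_t len, uint32_t h[5]) {
  h[0] = 0x67452301u; h[1] = 0xEFCDAB89u; h[2] = 0x98BADCFEu;
  h[3] = 0x10325476u; h[4] = 0xC3D2E1F0u;

  const uint64_t ml = static_cast<uint64_t>(len) * 8u;
  // padded length: message + 0x80 + zeros + 8-byte length, multiple of 64
  size_t total = len + 1 + 8;
  size_t padded = ((total + 63) / 64) * 64;

  std::string buf(padded, '\0');
  std::memcpy(&buf[0], msg, len);
  buf[len] = static_cast<char>(0x80);
  for (int i = 0; i < 8; ++i)
    buf[padded - 1 - i] = static_cast<char>((ml >> (8 * i)) & 0xFFu);

  uint32_t w[80];
  for (size_t chunk = 0; chunk < padded; chunk += 64) {
    const unsigned char *p =
        reinterpret_cast<const unsigned char *>(buf.data()) + chunk;
    for (int t = 0; t < 16; ++t)
      w[t] = (static_cast<uint32_t>(p[4 * t]) << 24) |
             (static_cast<uint32_t>(p[4 * t + 1]) << 16) |
             (static_cast<uint32_t>(p[4 * t + 2]) << 8) |
             static_cast<uint32_t>(p[4 * t + 3]);
    for (int t = 16; t < 80; ++t)
      w[t] = rol32(w[t - 3] ^ w[t - 8] ^ w[t - 14] ^ w[t - 16], 1);

    uint32_t a = h[0], b = h[1], c = h[2], d = h[3], e = h[4];
    for (int t = 0; t < 80; ++t) {
      uint32_t f, k;
      if (t < 20)      { f = (b & c) | ((~b) & d);          k = 0x5A827999u; }
      else if (t < 40) { f = b ^ c ^ d;                     k = 0x6ED9EBA1u; }
      else if (t < 60) { f = (b & c) | (b & d) | (c & d);   k = 0x8F1BBCDCu; }
      else             { f = b ^ c ^ d;                     k = 0xCA62C1D6u; }
      uint32_t tmp = rol32(a, 5) + f + e + k + w[t];
      e = d; d = c; c = rol32(b, 30); b = a; a = tmp;
    }
    h[0] += a; h[1] += b; h[2] += c; h[3] += d; h[4] += e;
  }
}

} // namespace

uint32_t sha1_first_word(const std::string &s) {
  uint32_t h[5];
  sha1_digest(reinterpret_cast<const unsigned char *>(s.data()), s.size(), h);
  return h[0];
}

//' @noRd
// [[Rcpp::export(name = "cpp_sha1_u32")]]
Rcpp::NumericVector cpp_sha1_u32(Rcpp::CharacterVector x) {
  R_xlen_t n = x.size();
  Rcpp::NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (Rcpp::CharacterVector::is_na(x[i]))
      Rcpp::stop("NA shingle cannot be hashed");
    std::string s = Rcpp::as<std::string>(x[i]);
    if (s.empty()) Rcpp::stop("empty shingle cannot be hashed");
    out[i] = static_cast<double>(sha1_first_word(s));
  }
  return out;
}
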