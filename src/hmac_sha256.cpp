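// Keyed one-way pseudonym primitive: HMAC-SHA256 (FIPS 198 / FIPS 180-4).
// Self-contained so the pseudonymization contract does not depend on any
// external crypto library.
#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <string>
#include <vector>

namespace {

struct Sha256 {
  uint32_t h[8];
  uint64_t bits;
  uint8_t buf[64];
  size_t buflen;

  Sha256() { reset(); }

  void reset() {
    static const uint32_t init[8] = {0x6a09e667u, 0xbb67ae85u, 0x3c6ef372u,
                                     0xa54ff53au, 0x510e527fu, 0x9b05688cu,
                                     0x1f83d9abu, 0x5be0cd19u};
    std::memcpy(h, init, sizeof(init));
    bits = 0;
    buflen = 0;
  }

  static uint32_t rotr(uint32_t x, int n) { return (x >> n) | (x << (32 - n)); }

  void block(const uint8_t* p) {
    static const uint32_t k[64] = {
        0x428a2f98u, 0x71374491u, 0xb5c0fbcfu, 0xe9b5dba5u, 0x3956c25bu,
        0x59f111f1u, 0x923f82a4u, 0xab1c5ed5u, 0xd807aa98u, 0x12835b01u,
        0x243185beu, 0x550c7dc3u, 0x72be5d74u, 0x80deb1feu, 0x9bdc06a7u,
        0xc19bf174u, 0xe49b69c1u, 0xefbe4786u, 0x0fc19dc6u, 0x240ca1ccu,
        0x2de92c6fu, 0x4a7484aau, 0x5cb0a9dcu, 0x76f988dau, 0x983e5152u,
        0xa831c66du, 0xb00327c8u, 0xbf597fc7u, 0xc6e00bf3u, 0xd5a79147u,
        0x06ca6351u, 0x14292967u, 0x27b70a85u, 0x2e1b2138u, 0x4d2c6dfcu,
        0x53380d13u, 0x650a7354u, 0x766a0abbu, 0x81c2c92eu, 0x92722c85u,
        0xa2bfe8a1u, 0xa81a664bu, 0xc24b8b70u, 0xc76c51a3u, 0xd192e819u,
        0xd6990624u, 0xf40e3585u, 0x106aa070u, 0x19a4c116u, 0x1e376c08u,
        0x2748774cu, 0x34b0bcb5u, 0x391c0cb3u, 0x4ed8aa4au, 0x5b9cca4fu,
        0x682e6ff3u, 0x748f82eeu, 0x78a5636fu, 0x84c87814u, 0x8cc70208u,
        0x90befffau, 0xa4506cebu, 0xbef9a3f7u, 0xc67178f2u};
    uint32_t w[64];
    for (int i = 0; i < 16; ++i)
      w[i] = (uint32_t(p[4 * i]) << 24) | (uint32_t(p[4 * i + 1]) << 16) |
             (uint32_t(p[4 * i + 2]) << 8) | uint32_t(p[4 * i + 3]);
    for (int i = 16; i < 64; ++i) {
      uint32_t s0 = rotr(w[i - 15], 7) ^ rotr(w[i - 15], 18) ^ (w[i - 15] >> 3);
      uint32_t s1 = rotr(w[i - 2], 17) ^ rotr(w[i - 2], 19) ^ (w[i - 2] >> 10);
      w[i] = w[i - 16] + s0 + w[i - 7] + s1;
    }
    uint32_t a = h[0], b = h[1], c = h[2], d = h[3], e = h[4], f = h[5],
             g = h[6], hh = h[7];
    for (int i = 0; i < 64; ++i) {
      uint32_t S1 = rotr(e, 6) ^ rotr(e, 11) ^ rotr(e, 25);
      uint32_t ch = (e & f) ^ (~e & g);
      uint32_t t1 = hh + S1 + ch + k[i] + w[i];
      uint32_t S0 = rotr(a, 2) ^ rotr(a, 13) ^ rotr(a, 22);
      uint32_t maj = (a & b) ^ (a & c) ^ (b & c);
      uint32_t t2 = S0 + maj;
      hh = g; g = f; f = e; e = d + t1;
      d = c; c = b; b = a; a = t1 + t2;
    }
    h[0] += a; h[1] += b; h[2] += c; h[3] += d;
    h[4] += e; h[5] += f; h[6] += g; h[7] += hh;
  }

  void update(const uint8_t* p, size_t n) {
    bits += uint64_t(n) * 8;
    while (n > 0) {
      size_t take = std::min(n, size_t(64) - buflen);
      std::memcpy(buf + buflen, p, take);
      buflen += take;
      p += take;
      n -= take;
      if (buflen == 64) {
        block(buf);
        buflen = 0;
      }
    }
  }

  void final(uint8_t out[32]) {
    uint64_t msgbits = bits;
    uint8_t pad = 0x80;
    update(&pad, 1);
    uint8_t zero = 0;
    while (buflen != 56) update(&zero, 1);
    uint8_t len[8];
    for (int i = 0; i < 8; ++i) len[i] = uint8_t(msgbits >> (56 - 8 * i));
    // bypass update()'s bit accounting for the length field
    std::memcpy(buf + 56, len, 8);
    block(buf);
    for (int i = 0; i < 8; ++i) {
      out[4 * i] = uint8_t(h[i] >> 24);
      out[4 * i + 1] = uint8_t(h[i] >> 16);
      out[4 * i + 2] = uint8_t(h[i] >> 8);
      out[4 * i + 3] = uint8_t(h[i]);
    }
  }
};

void hmac(const std::string& key, const std::string& msg, uint8_t out[32]) {
  uint8_t k[64];
  std::memset(k, 0, 64);
  if (key.size() > 64) {
    Sha256 s;
    s.update(reinterpret_cast<const uint8_t*>(key.data()), key.size());
    uint8_t kd[32];
    s.final(kd);
    std::memcpy(k, kd, 32);
  } else {
    std::memcpy(k, key.data(), key.size());
  }
  uint8_t ipad[64], opad[64];
  for (int i = 0; i < 64; ++i) {
    ipad[i] = k[i] ^ 0x36;
    opad[i] = k[i] ^ 0x5c;
  }
  Sha256 inner;
  inner.update(ipad, 64);
  inner.update(reinterpret_cast<const uint8_t*>(msg.data()), msg.size());
  uint8_t ih[32];
  inner.final(ih);
  Sha256 outer;
  outer.update(opad, 64);
  outer.update(ih, 32);
  outer.final(out);
}

}  // namespace

//' @noRd
// [[Rcpp::export(name = ".hmac_sha256_hex")]]
Rcpp::CharacterVector hmac_sha256_hex(std::string key,
                                      Rcpp::CharacterVector msgs,
                                      int nchar_out = 16) {
  static const char* hexd = "0123456789abcdef";
  if (nchar_out < 1 || nchar_out > 64)
    Rcpp::stop("nchar_out must be between 1 and 64");
  R_xlen_t n = msgs.size();
  Rcpp::CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (msgs[i] == NA_STRING) {
      out[i] = NA_STRING;
      continue;
    }
    std::string m = Rcpp::as<std::string>(msgs[i]);
    uint8_t d[32];
    hmac(key, m, d);
    std::string hex(64, '0');
    for (int j = 0; j < 32; ++j) {
      hex[2 * j] = hexd[d[j] >> 4];
      hex[2 * j + 1] = hexd[d[j] & 0xf];
    }
    out[i] = hex.substr(0, nchar_out);
  }
  return out;
}
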