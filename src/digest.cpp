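// Keccak-256 (original Keccak padding 0x01, as used by Ethereum) and SHA-256.
// Compact single-message implementations; inputs are raw byte vectors.
#include <Rcpp.h>
#include <cstdint>
#include <cstring>

using Rcpp::RawVector;
using Rcpp::String;

// ---------------------------------------------------------------------------
// Keccak-f[1600]
// ---------------------------------------------------------------------------

static const uint64_t keccakf_rndc[24] = {
    0x0000000000000001ULL, 0x0000000000008082ULL, 0x800000000000808aULL,
    0x8000000080008000ULL, 0x000000000000808bULL, 0x0000000080000001ULL,
    0x8000000080008081ULL, 0x8000000000008009ULL, 0x000000000000008aULL,
    0x0000000000000088ULL, 0x0000000080008009ULL, 0x000000008000000aULL,
    0x000000008000808bULL, 0x800000000000008bULL, 0x8000000000008089ULL,
    0x8000000000008003ULL, 0x8000000000008002ULL, 0x8000000000000080ULL,
    0x000000000000800aULL, 0x800000008000000aULL, 0x8000000080008081ULL,
    0x8000000000008080ULL, 0x0000000080000001ULL, 0x8000000080008008ULL};

static const int keccakf_rotc[24] = {1,  3,  6,  10, 15, 21, 28, 36,
                                     45, 55, 2,  14, 27, 41, 56, 8,
                                     25, 43, 62, 18, 39, 61, 20, 44};

static const int keccakf_piln[24] = {10, 7,  11, 17, 18, 3, 5,  16,
                                     8,  21, 24, 4,  15, 23, 19, 13,
                                     12, 2,  20, 14, 22, 9,  6,  1};

static inline uint64_t rotl64(uint64_t x, int s) {
    return (x << s) | (x >> (64 - s));
}

static void keccakf(uint64_t st[25]) {
    uint64_t bc[5], t;
    for (int round = 0; round < 24; round++) {
        // theta
        for (int i = 0; i < 5; i++)
            bc[i] = st[i] ^ st[i + 5] ^ st[i + 10] ^ st[i + 15] ^ st[i + 20];
        for (int i = 0; i < 5; i++) {
            t = bc[(i + 4) % 5] ^ rotl64(bc[(i + 1) % 5], 1);
            for (int j = 0; j < 25; j += 5) st[j + i] ^= t;
        }
        // rho + pi
        t = st[1];
        for (int i = 0; i < 24; i++) {
            int j = keccakf_piln[i];
            bc[0] = st[j];
            st[j] = rotl64(t, keccakf_rotc[i]);
            t = bc[0];
        }
        // chi
        for (int j = 0; j < 25; j += 5) {
            for (int i = 0; i < 5; i++) bc[i] = st[j + i];
            for (int i = 0; i < 5; i++)
                st[j + i] ^= (~bc[(i + 1) % 5]) & bc[(i + 2) % 5];
        }
        st[0] ^= keccakf_rndc[round];
    }
}

static void keccak256_raw(const uint8_t *in, size_t inlen, uint8_t out[32]) {
    const size_t rate = 136;  // 1088-bit rate for 256-bit output
    uint64_t st[25];
    std::memset(st, 0, sizeof(st));
    uint8_t *state_bytes = reinterpret_cast<uint8_t *>(st);

    while (inlen >= rate) {
        for (size_t i = 0; i < rate; i++) state_bytes[i] ^= in[i];
        keccakf(st);
        in += rate;
        inlen -= rate;
    }
    // final partial block, multi-rate padding 0x01 ... 0x80
    for (size_t i = 0; i < inlen; i++) state_bytes[i] ^= in[i];
    state_bytes[inlen] ^= 0x01;
    state_bytes[rate - 1] ^= 0x80;
    keccakf(st);
    std::memcpy(out, state_bytes, 32);
}

// ---------------------------------------------------------------------------
// SHA-256
// ---------------------------------------------------------------------------

static const uint32_t sha256_k[64] = {
    0x428a2f98, 0x71374491, 0xb5c0fbcf, 0xe9b5dba5, 0x3956c25b, 0x59f111f1,
    0x923f82a4, 0xab1c5ed5, 0xd807aa98, 0x12835b01, 0x243185be, 0x550c7dc3,
    0x72be5d74, 0x80deb1fe, 0x9bdc06a7, 0xc19bf174, 0xe49b69c1, 0xefbe4786,
    0x0fc19dc6, 0x240ca1cc, 0x2de92c6f, 0x4a7484aa, 0x5cb0a9dc, 0x76f988da,
    0x983e5152, 0xa831c66d, 0xb00327c8, 0xbf597fc7, 0xc6e00bf3, 0xd5a79147,
    0x06ca6351, 0x14292967, 0x27b70a85, 0x2e1b2138, 0x4d2c6dfc, 0x53380d13,
    0x650a7354, 0x766a0abb, 0x81c2c92e, 0x92722c85, 0xa2bfe8a1, 0xa81a664b,
    0xc24b8b70, 0xc76c51a3, 0xd192e819, 0xd6990624, 0xf40e3585, 0x106aa070,
    0x19a4c116, 0x1e376c08, 0x2748774c, 0x34b0bcb5, 0x391c0cb3, 0x4ed8aa4a,
    0x5b9cca4f, 0x682e6ff3, 0x748f82ee, 0x78a5636f, 0x84c87814, 0x8cc70208,
    0x90befffa, 0xa4506ceb, 0xbef9a3f7, 0xc67178f2};

static inline uint32_t rotr32(uint32_t x, int s) {
    return (x >> s) | (x << (32 - s));
}

static void sha256_block(uint32_t h[8], const uint8_t *p) {
    uint32_t w[64];
    for (int i = 0; i < 16; i++)
        w[i] = (uint32_t(p[4 * i]) << 24) | (uint32_t(p[4 * i + 1]) << 16) |
               (uint32_t(p[4 * i + 2]) << 8) | uint32_t(p[4 * i + 3]);
    for (int i = 16; i < 64; i++) {
        uint32_t s0 = rotr32(w[i - 15], 7) ^ rotr32(w[i - 15], 18) ^ (w[i - 15] >> 3);
        uint32_t s1 = rotr32(w[i - 2], 17) ^ rotr32(w[i - 2], 19) ^ (w[i - 2] >> 10);
        w[i] = w[i - 16] + s0 + w[i - 7] + s1;
    }
    uint32_t a = h[0], b = h[1], c = h[2], d = h[3];
    uint32_t e = h[4], f = h[5], g = h[6], hh = h[7];
    for (int i = 0; i < 64; i++) {
        uint32_t S1 = rotr32(e, 6) ^ rotr32(e, 11) ^ rotr32(e, 25);
        uint32_t ch = (e & f) ^ ((~e) & g);
        uint32_t t1 = hh + S1 + ch + sha256_k[i] + w[i];
        uint32_t S0 = rotr32(a, 2) ^ rotr32(a, 13) ^ rotr32(a, 22);
        uint32_t maj = (a & b) ^ (a & c) ^ (b & c);
        uint32_t t2 = S0 + maj;
        hh = g; g = f; f = e; e = d + t1;
        d = c; c = b; b = a; a = t1 + t2;
    }
    h[0] += a; h[1] += b; h[2] += c; h[3] += d;
    h[4] += e; h[5] += f; h[6] += g; h[7] += hh;
}

static void sha256_raw(const uint8_t *in, size_t inlen, uint8_t out[32]) {
    uint32_t h[8] = {0x6a09e667, 0xbb67ae85, 0x3c6ef372, 0xa54ff53a,
                     0x510e527f, 0x9b05688c, 0x1f83d9ab, 0x5be0cd19};
    size_t full = inlen / 64;
    for (size_t i = 0; i < full; i++) sha256_block(h, in + 64 * i);

    uint8_t tail[128];
    size_t rem = inlen - 64 * full;
    std::memcpy(tail, in + 64 * full, rem);
    tail[rem] = 0x80;
    size_t padded = (rem + 1 + 8 <= 64) ? 64 : 128;
    std::memset(tail + rem + 1, 0, padded - rem - 1 - 8);
    uint64_t bits = uint64_t(inlen) * 8;
    for (int i = 0; i < 8; i++)
        tail[padded - 1 - i] = uint8_t((bits >> (8 * i)) & 0xff);
    sha256_block(h, tail);
    if (padded == 128) sha256_block(h, tail + 64);

    for (int i = 0; i < 8; i++) {
        out[4 * i] = uint8_t(h[i] >> 24);
        out[4 * i + 1] = uint8_t(h[i] >> 16);
        out[4 * i + 2] = uint8_t(h[i] >> 8);
        out[4 * i + 3] = uint8_t(h[i]);
    }
}

// ---------------------------------------------------------------------------

static String to_hex(const uint8_t d[32]) {
    static const char *hex = "0123456789abcdef";
    char buf[65];
    for (int i = 0; i < 32; i++) {
        buf[2 * i] = hex[d[i] >> 4];
        buf[2 * i + 1] = hex[d[i] & 0x0f];
    }
    buf[64] = '\0';
    return String(buf);
}

//' @noRd
// [[Rcpp::export(name = ".digest_hex")]]
String digest_hex(RawVector bytes, std::string algorithm) {
    uint8_t out[32];
    const uint8_t *p = bytes.length() ? &bytes[0] : nullptr;
    if (algorithm == "keccak256")
        keccak256_raw(p, bytes.length(), out);
    else if (algorithm == "sha256")
        sha256_raw(p, bytes.length(), out);
    else
        Rcpp::stop("unknown digest algorithm: %s", algorithm.c_str());
    return to_hex(out);
}
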