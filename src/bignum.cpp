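// Arbitrary-precision unsigned integer arithmetic for the prime-order
// subgroup commitment: hex I/O, schoolbook multiply, binary-shift modular
// reduction, square-and-multiply modexp, Miller-Rabin primality.
// Numbers are little-endian vectors of 64-bit limbs.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>

using std::vector;
using std::string;

typedef vector<uint64_t> BN;
typedef unsigned __int128 u128;

static void bn_trim(BN &a) {
  while (a.size() > 1 && a.back() == 0) a.pop_back();
}

static bool bn_is_zero(const BN &a) {
  return a.size() == 1 && a[0] == 0;
}

static int bn_cmp(const BN &a, const BN &b) {
  if (a.size() != b.size()) return a.size() < b.size() ? -1 : 1;
  for (size_t i = a.size(); i-- > 0;) {
    if (a[i] != b[i]) return a[i] < b[i] ? -1 : 1;
  }
  return 0;
}

static BN bn_from_hex(const string &h) {
  BN a(1, 0);
  size_t start = 0;
  if (h.size() >= 2 && h[0] == '0' && (h[1] == 'x' || h[1] == 'X')) start = 2;
  size_t nd = h.size() - start;
  if (nd == 0) Rcpp::stop("empty hex string");
  size_t nlimb = (nd + 15) / 16;
  a.assign(nlimb, 0);
  size_t limb = 0, shift = 0;
  for (size_t i = h.size(); i-- > start;) {
    char c = h[i];
    uint64_t v;
    if (c >= '0' && c <= '9') v = c - '0';
    else if (c >= 'a' && c <= 'f') v = 10 + c - 'a';
    else if (c >= 'A' && c <= 'F') v = 10 + c - 'A';
    else Rcpp::stop("invalid hex digit");
    a[limb] |= v << shift;
    shift += 4;
    if (shift == 64) { shift = 0; ++limb; }
  }
  bn_trim(a);
  return a;
}

static string bn_to_hex(const BN &a) {
  static const char *dig = "0123456789abcdef";
  string s;
  for (size_t i = a.size(); i-- > 0;) {
    for (int nib = 15; nib >= 0; --nib) {
      s.push_back(dig[(a[i] >> (4 * nib)) & 0xF]);
    }
  }
  size_t pos = s.find_first_not_of('0');
  if (pos == string::npos) return "0";
  return s.substr(pos);
}

static int bn_bitlen(const BN &a) {
  if (bn_is_zero(a)) return 0;
  uint64_t top = a.back();
  int b = 0;
  while (top) { ++b; top >>= 1; }
  return (int)(64 * (a.size() - 1)) + b;
}

static BN bn_add(const BN &a, const BN &b) {
  const BN &x = a.size() >= b.size() ? a : b;
  const BN &y = a.size() >= b.size() ? b : a;
  BN r(x.size() + 1, 0);
  u128 carry = 0;
  for (size_t i = 0; i < x.size(); ++i) {
    u128 s = (u128)x[i] + (i < y.size() ? y[i] : 0) + carry;
    r[i] = (uint64_t)s;
    carry = s >> 64;
  }
  r[x.size()] = (uint64_t)carry;
  bn_trim(r);
  return r;
}

// requires a >= b
static BN bn_sub(const BN &a, const BN &b) {
  BN r(a.size(), 0);
  uint64_t borrow = 0;
  for (size_t i = 0; i < a.size(); ++i) {
    uint64_t bi = i < b.size() ? b[i] : 0;
    uint64_t ai = a[i];
    uint64_t d = ai - bi - borrow;
    borrow = (ai < bi + (u128)borrow) ? 1 : 0;
    r[i] = d;
  }
  bn_trim(r);
  return r;
}

static BN bn_mul(const BN &a, const BN &b) {
  BN r(a.size() + b.size(), 0);
  for (size_t i = 0; i < a.size(); ++i) {
    u128 carry = 0;
    for (size_t j = 0; j < b.size(); ++j) {
      u128 cur = (u128)a[i] * b[j] + r[i + j] + carry;
      r[i + j] = (uint64_t)cur;
      carry = cur >> 64;
    }
    r[i + b.size()] += (uint64_t)carry;
  }
  bn_trim(r);
  return r;
}

static BN bn_shl(const BN &a, int bits) {
  int limbs = bits / 64, rem = bits % 64;
  BN r(a.size() + limbs + 1, 0);
  for (size_t i = 0; i < a.size(); ++i) {
    r[i + limbs] |= a[i] << rem;
    if (rem) r[i + limbs + 1] |= a[i] >> (64 - rem);
  }
  bn_trim(r);
  return r;
}

// a mod m by aligned shift-and-subtract
static BN bn_mod(const BN &a, const BN &m) {
  if (bn_is_zero(m)) Rcpp::stop("modulus is zero");
  if (bn_cmp(a, m) < 0) return a;
  BN r = a;
  int shift = bn_bitlen(a) - bn_bitlen(m);
  BN msh = bn_shl(m, shift);
  for (; shift >= 0; --shift) {
    if (bn_cmp(r, msh) >= 0) r = bn_sub(r, msh);
    // shift msh right one bit
    for (size_t i = 0; i < msh.size(); ++i) {
      msh[i] >>= 1;
      if (i + 1 < msh.size()) msh[i] |= msh[i + 1] << 63;
    }
    bn_trim(msh);
  }
  return r;
}

static BN bn_mulmod(const BN &a, const BN &b, const BN &m) {
  return bn_mod(bn_mul(a, b), m);
}

// Montgomery arithmetic (CIOS) for odd moduli: keeps modexp free of
// per-step division. R = 2^(64 s) with s = limb count of m.
struct Mont {
  BN m;
  size_t s;
  uint64_t m0inv; // -m[0]^-1 mod 2^64
  Mont(const BN &mod) : m(mod), s(mod.size()) {
    uint64_t x = 1, m0 = m[0];
    for (int i = 0; i < 6; ++i) x *= 2 - m0 * x; // Newton: x = m0^-1 mod 2^64
    m0inv = ~x + 1; // -x
  }
  BN mul(const BN &a, const BN &b) const {
    std::vector<uint64_t> t(s + 2, 0);
    for (size_t i = 0; i < s; ++i) {
      uint64_t ai = i < a.size() ? a[i] : 0;
      u128 carry = 0;
      for (size_t j = 0; j < s; ++j) {
        u128 cur = (u128)ai * (j < b.size() ? b[j] : 0) + t[j] + carry;
        t[j] = (uint64_t)cur;
        carry = cur >> 64;
      }
      u128 cur = (u128)t[s] + carry;
      t[s] = (uint64_t)cur;
      t[s + 1] = (uint64_t)(cur >> 64);
      uint64_t u = t[0] * m0inv;
      carry = 0;
      for (size_t j = 0; j < s; ++j) {
        u128 c2 = (u128)u * m[j] + t[j] + carry;
        t[j] = (uint64_t)c2;
        carry = c2 >> 64;
      }
      cur = (u128)t[s] + carry;
      t[s] = (uint64_t)cur;
      t[s + 1] += (uint64_t)(cur >> 64);
      for (size_t j = 0; j <= s; ++j) t[j] = t[j + 1];
      t[s + 1] = 0;
    }
    BN r(t.begin(), t.begin() + s + 1);
    bn_trim(r);
    if (bn_cmp(r, m) >= 0) r = bn_sub(r, m);
    return r;
  }
  BN to_mont(const BN &a) const { return bn_mod(bn_shl(a, 64 * (int)s), m); }
  BN from_mont(const BN &a) const { return mul(a, BN(1, 1)); }
};

static BN bn_modexp(const BN &base, const BN &exp, const BN &m) {
  BN one(1, 1);
  if (bn_cmp(m, one) == 0) return BN(1, 0); // mod 1
  int nb = bn_bitlen(exp);
  if (m[0] & 1) { // odd modulus: Montgomery ladder
    Mont mg(m);
    BN b = mg.to_mont(bn_mod(base, m));
    BN result = mg.to_mont(one);
    for (int i = nb - 1; i >= 0; --i) {
      result = mg.mul(result, result);
      if ((exp[i / 64] >> (i % 64)) & 1) result = mg.mul(result, b);
    }
    return mg.from_mont(result);
  }
  BN b = bn_mod(base, m);
  BN result = one;
  for (int i = nb - 1; i >= 0; --i) {
    result = bn_mulmod(result, result, m);
    if ((exp[i / 64] >> (i % 64)) & 1) result = bn_mulmod(result, b, m);
  }
  return result;
}

// splitmix64: deterministic PRNG for Miller-Rabin bases
struct SplitMix {
  uint64_t s;
  explicit SplitMix(uint64_t seed) : s(seed) {}
  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
};

static const uint32_t SMALL_PRIMES[] = {
  2, 3, 5, 7, 11, 13, 17, 19, 23, 29, 31, 37, 41, 43, 47, 53, 59, 61, 67,
  71, 73, 79, 83, 89, 97, 101, 103, 107, 109, 113, 127, 131, 137, 139, 149,
  151, 157, 163, 167, 173, 179, 181, 191, 193, 197, 199, 211, 223, 227, 229,
  233, 239, 241, 251
};

static uint64_t bn_mod_small(const BN &a, uint64_t m) {
  u128 r = 0;
  for (size_t i = a.size(); i-- > 0;) r = ((r << 64) | a[i]) % m;
  return (uint64_t)r;
}

static bool miller_rabin(const BN &n, int rounds, uint64_t seed) {
  BN one(1, 1), two(1, 2);
  if (bn_cmp(n, two) < 0) return false;
  if (bn_cmp(n, two) == 0) return true;
  if ((n[0] & 1) == 0) return false;
  for (uint32_t sp : SMALL_PRIMES) {
    BN spb(1, sp);
    if (bn_cmp(n, spb) == 0) return true;
    if (bn_mod_small(n, sp) == 0) return false;
  }
  BN nm1 = bn_sub(n, one);
  // nm1 = d * 2^s with d odd
  BN d = nm1;
  int s = 0;
  while ((d[0] & 1) == 0) {
    for (size_t i = 0; i < d.size(); ++i) {
      d[i] >>= 1;
      if (i + 1 < d.size()) d[i] |= d[i + 1] << 63;
    }
    bn_trim(d);
    ++s;
  }
  SplitMix rng(seed);
  int nlimb = (int)n.size();
  for (int r = 0; r < rounds; ++r) {
    // random base in [2, n-2]
    BN a(nlimb, 0);
    for (int i = 0; i < nlimb; ++i) a[i] = rng.next();
    bn_trim(a);
    a = bn_mod(a, bn_sub(nm1, two));
    a = bn_add(a, two); // 2 <= a <= n-2
    BN x = bn_modexp(a, d, n);
    if (bn_cmp(x, one) == 0 || bn_cmp(x, nm1) == 0) continue;
    bool composite = true;
    for (int i = 0; i < s - 1; ++i) {
      x = bn_mulmod(x, x, n);
      if (bn_cmp(x, nm1) == 0) { composite = false; break; }
    }
    if (composite) return false;
  }
  return true;
}

// [[Rcpp::export(name = ".bnModExp")]]
std::string bnModExp_cpp(std::string base, std::string exp, std::string mod) {
  return bn_to_hex(bn_modexp(bn_from_hex(base), bn_from_hex(exp), bn_from_hex(mod)));
}

// [[Rcpp::export(name = ".bnMulMod")]]
std::string bnMulMod_cpp(std::string a, std::string b, std::string mod) {
  return bn_to_hex(bn_mulmod(bn_from_hex(a), bn_from_hex(b), bn_from_hex(mod)));
}

// [[Rcpp::export(name = ".bnMod")]]
std::string bnMod_cpp(std::string a, std::string mod) {
  return bn_to_hex(bn_mod(bn_from_hex(a), bn_from_hex(mod)));
}

// [[Rcpp::export(name = ".bnAdd")]]
std::string bnAdd_cpp(std::string a, std::string b) {
  return bn_to_hex(bn_add(bn_from_hex(a), bn_from_hex(b)));
}

// [[Rcpp::export(name = ".bnSub")]]
std::string bnSub_cpp(std::string a, std::string b) {
  BN x = bn_from_hex(a), y = bn_from_hex(b);
  if (bn_cmp(x, y) < 0) Rcpp::stop("bnSub: negative result");
  return bn_to_hex(bn_sub(x, y));
}

// [[Rcpp::export(name = ".bnMul")]]
std::string bnMul_cpp(std::string a, std::string b) {
  return bn_to_hex(bn_mul(bn_from_hex(a), bn_from_hex(b)));
}

// [[Rcpp::export(name = ".bnCmp")]]
int bnCmp_cpp(std::string a, std::string b) {
  return bn_cmp(bn_from_hex(a), bn_from_hex(b));
}

// [[Rcpp::export(name = ".bnBitLength")]]
int bnBitLength_cpp(std::string a) {
  return bn_bitlen(bn_from_hex(a));
}

// [[Rcpp::export(name = ".bnIsPrime")]]
bool bnIsPrime_cpp(std::string n, int rounds, double seed) {
  return miller_rabin(bn_from_hex(n), rounds, (uint64_t)seed);
}
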