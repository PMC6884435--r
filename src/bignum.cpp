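// Exact signed integer arithmetic on decimal strings, plus prime-field
// helpers and the deterministic dealer randomness used by the MPC layer.
// Values are carried between R and C++ as decimal character vectors; all
// arithmetic is exact at any size (the field is ~2^127, well beyond doubles).
#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <vector>

using namespace Rcpp;

static const uint32_t BASE = 1000000000u; // base 1e9, little-endian limbs

struct BN {
  int sign = 0;                // -1, 0, 1; d empty iff sign == 0
  std::vector<uint32_t> d;
};

static void trim(BN &a) {
  while (!a.d.empty() && a.d.back() == 0) a.d.pop_back();
  if (a.d.empty()) a.sign = 0;
  else if (a.sign == 0) a.sign = 1;
}

static BN parse_bn(const std::string &s) {
  BN r;
  size_t i = 0;
  int sg = 1;
  if (i < s.size() && (s[i] == '-' || s[i] == '+')) {
    if (s[i] == '-') sg = -1;
    ++i;
  }
  if (i >= s.size()) stop("invalid integer string: '%s'", s.c_str());
  for (size_t j = i; j < s.size(); ++j)
    if (s[j] < '0' || s[j] > '9') stop("invalid integer string: '%s'", s.c_str());
  while (i < s.size() - 1 && s[i] == '0') ++i;
  size_t end = s.size();
  r.d.reserve((end - i + 8) / 9);
  while (end > i) {
    size_t beg = (end - i > 9) ? end - 9 : i;
    uint32_t limb = 0;
    for (size_t j = beg; j < end; ++j) limb = limb * 10u + (uint32_t)(s[j] - '0');
    r.d.push_back(limb);
    end = beg;
  }
  trim(r);
  r.sign = r.d.empty() ? 0 : sg;
  return r;
}

static std::string fmt_bn(const BN &a) {
  if (a.sign == 0) return "0";
  std::string out;
  if (a.sign < 0) out.push_back('-');
  char buf[16];
  snprintf(buf, sizeof(buf), "%u", a.d.back());
  out += buf;
  for (size_t i = a.d.size() - 1; i-- > 0;) {
    snprintf(buf, sizeof(buf), "%09u", a.d[i]);
    out += buf;
  }
  return out;
}

static int cmp_abs(const BN &a, const BN &b) {
  if (a.d.size() != b.d.size()) return a.d.size() < b.d.size() ? -1 : 1;
  for (size_t i = a.d.size(); i-- > 0;) {
    if (a.d[i] != b.d[i]) return a.d[i] < b.d[i] ? -1 : 1;
  }
  return 0;
}

static BN add_abs(const BN &a, const BN &b) {
  BN r;
  r.sign = 1;
  size_t n = std::max(a.d.size(), b.d.size());
  r.d.assign(n + 1, 0);
  uint64_t carry = 0;
  for (size_t i = 0; i < n; ++i) {
    uint64_t s = carry;
    if (i < a.d.size()) s += a.d[i];
    if (i < b.d.size()) s += b.d[i];
    r.d[i] = (uint32_t)(s % BASE);
    carry = s / BASE;
  }
  r.d[n] = (uint32_t)carry;
  trim(r);
  return r;
}

// requires |a| >= |b|
static BN sub_abs(const BN &a, const BN &b) {
  BN r;
  r.sign = 1;
  r.d.assign(a.d.size(), 0);
  int64_t borrow = 0;
  for (size_t i = 0; i < a.d.size(); ++i) {
    int64_t s = (int64_t)a.d[i] - borrow - (i < b.d.size() ? (int64_t)b.d[i] : 0);
    if (s < 0) { s += BASE; borrow = 1; } else borrow = 0;
    r.d[i] = (uint32_t)s;
  }
  trim(r);
  return r;
}

static BN add_bn(const BN &a, const BN &b) {
  if (a.sign == 0) return b;
  if (b.sign == 0) return a;
  if (a.sign == b.sign) {
    BN r = add_abs(a, b);
    r.sign = a.sign;
    trim(r);
    return r;
  }
  int c = cmp_abs(a, b);
  if (c == 0) return BN();
  BN r = (c > 0) ? sub_abs(a, b) : sub_abs(b, a);
  r.sign = (c > 0) ? a.sign : b.sign;
  trim(r);
  return r;
}

static BN neg_bn(const BN &a) {
  BN r = a;
  r.sign = -r.sign;
  return r;
}

static BN sub_bn(const BN &a, const BN &b) { return add_bn(a, neg_bn(b)); }

static BN mul_bn(const BN &a, const BN &b) {
  if (a.sign == 0 || b.sign == 0) return BN();
  BN r;
  r.sign = a.sign * b.sign;
  r.d.assign(a.d.size() + b.d.size(), 0);
  for (size_t i = 0; i < a.d.size(); ++i) {
    uint64_t carry = 0;
    uint64_t ai = a.d[i];
    for (size_t j = 0; j < b.d.size(); ++j) {
      uint64_t cur = r.d[i + j] + ai * b.d[j] + carry;
      r.d[i + j] = (uint32_t)(cur % BASE);
      carry = cur / BASE;
    }
    size_t j = b.d.size();
    while (carry) {
      uint64_t cur = r.d[i + j] + carry;
      r.d[i + j] = (uint32_t)(cur % BASE);
      carry = cur / BASE;
      ++j;
    }
  }
  trim(r);
  return r;
}

static BN mul_small(const BN &a, uint32_t m) {
  if (a.sign == 0 || m == 0) return BN();
  BN r;
  r.sign = a.sign;
  r.d.assign(a.d.size() + 1, 0);
  uint64_t carry = 0;
  for (size_t i = 0; i < a.d.size(); ++i) {
    uint64_t cur = (uint64_t)a.d[i] * m + carry;
    r.d[i] = (uint32_t)(cur % BASE);
    carry = cur / BASE;
  }
  r.d[a.d.size()] = (uint32_t)carry;
  trim(r);
  return r;
}

static uint64_t to_u64(const BN &a) { // valid when a fits (<= 2 limbs ~ 1e18)
  uint64_t v = 0;
  for (size_t i = a.d.size(); i-- > 0;) v = v * BASE + a.d[i];
  return v;
}

static BN from_u64(uint64_t v) {
  BN r;
  while (v) {
    r.d.push_back((uint32_t)(v % BASE));
    v /= BASE;
  }
  trim(r);
  return r;
}

// |u| / |v| with remainder; signs handled by callers
static void divmod_abs(const BN &u, const BN &v, BN &q, BN &r) {
  if (v.sign == 0) stop("division by zero");
  if (cmp_abs(u, v) < 0) {
    q = BN();
    r = u;
    r.sign = r.d.empty() ? 0 : 1;
    return;
  }
  if (u.d.size() <= 2 && v.d.size() <= 2) { // fast native path
    uint64_t uu = to_u64(u), vv = to_u64(v);
    q = from_u64(uu / vv);
    r = from_u64(uu % vv);
    return;
  }
  if (v.d.size() == 1) { // short division by a single limb
    uint32_t vv = v.d[0];
    q.d.assign(u.d.size(), 0);
    q.sign = 1;
    uint64_t rem64 = 0;
    for (size_t i = u.d.size(); i-- > 0;) {
      uint64_t cur = rem64 * BASE + u.d[i];
      q.d[i] = (uint32_t)(cur / vv);
      rem64 = cur % vv;
    }
    trim(q);
    r = from_u64(rem64);
    return;
  }
  size_t n = u.d.size(), m = v.d.size();
  q.d.assign(n, 0);
  q.sign = 1;
  // approximate value of the top (up to) 3 limbs as long double
  auto top3 = [](const BN &x) -> long double {
    long double a = 0;
    size_t l = x.d.size();
    size_t take = std::min<size_t>(l, 3);
    for (size_t t = 0; t < take; ++t) a = a * BASE + x.d[l - 1 - t];
    return a;
  };
  long double av = top3(v);
  BN rem; // running remainder; invariant: rem < v before each append
  for (size_t i = n; i-- > 0;) {
    // rem = rem * BASE + u.d[i]  (so rem < v * BASE, digit fits in [0, BASE))
    rem.d.insert(rem.d.begin(), u.d[i]);
    trim(rem);
    if (cmp_abs(rem, v) < 0) continue;
    size_t rl = rem.d.size();
    long double est = top3(rem) / av;
    // top3 truncates only limbs beyond the third; align the magnitudes
    int e = (int)(rl > 3 ? rl - 3 : 0) - (int)(m > 3 ? m - 3 : 0);
    if (e >= 1) est *= (long double)BASE;
    if (est > (long double)(BASE - 1)) est = (long double)(BASE - 1);
    if (est < 1) est = 1;
    uint32_t t = (uint32_t)est;
    BN pr = mul_small(v, t);
    while (t > 0 && cmp_abs(pr, rem) > 0) { --t; pr = mul_small(v, t); }
    while (t < BASE - 1) {
      BN p2 = mul_small(v, t + 1);
      if (cmp_abs(p2, rem) <= 0) { ++t; pr = p2; } else break;
    }
    if (t) {
      rem = sub_abs(rem, pr);
      q.d[i] = t;
    }
  }
  trim(q);
  r = rem;
  trim(r);
}

// Euclidean division: a = q*b + r with remainder r always in [0, |b|)
static void divmod_floor(const BN &a, const BN &b, BN &q, BN &r) {
  BN qa, ra;
  divmod_abs(a, b, qa, ra);
  bool neg = (a.sign < 0);
  if (!neg) {
    q = qa;
    if (b.sign < 0) q.sign = -q.sign;
    r = ra;
  } else {
    if (ra.sign == 0) {
      q = qa;
      q.sign = (b.sign < 0) ? qa.sign : -qa.sign;
      r = BN();
    } else {
      BN one;
      one.sign = 1;
      one.d.push_back(1);
      q = add_abs(qa, one);
      q.sign = (b.sign < 0) ? 1 : -1;
      BN babs = b;
      babs.sign = 1;
      r = sub_abs(babs, ra);
    }
  }
  trim(q);
  trim(r);
}

static BN mod_pos(const BN &a, const BN &p) { // a mod p in [0, p)
  BN q, r;
  divmod_floor(a, p, q, r);
  return r;
}

// ---- Barrett reduction for a fixed modulus -------------------------------
// mu = floor(BASE^(2k) / p) precomputed once per exported call; reduces any
// non-negative x < BASE^(2k) with two multiplications and <= 2 corrections.

static BN shr_limbs(const BN &x, size_t s) {
  if (x.d.size() <= s) return BN();
  BN r;
  r.sign = 1;
  r.d.assign(x.d.begin() + s, x.d.end());
  trim(r);
  return r;
}

static BN low_limbs(const BN &x, size_t s) {
  BN r;
  r.sign = 1;
  size_t t = std::min(s, x.d.size());
  r.d.assign(x.d.begin(), x.d.begin() + t);
  trim(r);
  return r;
}

struct Barrett {
  BN p;
  size_t k;
  BN mu;
  BN half; // (p-1)/2
  explicit Barrett(const BN &pp) : p(pp), k(pp.d.size()) {
    BN b2k;
    b2k.sign = 1;
    b2k.d.assign(2 * k, 0);
    b2k.d.push_back(1);
    BN r;
    divmod_abs(b2k, p, mu, r);
    BN one; one.sign = 1; one.d.push_back(1);
    BN two; two.sign = 1; two.d.push_back(2);
    divmod_abs(sub_abs(p, one), two, half, r);
  }
  // x >= 0
  BN reduce(const BN &x) const {
    if (x.sign == 0 || cmp_abs(x, p) < 0) return x;
    if (x.d.size() > 2 * k) {
      BN q, r;
      divmod_abs(x, p, q, r);
      return r;
    }
    BN q1 = shr_limbs(x, k - 1);
    BN q3 = shr_limbs(mul_bn(q1, mu), k + 1);
    BN r1 = low_limbs(x, k + 1);
    BN r2 = low_limbs(mul_bn(q3, p), k + 1);
    BN r;
    if (cmp_abs(r1, r2) >= 0) r = sub_abs(r1, r2);
    else {
      BN bk1;
      bk1.sign = 1;
      bk1.d.assign(k + 1, 0);
      bk1.d.push_back(1);
      r = sub_abs(add_abs(r1, bk1), r2);
    }
    while (r.sign != 0 && cmp_abs(r, p) >= 0) r = sub_abs(r, p);
    r.sign = r.d.empty() ? 0 : 1;
    return r;
  }
  // any sign, |x| < BASE^(2k)
  BN reduce_signed(const BN &x) const {
    if (x.sign >= 0) return reduce(x);
    BN ax = x;
    ax.sign = 1;
    BN r = reduce(ax);
    if (r.sign == 0) return r;
    return sub_abs(p, r);
  }
  // for a, b already in [0, p)
  BN add_mod(const BN &a, const BN &b) const {
    BN s = add_abs_or_zero(a, b);
    if (cmp_abs(s, p) >= 0) {
      s = sub_abs(s, p);
      if (cmp_abs(s, p) >= 0) s = reduce(s);
    }
    s.sign = s.d.empty() ? 0 : 1;
    return s;
  }
  BN sub_mod(const BN &a, const BN &b) const {
    BN s;
    if (cmp_abs(a, b) >= 0) s = sub_abs(a, b);
    else s = sub_abs(add_abs(a, p), b);
    if (cmp_abs(s, p) >= 0) s = reduce(s);
    s.sign = s.d.empty() ? 0 : 1;
    return s;
  }
  BN mul_mod(const BN &a, const BN &b) const { return reduce(mul_bn(a, b)); }
  static BN add_abs_or_zero(const BN &a, const BN &b) {
    if (a.sign == 0) return b;
    if (b.sign == 0) return a;
    return add_abs(a, b);
  }
};

static BN gcd_bn(BN a, BN b) {
  a.sign = a.d.empty() ? 0 : 1;
  b.sign = b.d.empty() ? 0 : 1;
  while (b.sign != 0) {
    BN q, r;
    divmod_abs(a, b, q, r);
    a = b;
    b = r;
  }
  return a;
}

static int bitlen_bn(BN a) {
  int n = 0;
  a.sign = a.d.empty() ? 0 : 1;
  // count bits by halving in base 1e9
  while (a.sign != 0) {
    ++n;
    // a /= 2
    uint32_t carry = 0;
    for (size_t i = a.d.size(); i-- > 0;) {
      uint64_t cur = (uint64_t)carry * BASE + a.d[i];
      a.d[i] = (uint32_t)(cur >> 1);
      carry = (uint32_t)(cur & 1);
    }
    trim(a);
  }
  return n;
}

static BN two_pow_bn(int k) {
  BN r;
  r.sign = 1;
  r.d.push_back(1);
  BN two;
  two.sign = 1;
  two.d.push_back(2);
  for (int i = 0; i < k; ++i) r = mul_bn(r, two); // k <= ~200, fine
  return r;
}

static inline const char *cstr(const CharacterVector &x, R_xlen_t i, R_xlen_t n) {
  return CHAR(STRING_ELT(x, i % n));
}

typedef BN (*binop)(const BN &, const BN &);

static CharacterVector map2(const CharacterVector &a, const CharacterVector &b, binop f) {
  R_xlen_t na = a.size(), nb = b.size();
  R_xlen_t n = std::max(na, nb);
  if (na == 0 || nb == 0) return CharacterVector(0);
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    BN r = f(parse_bn(cstr(a, i, na)), parse_bn(cstr(b, i, nb)));
    out[i] = fmt_bn(r);
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector bn_add(CharacterVector a, CharacterVector b) { return map2(a, b, add_bn); }

// [[Rcpp::export]]
CharacterVector bn_sub(CharacterVector a, CharacterVector b) { return map2(a, b, sub_bn); }

// [[Rcpp::export]]
CharacterVector bn_mul(CharacterVector a, CharacterVector b) { return map2(a, b, mul_bn); }

// [[Rcpp::export]]
CharacterVector bn_neg(CharacterVector a) {
  R_xlen_t n = a.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = fmt_bn(neg_bn(parse_bn(cstr(a, i, n))));
  return out;
}

// [[Rcpp::export]]
IntegerVector bn_cmp(CharacterVector a, CharacterVector b) {
  R_xlen_t na = a.size(), nb = b.size();
  R_xlen_t n = std::max(na, nb);
  if (na == 0 || nb == 0) return IntegerVector(0);
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    BN x = parse_bn(cstr(a, i, na)), y = parse_bn(cstr(b, i, nb));
    BN d = sub_bn(x, y);
    out[i] = d.sign;
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector bn_div(CharacterVector a, CharacterVector b) { // Euclidean quotient
  R_xlen_t na = a.size(), nb = b.size();
  R_xlen_t n = std::max(na, nb);
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    BN q, r;
    divmod_floor(parse_bn(cstr(a, i, na)), parse_bn(cstr(b, i, nb)), q, r);
    out[i] = fmt_bn(q);
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector bn_mod(CharacterVector a, CharacterVector b) { // Euclidean mod, in [0, |b|)
  R_xlen_t na = a.size(), nb = b.size();
  R_xlen_t n = std::max(na, nb);
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    BN q, r;
    divmod_floor(parse_bn(cstr(a, i, na)), parse_bn(cstr(b, i, nb)), q, r);
    out[i] = fmt_bn(r);
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector bn_gcd(CharacterVector a, CharacterVector b) {
  R_xlen_t na = a.size(), nb = b.size();
  R_xlen_t n = std::max(na, nb);
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = fmt_bn(gcd_bn(parse_bn(cstr(a, i, na)), parse_bn(cstr(b, i, nb))));
  return out;
}

// [[Rcpp::export]]
String bn_sum(CharacterVector a) {
  BN acc;
  for (R_xlen_t i = 0; i < a.size(); ++i) acc = add_bn(acc, parse_bn(CHAR(STRING_ELT(a, i))));
  return fmt_bn(acc);
}

// [[Rcpp::export]]
CharacterVector bn_grouped_sum(CharacterVector a, IntegerVector group, int ngroups) {
  std::vector<BN> acc(ngroups);
  if (a.size() != group.size()) stop("length mismatch in bn_grouped_sum");
  for (R_xlen_t i = 0; i < a.size(); ++i) {
    int g = group[i];
    if (g < 1 || g > ngroups) stop("group index out of range");
    acc[g - 1] = add_bn(acc[g - 1], parse_bn(CHAR(STRING_ELT(a, i))));
  }
  CharacterVector out(ngroups);
  for (int g = 0; g < ngroups; ++g) out[g] = fmt_bn(acc[g]);
  return out;
}

// [[Rcpp::export]]
CharacterVector bn_two_pow(IntegerVector k) {
  CharacterVector out(k.size());
  for (R_xlen_t i = 0; i < k.size(); ++i) {
    if (k[i] < 0) stop("negative exponent");
    out[i] = fmt_bn(two_pow_bn(k[i]));
  }
  return out;
}

// [[Rcpp::export]]
int bn_bitlen(String a) { return bitlen_bn(parse_bn(a.get_cstring())); }

// bits of non-negative a, little-endian, a < 2^nbits
// [[Rcpp::export]]
IntegerMatrix bn_to_bits(CharacterVector a, int nbits) {
  R_xlen_t n = a.size();
  IntegerMatrix out(n, nbits);
  for (R_xlen_t i = 0; i < n; ++i) {
    BN x = parse_bn(CHAR(STRING_ELT(a, i)));
    if (x.sign < 0) stop("bn_to_bits: negative value");
    for (int b = 0; b < nbits; ++b) {
      uint32_t carry = 0;
      int bit = 0;
      if (x.sign != 0) {
        bit = x.d[0] & 1;
        for (size_t j = x.d.size(); j-- > 0;) {
          uint64_t cur = (uint64_t)carry * BASE + x.d[j];
          x.d[j] = (uint32_t)(cur >> 1);
          carry = (uint32_t)(cur & 1);
        }
        bit = (int)carry;
        trim(x);
      }
      out(i, b) = bit;
    }
    if (x.sign != 0) stop("bn_to_bits: value does not fit in %d bits", nbits);
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector bn_from_bits(IntegerMatrix bits) { // little-endian columns
  R_xlen_t n = bits.nrow();
  int m = bits.ncol();
  CharacterVector out(n);
  BN two;
  two.sign = 1;
  two.d.push_back(2);
  for (R_xlen_t i = 0; i < n; ++i) {
    BN v;
    for (int b = m; b-- > 0;) {
      v = mul_bn(v, two);
      if (bits(i, b)) {
        BN one;
        one.sign = 1;
        one.d.push_back(1);
        v = add_bn(v, one);
      }
    }
    out[i] = fmt_bn(v);
  }
  return out;
}

// ---- prime field helpers -------------------------------------------------

// [[Rcpp::export]]
CharacterVector fp_norm(CharacterVector a, String p) {
  Barrett M(parse_bn(p.get_cstring()));
  R_xlen_t n = a.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    BN x = parse_bn(cstr(a, i, n));
    if (x.sign >= 0 && x.d.size() <= 2 * M.k) out[i] = fmt_bn(M.reduce(x));
    else if (x.sign < 0 && x.d.size() <= 2 * M.k) out[i] = fmt_bn(M.reduce_signed(x));
    else out[i] = fmt_bn(mod_pos(x, M.p));
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector fp_add(CharacterVector a, CharacterVector b, String p) {
  Barrett M(parse_bn(p.get_cstring()));
  R_xlen_t na = a.size(), nb = b.size();
  R_xlen_t n = std::max(na, nb);
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    out[i] = fmt_bn(M.add_mod(parse_bn(cstr(a, i, na)), parse_bn(cstr(b, i, nb))));
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector fp_sub(CharacterVector a, CharacterVector b, String p) {
  Barrett M(parse_bn(p.get_cstring()));
  R_xlen_t na = a.size(), nb = b.size();
  R_xlen_t n = std::max(na, nb);
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    out[i] = fmt_bn(M.sub_mod(parse_bn(cstr(a, i, na)), parse_bn(cstr(b, i, nb))));
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector fp_mul(CharacterVector a, CharacterVector b, String p) {
  Barrett M(parse_bn(p.get_cstring()));
  R_xlen_t na = a.size(), nb = b.size();
  R_xlen_t n = std::max(na, nb);
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    out[i] = fmt_bn(M.mul_mod(parse_bn(cstr(a, i, na)), parse_bn(cstr(b, i, nb))));
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector fp_to_signed(CharacterVector a, String p) {
  Barrett M(parse_bn(p.get_cstring()));
  R_xlen_t n = a.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    BN v = parse_bn(cstr(a, i, n));
    BN x = (v.d.size() <= 2 * M.k) ? M.reduce_signed(v) : mod_pos(v, M.p);
    if (cmp_abs(x, M.half) > 0) out[i] = fmt_bn(sub_bn(x, M.p));
    else out[i] = fmt_bn(x);
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector fp_grouped_sum(CharacterVector a, IntegerVector group, int ngroups, String p) {
  BN pp = parse_bn(p.get_cstring());
  Barrett M(pp);
  std::vector<BN> acc(ngroups);
  if (a.size() != group.size()) stop("length mismatch in fp_grouped_sum");
  for (R_xlen_t i = 0; i < a.size(); ++i) {
    int g = group[i];
    if (g < 1 || g > ngroups) stop("group index out of range");
    acc[g - 1] = M.add_mod(acc[g - 1], parse_bn(CHAR(STRING_ELT(a, i))));
  }
  CharacterVector out(ngroups);
  for (int g = 0; g < ngroups; ++g) out[g] = fmt_bn(acc[g]);
  return out;
}

// sum_i 2^i * v_i mod p over a list of m parallel share vectors
// [[Rcpp::export]]
CharacterVector fp_dot_pow2(List vs, String p) {
  BN pp = parse_bn(p.get_cstring());
  Barrett M(pp);
  int m = vs.size();
  if (m == 0) return CharacterVector(0);
  CharacterVector first = vs[0];
  R_xlen_t n = first.size();
  std::vector<BN> acc(n);
  BN w;
  w.sign = 1;
  w.d.push_back(1); // 2^i
  BN two;
  two.sign = 1;
  two.d.push_back(2);
  for (int i = 0; i < m; ++i) {
    CharacterVector v = vs[i];
    if (v.size() != n) stop("ragged share list in fp_dot_pow2");
    for (R_xlen_t j = 0; j < n; ++j) {
      BN t = mul_bn(parse_bn(CHAR(STRING_ELT(v, j))), w);
      acc[j] = M.add_mod(acc[j], M.reduce(t));
    }
    w = mul_bn(w, two);
  }
  CharacterVector out(n);
  for (R_xlen_t j = 0; j < n; ++j) out[j] = fmt_bn(acc[j]);
  return out;
}

// [[Rcpp::export]]
String fp_pow_ui(String base, int e, String p) {
  BN pp = parse_bn(p.get_cstring());
  Barrett M(pp);
  BN b = mod_pos(parse_bn(base.get_cstring()), pp);
  BN r;
  r.sign = 1;
  r.d.push_back(1);
  while (e > 0) {
    if (e & 1) r = M.mul_mod(r, b);
    b = M.mul_mod(b, b);
    e >>= 1;
  }
  return fmt_bn(r);
}

// ---- deterministic dealer randomness (counter-mode splitmix64) ----------

static inline uint64_t mix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

struct Chain {
  uint64_t s;
  explicit Chain(uint64_t key, double ctr, R_xlen_t i) {
    s = mix64(key ^ (0xD1B54A32D192ED03ULL * (uint64_t)((double)ctr + (double)i + 1.0)));
  }
  uint64_t next() {
    s += 0x9E3779B97F4A7C15ULL;
    return mix64(s);
  }
};

static BN rnd_bits(Chain &ch, int nbits) { // uniform in [0, 2^nbits)
  BN v;
  static const BN shift = two_pow_bn(64);
  int full = nbits / 64, rem = nbits % 64;
  std::vector<uint64_t> words(full + (rem ? 1 : 0));
  for (size_t i = 0; i < words.size(); ++i) words[i] = ch.next();
  if (rem) words.back() &= (rem == 64) ? ~0ULL : ((1ULL << rem) - 1ULL);
  for (size_t i = words.size(); i-- > 0;) {
    v = mul_bn(v, shift);
    v = add_bn(v, from_u64(words[i]));
  }
  return v;
}

static BN rnd_below(Chain &ch, const BN &bound, int bound_bits) { // uniform in [0, bound)
  for (;;) {
    BN v = rnd_bits(ch, bound_bits);
    if (cmp_abs(v, bound) < 0) return v;
  }
}

// n uniform field elements; element i drawn from chain (key, ctr + i)
// [[Rcpp::export]]
CharacterVector rng_field(double key, double ctr, int n, String p) {
  BN pp = parse_bn(p.get_cstring());
  int bits = bitlen_bn(pp);
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    Chain ch((uint64_t)key, ctr, i);
    out[i] = fmt_bn(rnd_below(ch, pp, bits));
  }
  return out;
}

// Beaver triples: secrets a, b uniform, c = ab; additive shares of each.
// Chains: element i uses (key, ctr + i).
// [[Rcpp::export]]
List dealer_triples(double key, double ctr, int n, String p) {
  BN pp = parse_bn(p.get_cstring());
  Barrett M(pp);
  int bits = bitlen_bn(pp);
  CharacterVector a0(n), a1(n), b0(n), b1(n), c0(n), c1(n);
  for (int i = 0; i < n; ++i) {
    Chain ch((uint64_t)key, ctr, i);
    BN a = rnd_below(ch, pp, bits);
    BN b = rnd_below(ch, pp, bits);
    BN c = M.mul_mod(a, b);
    BN ra = rnd_below(ch, pp, bits);
    BN rb = rnd_below(ch, pp, bits);
    BN rc = rnd_below(ch, pp, bits);
    a0[i] = fmt_bn(ra);
    a1[i] = fmt_bn(M.sub_mod(a, ra));
    b0[i] = fmt_bn(rb);
    b1[i] = fmt_bn(M.sub_mod(b, rb));
    c0[i] = fmt_bn(rc);
    c1[i] = fmt_bn(M.sub_mod(c, rc));
  }
  return List::create(_["a0"] = a0, _["a1"] = a1, _["b0"] = b0, _["b1"] = b1,
                      _["c0"] = c0, _["c1"] = c1);
}

// n shared uniform random bits
// [[Rcpp::export]]
List dealer_bits(double key, double ctr, int n, String p) {
  BN pp = parse_bn(p.get_cstring());
  Barrett M(pp);
  int bits = bitlen_bn(pp);
  CharacterVector s0(n), s1(n);
  for (int i = 0; i < n; ++i) {
    Chain ch((uint64_t)key, ctr, i);
    uint64_t b = ch.next() & 1ULL;
    BN r = rnd_below(ch, pp, bits);
    BN bv = from_u64(b);
    s0[i] = fmt_bn(r);
    s1[i] = fmt_bn(M.sub_mod(bv, r));
  }
  return List::create(_["s0"] = s0, _["s1"] = s1);
}

// n shared values uniform in [0, 2^nbits)
// [[Rcpp::export]]
List dealer_pow2(double key, double ctr, int n, int nbits, String p) {
  BN pp = parse_bn(p.get_cstring());
  Barrett M(pp);
  int bits = bitlen_bn(pp);
  CharacterVector s0(n), s1(n);
  for (int i = 0; i < n; ++i) {
    Chain ch((uint64_t)key, ctr, i);
    BN v = rnd_bits(ch, nbits);
    BN r = rnd_below(ch, pp, bits);
    s0[i] = fmt_bn(r);
    s1[i] = fmt_bn(M.sub_mod(v, r));
  }
  return List::create(_["s0"] = s0, _["s1"] = s1);
}

// n shared uniform nonzero field elements (for the zero test)
// [[Rcpp::export]]
List dealer_nonzero(double key, double ctr, int n, String p) {
  BN pp = parse_bn(p.get_cstring());
  Barrett M(pp);
  int bits = bitlen_bn(pp);
  CharacterVector s0(n), s1(n);
  for (int i = 0; i < n; ++i) {
    Chain ch((uint64_t)key, ctr, i);
    BN v;
    do { v = rnd_below(ch, pp, bits); } while (v.sign == 0);
    BN r = rnd_below(ch, pp, bits);
    s0[i] = fmt_bn(r);
    s1[i] = fmt_bn(M.sub_mod(v, r));
  }
  return List::create(_["s0"] = s0, _["s1"] = s1);
}

// ---- limb-matrix field elements ------------------------------------------
// The MPC hot path stores vectors of field elements as numeric matrices
// (n rows, one column per base-1e9 limb, little-endian, residues in [0,p)).
// A matrix is a single R object, so garbage-collection cost is independent
// of n -- unlike character vectors, which the share volumes of a secure run
// (millions of values) would make GC-bound.

static BN row_bn(const NumericMatrix &A, R_xlen_t i) {
  BN v;
  int k = A.ncol();
  R_xlen_t n = A.nrow();
  R_xlen_t ii = i % n;
  v.d.reserve(k);
  for (int j = 0; j < k; ++j) v.d.push_back((uint32_t)A(ii, j));
  trim(v);
  return v;
}

static void set_row(NumericMatrix &A, R_xlen_t i, const BN &v) {
  int k = A.ncol();
  if ((int)v.d.size() > k) stop("internal: limb overflow in set_row");
  for (int j = 0; j < k; ++j) A(i, j) = (j < (int)v.d.size()) ? (double)v.d[j] : 0.0;
}

// [[Rcpp::export]]
int bn_nlimb(String p) {
  return (int)parse_bn(p.get_cstring()).d.size();
}

// [[Rcpp::export]]
NumericMatrix fx_from_str(CharacterVector x, String p) {
  BN pp = parse_bn(p.get_cstring());
  Barrett M(pp);
  int k = (int)pp.d.size();
  R_xlen_t n = x.size();
  NumericMatrix out(n, k);
  for (R_xlen_t i = 0; i < n; ++i) {
    BN v = parse_bn(CHAR(STRING_ELT(x, i)));
    BN r = (v.d.size() <= 2 * M.k) ? M.reduce_signed(v) : mod_pos(v, pp);
    set_row(out, i, r);
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector fx_to_str(NumericMatrix A) {
  R_xlen_t n = A.nrow();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = fmt_bn(row_bn(A, i));
  return out;
}

// [[Rcpp::export]]
CharacterVector fx_to_signed_str(NumericMatrix A, String p) {
  Barrett M(parse_bn(p.get_cstring()));
  R_xlen_t n = A.nrow();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    BN x = row_bn(A, i);
    if (cmp_abs(x, M.half) > 0) out[i] = fmt_bn(sub_bn(x, M.p));
    else out[i] = fmt_bn(x);
  }
  return out;
}

static NumericMatrix fx_bin(const NumericMatrix &A, const NumericMatrix &B, String p,
                            int op) {
  Barrett M(parse_bn(p.get_cstring()));
  R_xlen_t na = A.nrow(), nb = B.nrow();
  R_xlen_t n = std::max(na, nb);
  if (A.ncol() != B.ncol()) stop("limb-width mismatch");
  NumericMatrix out(n, A.ncol());
  for (R_xlen_t i = 0; i < n; ++i) {
    BN a = row_bn(A, i), b = row_bn(B, i), r;
    if (op == 0) r = M.add_mod(a, b);
    else if (op == 1) r = M.sub_mod(a, b);
    else r = M.mul_mod(a, b);
    set_row(out, i, r);
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix fx_add(NumericMatrix A, NumericMatrix B, String p) { return fx_bin(A, B, p, 0); }
// [[Rcpp::export]]
NumericMatrix fx_sub(NumericMatrix A, NumericMatrix B, String p) { return fx_bin(A, B, p, 1); }
// [[Rcpp::export]]
NumericMatrix fx_mul(NumericMatrix A, NumericMatrix B, String p) { return fx_bin(A, B, p, 2); }

// constant (scalar or length-n character) times / plus a matrix
// [[Rcpp::export]]
NumericMatrix fx_mulc(NumericMatrix A, CharacterVector c, String p) {
  BN pp = parse_bn(p.get_cstring());
  Barrett M(pp);
  R_xlen_t n = A.nrow(), nc = c.size();
  NumericMatrix out(n, A.ncol());
  std::vector<BN> cs(nc);
  for (R_xlen_t j = 0; j < nc; ++j) {
    BN v = parse_bn(CHAR(STRING_ELT(c, j)));
    cs[j] = (v.d.size() <= 2 * M.k) ? M.reduce_signed(v) : mod_pos(v, pp);
  }
  for (R_xlen_t i = 0; i < n; ++i) set_row(out, i, M.mul_mod(row_bn(A, i), cs[i % nc]));
  return out;
}

// [[Rcpp::export]]
NumericMatrix fx_addc(NumericMatrix A, CharacterVector c, String p) {
  BN pp = parse_bn(p.get_cstring());
  Barrett M(pp);
  R_xlen_t n = A.nrow(), nc = c.size();
  NumericMatrix out(n, A.ncol());
  std::vector<BN> cs(nc);
  for (R_xlen_t j = 0; j < nc; ++j) {
    BN v = parse_bn(CHAR(STRING_ELT(c, j)));
    cs[j] = (v.d.size() <= 2 * M.k) ? M.reduce_signed(v) : mod_pos(v, pp);
  }
  for (R_xlen_t i = 0; i < n; ++i) set_row(out, i, M.add_mod(row_bn(A, i), cs[i % nc]));
  return out;
}

// c - A (rowwise), c scalar/vector constant
// [[Rcpp::export]]
NumericMatrix fx_rsubc(CharacterVector c, NumericMatrix A, String p) {
  BN pp = parse_bn(p.get_cstring());
  Barrett M(pp);
  R_xlen_t n = A.nrow(), nc = c.size();
  NumericMatrix out(n, A.ncol());
  std::vector<BN> cs(nc);
  for (R_xlen_t j = 0; j < nc; ++j) {
    BN v = parse_bn(CHAR(STRING_ELT(c, j)));
    cs[j] = (v.d.size() <= 2 * M.k) ? M.reduce_signed(v) : mod_pos(v, pp);
  }
  for (R_xlen_t i = 0; i < n; ++i) set_row(out, i, M.sub_mod(cs[i % nc], row_bn(A, i)));
  return out;
}

// [[Rcpp::export]]
NumericMatrix fx_grouped_sum(NumericMatrix A, IntegerVector group, int ngroups, String p) {
  Barrett M(parse_bn(p.get_cstring()));
  if (A.nrow() != group.size()) stop("length mismatch in fx_grouped_sum");
  std::vector<BN> acc(ngroups);
  for (R_xlen_t i = 0; i < A.nrow(); ++i) {
    int g = group[i];
    if (g < 1 || g > ngroups) stop("group index out of range");
    acc[g - 1] = M.add_mod(acc[g - 1], row_bn(A, i));
  }
  NumericMatrix out(ngroups, A.ncol());
  for (int g = 0; g < ngroups; ++g) set_row(out, g, acc[g]);
  return out;
}

// A has n*bits rows in bit-major blocks; returns sum_b 2^b * A[b*n + i]
// [[Rcpp::export]]
NumericMatrix fx_wsum_pow2(NumericMatrix A, int n, int bits, String p) {
  Barrett M(parse_bn(p.get_cstring()));
  if (A.nrow() != (R_xlen_t)n * bits) stop("shape mismatch in fx_wsum_pow2");
  NumericMatrix out(n, A.ncol());
  std::vector<BN> acc(n);
  BN w;
  w.sign = 1;
  w.d.push_back(1);
  BN two;
  two.sign = 1;
  two.d.push_back(2);
  for (int b = 0; b < bits; ++b) {
    for (int i = 0; i < n; ++i) {
      BN t = M.reduce(mul_bn(row_bn(A, (R_xlen_t)b * n + i), w));
      acc[i] = M.add_mod(acc[i], t);
    }
    w = M.reduce(mul_bn(w, two));
  }
  for (int i = 0; i < n; ++i) set_row(out, i, acc[i]);
  return out;
}

// low `bits` bits of each (non-negative, already unwrapped) row value:
// returns the bit matrix and the value mod 2^bits as a limb matrix
// [[Rcpp::export]]
List fx_lowbits(NumericMatrix A, int bits) {
  R_xlen_t n = A.nrow();
  IntegerMatrix cb(n, bits);
  NumericMatrix cp(n, A.ncol());
  for (R_xlen_t i = 0; i < n; ++i) {
    BN x = row_bn(A, i);
    BN acc;
    BN w;
    w.sign = 1;
    w.d.push_back(1);
    BN two;
    two.sign = 1;
    two.d.push_back(2);
    for (int b = 0; b < bits; ++b) {
      int bit = 0;
      if (x.sign != 0) {
        uint32_t carry = 0;
        for (size_t j = x.d.size(); j-- > 0;) {
          uint64_t cur = (uint64_t)carry * BASE + x.d[j];
          x.d[j] = (uint32_t)(cur >> 1);
          carry = (uint32_t)(cur & 1);
        }
        bit = (int)carry;
        trim(x);
      }
      cb(i, b) = bit;
      if (bit) acc = add_bn(acc, w);
      w = mul_bn(w, two);
    }
    set_row(cp, i, acc);
  }
  return List::create(_["bits"] = cb, _["low"] = cp);
}

// flag ? (c - A_i mod p) : A_i   (per row; for XOR with a public bit)
// [[Rcpp::export]]
NumericMatrix fx_select_csub(IntegerVector flag, NumericMatrix A, String c, String p) {
  Barrett M(parse_bn(p.get_cstring()));
  BN cv = parse_bn(c.get_cstring());
  R_xlen_t n = A.nrow();
  if (flag.size() != n) stop("flag length mismatch");
  NumericMatrix out(n, A.ncol());
  for (R_xlen_t i = 0; i < n; ++i) {
    BN a = row_bn(A, i);
    set_row(out, i, flag[i] ? M.sub_mod(cv, a) : a);
  }
  return out;
}

// [[Rcpp::export]]
LogicalVector fx_is_zero(NumericMatrix A) {
  R_xlen_t n = A.nrow();
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = (row_bn(A, i).sign == 0);
  return out;
}

// ---- dealer randomness, limb-matrix editions -----------------------------

// [[Rcpp::export]]
NumericMatrix rng2_field(double key, double ctr, int n, String p) {
  BN pp = parse_bn(p.get_cstring());
  int bits = bitlen_bn(pp);
  int k = (int)pp.d.size();
  NumericMatrix out(n, k);
  for (int i = 0; i < n; ++i) {
    Chain ch((uint64_t)key, ctr, i);
    set_row(out, i, rnd_below(ch, pp, bits));
  }
  return out;
}

// [[Rcpp::export]]
List dealer2_triples(double key, double ctr, int n, String p) {
  BN pp = parse_bn(p.get_cstring());
  Barrett M(pp);
  int bits = bitlen_bn(pp);
  int k = (int)pp.d.size();
  NumericMatrix a0(n, k), a1(n, k), b0(n, k), b1(n, k), c0(n, k), c1(n, k);
  for (int i = 0; i < n; ++i) {
    Chain ch((uint64_t)key, ctr, i);
    BN a = rnd_below(ch, pp, bits);
    BN b = rnd_below(ch, pp, bits);
    BN c = M.mul_mod(a, b);
    BN ra = rnd_below(ch, pp, bits);
    BN rb = rnd_below(ch, pp, bits);
    BN rc = rnd_below(ch, pp, bits);
    set_row(a0, i, ra); set_row(a1, i, M.sub_mod(a, ra));
    set_row(b0, i, rb); set_row(b1, i, M.sub_mod(b, rb));
    set_row(c0, i, rc); set_row(c1, i, M.sub_mod(c, rc));
  }
  return List::create(_["a0"] = a0, _["a1"] = a1, _["b0"] = b0, _["b1"] = b1,
                      _["c0"] = c0, _["c1"] = c1);
}

// [[Rcpp::export]]
List dealer2_bits(double key, double ctr, int n, String p) {
  BN pp = parse_bn(p.get_cstring());
  Barrett M(pp);
  int bits = bitlen_bn(pp);
  int k = (int)pp.d.size();
  NumericMatrix s0(n, k), s1(n, k);
  for (int i = 0; i < n; ++i) {
    Chain ch((uint64_t)key, ctr, i);
    uint64_t b = ch.next() & 1ULL;
    BN r = rnd_below(ch, pp, bits);
    set_row(s0, i, r);
    set_row(s1, i, M.sub_mod(from_u64(b), r));
  }
  return List::create(_["s0"] = s0, _["s1"] = s1);
}

// [[Rcpp::export]]
List dealer2_pow2(double key, double ctr, int n, int nbits, String p) {
  BN pp = parse_bn(p.get_cstring());
  Barrett M(pp);
  int bits = bitlen_bn(pp);
  int k = (int)pp.d.size();
  NumericMatrix s0(n, k), s1(n, k);
  for (int i = 0; i < n; ++i) {
    Chain ch((uint64_t)key, ctr, i);
    BN v = rnd_bits(ch, nbits);
    BN r = rnd_below(ch, pp, bits);
    set_row(s0, i, r);
    set_row(s1, i, M.sub_mod(v, r));
  }
  return List::create(_["s0"] = s0, _["s1"] = s1);
}

// [[Rcpp::export]]
List dealer2_nonzero(double key, double ctr, int n, String p) {
  BN pp = parse_bn(p.get_cstring());
  Barrett M(pp);
  int bits = bitlen_bn(pp);
  int k = (int)pp.d.size();
  NumericMatrix s0(n, k), s1(n, k);
  for (int i = 0; i < n; ++i) {
    Chain ch((uint64_t)key, ctr, i);
    BN v;
    do { v = rnd_below(ch, pp, bits); } while (v.sign == 0);
    BN r = rnd_below(ch, pp, bits);
    set_row(s0, i, r);
    set_row(s1, i, M.sub_mod(v, r));
  }
  return List::create(_["s0"] = s0, _["s1"] = s1);
}
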