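// Exact arbitrary-precision Laurent-polynomial arithmetic in two variables
// (v, z), used for Homfly polynomials of double-crossover links whose
// integer coefficients exceed the 53-bit range of R doubles.
//
// Coefficients cross the R boundary as signed decimal strings; exponents as
// machine integers.  A polynomial is an R list(vexp, zexp, coef) of equal
// length with no duplicate (vexp, zexp) pairs and no zero coefficients.

#include <Rcpp.h>
#include <cstdint>
#include <map>
#include <string>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------- BigInt --

// sign/magnitude, little-endian base 2^32 limbs; mag empty <=> value 0
struct BigInt {
    int sgn = 0;
    std::vector<uint32_t> mag;
};

static void trimMag(std::vector<uint32_t>& m) {
    while (!m.empty() && m.back() == 0) m.pop_back();
}

static int cmpMag(const std::vector<uint32_t>& a, const std::vector<uint32_t>& b) {
    if (a.size() != b.size()) return a.size() < b.size() ? -1 : 1;
    for (size_t i = a.size(); i-- > 0;) {
        if (a[i] != b[i]) return a[i] < b[i] ? -1 : 1;
    }
    return 0;
}

static std::vector<uint32_t> addMag(const std::vector<uint32_t>& a,
                                    const std::vector<uint32_t>& b) {
    std::vector<uint32_t> r(std::max(a.size(), b.size()) + 1, 0u);
    uint64_t carry = 0;
    for (size_t i = 0; i < r.size(); ++i) {
        uint64_t s = carry;
        if (i < a.size()) s += a[i];
        if (i < b.size()) s += b[i];
        r[i] = static_cast<uint32_t>(s);
        carry = s >> 32;
    }
    trimMag(r);
    return r;
}

// requires a >= b
static std::vector<uint32_t> subMag(const std::vector<uint32_t>& a,
                                    const std::vector<uint32_t>& b) {
    std::vector<uint32_t> r(a.size(), 0u);
    int64_t borrow = 0;
    for (size_t i = 0; i < a.size(); ++i) {
        int64_t s = static_cast<int64_t>(a[i]) - borrow - (i < b.size() ? b[i] : 0);
        if (s < 0) { s += (int64_t(1) << 32); borrow = 1; } else borrow = 0;
        r[i] = static_cast<uint32_t>(s);
    }
    trimMag(r);
    return r;
}

static std::vector<uint32_t> mulMag(const std::vector<uint32_t>& a,
                                    const std::vector<uint32_t>& b) {
    if (a.empty() || b.empty()) return {};
    std::vector<uint32_t> r(a.size() + b.size(), 0u);
    for (size_t i = 0; i < a.size(); ++i) {
        uint64_t carry = 0;
        for (size_t j = 0; j < b.size(); ++j) {
            uint64_t cur = r[i + j] + static_cast<uint64_t>(a[i]) * b[j] + carry;
            r[i + j] = static_cast<uint32_t>(cur);
            carry = cur >> 32;
        }
        r[i + b.size()] = static_cast<uint32_t>(carry);
    }
    trimMag(r);
    return r;
}

// divides in place by small d (1 <= d < 2^32), returns remainder
static uint32_t divMagSmall(std::vector<uint32_t>& m, uint32_t d) {
    uint64_t rem = 0;
    for (size_t i = m.size(); i-- > 0;) {
        uint64_t cur = (rem << 32) | m[i];
        m[i] = static_cast<uint32_t>(cur / d);
        rem = cur % d;
    }
    trimMag(m);
    return static_cast<uint32_t>(rem);
}

static BigInt bigAdd(const BigInt& a, const BigInt& b) {
    if (a.sgn == 0) return b;
    if (b.sgn == 0) return a;
    BigInt r;
    if (a.sgn == b.sgn) {
        r.sgn = a.sgn;
        r.mag = addMag(a.mag, b.mag);
    } else {
        int c = cmpMag(a.mag, b.mag);
        if (c == 0) return r;  // zero
        if (c > 0) { r.sgn = a.sgn; r.mag = subMag(a.mag, b.mag); }
        else       { r.sgn = b.sgn; r.mag = subMag(b.mag, a.mag); }
    }
    return r;
}

static BigInt bigNeg(BigInt a) {
    a.sgn = -a.sgn;
    return a;
}

static BigInt bigMul(const BigInt& a, const BigInt& b) {
    BigInt r;
    if (a.sgn == 0 || b.sgn == 0) return r;
    r.sgn = a.sgn * b.sgn;
    r.mag = mulMag(a.mag, b.mag);
    return r;
}

// exact division by small signed integer; stops with an R error otherwise
static BigInt bigDivExactSmall(const BigInt& a, int64_t d, const char* ctx) {
    if (d == 0) stop("division by zero in %s", ctx);
    BigInt r = a;
    if (r.sgn == 0) return r;
    if (d < 0) { r.sgn = -r.sgn; d = -d; }
    if (d > 0xffffffffLL) stop("divisor too large in %s", ctx);
    uint32_t rem = divMagSmall(r.mag, static_cast<uint32_t>(d));
    if (rem != 0) stop("non-exact integer division in %s", ctx);
    if (r.mag.empty()) r.sgn = 0;
    return r;
}

// exact division by an arbitrary divisor (bit-wise long division; sizes in
// this pipeline are a handful of limbs, so the O(bits^2) cost is irrelevant)
static BigInt bigDivExact(const BigInt& a, const BigInt& b, const char* ctx) {
    if (b.sgn == 0) stop("division by zero in %s", ctx);
    if (a.sgn == 0) return a;
    if (b.mag.size() == 1) {
        BigInt q = a;
        if (b.sgn < 0) q.sgn = -q.sgn;
        uint32_t rem = divMagSmall(q.mag, b.mag[0]);
        if (rem != 0) stop("non-exact integer division in %s", ctx);
        if (q.mag.empty()) q.sgn = 0;
        return q;
    }
    int nbits = static_cast<int>(a.mag.size()) * 32;
    std::vector<uint32_t> q(a.mag.size(), 0u), r;
    for (int i = nbits - 1; i >= 0; --i) {
        // r = r << 1 | bit_i(a)
        uint32_t carry = (a.mag[i / 32] >> (i % 32)) & 1u;
        for (size_t j = 0; j < r.size(); ++j) {
            uint32_t hi = r[j] >> 31;
            r[j] = (r[j] << 1) | carry;
            carry = hi;
        }
        if (carry) r.push_back(carry);
        trimMag(r);
        if (cmpMag(r, b.mag) >= 0) {
            r = subMag(r, b.mag);
            q[i / 32] |= (1u << (i % 32));
        }
    }
    if (!r.empty()) stop("non-exact integer division in %s", ctx);
    trimMag(q);
    BigInt out;
    out.mag = q;
    out.sgn = out.mag.empty() ? 0 : a.sgn * b.sgn;
    return out;
}

static BigInt bigFromInt64(int64_t x) {
    BigInt r;
    if (x == 0) return r;
    r.sgn = x < 0 ? -1 : 1;
    uint64_t u = x < 0 ? static_cast<uint64_t>(-(x + 1)) + 1 : static_cast<uint64_t>(x);
    r.mag.push_back(static_cast<uint32_t>(u));
    if (u >> 32) r.mag.push_back(static_cast<uint32_t>(u >> 32));
    return r;
}

static BigInt bigFromDec(const std::string& s) {
    BigInt r;
    size_t i = 0;
    int sgn = 1;
    if (i < s.size() && (s[i] == '+' || s[i] == '-')) {
        if (s[i] == '-') sgn = -1;
        ++i;
    }
    if (i >= s.size()) stop("empty integer literal '%s'", s.c_str());
    for (; i < s.size(); ++i) {
        char c = s[i];
        if (c < '0' || c > '9') stop("bad integer literal '%s'", s.c_str());
        // r = r*10 + digit
        uint64_t carry = static_cast<uint64_t>(c - '0');
        for (size_t j = 0; j < r.mag.size(); ++j) {
            uint64_t cur = static_cast<uint64_t>(r.mag[j]) * 10u + carry;
            r.mag[j] = static_cast<uint32_t>(cur);
            carry = cur >> 32;
        }
        if (carry) r.mag.push_back(static_cast<uint32_t>(carry));
    }
    trimMag(r.mag);
    r.sgn = r.mag.empty() ? 0 : sgn;
    return r;
}

static std::string bigToDec(const BigInt& a) {
    if (a.sgn == 0) return "0";
    std::vector<uint32_t> m = a.mag;
    std::string digits;
    while (!m.empty()) {
        uint32_t rem = divMagSmall(m, 1000000000u);
        char buf[16];
        if (m.empty()) snprintf(buf, sizeof buf, "%u", rem);
        else snprintf(buf, sizeof buf, "%09u", rem);
        digits.insert(0, buf);
    }
    if (a.sgn < 0) digits.insert(0, "-");
    return digits;
}

// ------------------------------------------------------------- Laurent2 ---

// key orders terms lexicographically by z-exponent, then v-exponent
static const int64_t EXP_OFFSET = 1 << 22;

static int64_t encKey(int vexp, int zexp) {
    return ((static_cast<int64_t>(zexp) + EXP_OFFSET) << 24) +
           (static_cast<int64_t>(vexp) + EXP_OFFSET);
}
static int decV(int64_t key) {
    return static_cast<int>((key & ((1 << 24) - 1)) - EXP_OFFSET);
}
static int decZ(int64_t key) {
    return static_cast<int>((key >> 24) - EXP_OFFSET);
}

typedef std::map<int64_t, BigInt> Poly;

static void polyAddTerm(Poly& p, int64_t key, const BigInt& c) {
    if (c.sgn == 0) return;
    auto it = p.find(key);
    if (it == p.end()) {
        p.emplace(key, c);
    } else {
        it->second = bigAdd(it->second, c);
        if (it->second.sgn == 0) p.erase(it);
    }
}

static Poly polyFromR(List A) {
    IntegerVector vexp = A["vexp"], zexp = A["zexp"];
    CharacterVector coef = A["coef"];
    if (vexp.size() != zexp.size() || vexp.size() != coef.size())
        stop("polynomial components have unequal length");
    Poly p;
    for (R_xlen_t i = 0; i < vexp.size(); ++i) {
        BigInt c = bigFromDec(as<std::string>(coef[i]));
        polyAddTerm(p, encKey(vexp[i], zexp[i]), c);
    }
    return p;
}

static List polyToR(const Poly& p) {
    // emitted in descending z-degree then descending v-degree (paper order)
    IntegerVector vexp(p.size()), zexp(p.size());
    CharacterVector coef(p.size());
    R_xlen_t i = 0;
    for (auto it = p.rbegin(); it != p.rend(); ++it, ++i) {
        vexp[i] = decV(it->first);
        zexp[i] = decZ(it->first);
        coef[i] = bigToDec(it->second);
    }
    List out = List::create(_["vexp"] = vexp, _["zexp"] = zexp, _["coef"] = coef);
    out.attr("class") = "lp2_raw";
    return out;
}

static Poly polyAdd(const Poly& a, const Poly& b) {
    Poly r = a;
    for (auto& kv : b) polyAddTerm(r, kv.first, kv.second);
    return r;
}

static Poly polyNeg(const Poly& a) {
    Poly r = a;
    for (auto& kv : r) kv.second.sgn = -kv.second.sgn;
    return r;
}

static Poly polyMul(const Poly& a, const Poly& b) {
    Poly r;
    if (a.empty() || b.empty()) return r;
    for (auto& ka : a)
        for (auto& kb : b)
            polyAddTerm(r, ka.first + kb.first - encKey(0, 0),
                        bigMul(ka.second, kb.second));
    return r;
}

static Poly polyPow(const Poly& a, int k) {
    if (k < 0) stop("negative power of a Laurent polynomial");
    Poly r;
    r.emplace(encKey(0, 0), bigFromInt64(1));
    Poly base = a;
    while (k > 0) {
        if (k & 1) r = polyMul(r, base);
        k >>= 1;
        if (k) base = polyMul(base, base);
    }
    return r;
}

// exact division; errors unless b divides a in Z[v^(+-1), z^(+-1)]
static Poly polyDivExact(const Poly& a, const Poly& b) {
    if (b.empty()) stop("division by the zero polynomial");
    Poly r = a, q;
    auto lb = b.rbegin();  // leading term of divisor (max key)
    int64_t lbKey = lb->first;
    const BigInt& lbCoef = lb->second;
    size_t guard = 64 * (a.size() + b.size() + 16) * (a.size() + 16);
    while (!r.empty()) {
        if (guard-- == 0) stop("polynomial division does not terminate: not divisible");
        auto lr = r.rbegin();
        int64_t qKey = lr->first - lbKey + encKey(0, 0);
        BigInt qc = bigDivExact(lr->second, lbCoef, "Laurent division");
        q.emplace(qKey, qc);
        // r -= qc * key^qKey * b
        for (auto& kb : b)
            polyAddTerm(r, qKey + kb.first - encKey(0, 0),
                        bigNeg(bigMul(qc, kb.second)));
    }
    return q;
}

// [[Rcpp::export(name = ".lp2_build")]]
List lp2_build(IntegerVector vexp, IntegerVector zexp, CharacterVector coef) {
    return polyToR(polyFromR(List::create(_["vexp"] = vexp, _["zexp"] = zexp,
                                          _["coef"] = coef)));
}

// [[Rcpp::export(name = ".lp2_add")]]
List lp2_add(List A, List B) { return polyToR(polyAdd(polyFromR(A), polyFromR(B))); }

// [[Rcpp::export(name = ".lp2_neg")]]
List lp2_neg(List A) { return polyToR(polyNeg(polyFromR(A))); }

// [[Rcpp::export(name = ".lp2_sub")]]
List lp2_sub(List A, List B) {
    return polyToR(polyAdd(polyFromR(A), polyNeg(polyFromR(B))));
}

// [[Rcpp::export(name = ".lp2_mul")]]
List lp2_mul(List A, List B) { return polyToR(polyMul(polyFromR(A), polyFromR(B))); }

// [[Rcpp::export(name = ".lp2_pow")]]
List lp2_pow(List A, int k) { return polyToR(polyPow(polyFromR(A), k)); }

// [[Rcpp::export(name = ".lp2_divexact")]]
List lp2_divexact(List A, List B) {
    return polyToR(polyDivExact(polyFromR(A), polyFromR(B)));
}

// v -> -v^(-1): the positive/negative mirror of the link polynomial
// [[Rcpp::export(name = ".lp2_mirror")]]
List lp2_mirror(List A) {
    Poly a = polyFromR(A), r;
    for (auto& kv : a) {
        int v = decV(kv.first), z = decZ(kv.first);
        BigInt c = kv.second;
        if (v & 1) c.sgn = -c.sgn;
        polyAddTerm(r, encKey(-v, z), c);
    }
    return polyToR(r);
}

// [[Rcpp::export(name = ".lp2_coeff")]]
CharacterVector lp2_coeff(List A, IntegerVector vexp, IntegerVector zexp) {
    Poly a = polyFromR(A);
    CharacterVector out(vexp.size());
    for (R_xlen_t i = 0; i < vexp.size(); ++i) {
        auto it = a.find(encKey(vexp[i], zexp[i]));
        out[i] = it == a.end() ? "0" : bigToDec(it->second);
    }
    return out;
}

// Conway specialization: v = 1; any surviving negative z-power is an error
// [[Rcpp::export(name = ".lp2_conway")]]
List lp2_conway(List A) {
    Poly a = polyFromR(A);
    std::map<int, BigInt> byZ;
    for (auto& kv : a) {
        int z = decZ(kv.first);
        auto it = byZ.find(z);
        if (it == byZ.end()) byZ.emplace(z, kv.second);
        else {
            it->second = bigAdd(it->second, kv.second);
            if (it->second.sgn == 0) byZ.erase(it);
        }
    }
    for (auto& kv : byZ)
        if (kv.first < 0)
            stop("negative z-power z^%d survives evaluation at v = 1", kv.first);
    IntegerVector zexp(byZ.size());
    CharacterVector coef(byZ.size());
    R_xlen_t i = 0;
    for (auto it = byZ.rbegin(); it != byZ.rend(); ++it, ++i) {
        zexp[i] = it->first;
        coef[i] = bigToDec(it->second);
    }
    return List::create(_["zexp"] = zexp, _["coef"] = coef);
}

// Jones specialization: v = s^2, z = s - s^(-1), with s = t^(1/2).
// Negative z-powers are cleared by multiplying through by z^Z first and
// dividing the univariate result by (s - s^(-1))^Z exactly at the end.
// [[Rcpp::export(name = ".lp2_jones")]]
List lp2_jones(List A) {
    Poly a = polyFromR(A);
    int minZ = 0, maxZ = 0;
    bool first = true;
    for (auto& kv : a) {
        int z = decZ(kv.first);
        if (first) { minZ = maxZ = z; first = false; }
        minZ = std::min(minZ, z);
        maxZ = std::max(maxZ, z);
    }
    int shift = minZ < 0 ? -minZ : 0;

    // Pascal rows up to maxZ + shift, in BigInt
    int qmax = maxZ + shift;
    std::vector<std::vector<BigInt>> choose(qmax + 1);
    for (int n = 0; n <= qmax; ++n) {
        choose[n].resize(n + 1);
        choose[n][0] = bigFromInt64(1);
        for (int k = 1; k <= n; ++k) {
            // C(n,k) = C(n,k-1) * (n-k+1) / k
            BigInt t = bigMul(choose[n][k - 1], bigFromInt64(n - k + 1));
            choose[n][k] = bigDivExactSmall(t, k, "binomial");
        }
    }

    std::map<int, BigInt> uni;  // s-exponent -> coefficient
    for (auto& kv : a) {
        int v = decV(kv.first), q = decZ(kv.first) + shift;
        // term c * s^(2v) * (s - s^(-1))^q
        for (int i = 0; i <= q; ++i) {
            BigInt c = bigMul(kv.second, choose[q][i]);
            if (i & 1) c.sgn = -c.sgn;
            int e = 2 * v + q - 2 * i;
            auto it = uni.find(e);
            if (it == uni.end()) uni.emplace(e, c);
            else {
                it->second = bigAdd(it->second, c);
                if (it->second.sgn == 0) uni.erase(it);
            }
        }
    }

    // divide by (s - s^(-1))^shift, exactly
    for (int rep = 0; rep < shift; ++rep) {
        std::map<int, BigInt> quo;
        int floorE = uni.empty() ? 0 : uni.begin()->first;
        while (!uni.empty()) {
            auto lr = uni.rbegin();
            int e = lr->first - 1;  // divide leading term by s
            if (e < floorE - 1)
                stop("univariate division by (s - 1/s) is not exact");
            BigInt qc = lr->second;
            quo.emplace(e, qc);
            // uni -= qc * (s^(e+1) - s^(e-1))
            for (int d : {e + 1, e - 1}) {
                BigInt c = qc;
                if (d == e - 1) c.sgn = -c.sgn;
                c.sgn = -c.sgn;
                auto it = uni.find(d);
                if (it == uni.end()) { if (c.sgn) uni.emplace(d, c); }
                else {
                    it->second = bigAdd(it->second, c);
                    if (it->second.sgn == 0) uni.erase(it);
                }
            }
        }
        uni.swap(quo);
    }

    IntegerVector sexp(uni.size());
    CharacterVector coef(uni.size());
    R_xlen_t i = 0;
    for (auto it = uni.rbegin(); it != uni.rend(); ++it, ++i) {
        sexp[i] = it->first;
        coef[i] = bigToDec(it->second);
    }
    return List::create(_["sexp"] = sexp, _["coef"] = coef);
}
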