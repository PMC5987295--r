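// Bounded-distance BCH decoding over GF(2^m): syndrome computation,
// Berlekamp-Massey error locator, Chien search. Field arithmetic uses the
// log/antilog tables built in R (element values 1..n, exponents 0..n-1).

#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

namespace {

struct GF {
  int n; // 2^m - 1
  const int *logt;    // logt[value-1] = exponent
  const int *antilog; // antilog[exponent] = value
  int mul(int a, int b) const {
    if (a == 0 || b == 0) return 0;
    int e = logt[a - 1] + logt[b - 1];
    if (e >= n) e -= n;
    return antilog[e];
  }
  int inv(int a) const {
    int e = (n - logt[a - 1]) % n;
    return antilog[e];
  }
  int pow_alpha(int e) const { // alpha^e, e may exceed n
    return antilog[((e % n) + n) % n];
  }
};

// syndromes S_1..S_2t of word r (0/1), S_j = sum_{i: r_i=1} alpha^{i*j}
void syndromes(const GF &gf, const IntegerVector &r, int t, std::vector<int> &S) {
  S.assign(2 * t, 0);
  std::vector<int> pos;
  for (int i = 0; i < (int)r.size(); ++i) if (r[i]) pos.push_back(i);
  for (int j = 1; j <= 2 * t; ++j) {
    int s = 0;
    for (int i : pos) s ^= gf.pow_alpha((long long)(i) * j % gf.n);
    S[j - 1] = s;
  }
}

bool all_zero(const std::vector<int> &v) {
  for (int x : v) if (x) return false;
  return true;
}

} // namespace

// Returns the corrected codeword, or integer(0) if no codeword lies within
// Hamming distance t of the received word (bounded-distance failure).
// [[Rcpp::export(name = ".bchDecodeCpp")]]
IntegerVector bchDecode_cpp(IntegerVector received, IntegerVector logTable,
                            IntegerVector antilogTable, int t) {
  int n = received.size();
  GF gf;
  gf.n = n;
  std::vector<int> logv(logTable.begin(), logTable.end());
  std::vector<int> alogv(antilogTable.begin(), antilogTable.end());
  gf.logt = logv.data();
  gf.antilog = alogv.data();

  std::vector<int> S;
  syndromes(gf, received, t, S);
  if (all_zero(S)) return clone(received);

  // Berlekamp-Massey: find minimal LFSR Lambda with Lambda(0)=1
  std::vector<int> C(2 * t + 1, 0), B(2 * t + 1, 0), Tmp;
  C[0] = 1; B[0] = 1;
  int L = 0, m = 1, b = 1;
  for (int i = 0; i < 2 * t; ++i) {
    int d = S[i];
    for (int j = 1; j <= L; ++j) d ^= gf.mul(C[j], S[i - j]);
    if (d == 0) {
      ++m;
    } else if (2 * L <= i) {
      Tmp = C;
      int coef = gf.mul(d, gf.inv(b));
      for (int j = 0; j + m <= 2 * t; ++j)
        C[j + m] ^= gf.mul(coef, B[j]);
      L = i + 1 - L;
      B = Tmp;
      b = d;
      m = 1;
    } else {
      int coef = gf.mul(d, gf.inv(b));
      for (int j = 0; j + m <= 2 * t; ++j)
        C[j + m] ^= gf.mul(coef, B[j]);
      ++m;
    }
  }
  if (L > t) return IntegerVector(0);

  // Chien search: Lambda(alpha^j) == 0 -> error at position (n - j) mod n
  std::vector<int> errpos;
  for (int j = 0; j < n; ++j) {
    int acc = 0;
    for (int k = L; k >= 0; --k) {
      // Horner at x = alpha^j
      acc = gf.mul(acc, gf.pow_alpha(j)) ^ C[k];
    }
    if (acc == 0) errpos.push_back((n - j) % n);
  }
  if ((int)errpos.size() != L) return IntegerVector(0);

  IntegerVector corrected = clone(received);
  for (int p : errpos) corrected[p] ^= 1;

  std::vector<int> S2;
  syndromes(gf, corrected, t, S2);
  if (!all_zero(S2)) return IntegerVector(0);
  return corrected;
}

// [[Rcpp::export(name = ".bchSyndromesCpp")]]
IntegerVector bchSyndromes_cpp(IntegerVector word, IntegerVector logTable,
                               IntegerVector antilogTable, int t) {
  int n = word.size();
  GF gf;
  gf.n = n;
  std::vector<int> logv(logTable.begin(), logTable.end());
  std::vector<int> alogv(antilogTable.begin(), antilogTable.end());
  gf.logt = logv.data();
  gf.antilog = alogv.data();
  std::vector<int> S;
  syndromes(gf, word, t, S);
  return IntegerVector(S.begin(), S.end());
}
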