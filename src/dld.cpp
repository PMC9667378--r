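#include <Rcpp.h>
#include <cstring>
#include <vector>

using namespace Rcpp;

// Restricted Damerau-Levenshtein (optimal string alignment) distance.
// Allowed operations: insertion, deletion, substitution, transposition of
// two adjacent characters; no substring is edited twice.
static int osa_dist_buf(const char *a, int la, const char *b, int lb,
                        int *prev2, int *prev, int *cur) {
  if (la == 0) return lb;
  if (lb == 0) return la;
  for (int j = 0; j <= lb; ++j) prev[j] = j;
  for (int i = 1; i <= la; ++i) {
    cur[0] = i;
    for (int j = 1; j <= lb; ++j) {
      int cost = (a[i - 1] == b[j - 1]) ? 0 : 1;
      int d = std::min(std::min(prev[j] + 1, cur[j - 1] + 1),
                       prev[j - 1] + cost);
      if (i > 1 && j > 1 && a[i - 1] == b[j - 2] && a[i - 2] == b[j - 1])
        d = std::min(d, prev2[j - 2] + 1);
      cur[j] = d;
    }
    int *t = prev2;
    prev2 = prev;
    prev = cur;
    cur = t;
  }
  return prev[lb];
}

// three rolling rows of the DP table
static int osa_dist(const char *a, int la, const char *b, int lb) {
  std::vector<int> buf(3 * (lb + 1));
  return osa_dist_buf(a, la, b, lb, buf.data(), buf.data() + (lb + 1),
                      buf.data() + 2 * (lb + 1));
}

// Independent route used only for self-checks: naive recursion on the OSA
// recurrence, memoised. Shares no code with osa_dist beyond the cost test.
static int osa_rec(const char *a, const char *b, int i, int j,
                   std::vector<int> &memo, int w) {
  if (i == 0) return j;
  if (j == 0) return i;
  int &m = memo[i * w + j];
  if (m >= 0) return m;
  int best = osa_rec(a, b, i - 1, j, memo, w) + 1;
  int del = osa_rec(a, b, i, j - 1, memo, w) + 1;
  if (del < best) best = del;
  int sub = osa_rec(a, b, i - 1, j - 1, memo, w) +
            ((a[i - 1] == b[j - 1]) ? 0 : 1);
  if (sub < best) best = sub;
  if (i > 1 && j > 1 && a[i - 1] == b[j - 2] && a[i - 2] == b[j - 1]) {
    int tr = osa_rec(a, b, i - 2, j - 2, memo, w) + 1;
    if (tr < best) best = tr;
  }
  m = best;
  return best;
}

static int osa_dist_rec(const char *a, int la, const char *b, int lb,
                        std::vector<int> &memo) {
  memo.assign((size_t)(la + 1) * (lb + 1), -1);
  return osa_rec(a, b, la, lb, memo, lb + 1);
}

// [[Rcpp::export(name = ".dld_cpp")]]
IntegerVector dld_cpp(CharacterVector a, CharacterVector b) {
  R_xlen_t na = a.size(), nb = b.size();
  R_xlen_t n = std::max(na, nb);
  if (na == 0 || nb == 0) return IntegerVector(0);
  IntegerVector out(n);
  for (R_xlen_t k = 0; k < n; ++k) {
    SEXP sa = a[k % na], sb = b[k % nb];
    if (sa == NA_STRING || sb == NA_STRING) {
      out[k] = NA_INTEGER;
      continue;
    }
    const char *ca = CHAR(sa);
    const char *cb = CHAR(sb);
    out[k] = osa_dist(ca, (int)std::strlen(ca), cb, (int)std::strlen(cb));
  }
  return out;
}

// Exhaustive agreement sweep between the DP and the memoised-recursion
// implementations over every ordered pair of strings of length <= maxlen
// drawn from an alphabet of `alphabet` letters (a, b, c, ...). Each
// unordered pair is checked against the recursion once; the reversed
// ordering is covered by an explicit DP symmetry check in the same loop.
// Returns c(pairs_checked, mismatches).
// [[Rcpp::export(name = ".dld_selfcheck_cpp")]]
NumericVector dld_selfcheck_cpp(int maxlen, int alphabet) {
  if (maxlen < 0 || maxlen > 10 || alphabet < 1 || alphabet > 26)
    stop("maxlen must be in 0..10 and alphabet in 1..26");
  // enumerate all strings of length 0..maxlen
  std::vector<std::string> pool;
  pool.push_back("");
  size_t lo = 0;
  for (int len = 1; len <= maxlen; ++len) {
    size_t hi = pool.size();
    for (size_t s = lo; s < hi; ++s)
      for (int c = 0; c < alphabet; ++c)
        pool.push_back(pool[s] + (char)('a' + c));
    lo = hi;
  }
  double pairs = 0, bad = 0;
  size_t np = pool.size();
  std::vector<int> dp(3 * (maxlen + 1));
  std::vector<int> memo;
  memo.reserve((size_t)(maxlen + 1) * (maxlen + 1));
  int *r0 = dp.data(), *r1 = dp.data() + (maxlen + 1),
      *r2 = dp.data() + 2 * (maxlen + 1);
  for (size_t i = 0; i < np; ++i) {
    const char *ca = pool[i].c_str();
    int la = (int)pool[i].size();
    for (size_t j = i; j < np; ++j) {
      const char *cb = pool[j].c_str();
      int lb = (int)pool[j].size();
      int d1 = osa_dist_buf(ca, la, cb, lb, r0, r1, r2);
      if (d1 != osa_dist_rec(ca, la, cb, lb, memo)) bad += 1;
      pairs += 1;
      if (j > i) {
        if (osa_dist_buf(cb, lb, ca, la, r0, r1, r2) != d1) bad += 1;
        pairs += 1;
      }
    }
    if (i % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return NumericVector::create(pairs, bad);
}
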