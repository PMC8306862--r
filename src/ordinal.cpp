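#include <Rcpp.h>
using namespace Rcpp;

// Ordinal pattern rank (lexicographic permutation rank, 0-based) for every
// embedded window of x. The pattern of a window is the permutation of
// positions that sorts the window ascending; exact ties are broken by the
// earlier position (stable sort), so the map is deterministic.
// [[Rcpp::export]]
IntegerVector ordinal_pattern_ranks(NumericVector x, int m, int tau) {
  const int T = x.size();
  if (m < 2) stop("embedding dimension m must be >= 2");
  if (m > 12) stop("embedding dimension m > 12 not supported (m! overflows)");
  if (tau < 1) stop("time delay tau must be >= 1");
  const int nwin = T - (m - 1) * tau;
  if (nwin < 1) stop("series too short for embedding: need at least (m-1)*tau + 1 samples");

  std::vector<long long> fact(m + 1);
  fact[0] = 1;
  for (int i = 1; i <= m; ++i) fact[i] = fact[i - 1] * i;

  std::vector<int> idx(m);
  IntegerVector out(nwin);
  for (int k = 0; k < nwin; ++k) {
    for (int j = 0; j < m; ++j) idx[j] = j;
    // stable insertion sort of positions by value (strict > keeps ties stable)
    for (int a = 1; a < m; ++a) {
      int p = idx[a];
      double v = x[k + p * tau];
      int b = a - 1;
      while (b >= 0 && x[k + idx[b] * tau] > v) {
        idx[b + 1] = idx[b];
        --b;
      }
      idx[b + 1] = p;
    }
    // Lehmer code -> lexicographic rank
    long long rank = 0;
    for (int j = 0; j < m; ++j) {
      int c = 0;
      for (int l = j + 1; l < m; ++l)
        if (idx[l] < idx[j]) ++c;
      rank += c * fact[m - 1 - j];
    }
    out[k] = (int) rank;
  }
  return out;
}

// Per-window amplitude weight: population variance (1/m) * sum (x - mean)^2
// of each embedded window, used by the weighted ordinal distribution.
// [[Rcpp::export]]
NumericVector ordinal_window_weights(NumericVector x, int m, int tau) {
  const int T = x.size();
  if (m < 2) stop("embedding dimension m must be >= 2");
  if (tau < 1) stop("time delay tau must be >= 1");
  const int nwin = T - (m - 1) * tau;
  if (nwin < 1) stop("series too short for embedding: need at least (m-1)*tau + 1 samples");
  NumericVector w(nwin);
  for (int k = 0; k < nwin; ++k) {
    double s = 0.0, ss = 0.0;
    for (int j = 0; j < m; ++j) {
      double v = x[k + j * tau];
      s += v;
      ss += v * v;
    }
    double mean = s / m;
    double var = ss / m - mean * mean;
    w[k] = var > 0 ? var : 0.0;
  }
  return w;
}

// Number of phrases c(n) in the Lempel-Ziv 1976 exhaustive-history parsing
// (Kaspar-Schuster scheme): each phrase is the shortest continuation that is
// not a substring of the text preceding its last character.
// [[Rcpp::export]]
int lz76_phrase_count(IntegerVector s) {
  const int n = s.size();
  if (n < 1) stop("empty symbol sequence");
  if (n == 1) return 1;
  int c = 1;    // first symbol is always a new phrase
  int l = 1;    // start (0-based length of parsed prefix) of current phrase
  int i = 0;    // candidate match start within the prefix
  int k = 1;    // current match length being attempted
  int kmax = 1; // longest reproducible extension seen for this phrase
  while (true) {
    if (s[i + k - 1] == s[l + k - 1]) {
      ++k;
      if (l + k > n) { // phrase ran off the end while still reproducible
        ++c;
        break;
      }
    } else {
      if (k > kmax) kmax = k;
      ++i;
      if (i == l) { // no candidate reproduces the extension: close phrase
        ++c;
        l += kmax;
        if (l + 1 > n) break;
        i = 0;
        k = 1;
        kmax = 1;
      } else {
        k = 1;
      }
    }
  }
  return c;
}
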