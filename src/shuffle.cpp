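#include <Rcpp.h>
using namespace Rcpp;

// Fisher-Yates shuffle of idx in place using R's RNG
static inline void shuffle_idx(std::vector<int> &idx) {
  const int n = idx.size();
  for (int j = n - 1; j > 0; --j) {
    int k = (int)std::floor(unif_rand() * (j + 1));
    if (k > j) k = j; // guard against unif_rand() returning 1.0
    std::swap(idx[j], idx[k]);
  }
}

// Monte-Carlo null sample for the domain/spacer index-shuffle test.
//
// A: domain lengths, S: spacer lengths (N+1), both in bp.
// ts/te: merged, sorted track intervals in 0-based half-open coords.
// Each iteration permutes the A and S index arrays independently, lays
// the chromosome out as S A S A ... S, and records the statistic:
// total overlap bp with the track (count_stat = false) or the number of
// domains overlapping the track by >= 1 bp (count_stat = true).
// Coordinates are doubles; exact for genome-scale integers.
// [[Rcpp::export]]
NumericVector cpp_shuffle_null(NumericVector A, NumericVector S,
                               NumericVector ts, NumericVector te,
                               int M, bool count_stat) {
  const int N = A.size(), T = ts.size();
  if (S.size() != N + 1) stop("need N+1 spacers for N domains");
  if (M < 1) stop("M must be >= 1");
  NumericVector out(M);
  if (N == 0 || T == 0) return out; // statistic identically 0
  std::vector<int> ai(N), si(N + 1);
  for (int m = 0; m < M; ++m) {
    for (int i = 0; i < N; ++i) ai[i] = i;
    for (int i = 0; i <= N; ++i) si[i] = i;
    shuffle_idx(ai);
    shuffle_idx(si);
    double pos = 0.0, stat = 0.0;
    int ti = 0; // first track interval possibly overlapping current domain
    for (int i = 0; i < N; ++i) {
      pos += S[si[i]];
      const double ds = pos;
      pos += A[ai[i]];
      const double de = pos;
      while (ti < T && te[ti] <= ds) ++ti;
      if (count_stat) {
        if (ti < T && ts[ti] < de) stat += 1.0;
      } else {
        for (int tj = ti; tj < T && ts[tj] < de; ++tj) {
          const double lo = ts[tj] > ds ? ts[tj] : ds;
          const double hi = te[tj] < de ? te[tj] : de;
          if (hi > lo) stat += hi - lo;
        }
      }
    }
    out[m] = stat;
  }
  return out;
}
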