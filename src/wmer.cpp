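#include <Rcpp.h>
using namespace Rcpp;

// w-mer pair counting over all diagonals of the (La x Lb) alignment grid.
//
// Sequences arrive as integer vectors: 0..3 for A,C,G,T and -1 for any
// ambiguity code. Ambiguous positions never match anything, themselves
// included, so a match requires a[i] >= 0 && a[i] == b[j].
//
// For a fixed shift s = j - i the identity count of consecutive window
// pairs along that diagonal changes by at most two positions, so each
// diagonal is swept once with a rolling update: subtract the leaving
// position, add the entering one. Total work is O(La * Lb).
//
// Returns both the all-pairs count (number of window pairs with identity
// strictly above n, or >= n when strict = false) and the per-window best
// identity for sequence a, from which the best-pair count and the
// conservation profile are derived in R.

// [[Rcpp::export(name = ".wmer_scan_cpp")]]
List wmer_scan_cpp(IntegerVector a, IntegerVector b, int w, int n,
                   bool strict) {
  const int La = a.size(), Lb = b.size();
  const int na_ = La - w + 1;  // windows in a
  const int nb_ = Lb - w + 1;  // windows in b
  if (na_ < 1 || nb_ < 1)
    stop("both sequences must be at least w nucleotides long");

  const int thr = strict ? n + 1 : n;  // identity needed to qualify
  double total = 0.0;                  // all-pairs count (can exceed 2^31)
  IntegerVector best(na_, 0);          // per-a-window max identity

  const int* pa = INTEGER(a);
  const int* pb = INTEGER(b);
  int* pbest = INTEGER(best);

  // shift s = j - i ranges over [-(na_-1), nb_-1]
  for (int s = -(na_ - 1); s <= nb_ - 1; ++s) {
    const int i0 = s < 0 ? -s : 0;                     // first valid i
    const int i1 = (nb_ - 1 - s) < (na_ - 1) ? (nb_ - 1 - s) : (na_ - 1);
    if (i0 > i1) continue;

    // identity of window pair (i0, i0 + s)
    int ident = 0;
    {
      const int joff = i0 + s;
      for (int k = 0; k < w; ++k) {
        const int x = pa[i0 + k];
        if (x >= 0 && x == pb[joff + k]) ++ident;
      }
    }
    for (int i = i0; ; ++i) {
      if (ident >= thr) total += 1.0;
      if (ident > pbest[i]) pbest[i] = ident;
      if (i == i1) break;
      // roll to window pair (i+1, i+1+s)
      const int xl = pa[i], yl = pb[i + s];
      if (xl >= 0 && xl == yl) --ident;
      const int xe = pa[i + w], ye = pb[i + w + s];
      if (xe >= 0 && xe == ye) ++ident;
    }
  }

  // best-pair count: a-windows whose maximum identity qualifies
  int best_count = 0;
  for (int i = 0; i < na_; ++i)
    if (pbest[i] >= thr) ++best_count;

  return List::create(_["all_pairs"] = total,
                      _["best_pairs"] = best_count,
                      _["best_identity"] = best);
}
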