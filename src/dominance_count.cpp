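#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Fenwick (binary indexed) tree over 1..n with point update / prefix query.
struct Fenwick {
  std::vector<int> t;
  int n;
  explicit Fenwick(int n_) : t(n_ + 1, 0), n(n_) {}
  void add(int i) { for (; i <= n; i += i & (-i)) t[i]++; }
  int query(int i) const { int s = 0; for (; i > 0; i -= i & (-i)) s += t[i]; return s; }
};

//' Joint lower-quadrant counts at the observed points.
//'
//' For each point k returns #\{ m : x[m] <= x[k] and y[m] <= y[k] \}, the
//' point itself included. Ties are handled with <= on both axes, so the
//' count is at least 1. O(n log n) via a Fenwick tree over y-ranks.
//'
//' @param x,y numeric vectors of equal length (no NAs).
//' @return integer vector of counts.
//' @keywords internal
// [[Rcpp::export]]
IntegerVector joint_dominance_count(NumericVector x, NumericVector y) {
  const int n = x.size();
  if (y.size() != n) stop("x and y must have equal length");
  if (n == 0) return IntegerVector(0);

  // compress y to ranks (equal values share a rank)
  std::vector<double> ys(y.begin(), y.end());
  std::sort(ys.begin(), ys.end());
  ys.erase(std::unique(ys.begin(), ys.end()), ys.end());
  std::vector<int> yr(n);
  for (int i = 0; i < n; ++i)
    yr[i] = 1 + (int)(std::lower_bound(ys.begin(), ys.end(), y[i]) - ys.begin());

  // order points by x ascending; process tie groups in x together
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return x[a] < x[b]; });

  Fenwick fw((int)ys.size());
  IntegerVector out(n);
  int i = 0;
  while (i < n) {
    int j = i;
    while (j < n && x[ord[j]] == x[ord[i]]) ++j;
    // insert the whole x-tie group first so mutual ties count both ways
    for (int k = i; k < j; ++k) fw.add(yr[ord[k]]);
    for (int k = i; k < j; ++k) out[ord[k]] = fw.query(yr[ord[k]]);
    i = j;
  }
  return out;
}
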