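#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Prefix sums for O(1) linear-fit RSS on any observation window.
// long double guards against cancellation when t spans hundreds of months.
struct Prefix {
  std::vector<long double> s1, st, stt, sy, sty, syy;
  Prefix(const NumericVector& t, const NumericVector& y) {
    int n = t.size();
    s1.assign(n + 1, 0.0L); st.assign(n + 1, 0.0L); stt.assign(n + 1, 0.0L);
    sy.assign(n + 1, 0.0L); sty.assign(n + 1, 0.0L); syy.assign(n + 1, 0.0L);
    for (int i = 0; i < n; ++i) {
      s1[i + 1]  = s1[i] + 1.0L;
      st[i + 1]  = st[i] + (long double)t[i];
      stt[i + 1] = stt[i] + (long double)t[i] * t[i];
      sy[i + 1]  = sy[i] + (long double)y[i];
      sty[i + 1] = sty[i] + (long double)t[i] * y[i];
      syy[i + 1] = syy[i] + (long double)y[i] * y[i];
    }
  }
  // RSS of least-squares line fitted on observations i..j inclusive (0-based)
  inline double rss(int i, int j) const {
    long double n = s1[j + 1] - s1[i];
    long double St = st[j + 1] - st[i], Stt = stt[j + 1] - stt[i];
    long double Sy = sy[j + 1] - sy[i], Sty = sty[j + 1] - sty[i];
    long double Syy = syy[j + 1] - syy[i];
    long double mt = St / n, my = Sy / n;
    long double sxx = Stt - n * mt * mt;
    long double sxy = Sty - n * mt * my;
    long double syyc = Syy - n * my * my;
    long double out = (sxx > 1e-12L) ? syyc - sxy * sxy / sxx : syyc;
    if (out < 0.0L) out = 0.0L;
    return (double)out;
  }
};

// Optimal partition of an ordered series into (m+1) linear segments for
// m = 0..max_breaks. Interior segments hold >= min_seg observations; the
// first and last segments (series boundaries) only >= min_edge, so
// disturbances near the start or end of the record remain detectable.
// Returns, per m, the minimal total RSS (Inf when infeasible) and the
// 1-based indices of the last observation of each left segment.
// [[Rcpp::export(name = ".dp_breakpoints_cpp")]]
List dp_breakpoints_cpp(NumericVector t, NumericVector y, int min_seg,
                        int min_edge, int max_breaks) {
  int n = t.size();
  if (n != y.size()) stop("t and y lengths differ");
  if (min_seg < 2) min_seg = 2;
  if (min_edge < 2) min_edge = 2;
  if (min_edge > min_seg) min_edge = min_seg;
  if (max_breaks < 0) max_breaks = 0;
  Prefix P(t, y);
  const double INF = R_PosInf;

  // F[m][j]: best RSS for obs 0..j split into m+1 segments, first segment
  // >= min_edge, all later segments >= min_seg (interior rule);
  // the final segment of the full series is handled separately below.
  std::vector< std::vector<double> > F(max_breaks + 1,
                                       std::vector<double>(n, INF));
  std::vector< std::vector<int> > K(max_breaks + 1, std::vector<int>(n, -1));
  for (int j = min_edge - 1; j < n; ++j) F[0][j] = P.rss(0, j);
  for (int m = 1; m <= max_breaks; ++m) {
    for (int j = 0; j < n; ++j) {
      double best = INF; int arg = -1;
      int khi = j - min_seg;
      for (int k = 0; k <= khi; ++k) {
        if (F[m - 1][k] == INF) continue;
        double cand = F[m - 1][k] + P.rss(k + 1, j);
        if (cand < best) { best = cand; arg = k; }
      }
      F[m][j] = best; K[m][j] = arg;
    }
  }

  NumericVector rss(max_breaks + 1);
  List breaks(max_breaks + 1);
  std::vector<int> last_k(max_breaks + 1, -1);
  rss[0] = P.rss(0, n - 1);
  breaks[0] = IntegerVector(0);
  for (int m = 1; m <= max_breaks; ++m) {
    double best = INF; int arg = -1;
    int khi = n - 1 - min_edge;  // final segment is a boundary segment
    for (int k = 0; k <= khi; ++k) {
      if (F[m - 1][k] == INF) continue;
      double cand = F[m - 1][k] + P.rss(k + 1, n - 1);
      if (cand < best) { best = cand; arg = k; }
    }
    rss[m] = best; last_k[m] = arg;
    IntegerVector bp(m);
    if (arg >= 0) {
      int j = arg; bp[m - 1] = arg + 1;
      for (int mm = m - 1; mm >= 1; --mm) {
        int k = K[mm][j];
        bp[mm - 1] = k + 1;
        j = k;
      }
    }
    breaks[m] = bp;
  }
  return List::create(_["rss"] = rss, _["breaks"] = breaks);
}

// Single-repositioning RSS profile for one break, all other breaks held
// fixed. breaks: 1-based last-obs indices (sorted); which: 1-based break to
// move. Boundary segments obey min_edge, interior segments min_seg.
// [[Rcpp::export(name = ".reposition_rss_cpp")]]
List reposition_rss_cpp(NumericVector t, NumericVector y, IntegerVector breaks,
                        int which, int min_seg, int min_edge) {
  int n = t.size(), m = breaks.size();
  if (which < 1 || which > m) stop("'which' out of range");
  if (min_seg < 2) min_seg = 2;
  if (min_edge < 2) min_edge = 2;
  if (min_edge > min_seg) min_edge = min_seg;
  Prefix P(t, y);

  int left_start = (which == 1) ? 0 : breaks[which - 2];        // 0-based start
  int right_end  = (which == m) ? n - 1 : breaks[which] - 1;     // 0-based end
  int lmin = (which == 1) ? min_edge : min_seg;
  int rmin = (which == m) ? min_edge : min_seg;
  int lo = left_start + lmin;       // smallest admissible 1-based position
  int hi = right_end + 1 - rmin;    // largest admissible 1-based position
  if (lo > hi) stop("no admissible repositioning window");

  // RSS of all segments not adjacent to the moving break
  double fixed = 0.0;
  int prev = 0;
  for (int b = 0; b <= m; ++b) {
    int end = (b == m) ? n - 1 : breaks[b] - 1;
    if (b != which - 1 && b != which) fixed += P.rss(prev, end);
    prev = end + 1;
  }
  int npos = hi - lo + 1;
  IntegerVector pos(npos);
  NumericVector rss(npos);
  for (int i = 0; i < npos; ++i) {
    int b = lo + i;  // 1-based candidate
    pos[i] = b;
    rss[i] = fixed + P.rss(left_start, b - 1) + P.rss(b, right_end);
  }
  return List::create(_["pos"] = pos, _["rss"] = rss);
}

// Connected-component labeling of a logical mask, rook (4) or queen (8)
// connectivity. 0 = background, components numbered from 1 in scan order.
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerMatrix label_components_cpp(LogicalMatrix mask, int connectivity) {
  int nr = mask.nrow(), nc = mask.ncol();
  if (connectivity != 4 && connectivity != 8) stop("connectivity must be 4 or 8");
  IntegerMatrix lab(nr, nc);
  int next = 0;
  const int dr4[] = {-1, 1, 0, 0}, dc4[] = {0, 0, -1, 1};
  const int dr8[] = {-1, 1, 0, 0, -1, -1, 1, 1}, dc8[] = {0, 0, -1, 1, -1, 1, -1, 1};
  int nd = (connectivity == 4) ? 4 : 8;
  const int* dr = (connectivity == 4) ? dr4 : dr8;
  const int* dc = (connectivity == 4) ? dc4 : dc8;
  std::queue< std::pair<int,int> > q;
  for (int c0 = 0; c0 < nc; ++c0) for (int r0 = 0; r0 < nr; ++r0) {
    if (!mask(r0, c0) || lab(r0, c0) != 0) continue;
    lab(r0, c0) = ++next;
    q.push(std::make_pair(r0, c0));
    while (!q.empty()) {
      int r = q.front().first, c = q.front().second; q.pop();
      for (int d = 0; d < nd; ++d) {
        int rr = r + dr[d], cc = c + dc[d];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        if (mask(rr, cc) && lab(rr, cc) == 0) {
          lab(rr, cc) = next;
          q.push(std::make_pair(rr, cc));
        }
      }
    }
  }
  return lab;
}
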