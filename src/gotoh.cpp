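#include <Rcpp.h>
using namespace Rcpp;

// Three-layer affine-gap (Gotoh) global alignment over precomputed
// column-pair scores, with per-layer branch matrices recording, for every
// cell, which layer the optimal path entered it from. The alignment is
// recovered from the branch matrices alone (traceback lives in R).
//
// Layers: M = column aligned to column (diagonal move),
//         X = column of A against a gap in B (up move),
//         Y = column of B against a gap in A (left move).
// Branch codes: 1 = from M, 2 = from X, 3 = from Y, 0 = path start.
// Ties prefer M > X > Y everywhere, i.e. diagonal > up > left.

static const double NEG_INF = -1e300;

static inline int best3(double m, double x, double y, double *out) {
  // preference order M > X > Y on exact ties
  int code = 1; double v = m;
  if (x > v) { v = x; code = 2; }
  if (y > v) { v = y; code = 3; }
  *out = v;
  return code;
}

// [[Rcpp::export(name = ".gotoh_dp")]]
List gotoh_dp(NumericMatrix P, double gap_open, double gap_ext) {
  const int m = P.nrow(), n = P.ncol();
  NumericMatrix M(m + 1, n + 1), X(m + 1, n + 1), Y(m + 1, n + 1);
  IntegerMatrix bM(m + 1, n + 1), bX(m + 1, n + 1), bY(m + 1, n + 1);

  M(0, 0) = 0.0; X(0, 0) = NEG_INF; Y(0, 0) = NEG_INF;
  for (int i = 1; i <= m; ++i) {
    M(i, 0) = NEG_INF;
    Y(i, 0) = NEG_INF;
    X(i, 0) = -(gap_open + (i - 1) * gap_ext);
    bX(i, 0) = (i == 1) ? 1 : 2;
  }
  for (int j = 1; j <= n; ++j) {
    M(0, j) = NEG_INF;
    X(0, j) = NEG_INF;
    Y(0, j) = -(gap_open + (j - 1) * gap_ext);
    bY(0, j) = (j == 1) ? 1 : 3;
  }

  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      double v;
      // M: diagonal extension of any layer
      int c = best3(M(i - 1, j - 1), X(i - 1, j - 1), Y(i - 1, j - 1), &v);
      M(i, j) = (v <= NEG_INF / 2) ? NEG_INF : v + P(i - 1, j - 1);
      bM(i, j) = c;
      // X: consume a row of A against a gap in B
      c = best3(M(i - 1, j) - gap_open,
                X(i - 1, j) - gap_ext,
                Y(i - 1, j) - gap_open, &v);
      X(i, j) = (v <= NEG_INF / 2) ? NEG_INF : v;
      bX(i, j) = c;
      // Y: consume a column of B against a gap in A
      c = best3(M(i, j - 1) - gap_open,
                X(i, j - 1) - gap_open,
                Y(i, j - 1) - gap_ext, &v);
      Y(i, j) = (v <= NEG_INF / 2) ? NEG_INF : v;
      bY(i, j) = c;
    }
  }

  double score;
  int final_layer = best3(M(m, n), X(m, n), Y(m, n), &score);
  return List::create(_["score"] = score,
                      _["final_layer"] = final_layer,
                      _["M"] = M, _["X"] = X, _["Y"] = Y,
                      _["bM"] = bM, _["bX"] = bX, _["bY"] = bY);
}
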