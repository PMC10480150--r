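#include <Rcpp.h>
using namespace Rcpp;

// One dynamic-time-warping pass with per-cell cost |p_i - q_j| - lambda.
//
// Steps are {(1,0),(0,1),(1,1)}; free_begin/free_end open the path
// endpoints on the q (column) axis only, which is how the open-begin-end
// variant searches a short profile inside a longer one.  The pass returns
// the path minimizing the lambda-adjusted accumulated cost together with
// its raw accumulated cost and length (number of cells), which is what the
// Dinkelbach iteration in R needs to minimize raw_cost / length exactly.
//
// Tie-break is deterministic: diagonal, then vertical (i-1,j), then
// horizontal (i,j-1); among equal free end columns the smallest j wins.
// [[Rcpp::export(rng = false)]]
List dtw_pass(NumericVector p, NumericVector q, double lambda,
              bool free_begin, bool free_end) {
  const int m = p.size(), n = q.size();
  if (m == 0 || n == 0) stop("profiles must be non-empty");
  NumericMatrix D(m, n);
  IntegerMatrix B(m, n); // 0 = diag, 1 = up (i-1,j), 2 = left (i,j-1), 3 = path start

  for (int j = 0; j < n; ++j) {
    double c = std::fabs(p[0] - q[j]) - lambda;
    if (free_begin) {
      // either start a fresh path at (0, j) or extend one along row 0
      if (j > 0 && D(0, j - 1) < 0) {
        D(0, j) = D(0, j - 1) + c;
        B(0, j) = 2;
      } else {
        D(0, j) = c;
        B(0, j) = 3;
      }
    } else if (j == 0) {
      D(0, 0) = c;
      B(0, 0) = 3;
    } else {
      D(0, j) = D(0, j - 1) + c;
      B(0, j) = 2;
    }
  }
  for (int i = 1; i < m; ++i) {
    D(i, 0) = D(i - 1, 0) + std::fabs(p[i] - q[0]) - lambda;
    B(i, 0) = 1;
    for (int j = 1; j < n; ++j) {
      double c = std::fabs(p[i] - q[j]) - lambda;
      double diag = D(i - 1, j - 1), up = D(i - 1, j), left = D(i, j - 1);
      double best = diag;
      int move = 0;
      if (up < best)   { best = up;   move = 1; }
      if (left < best) { best = left; move = 2; }
      D(i, j) = best + c;
      B(i, j) = move;
    }
  }

  int jend = n - 1;
  if (free_end) {
    for (int j = 0; j < n; ++j)
      if (D(m - 1, j) < D(m - 1, jend)) jend = j;
    // keep the smallest j among exact ties
    for (int j = 0; j < n; ++j)
      if (D(m - 1, j) == D(m - 1, jend)) { jend = j; break; }
  }

  // traceback
  std::vector<int> pi, pj;
  int i = m - 1, j = jend;
  for (;;) {
    pi.push_back(i);
    pj.push_back(j);
    int move = B(i, j);
    if (move == 3) break;
    if (move == 0)      { --i; --j; }
    else if (move == 1) { --i; }
    else                { --j; }
  }
  const int len = (int) pi.size();
  IntegerVector path_i(len), path_j(len);
  double raw = 0.0;
  for (int t = 0; t < len; ++t) {
    path_i[t] = pi[len - 1 - t];
    path_j[t] = pj[len - 1 - t];
    raw += std::fabs(p[path_i[t]] - q[path_j[t]]);
  }

  return List::create(_["adjusted"] = D(m - 1, jend),
                      _["cost"] = raw,
                      _["length"] = len,
                      _["path_i"] = path_i,
                      _["path_j"] = path_j);
}
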