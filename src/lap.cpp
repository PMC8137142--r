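#include <Rcpp.h>
#include <vector>
#include <limits>

// Minimum-cost perfect assignment on a square cost matrix by shortest
// augmenting paths with dual-variable updates (Jonker-Volgenant style,
// O(n^3)).  Entries may be "forbidden" by setting them large but finite;
// the caller is responsible for making the instance feasible (the gated
// matching construction in match_spots() always is, via dummy slots).
//
// Returns the 1-based column assigned to each row.

// [[Rcpp::export]]
Rcpp::IntegerVector lap_solve(Rcpp::NumericMatrix cost) {
  const int n = cost.nrow();
  if (cost.ncol() != n) Rcpp::stop("cost matrix must be square");
  const double INF = std::numeric_limits<double>::infinity();

  std::vector<double> u(n, 0.0), v(n, 0.0);
  std::vector<int> col_of_row(n, -1), row_of_col(n, -1);
  std::vector<double> shortest(n);
  std::vector<int> path(n);
  std::vector<char> in_remaining(n);

  for (int cur = 0; cur < n; ++cur) {
    double minVal = 0.0;
    int i = cur;
    std::fill(shortest.begin(), shortest.end(), INF);
    std::fill(path.begin(), path.end(), -1);
    std::fill(in_remaining.begin(), in_remaining.end(), 1);
    std::vector<int> SR, SC;
    int sink = -1;

    while (sink == -1) {
      SR.push_back(i);
      int index = -1;
      double lowest = INF;
      for (int j = 0; j < n; ++j) {
        if (!in_remaining[j]) continue;
        double r = minVal + cost(i, j) - u[i] - v[j];
        if (r < shortest[j]) { shortest[j] = r; path[j] = i; }
        if (shortest[j] < lowest ||
            (shortest[j] == lowest && row_of_col[j] == -1)) {
          lowest = shortest[j];
          index = j;
        }
      }
      minVal = lowest;
      if (index == -1 || minVal == INF)
        Rcpp::stop("assignment problem is infeasible");
      int j = index;
      in_remaining[j] = 0;
      SC.push_back(j);
      if (row_of_col[j] == -1) sink = j; else i = row_of_col[j];
    }

    u[cur] += minVal;
    for (size_t k = 0; k < SR.size(); ++k) {
      int r = SR[k];
      if (r == cur) continue;
      u[r] += minVal - shortest[col_of_row[r]];
    }
    for (size_t k = 0; k < SC.size(); ++k) {
      int c = SC[k];
      v[c] -= minVal - shortest[c];
    }

    // augment along the alternating path back to cur
    int j = sink;
    while (true) {
      int r = path[j];
      row_of_col[j] = r;
      int tmp = col_of_row[r];
      col_of_row[r] = j;
      j = tmp;
      if (r == cur) break;
    }
  }

  Rcpp::IntegerVector out(n);
  for (int r = 0; r < n; ++r) out[r] = col_of_row[r] + 1;
  return out;
}
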