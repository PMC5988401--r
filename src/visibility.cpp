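#include <Rcpp.h>
#include <vector>
#include <utility>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Divide-and-conquer natural visibility construction.
//
// On a segment [l, r] the (first) maximum m blocks every line of sight
// between a node on its left and a node on its right: the straight segment
// between i < m < j evaluates at m to a convex combination of y_i and y_j,
// which cannot strictly exceed y_m. Hence all edges either are incident to
// m (found by two running-max-slope sweeps) or lie entirely inside
// [l, m-1] or [m+1, r] (found by recursion). Strict inequalities
// throughout: collinear or tied points block visibility.
static void nvg_segment(const std::vector<double>& y, int l, int r,
                        std::vector<int>& ei, std::vector<int>& ej) {
  std::vector<std::pair<int, int>> stack;
  stack.emplace_back(l, r);
  while (!stack.empty()) {
    int a = stack.back().first, b = stack.back().second;
    stack.pop_back();
    if (b - a < 1) continue;
    int m = a;
    for (int k = a + 1; k <= b; ++k)
      if (y[k] > y[m]) m = k;  // first occurrence of the maximum
    // left sweep: i visible from m iff its slope towards m beats all
    // slopes of the nodes in between (strictly)
    double run = -std::numeric_limits<double>::infinity();
    for (int i = m - 1; i >= a; --i) {
      double s = (y[i] - y[m]) / static_cast<double>(m - i);
      if (s > run) {
        ei.push_back(i);
        ej.push_back(m);
        run = s;
      }
    }
    run = -std::numeric_limits<double>::infinity();
    for (int j = m + 1; j <= b; ++j) {
      double s = (y[j] - y[m]) / static_cast<double>(j - m);
      if (s > run) {
        ei.push_back(m);
        ej.push_back(j);
        run = s;
      }
    }
    if (m - 1 > a) stack.emplace_back(a, m - 1);
    if (b > m + 1) stack.emplace_back(m + 1, b);
  }
}

// [[Rcpp::export(name = ".nvg_fast_edges")]]
IntegerMatrix nvg_fast_edges(NumericVector y) {
  int n = y.size();
  std::vector<double> v(y.begin(), y.end());
  std::vector<int> ei, ej;
  ei.reserve(2 * n);
  ej.reserve(2 * n);
  nvg_segment(v, 0, n - 1, ei, ej);
  IntegerMatrix out(ei.size(), 2);
  for (size_t e = 0; e < ei.size(); ++e) {
    out(e, 0) = ei[e] + 1;  // 1-based for R
    out(e, 1) = ej[e] + 1;
  }
  return out;
}

// Stack-based horizontal visibility construction, O(N) amortized.
// Node j sees backwards every stacked node strictly taller than all
// nodes in between; ties block further sight but are themselves visible.
// [[Rcpp::export(name = ".hvg_edges")]]
IntegerMatrix hvg_edges(NumericVector y) {
  int n = y.size();
  std::vector<int> st;
  st.reserve(n);
  std::vector<int> ei, ej;
  ei.reserve(2 * n);
  ej.reserve(2 * n);
  for (int j = 0; j < n; ++j) {
    while (!st.empty() && y[st.back()] < y[j]) {
      ei.push_back(st.back());
      ej.push_back(j);
      st.pop_back();
    }
    if (!st.empty()) {
      ei.push_back(st.back());
      ej.push_back(j);
      if (y[st.back()] == y[j]) st.pop_back();
    }
    st.push_back(j);
  }
  IntegerMatrix out(ei.size(), 2);
  for (size_t e = 0; e < ei.size(); ++e) {
    out(e, 0) = ei[e] + 1;
    out(e, 1) = ej[e] + 1;
  }
  return out;
}
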