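#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Binary erosion with a discrete disk structuring element
// {(di, dj) : di^2 + dj^2 <= radius^2}. Pixels outside the image count as
// background, so the foreground shrinks at image borders too.
// [[Rcpp::export]]
LogicalMatrix cpp_erode_disk(const LogicalMatrix& m, const double radius) {
  const int nr = m.nrow(), nc = m.ncol();
  const int r = (int)std::floor(radius);
  std::vector<int> di, dj;
  for (int a = -r; a <= r; ++a)
    for (int b = -r; b <= r; ++b)
      if ((double)(a * a + b * b) <= radius * radius) {
        di.push_back(a);
        dj.push_back(b);
      }
  const int K = (int)di.size();
  LogicalMatrix out(nr, nc);
  const int* src = LOGICAL(m);
  int* dst = LOGICAL(out);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!src[(size_t)j * nr + i]) { dst[(size_t)j * nr + i] = 0; continue; }
      bool keep = true;
      for (int k = 0; k < K; ++k) {
        const int ii = i + di[k], jj = j + dj[k];
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc ||
            !src[(size_t)jj * nr + ii]) {
          keep = false;
          break;
        }
      }
      dst[(size_t)j * nr + i] = keep ? 1 : 0;
    }
  }
  return out;
}

// Largest 8-connected component of a binary mask; all-FALSE input gives an
// all-FALSE output. Ties broken by lowest label (scan order), which is
// deterministic.
// [[Rcpp::export]]
LogicalMatrix cpp_largest_component8(const LogicalMatrix& m) {
  const int nr = m.nrow(), nc = m.ncol();
  std::vector<int> lab((size_t)nr * nc, 0);
  int next = 0;
  std::vector<long> area;
  std::queue<int> q;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      const int idx = j * nr + i;
      if (!m(i, j) || lab[idx]) continue;
      ++next;
      area.push_back(0);
      lab[idx] = next;
      q.push(idx);
      while (!q.empty()) {
        const int cur = q.front();
        q.pop();
        ++area[next - 1];
        const int ci = cur % nr, cj = cur / nr;
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj) continue;
            const int ii = ci + di, jj = cj + dj;
            if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
            const int nidx = jj * nr + ii;
            if (m(ii, jj) && !lab[nidx]) {
              lab[nidx] = next;
              q.push(nidx);
            }
          }
        }
      }
    }
  }
  LogicalMatrix out(nr, nc);
  if (next == 0) return out;
  int best = 1;
  for (int k = 2; k <= next; ++k)
    if (area[k - 1] > area[best - 1]) best = k;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      out(i, j) = (lab[(size_t)j * nr + i] == best);
  return out;
}
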