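#include <Rcpp.h>
#include <vector>
#include <string>

using namespace Rcpp;

// Greedy O(ND) shortest-edit-script search (insertions/deletions, unit
// cost). Substitutions are not scored directly; a mismatch costs one
// deletion plus one insertion and is collapsed to an 'S' op in R. The full
// V vector is snapshotted per d-round for traceback, so memory grows as
// D^2; common prefix/suffix stripping keeps D small for the near-identical
// chromosome windows this package targets. max_d bounds the search.
//
// Returns a single string over {M,D,I}: M consumes one base of both
// sequences, D one base of a only, I one base of b only.

// [[Rcpp::export]]
std::string myers_ops(std::string a, std::string b, int max_d) {
  int pre = 0;
  int na = a.size(), nb = b.size();
  while (pre < na && pre < nb && a[pre] == b[pre]) ++pre;
  int suf = 0;
  while (suf < na - pre && suf < nb - pre &&
         a[na - 1 - suf] == b[nb - 1 - suf]) ++suf;

  const int n = na - pre - suf;
  const int m = nb - pre - suf;
  const char* A = a.data() + pre;
  const char* B = b.data() + pre;

  std::string mid;
  if (n == 0) {
    mid.assign(m, 'I');
  } else if (m == 0) {
    mid.assign(n, 'D');
  } else {
    int dmax = n + m;
    if (max_d > 0 && max_d < dmax) dmax = max_d;
    const int offset = dmax + 1;
    std::vector<int> V(2 * dmax + 3, 0);
    std::vector< std::vector<int> > trace;  // snapshot after each round
    trace.reserve(dmax + 1);
    int dfound = -1;
    for (int d = 0; d <= dmax && dfound < 0; ++d) {
      for (int k = -d; k <= d; k += 2) {
        int x;
        if (k == -d || (k != d && V[offset + k - 1] < V[offset + k + 1]))
          x = V[offset + k + 1];          // step down: insertion
        else
          x = V[offset + k - 1] + 1;      // step right: deletion
        int y = x - k;
        while (x < n && y < m && A[x] == B[y]) { ++x; ++y; }
        V[offset + k] = x;
        if (x >= n && y >= m) { dfound = d; }
      }
      // keep k in [-d, d]
      trace.push_back(std::vector<int>(V.begin() + (offset - d),
                                       V.begin() + (offset + d + 1)));
      Rcpp::checkUserInterrupt();
    }
    if (dfound < 0)
      stop("sequences differ by more than max_d = %d edits; "
           "raise max_d or align smaller windows", dmax);

    // traceback
    std::string rev;
    int x = n, y = m;
    for (int d = dfound; d > 0; --d) {
      const std::vector<int>& Vp = trace[d - 1];  // indices k: -(d-1)..(d-1)
      int k = x - y;
      // decide move exactly as the forward pass did
      int vkm1 = (k - 1 >= -(d - 1) && k - 1 <= d - 1) ? Vp[(k - 1) + (d - 1)]
                                                       : -1;
      int vkp1 = (k + 1 >= -(d - 1) && k + 1 <= d - 1) ? Vp[(k + 1) + (d - 1)]
                                                       : -1;
      int prev_k;
      if (k == -d || (k != d && vkm1 < vkp1)) prev_k = k + 1;
      else prev_k = k - 1;
      int prev_x = Vp[prev_k + (d - 1)];
      int prev_y = prev_x - prev_k;
      while (x > prev_x && y > prev_y) { rev.push_back('M'); --x; --y; }
      if (d > 0) {
        if (x == prev_x) { rev.push_back('I'); --y; }
        else             { rev.push_back('D'); --x; }
      }
    }
    while (x > 0 && y > 0) { rev.push_back('M'); --x; --y; }
    while (x > 0) { rev.push_back('D'); --x; }
    while (y > 0) { rev.push_back('I'); --y; }
    mid.assign(rev.rbegin(), rev.rend());
  }

  std::string out;
  out.reserve(pre + mid.size() + suf);
  out.append(pre, 'M');
  out.append(mid);
  out.append(suf, 'M');
  return out;
}
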