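#include <Rcpp.h>
#include <cstring>
#include <vector>
using namespace Rcpp;

// Count (possibly overlapping) exact occurrences of pattern in region.
// [[Rcpp::export]]
int cpp_occurrence_count(std::string pattern, std::string region) {
  const int n = (int) pattern.size();
  const int m = (int) region.size();
  if (n == 0) stop("pattern must be non-empty");
  if (n > m) return 0;
  int count = 0;
  const char *p = pattern.data();
  const char *r = region.data();
  for (int i = 0; i + n <= m; ++i) {
    if (std::memcmp(r + i, p, (size_t) n) == 0) ++count;
  }
  return count;
}

// Incremental pattern growth from one end of `read` against `region`.
//
// from3 = true : grow suffixes read[n-L, n); a match of length L at region
//                start q extends to length L+1 at start q-1 (fixed right end).
// from3 = false: grow prefixes read[0, L); a match at start q extends in
//                place (fixed left end).
//
// Occurrence counts over growth are non-increasing, so the set of lengths
// with exactly one occurrence is a contiguous run [firstU, lastU].  The
// reported minimum is the shortest unique length >= min_len, the maximum the
// longest unique length seen before the count reaches zero (or the read is
// exhausted).  If no unique length >= min_len exists, everything is -1.
//
// max_start_excl >= 0 restricts candidate matches to region-local start
// positions strictly below that value (the small-TD termination rule).
//
// Returns integer vector c(min_read_start, min_read_end, min_ref_start,
// min_ref_end, max_read_start, max_read_end, max_ref_start, max_ref_end)
// with region-local ref coordinates, or all -1 when nothing qualifies.
// [[Rcpp::export]]
IntegerVector cpp_grow_unique(std::string read, std::string region,
                              bool from3, int min_len, int max_start_excl) {
  const int n = (int) read.size();
  const int m = (int) region.size();
  IntegerVector out(8, -1);
  if (n == 0 || m == 0) return out;

  std::vector<int> pos;
  pos.reserve(64);
  const char c0 = from3 ? read[n - 1] : read[0];
  for (int q = 0; q < m; ++q) {
    if (region[q] != c0) continue;
    if (max_start_excl >= 0 && q >= max_start_excl) continue;
    pos.push_back(q);
  }

  int firstU = -1, lastU = -1, lastUpos = -1;
  int L = 1;
  for (;;) {
    const int cnt = (int) pos.size();
    if (cnt == 0) break;
    if (cnt == 1) {
      if (firstU < 0) firstU = L;
      lastU = L;
      lastUpos = pos[0];
    }
    if (L == n) break;
    const char nc = from3 ? read[n - 1 - L] : read[L];
    std::vector<int> np;
    np.reserve(pos.size());
    for (size_t i = 0; i < pos.size(); ++i) {
      const int q = pos[i];
      if (from3) {
        if (q - 1 >= 0 && region[q - 1] == nc) np.push_back(q - 1);
      } else {
        if (q + L < m && region[q + L] == nc) np.push_back(q);
      }
    }
    pos.swap(np);
    ++L;
  }

  if (lastU < 0 || lastU < min_len) return out;
  const int minL = firstU > min_len ? firstU : min_len;
  // unique lengths are contiguous; recover the start position at minL
  const int minPos = from3 ? lastUpos + (lastU - minL) : lastUpos;

  if (from3) {
    out[0] = n - minL; out[1] = n;
    out[2] = minPos;   out[3] = minPos + minL;
    out[4] = n - lastU; out[5] = n;
    out[6] = lastUpos;  out[7] = lastUpos + lastU;
  } else {
    out[0] = 0;    out[1] = minL;
    out[2] = minPos; out[3] = minPos + minL;
    out[4] = 0;      out[5] = lastU;
    out[6] = lastUpos; out[7] = lastUpos + lastU;
  }
  return out;
}
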