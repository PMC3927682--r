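#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// N never matches anything, including another N.
static inline int sub_cost(char a, char b) {
  return (a == b && a != 'N') ? 0 : 1;
}

static std::string rle_cigar(const std::vector<char>& ops) {
  std::string out;
  size_t i = 0;
  while (i < ops.size()) {
    size_t j = i;
    while (j < ops.size() && ops[j] == ops[i]) ++j;
    out += std::to_string(j - i);
    out += ops[i];
    i = j;
  }
  return out;
}

// Banded (half-width k) alignment of the full read against window[s..],
// anchored at offset s, end free but not past the window.  On success
// (distance <= k) fills dist/end/cigar and returns true.  Among co-minimal
// end offsets the lexicographically smallest CIGAR wins; traceback prefers
// diagonal over deletion over insertion.  A co-minimal end never ends in a
// deletion, so CIGARs are free of trailing deletions by construction.
static bool band_align(const std::string& read, const std::string& window,
                       int s, int k, int& dist, int& end, std::string& cigar) {
  const int m = read.size();
  const int wl = std::min((int)window.size() - s, m + k);
  if (wl < m - k) return false;
  const int bw = 2 * k + 1;
  const int INF = k + 2;
  std::vector<int> B((m + 1) * bw, INF);
  // B[i*bw + t] = D[i][j], j = i + t - k
  for (int t = k; t < bw && t - k <= wl; ++t) B[t] = t - k;
  for (int i = 1; i <= m; ++i) {
    const char rc = read[i - 1];
    const int jlo = std::max(0, i - k), jhi = std::min(wl, i + k);
    for (int j = jlo; j <= jhi; ++j) {
      const int t = j - i + k;
      int v = INF;
      if (j == 0) v = i;
      else {
        int diag = B[(i - 1) * bw + t];  // D[i-1][j-1]
        if (diag < INF) v = diag + sub_cost(rc, window[s + j - 1]);
        if (t > 0) {
          int left = B[i * bw + t - 1];  // D[i][j-1]
          if (left + 1 < v) v = left + 1;
        }
        if (t + 1 < bw) {
          int up = B[(i - 1) * bw + t + 1];  // D[i-1][j]
          if (up + 1 < v) v = up + 1;
        }
      }
      B[i * bw + t] = std::min(v, INF);
    }
  }
  dist = INF;
  for (int t = 0; t < bw; ++t) {
    const int j = m + t - k;
    if (j < 0 || j > wl) continue;
    dist = std::min(dist, B[m * bw + t]);
  }
  if (dist > k) return false;
  std::string best_cigar;
  int best_end = -1;
  for (int je = std::max(0, m - k); je <= std::min(wl, m + k); ++je) {
    if (B[m * bw + je - m + k] != dist) continue;
    int i = m, j = je;
    std::vector<char> ops;
    while (i > 0) {
      const int t = j - i + k;
      const int cur = B[i * bw + t];
      if (j > 0 && B[(i - 1) * bw + t] < INF &&
          B[(i - 1) * bw + t] + sub_cost(read[i - 1], window[s + j - 1]) == cur) {
        ops.push_back('M'); --i; --j;
      } else if (j > 0 && t > 0 && B[i * bw + t - 1] + 1 == cur) {
        ops.push_back('D'); --j;
      } else {
        ops.push_back('I'); --i;
      }
    }
    // leading deletions: the anchored path may consume j window bases
    // before the first read base; they are charged in the distance and
    // belong in the CIGAR
    for (; j > 0; --j) ops.push_back('D');
    std::reverse(ops.begin(), ops.end());
    std::string cg = rle_cigar(ops);
    if (best_end < 0 || cg < best_cigar) { best_cigar = cg; best_end = je; }
  }
  end = s + best_end - 1;  // 0-based inclusive end of the consumed span
  cigar = best_cigar;
  return true;
}

// Semi-global alignment of a full read against a reference window: a
// complete per-start scan.  Every window offset s is tried as an anchored
// start (banded, half-width k, end free but not past the window) and its
// minimal distance d_s computed.  free_start = true admits every start with
// d_s <= k.  free_start = false treats the window start as the anchor:
// start s is admitted only when the s skipped leading window bases, charged
// as deletions, still fit the threshold together with the alignment
// (d_s + s <= k); the reported distance is d_s, i.e. the charge is stripped.
// Because every start is scanned independently, co-optimal alignments at
// distinct starts are never lost to traceback tie-breaking.
// [[Rcpp::export]]
DataFrame cpp_semiglobal(std::string read, std::string window, int k,
                         bool free_start) {
  const int m = read.size(), w = window.size();
  if (m < 1) stop("read must be non-empty");
  std::vector<int> starts, ends, dists;
  std::vector<std::string> cigars;
  const int smax = free_start ? w : std::min(w, k);
  for (int s = 0; s <= smax; ++s) {
    int dist, end; std::string cigar;
    if (!band_align(read, window, s, k, dist, end, cigar)) continue;
    if (!free_start && dist + s > k) continue;
    starts.push_back(s); ends.push_back(end);
    dists.push_back(dist); cigars.push_back(cigar);
  }
  return DataFrame::create(_["start"] = starts, _["end"] = ends,
                           _["distance"] = dists, _["cigar"] = cigars,
                           _["stringsAsFactors"] = false);
}

// Plain uncapped Levenshtein distance (full dynamic program, two rows).
// [[Rcpp::export]]
int cpp_global_edit(std::string a, std::string b) {
  const int m = a.size(), n = b.size();
  std::vector<int> prev(n + 1), cur(n + 1);
  for (int j = 0; j <= n; ++j) prev[j] = j;
  for (int i = 1; i <= m; ++i) {
    cur[0] = i;
    for (int j = 1; j <= n; ++j) {
      cur[j] = std::min(prev[j - 1] + sub_cost(a[i - 1], b[j - 1]),
                        std::min(cur[j - 1], prev[j]) + 1);
    }
    std::swap(prev, cur);
  }
  return prev[n];
}

// [[Rcpp::export]]
int cpp_hamming(std::string a, std::string b) {
  if (a.size() != b.size()) stop("sequences must have equal length");
  int d = 0;
  for (size_t i = 0; i < a.size(); ++i) d += sub_cost(a[i], b[i]);
  return d;
}

// Exhaustive full-sensitivity scan of one chromosome, one orientation.
// Hamming mode: every window start with <= k mismatches.  Edit mode: every
// start p from which a semi-global alignment of the full read (start anchored
// at p, end free within p + m + k) achieves distance <= k.  Deliberately a
// plain unbanded DP, independent of the banded production kernel.
// [[Rcpp::export]]
DataFrame cpp_oracle_scan(std::string chrom, std::string read, int k,
                          bool edit) {
  const int n = chrom.size(), m = read.size();
  std::vector<int> starts, ends, dists;
  if (!edit) {
    for (int p = 0; p + m <= n; ++p) {
      int d = 0;
      for (int i = 0; i < m && d <= k; ++i) d += sub_cost(read[i], chrom[p + i]);
      if (d <= k) {
        starts.push_back(p); ends.push_back(p + m - 1); dists.push_back(d);
      }
    }
  } else {
    std::vector<int> prev(m + k + 1), cur(m + k + 1);
    for (int p = 0; p < n; ++p) {
      const int wlen = std::min(m + k, n - p);
      if (wlen < m - k) break;
      for (int j = 0; j <= wlen; ++j) prev[j] = j;
      for (int i = 1; i <= m; ++i) {
        cur[0] = i;
        for (int j = 1; j <= wlen; ++j) {
          cur[j] = std::min(prev[j - 1] + sub_cost(read[i - 1], chrom[p + j - 1]),
                            std::min(cur[j - 1], prev[j]) + 1);
        }
        std::swap(prev, cur);
      }
      int best = prev[0], jbest = 0;
      for (int j = 1; j <= wlen; ++j) {
        if (prev[j] < best) { best = prev[j]; jbest = j; }
      }
      if (best <= k) {
        starts.push_back(p); ends.push_back(p + jbest - 1);
        dists.push_back(best);
      }
    }
  }
  return DataFrame::create(_["start"] = starts, _["end"] = ends,
                           _["distance"] = dists);
}

// [[Rcpp::export]]
std::string cpp_revcomp(std::string s) {
  std::string out(s.rbegin(), s.rend());
  for (char& c : out) {
    switch (c) {
      case 'A': c = 'T'; break;
      case 'C': c = 'G'; break;
      case 'G': c = 'C'; break;
      case 'T': c = 'A'; break;
      default:  c = 'N'; break;
    }
  }
  return out;
}
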