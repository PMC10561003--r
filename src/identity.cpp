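#include <Rcpp.h>
#include <vector>
#include <string>
#include <unordered_map>
#include <algorithm>
#include <climits>
using namespace Rcpp;

static inline int base2(char c) {
  switch (c) { case 'A': return 0; case 'C': return 1; case 'G': return 2; case 'T': return 3; }
  return -1;
}

// Number of k-mers shared between read and ref (positions, not distinct
// k-mers), plus the modal diagonal (ref_pos - read_pos) of the matches.
// K-mers containing non-ACGT characters are skipped. k <= 15.
static void kmer_hits(const std::string& read, const std::string& ref, int k,
                      long& n_hits, int& best_diag) {
  n_hits = 0; best_diag = 0;
  int m = (int) read.size(), n = (int) ref.size();
  if (k < 1 || k > 15 || m < k || n < k) return;
  uint32_t mask = (k == 16) ? 0xFFFFFFFFu : ((1u << (2 * k)) - 1u);
  std::unordered_map<uint32_t, std::vector<int> > index;
  uint32_t h = 0; int run = 0;
  for (int i = 0; i < n; ++i) {
    int b = base2(ref[i]);
    if (b < 0) { run = 0; h = 0; continue; }
    h = ((h << 2) | (uint32_t) b) & mask;
    if (++run >= k) index[h].push_back(i - k + 1);
  }
  std::unordered_map<int, long> diag_votes;
  h = 0; run = 0;
  for (int i = 0; i < m; ++i) {
    int b = base2(read[i]);
    if (b < 0) { run = 0; h = 0; continue; }
    h = ((h << 2) | (uint32_t) b) & mask;
    if (++run >= k) {
      std::unordered_map<uint32_t, std::vector<int> >::iterator it = index.find(h);
      if (it != index.end()) {
        int rpos = i - k + 1;
        for (size_t j = 0; j < it->second.size(); ++j) {
          ++n_hits;
          ++diag_votes[it->second[j] - rpos];
        }
      }
    }
  }
  long best = -1;
  for (std::unordered_map<int, long>::iterator it = diag_votes.begin();
       it != diag_votes.end(); ++it) {
    if (it->second > best || (it->second == best && it->first < best_diag)) {
      best = it->second; best_diag = it->first;
    }
  }
}

// [[Rcpp::export]]
double cpp_kmer_hits(std::string read, std::string ref, int k) {
  long n; int d;
  kmer_hits(read, ref, k, n, d);
  return (double) n;
}

// Semi-global edit distance: the read is aligned end-to-end, the reference
// window absorbs free leading/trailing gaps. Unit costs. Band limits the
// explored diagonals around the expected placement; band <= 0 runs the full
// DP. Returns the minimum distance.
static int semiglobal_dist(const std::string& read, const std::string& ref,
                           int exp_off, int band) {
  int m = (int) read.size(), n = (int) ref.size();
  if (m == 0) return 0;
  if (n == 0) return m;
  const int INF = INT_MAX / 4;
  std::vector<int> prev(n + 1), cur(n + 1);
  int lo_prev = 0, hi_prev = n;
  for (int j = 0; j <= n; ++j) prev[j] = 0;  // free start in ref
  for (int i = 1; i <= m; ++i) {
    int lo = 0, hi = n;
    if (band > 0) {
      lo = std::max(0, i + exp_off - band);
      hi = std::min(n, i + exp_off + band);
      if (lo > hi) return INF;
    }
    for (int j = lo; j <= hi; ++j) cur[j] = INF;
    if (lo == 0) cur[0] = i;  // leading read bases deleted
    for (int j = std::max(lo, 1); j <= hi; ++j) {
      int best = INF;
      if (j - 1 >= lo_prev && j - 1 <= hi_prev && prev[j - 1] < INF) {
        int c = prev[j - 1] + (read[i - 1] == ref[j - 1] ? 0 : 1);
        if (c < best) best = c;
      }
      if (j >= lo_prev && j <= hi_prev && prev[j] < INF && prev[j] + 1 < best)
        best = prev[j] + 1;               // read base unmatched
      if (cur[j - 1] < INF && cur[j - 1] + 1 < best)
        best = cur[j - 1] + 1;            // ref base unmatched (gap in read)
      cur[j] = best;
    }
    std::swap(prev, cur);
    lo_prev = lo; hi_prev = hi;
  }
  int d = INF;
  for (int j = lo_prev; j <= hi_prev; ++j) d = std::min(d, prev[j]);
  return d;
}

static std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) {
    switch (r[i]) {
      case 'A': r[i] = 'T'; break; case 'T': r[i] = 'A'; break;
      case 'C': r[i] = 'G'; break; case 'G': r[i] = 'C'; break;
      default: break;
    }
  }
  return r;
}

static double banded_identity(const std::string& read, const std::string& ref,
                              long hits, int diag, int band) {
  int m = (int) read.size(), n = (int) ref.size();
  int d;
  if (hits == 0) {
    d = semiglobal_dist(read, ref, 0, 0);
  } else {
    int pad = band > 0 ? band : 32;
    int lo = std::max(0, diag - pad);
    int hi = std::min(n, diag + m + pad);
    std::string window = ref.substr(lo, hi - lo);
    d = semiglobal_dist(read, window, diag - lo, band);
  }
  if (d > m) d = m;
  return 1.0 - (double) d / (double) m;
}

// Batch best-hit classification: reference k-mer indexes are built once,
// then each read is scored against the top_n references sharing the most
// k-mers (both read orientations), by banded semi-global identity.
// Returns the 1-based index of the best reference (ties -> earlier ref),
// its identity, and the number of candidate refs with shared k-mers.
// [[Rcpp::export]]
DataFrame cpp_assign(std::vector<std::string> reads,
                     std::vector<std::string> refs, int k, int band,
                     int top_n) {
  int nref = (int) refs.size();
  uint32_t mask = (1u << (2 * k)) - 1u;
  std::vector<std::unordered_map<uint32_t, std::vector<int> > > index(nref);
  for (int r = 0; r < nref; ++r) {
    const std::string& s = refs[r];
    uint32_t h = 0; int run = 0;
    for (int i = 0; i < (int) s.size(); ++i) {
      int b = base2(s[i]);
      if (b < 0) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint32_t) b) & mask;
      if (++run >= k) index[r][h].push_back(i - k + 1);
    }
  }
  int nread = (int) reads.size();
  IntegerVector best_ref(nread), n_cand(nread);
  NumericVector identity(nread);
  for (int i = 0; i < nread; ++i) {
    std::string fwd = reads[i];
    std::string rc = revcomp_str(fwd);
    // shared k-mer count and modal diagonal per ref per orientation
    std::vector<long> hits(2 * nref, 0);
    std::vector<int> diag(2 * nref, 0);
    for (int o = 0; o < 2; ++o) {
      const std::string& rd = o == 0 ? fwd : rc;
      std::vector<uint32_t> kmers;
      std::vector<int> kpos;
      uint32_t h = 0; int run = 0;
      for (int p = 0; p < (int) rd.size(); ++p) {
        int b = base2(rd[p]);
        if (b < 0) { run = 0; h = 0; continue; }
        h = ((h << 2) | (uint32_t) b) & mask;
        if (++run >= k) { kmers.push_back(h); kpos.push_back(p - k + 1); }
      }
      for (int r = 0; r < nref; ++r) {
        std::unordered_map<int, long> votes;
        long tot = 0;
        for (size_t q = 0; q < kmers.size(); ++q) {
          std::unordered_map<uint32_t, std::vector<int> >::iterator it =
            index[r].find(kmers[q]);
          if (it == index[r].end()) continue;
          for (size_t j = 0; j < it->second.size(); ++j) {
            ++tot;
            ++votes[it->second[j] - kpos[q]];
          }
        }
        hits[o * nref + r] = tot;
        long best = -1; int bd = 0;
        for (std::unordered_map<int, long>::iterator it = votes.begin();
             it != votes.end(); ++it) {
          if (it->second > best) { best = it->second; bd = it->first; }
        }
        diag[o * nref + r] = bd;
      }
    }
    // candidate refs: top_n by max-orientation shared k-mers, hits > 0
    std::vector<std::pair<long, int> > order;  // (-hits, ref)
    for (int r = 0; r < nref; ++r) {
      long hmax = std::max(hits[r], hits[nref + r]);
      if (hmax > 0) order.push_back(std::make_pair(-hmax, r));
    }
    std::sort(order.begin(), order.end());
    int ncand = std::min((int) order.size(), top_n);
    n_cand[i] = (int) order.size();
    double best_id = -1.0; int best_r = 0;
    for (int c = 0; c < ncand; ++c) {
      int r = order[c].second;
      double id = -1.0;
      if (hits[r] > 0)
        id = banded_identity(fwd, refs[r], hits[r], diag[r], band);
      if (hits[nref + r] > 0) {
        double id2 = banded_identity(rc, refs[r], hits[nref + r],
                                     diag[nref + r], band);
        if (id2 > id) id = id2;
      }
      if (id > best_id + 1e-12 ||
          (id >= best_id - 1e-12 && r < best_r)) {
        best_id = id; best_r = r;
      }
    }
    best_ref[i] = ncand > 0 ? best_r + 1 : NA_INTEGER;
    identity[i] = ncand > 0 ? best_id : NA_REAL;
  }
  return DataFrame::create(_["best_ref"] = best_ref,
                           _["identity"] = identity,
                           _["n_candidates"] = n_cand);
}

// Best-placement identity of a read against a reference: k-mer seeding picks
// the modal diagonal, a window of the reference around it is extracted, and
// a banded semi-global alignment scores it. identity = 1 - dist/len(read).
// With no k-mer hit the full (unbanded) semi-global DP is used.
// [[Rcpp::export]]
double cpp_best_identity(std::string read, std::string ref, int k, int band) {
  int m = (int) read.size(), n = (int) ref.size();
  if (m == 0 || n == 0) return 0.0;
  long hits; int diag;
  kmer_hits(read, ref, k, hits, diag);
  int d;
  if (hits == 0) {
    d = semiglobal_dist(read, ref, 0, 0);
  } else {
    int pad = band > 0 ? band : 32;
    int lo = std::max(0, diag - pad);
    int hi = std::min(n, diag + m + pad);
    std::string window = ref.substr(lo, hi - lo);
    // expected read offset within window
    int exp_off = diag - lo;
    d = semiglobal_dist(read, window, exp_off, band > 0 ? band : 0);
  }
  if (d > m) d = m;
  return 1.0 - (double) d / (double) m;
}
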