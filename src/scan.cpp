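#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// IUPAC nucleotide codes as 4-bit masks: A=1, C=2, G=4, T=8.
static inline int iupac_bits(char c) {
  switch (c) {
    case 'A': return 1;  case 'C': return 2;  case 'G': return 4;  case 'T': return 8;
    case 'R': return 5;  case 'Y': return 10; case 'S': return 6;  case 'W': return 9;
    case 'K': return 12; case 'M': return 3;  case 'B': return 14; case 'D': return 13;
    case 'H': return 11; case 'V': return 7;  case 'N': return 15;
    default:  return 0;  // gaps / unknown: compatible with nothing
  }
}

// complement of a 4-bit base set: swap A<->T, C<->G
static inline int comp_bits(int m) {
  return ((m & 1) << 3) | ((m & 2) << 1) | ((m & 4) >> 1) | ((m & 8) >> 3);
}

static std::vector<int> encode(const std::string& s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = iupac_bits(s[i]);
  return v;
}

// Scan one template for binding sites of a (possibly degenerate) primer.
// A site qualifies when IUPAC-incompatible positions <= max_mm and the
// primer's 3'-terminal three_prime_exact positions are all compatible.
// start is the leftmost plus-strand coordinate of the footprint (0-based).
// [[Rcpp::export]]
DataFrame cpp_scan_sites(std::string primer, std::string templ,
                         int max_mm, int three_prime_exact) {
  std::vector<int> p = encode(primer);
  int L = (int) p.size();
  std::vector<int> t = encode(templ);
  int n = (int) t.size();

  // minus-strand comparison oligo: reverse complement of the primer,
  // compared against the plus strand left-to-right
  std::vector<int> pr(L);
  for (int i = 0; i < L; ++i) pr[i] = comp_bits(p[L - 1 - i]);

  std::vector<int> starts, mms;
  std::vector<std::string> strands;
  if (L > 0 && n >= L) {
    int tpe = three_prime_exact < 0 ? 0 : three_prime_exact;
    if (tpe > L) tpe = L;
    for (int off = 0; off + L <= n; ++off) {
      // plus strand: primer 3' end at the right
      int mm = 0; bool ok = true;
      for (int j = L - 1; j >= 0; --j) {
        if ((p[j] & t[off + j]) == 0) {
          if (j >= L - tpe) { ok = false; break; }
          if (++mm > max_mm) { ok = false; break; }
        }
      }
      if (ok) { starts.push_back(off); mms.push_back(mm); strands.push_back("+"); }
      // minus strand: primer 3' end at the left
      mm = 0; ok = true;
      for (int j = 0; j < L; ++j) {
        if ((pr[j] & t[off + j]) == 0) {
          if (j < tpe) { ok = false; break; }
          if (++mm > max_mm) { ok = false; break; }
        }
      }
      if (ok) { starts.push_back(off); mms.push_back(mm); strands.push_back("-"); }
    }
  }
  return DataFrame::create(_["strand"] = strands, _["start"] = starts,
                           _["mismatches"] = mms,
                           _["stringsAsFactors"] = false);
}

// Does the primer have at least one qualifying site on each template?
// Same rule as cpp_scan_sites, early exit per template.
// [[Rcpp::export]]
LogicalVector cpp_binds_any(std::string primer,
                            std::vector<std::string> templates,
                            int max_mm, int three_prime_exact) {
  std::vector<int> p = encode(primer);
  int L = (int) p.size();
  std::vector<int> pr(L);
  for (int i = 0; i < L; ++i) pr[i] = comp_bits(p[L - 1 - i]);
  int tpe = three_prime_exact < 0 ? 0 : three_prime_exact;
  if (tpe > L) tpe = L;
  LogicalVector out(templates.size());
  for (size_t ti = 0; ti < templates.size(); ++ti) {
    std::vector<int> t = encode(templates[ti]);
    int n = (int) t.size();
    bool found = false;
    for (int off = 0; off + L <= n && !found; ++off) {
      int mm = 0; bool ok = true;
      for (int j = L - 1; j >= 0; --j) {
        if ((p[j] & t[off + j]) == 0) {
          if (j >= L - tpe) { ok = false; break; }
          if (++mm > max_mm) { ok = false; break; }
        }
      }
      if (ok) { found = true; break; }
      mm = 0; ok = true;
      for (int j = 0; j < L; ++j) {
        if ((pr[j] & t[off + j]) == 0) {
          if (j < tpe) { ok = false; break; }
          if (++mm > max_mm) { ok = false; break; }
        }
      }
      if (ok) found = true;
    }
    out[ti] = found;
  }
  return out;
}
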