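#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
#include <string>

using namespace Rcpp;

// 2-bit encoding A=0 C=1 G=2 T=3; lexicographic order on strings over
// {A,C,G,T} coincides with numeric order on codes, so the canonical
// (lexicographic-min) K-mer is the numeric min of the two orientations.
static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
  }
}

static std::string decode_kmer(uint64_t code, int k) {
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    s[i] = bases[code & 3ULL];
    code >>= 2;
  }
  return s;
}

// Rolling canonical count over one sequence; windows containing a non-ACGT
// character contribute nothing (the run restarts after it).
static void count_seq(const std::string& seq, int k,
                      std::unordered_map<uint64_t, double>& tab) {
  const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1ULL) : ~0ULL;
  const int shift = 2 * (k - 1);
  uint64_t fwd = 0, rev = 0;
  int run = 0;
  const size_t n = seq.size();
  for (size_t i = 0; i < n; ++i) {
    int c = base_code(seq[i]);
    if (c < 0) { run = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)c) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - c) << shift);
    if (++run >= k) {
      uint64_t canon = fwd < rev ? fwd : rev;
      tab[canon] += 1.0;
    }
  }
}

static List tab_to_list(const std::unordered_map<uint64_t, double>& tab, int k) {
  const size_t m = tab.size();
  CharacterVector kmers(m);
  NumericVector counts(m);
  size_t i = 0;
  for (auto it = tab.begin(); it != tab.end(); ++it, ++i) {
    kmers[i] = decode_kmer(it->first, k);
    counts[i] = it->second;
  }
  return List::create(_["kmer"] = kmers, _["count"] = counts);
}

// [[Rcpp::export(name = ".cpp_count_kmers")]]
List cpp_count_kmers(std::string seq, int k) {
  std::unordered_map<uint64_t, double> tab;
  count_seq(seq, k, tab);
  return tab_to_list(tab, k);
}

// [[Rcpp::export(name = ".cpp_count_kmers_batch")]]
List cpp_count_kmers_batch(CharacterVector seqs, int k) {
  std::unordered_map<uint64_t, double> tab;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    count_seq(s, k, tab);
  }
  return tab_to_list(tab, k);
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    case 'N': return 'N';
    default:  return c;
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) r[i] = comp_base(r[i]);
  return r;
}

// [[Rcpp::export(name = ".cpp_revcomp")]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
  CharacterVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i)
    out[i] = revcomp(as<std::string>(seqs[i]));
  return out;
}

// Family key for heterozygous-pair grouping: mask position `pos` (1-based)
// of each K-mer. Masking position pos of K corresponds to masking position
// k+1-pos of revcomp(K), and the masked revcomp equals the revcomp of the
// masked string; the key is the (tag, sequence)-lexicographic minimum of
// the two oriented candidates, so a K-mer and its reverse complement always
// land in the same family.
// [[Rcpp::export(name = ".cpp_pair_keys")]]
CharacterVector cpp_pair_keys(CharacterVector kmers, int pos) {
  R_xlen_t n = kmers.size();
  CharacterVector out(n);
  char tag1[8], tag2[8];
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string km = as<std::string>(kmers[i]);
    int k = (int)km.size();
    std::string m1 = km.substr(0, pos - 1) + km.substr(pos);
    std::string m2 = revcomp(m1);
    int p2 = k + 1 - pos;
    snprintf(tag1, sizeof(tag1), "%03d|", pos);
    snprintf(tag2, sizeof(tag2), "%03d|", p2);
    std::string k1 = std::string(tag1) + m1;
    std::string k2 = std::string(tag2) + m2;
    out[i] = (k1 <= k2) ? k1 : k2;
  }
  return out;
}
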