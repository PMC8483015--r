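// Small sequence helpers: per-base substitution errors (driven by R's RNG so
// results follow set.seed), and mean phred quality per read.
#include <Rcpp.h>
#include <string>

using namespace Rcpp;

// [[Rcpp::export]]
CharacterVector cpp_add_substitutions(CharacterVector seqs, double rate) {
  if (rate < 0 || rate >= 1) stop("substitution rate must be in [0, 1)");
  if (rate == 0) return clone(seqs);
  static const char BASES[4] = {'A', 'C', 'G', 'T'};
  RNGScope scope;
  CharacterVector out(seqs.size());
  for (R_xlen_t r = 0; r < seqs.size(); ++r) {
    std::string s = as<std::string>(seqs[r]);
    for (size_t i = 0; i < s.size(); ++i) {
      if (unif_rand() >= rate) continue;
      int cur;
      switch (s[i]) {
        case 'A': cur = 0; break;
        case 'C': cur = 1; break;
        case 'G': cur = 2; break;
        case 'T': cur = 3; break;
        default: continue;
      }
      int shift = 1 + (int)(unif_rand() * 3.0);
      if (shift > 3) shift = 3;
      s[i] = BASES[(cur + shift) % 4];
    }
    out[r] = s;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_mean_phred(CharacterVector quals) {
  NumericVector out(quals.size());
  for (R_xlen_t r = 0; r < quals.size(); ++r) {
    const char *s = CHAR(STRING_ELT(quals, r));
    int len = (int)LENGTH(STRING_ELT(quals, r));
    if (len == 0) { out[r] = NA_REAL; continue; }
    double tot = 0;
    for (int i = 0; i < len; ++i) tot += (double)(s[i] - 33);
    out[r] = tot / len;
  }
  return out;
}
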