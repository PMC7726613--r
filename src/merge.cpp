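#include <Rcpp.h>
using namespace Rcpp;

static inline char comp(char c) {
  switch (c) {
  case 'A': return 'T'; case 'C': return 'G';
  case 'G': return 'C'; case 'T': return 'A';
  case 'a': return 't'; case 'c': return 'g';
  case 'g': return 'c'; case 't': return 'a';
  default: return 'N';
  }
}

// Best-scoring ungapped overlap merge of one read pair. read2/qual2 are as
// sequenced; the reverse complement is taken internally. Candidate offsets
// place the reverse-complemented read2 at position `off` (0-based) of read1;
// the overlap must be >= min_overlap and its mismatch fraction <=
// max_mismatch_frac. Among qualifying offsets the lowest mismatch fraction
// wins, ties broken by the larger overlap, then the smaller offset. At
// mismatched overlap positions the higher-quality base is taken (read1 on
// quality ties).
// [[Rcpp::export(name = ".merge_pairs_cpp")]]
CharacterVector merge_pairs_cpp(CharacterVector read1, CharacterVector qual1,
                                CharacterVector read2, CharacterVector qual2,
                                int min_overlap, double max_mismatch_frac) {
  const R_xlen_t n = read1.size();
  if (qual1.size() != n || read2.size() != n || qual2.size() != n)
    stop("read/quality vectors must have equal length");
  CharacterVector out(n);
  std::string s2, q2r, merged;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (read1[i] == NA_STRING || read2[i] == NA_STRING) {
      out[i] = NA_STRING; continue;
    }
    const std::string s1 = as<std::string>(read1[i]);
    const std::string q1 = as<std::string>(qual1[i]);
    const std::string r2 = as<std::string>(read2[i]);
    const std::string q2 = as<std::string>(qual2[i]);
    const int L1 = (int)s1.size(), L2 = (int)r2.size();
    if ((int)q1.size() != L1 || (int)q2.size() != L2)
      stop("sequence/quality length mismatch at pair %d", (int)(i + 1));
    // reverse complement read2, reverse its qualities
    s2.assign(L2, 'N'); q2r.assign(L2, '!');
    for (int k = 0; k < L2; ++k) {
      s2[k] = comp(r2[L2 - 1 - k]);
      q2r[k] = q2[L2 - 1 - k];
    }
    int best_off = -1, best_ov = 0;
    double best_frac = 2.0;
    const int max_off = L1 - min_overlap;
    for (int off = 0; off <= max_off; ++off) {
      const int ov = std::min(L1 - off, L2);
      if (ov < min_overlap) break;
      int mm = 0;
      for (int k = 0; k < ov; ++k)
        if (s1[off + k] != s2[k]) ++mm;
      const double frac = (double)mm / ov;
      if (frac > max_mismatch_frac) continue;
      if (frac < best_frac - 1e-12 ||
          (std::abs(frac - best_frac) <= 1e-12 && ov > best_ov)) {
        best_frac = frac; best_ov = ov; best_off = off;
      }
    }
    if (best_off < 0) { out[i] = NA_STRING; continue; }
    const int off = best_off, ov = best_ov;
    merged.clear();
    merged.reserve(std::max(L1, off + L2));
    merged.append(s1, 0, off);
    for (int k = 0; k < ov; ++k) {
      if (s1[off + k] == s2[k]) merged.push_back(s1[off + k]);
      else merged.push_back(q2r[k] > q1[off + k] ? s2[k] : s1[off + k]);
    }
    if (off + L2 > L1) merged.append(s2, ov, L2 - ov);
    else if (L1 > off + ov) merged.append(s1, off + ov, L1 - off - ov);
    out[i] = merged;
  }
  return out;
}

// Substitution-only sequencing errors at per-base rate `rate`, drawn from
// R's RNG stream (deterministic under set.seed). Geometric skipping keeps
// the cost proportional to the number of errors, not bases.
// [[Rcpp::export(name = ".add_errors_cpp")]]
CharacterVector add_errors_cpp(CharacterVector seqs, double rate) {
  if (rate <= 0) return seqs;
  const char bases[4] = {'A', 'C', 'G', 'T'};
  const double log1m = std::log1p(-rate);
  const R_xlen_t n = seqs.size();
  CharacterVector out(n);
  RNGScope scope;
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    const int L = (int)s.size();
    double pos = std::floor(std::log(unif_rand()) / log1m);
    bool touched = false;
    while (pos < L) {
      const int p = (int)pos;
      char cur = s[p], sub;
      do {
        sub = bases[(int)(unif_rand() * 4) & 3];
      } while (sub == cur);
      s[p] = sub; touched = true;
      pos += 1 + std::floor(std::log(unif_rand()) / log1m);
    }
    out[i] = touched ? String(s) : seqs[i];
  }
  return out;
}
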