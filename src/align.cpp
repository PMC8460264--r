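#include <Rcpp.h>
using namespace Rcpp;

// Semi-global alignment of a 5'-anchored product read against a reference
// template. Scoring: match +1, mismatch -1, gap -2 (linear). Gaps over the
// 3'-terminal tail of the reference are free, so a partial-length product
// aligns from the primer (5') end and the uncovered tail is truncation, not
// deletion. Ties are broken mismatch-over-indel (diagonal first), then
// reference-gap before read-gap, which yields a deterministic traceback.

static inline int base_idx(char c) {
  switch (c) {
    case 'A': return 1;
    case 'C': return 2;
    case 'G': return 3;
    case 'U': return 4;
  }
  return 0;
}

// [[Rcpp::export]]
List align_semiglobal_cpp(std::string read, std::string ref,
                          int match = 1, int mismatch = -1, int gap = -2) {
  const int n = (int) read.size();
  const int m = (int) ref.size();
  std::vector<int> H((size_t)(n + 1) * (m + 1));
  const int W = m + 1;

  for (int j = 0; j <= m; ++j) H[j] = gap * j;
  for (int i = 1; i <= n; ++i) {
    H[(size_t)i * W] = gap * i;
    const char rc = read[i - 1];
    for (int j = 1; j <= m; ++j) {
      const int s = (rc == ref[j - 1]) ? match : mismatch;
      int best = H[(size_t)(i - 1) * W + (j - 1)] + s;
      const int del = H[(size_t)i * W + (j - 1)] + gap;       // consume ref
      const int ins = H[(size_t)(i - 1) * W + j] + gap;       // consume read
      if (del > best) best = del;
      if (ins > best) best = ins;
      H[(size_t)i * W + j] = best;
    }
  }

  // free 3'-terminal reference gaps: end anywhere on the last read row,
  // preferring the right-most column (covers most reference) among ties
  int end_j = 0;
  int score = H[(size_t)n * W];
  for (int j = 1; j <= m; ++j) {
    if (H[(size_t)n * W + j] >= score) { score = H[(size_t)n * W + j]; end_j = j; }
  }

  IntegerVector status(m);        // 0 uncovered, 1 match, 2 mismatch, 3 deletion
  IntegerVector mism(m);          // read base index (A=1..U=4) where status == 2
  IntegerVector ins_count(m + 1); // inserted read bases after ref position j
  std::vector<std::string> ins_bases((size_t)m + 1);

  int i = n, j = end_j;
  while (i > 0 || j > 0) {
    const int cur = H[(size_t)i * W + j];
    if (i > 0 && j > 0) {
      const int s = (read[i - 1] == ref[j - 1]) ? match : mismatch;
      if (cur == H[(size_t)(i - 1) * W + (j - 1)] + s) {
        status[j - 1] = (s == match) ? 1 : 2;
        if (s != match) mism[j - 1] = base_idx(read[i - 1]);
        --i; --j;
        continue;
      }
      if (cur == H[(size_t)i * W + (j - 1)] + gap) {
        status[j - 1] = 3;
        --j;
        continue;
      }
      ins_count[j] += 1;
      ins_bases[(size_t)j].insert(0, 1, read[i - 1]);
      --i;
      continue;
    }
    if (j > 0) { status[j - 1] = 3; --j; continue; }
    ins_count[0] += 1;
    ins_bases[0].insert(0, 1, read[i - 1]);
    --i;
  }

  CharacterVector insb(m + 1);
  for (int k = 0; k <= m; ++k) insb[k] = ins_bases[(size_t)k];

  return List::create(
    _["score"] = score,
    _["status"] = status,
    _["mism_base"] = mism,
    _["ins_count"] = ins_count,
    _["ins_bases"] = insb,
    _["span"] = IntegerVector::create(end_j > 0 ? 1 : 0, end_j),
    _["read_length"] = n);
}

// Batch aggregation used by the fidelity tally: aligns every read and
// accumulates per-position counts without materialising per-read objects.
// Returns matches/mismatch-by-base/deletions per position, insertions per
// junction, per-read score, end column and read length.
// [[Rcpp::export]]
List align_tally_cpp(CharacterVector reads, std::string ref,
                     int match = 1, int mismatch = -1, int gap = -2) {
  const int m = (int) ref.size();
  const int nr = reads.size();
  IntegerVector matches(m), deletions(m), coverage(m);
  IntegerMatrix mism_by_base(4, m);
  IntegerVector ins(m + 1);
  IntegerVector scores(nr), end_js(nr), read_lens(nr);

  for (int r = 0; r < nr; ++r) {
    std::string rd = as<std::string>(reads[r]);
    List a = align_semiglobal_cpp(rd, ref, match, mismatch, gap);
    IntegerVector status = a["status"];
    IntegerVector mb = a["mism_base"];
    IntegerVector ic = a["ins_count"];
    for (int j = 0; j < m; ++j) {
      if (status[j] == 0) continue;
      coverage[j] += 1;
      if (status[j] == 1) matches[j] += 1;
      else if (status[j] == 2) mism_by_base(mb[j] - 1, j) += 1;
      else deletions[j] += 1;
    }
    for (int j = 0; j <= m; ++j) ins[j] += ic[j];
    scores[r] = as<int>(a["score"]);
    IntegerVector sp = a["span"];
    end_js[r] = sp[1];
    read_lens[r] = as<int>(a["read_length"]);
  }

  return List::create(
    _["matches"] = matches,
    _["mismatch_by_base"] = mism_by_base,
    _["deletions"] = deletions,
    _["coverage"] = coverage,
    _["insertions"] = ins,
    _["score"] = scores,
    _["end_ref"] = end_js,
    _["read_length"] = read_lens);
}

// Unit-cost Levenshtein edit distance.
// [[Rcpp::export]]
IntegerVector levenshtein_cpp(CharacterVector a, std::string b) {
  const int m = (int) b.size();
  const int nr = a.size();
  IntegerVector out(nr);
  std::vector<int> prev(m + 1), cur(m + 1);
  for (int r = 0; r < nr; ++r) {
    std::string s = as<std::string>(a[r]);
    const int n = (int) s.size();
    for (int j = 0; j <= m; ++j) prev[j] = j;
    for (int i = 1; i <= n; ++i) {
      cur[0] = i;
      for (int j = 1; j <= m; ++j) {
        const int sub = prev[j - 1] + (s[i - 1] == b[j - 1] ? 0 : 1);
        cur[j] = std::min(sub, std::min(prev[j] + 1, cur[j - 1] + 1));
      }
      std::swap(prev, cur);
    }
    out[r] = prev[m];
  }
  return out;
}
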