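#include <Rcpp.h>
using namespace Rcpp;

// Leftmost 1-based position at which `adapter` matches `read`, allowing up to
// `max_mm` mismatches over the aligned region, which must be at least
// `min_seed` bases long (matches running off the 3' end are allowed as long
// as the remaining overlap reaches min_seed). 'N' never matches. NA if none.
// [[Rcpp::export]]
IntegerVector adapter_clip_pos(CharacterVector reads, std::string adapter,
                               int max_mm, int min_seed) {
  int n = reads.size();
  int alen = adapter.size();
  IntegerVector out(n, NA_INTEGER);
  for (int i = 0; i < n; ++i) {
    if (reads[i] == NA_STRING) continue;
    const char *r = CHAR(reads[i]);
    int rlen = LENGTH(STRING_ELT(reads, i));
    int last = rlen - min_seed;  // 0-based last admissible start
    for (int p = 0; p <= last; ++p) {
      int ov = std::min(alen, rlen - p);
      if (ov < min_seed) break;
      int mm = 0;
      for (int j = 0; j < ov; ++j) {
        char a = r[p + j], b = adapter[j];
        if (a != b || a == 'N' || b == 'N') {
          if (++mm > max_mm) break;
        }
      }
      if (mm <= max_mm) { out[i] = p + 1; break; }
    }
  }
  return out;
}

// Kept length after 5'->3' sliding-window quality truncation: the read is cut
// at the start of the first `window`-base window whose mean quality is below
// `minq`. Quality strings are Phred+33. Reads shorter than `window` are kept
// whole if their overall mean passes, else cut to 0.
// [[Rcpp::export]]
IntegerVector qual_trim_len(CharacterVector quals, int window, double minq) {
  int n = quals.size();
  IntegerVector out(n, NA_INTEGER);
  double thr = minq * window;
  for (int i = 0; i < n; ++i) {
    if (quals[i] == NA_STRING) continue;
    const char *q = CHAR(quals[i]);
    int len = LENGTH(STRING_ELT(quals, i));
    if (len == 0) { out[i] = 0; continue; }
    if (len < window) {
      double s = 0;
      for (int j = 0; j < len; ++j) s += q[j] - 33;
      out[i] = (s / len < minq) ? 0 : len;
      continue;
    }
    double s = 0;
    for (int j = 0; j < window; ++j) s += q[j] - 33;
    int cut = len;
    if (s < thr) cut = 0;
    else {
      for (int j = 1; j + window <= len; ++j) {
        s += (q[j + window - 1] - 33) - (q[j - 1] - 33);
        if (s < thr) { cut = j; break; }
      }
    }
    out[i] = cut;
  }
  return out;
}

// For each pair, scan all candidate overlaps o in [min_overlap, min(l1,l2)]
// between the 3' end of s1 and the 5' end of s2 (s2 already given on the
// same strand, i.e. reverse-complemented by the caller). Mismatch ratio
// mm/o is minimized; ties go to the larger overlap. 'N' counts as mismatch.
// Returns an n x 2 matrix (best overlap length, mismatches), 0/NA if no
// admissible overlap exists.
// [[Rcpp::export]]
IntegerMatrix best_overlap(CharacterVector s1, CharacterVector s2,
                           int min_overlap) {
  int n = s1.size();
  IntegerMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    const char *a = CHAR(s1[i]);
    const char *b = CHAR(s2[i]);
    int l1 = LENGTH(STRING_ELT(s1, i));
    int l2 = LENGTH(STRING_ELT(s2, i));
    int omax = std::min(l1, l2);
    int best_o = 0, best_mm = 0;
    double best_r = 2.0;
    for (int o = min_overlap; o <= omax; ++o) {
      const char *pa = a + (l1 - o);
      int mm = 0;
      for (int j = 0; j < o; ++j) {
        char x = pa[j], y = b[j];
        if (x != y || x == 'N' || y == 'N') ++mm;
      }
      double r = (double)mm / o;
      if (r < best_r || (r == best_r && o > best_o)) {
        best_r = r; best_o = o; best_mm = mm;
      }
    }
    out(i, 0) = best_o;
    out(i, 1) = best_mm;
  }
  return out;
}

// Ungapped x-drop extension of word seeds. qseqs/sseqs are the query and
// subject sequence sets; each seed row (qid, sid, qpos, spos) is 1-based.
// `sm` is a 128x128 score matrix indexed by character code. Extension
// proceeds left of the word and right of the word, stopping when the running
// score drops more than `xdrop` below the running maximum. Returns n x 5:
// score, qstart, qend, sstart, send (1-based, inclusive).
// [[Rcpp::export]]
IntegerMatrix xdrop_extend(CharacterVector qseqs, CharacterVector sseqs,
                           IntegerVector qid, IntegerVector sid,
                           IntegerVector qpos, IntegerVector spos,
                           int word, IntegerMatrix sm, int xdrop) {
  int n = qid.size();
  IntegerMatrix out(n, 5);
  for (int i = 0; i < n; ++i) {
    const char *q = CHAR(qseqs[qid[i] - 1]);
    const char *s = CHAR(sseqs[sid[i] - 1]);
    int ql = LENGTH(STRING_ELT(qseqs, qid[i] - 1));
    int sl = LENGTH(STRING_ELT(sseqs, sid[i] - 1));
    int q0 = qpos[i] - 1, s0 = spos[i] - 1;  // 0-based word start
    int score = 0;
    for (int j = 0; j < word; ++j)
      score += sm((unsigned char)q[q0 + j], (unsigned char)s[s0 + j]);
    // right extension
    int best = score, run = score;
    int qe = q0 + word - 1, se = s0 + word - 1, bqe = qe, bse = se;
    while (qe + 1 < ql && se + 1 < sl) {
      ++qe; ++se;
      run += sm((unsigned char)q[qe], (unsigned char)s[se]);
      if (run > best) { best = run; bqe = qe; bse = se; }
      if (run < best - xdrop) break;
    }
    // left extension
    int run2 = best;
    int best2 = best;
    int qs = q0, ss = s0, bqs = q0, bss = s0;
    while (qs > 0 && ss > 0) {
      --qs; --ss;
      run2 += sm((unsigned char)q[qs], (unsigned char)s[ss]);
      if (run2 > best2) { best2 = run2; bqs = qs; bss = ss; }
      if (run2 < best2 - xdrop) break;
    }
    out(i, 0) = best2;
    out(i, 1) = bqs + 1;
    out(i, 2) = bqe + 1;
    out(i, 3) = bss + 1;
    out(i, 4) = bse + 1;
  }
  return out;
}
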