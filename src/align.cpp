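#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Gotoh affine-gap alignment with gap cost(k) = gap_open + k * gap_extend.
//
// Two modes:
//   "glocal": read global, reference local (free reference overhangs).
//             Reads are amplicon subfragments, so every read base is
//             accounted for while the reference may extend past the read.
//   "local":  Smith-Waterman, used when scanning candidate vector
//             segments against the vector genome.
//
// Traceback preference is fixed (diagonal > deletion > insertion, and on
// equal end scores the smallest reference coordinate) so results are
// deterministic; indel left-alignment is finished off in R.

static const int NEG = -100000000;

inline int subscore(char a, char b, int match, int mismatch) {
  // N (or any non-ACGT) never counts as a match
  if (a != b) return -mismatch;
  switch (a) {
    case 'A': case 'C': case 'G': case 'T': return match;
    default: return -mismatch;
  }
}

// [[Rcpp::export]]
List affine_align_cpp(std::string read, std::string ref,
                      int match, int mismatch, int gap_open, int gap_extend,
                      std::string mode) {
  const int n = read.size(), m = ref.size();
  const bool local = (mode == "local");
  if (n == 0) stop("empty read");
  if (m == 0) stop("empty reference");

  // H: best score ending at (i,j); D: gap in read (consumes ref);
  // I: gap in ref (consumes read)
  std::vector<int> Hprev(m + 1), Hcur(m + 1), Iprev(m + 1), Icur(m + 1);
  std::vector<int> Dcur(m + 1);
  // traceback: state matrices, 2 bits per entry packed in bytes
  // tbH: 0=diag, 1=fromD, 2=fromI, 3=stop(local)/boundary
  std::vector<unsigned char> tbH((n + 1) * (m + 1), 3);
  std::vector<unsigned char> tbD((n + 1) * (m + 1), 0); // 1 = extend
  std::vector<unsigned char> tbI((n + 1) * (m + 1), 0);

  for (int j = 0; j <= m; ++j) {
    Hprev[j] = 0;                      // free ref prefix in both modes
    Iprev[j] = NEG;
  }
  int best = NEG, best_i = 0, best_j = 0;
  const int go = gap_open + gap_extend, ge = gap_extend;

  for (int i = 1; i <= n; ++i) {
    unsigned char *tH = &tbH[(size_t)i * (m + 1)];
    unsigned char *tD = &tbD[(size_t)i * (m + 1)];
    unsigned char *tI = &tbI[(size_t)i * (m + 1)];
    const char ri = read[i - 1];
    // read prefix must be consumed: leading insertion in glocal mode
    Icur[0] = -(gap_open + i * gap_extend);
    Hcur[0] = local ? 0 : Icur[0];
    Dcur[0] = NEG;
    if (!local) tH[0] = 2;
    int hdiag = Hprev[0];              // H[i-1][j-1]
    int hleft = Hcur[0], dleft = Dcur[0];
    for (int j = 1; j <= m; ++j) {
      // D: gap in read along j
      int d_open = hleft - go, d_ext = dleft - ge;
      int d; unsigned char td;
      if (d_ext > d_open) { d = d_ext; td = 1; } else { d = d_open; td = 0; }
      tD[j] = td;
      // I: gap in ref along i
      int i_open = Hprev[j] - go, i_ext = Iprev[j] - ge;
      int iv; unsigned char ti;
      if (i_ext > i_open) { iv = i_ext; ti = 1; } else { iv = i_open; ti = 0; }
      tI[j] = ti;
      // H
      int h = hdiag + subscore(ri, ref[j - 1], match, mismatch);
      unsigned char t = 0;
      if (d > h) { h = d; t = 1; }
      if (iv > h) { h = iv; t = 2; }
      if (local && h < 0) { h = 0; t = 3; }
      tH[j] = t;
      hdiag = Hprev[j];
      Hprev[j] = h; Iprev[j] = iv;     // reuse rows in place
      hleft = h; dleft = d;
      Dcur[j] = d;
      if (local && h > best) { best = h; best_i = i; best_j = j; }
    }
    Hprev[0] = Hcur[0]; Iprev[0] = Icur[0];
  }
  if (!local) {
    // free ref suffix: best over last row; smallest j on ties
    for (int j = 0; j <= m; ++j)
      if (Hprev[j] > best) { best = Hprev[j]; best_i = n; best_j = j; }
  }

  // Traceback needs full matrices for state values only; we stored the
  // choices, which is enough to walk back without scores.
  std::vector<int> op_code; std::vector<int> op_ref; std::vector<int> op_read;
  int i = best_i, j = best_j;
  int state = 0; // 0=H, 1=D, 2=I
  // ops recorded per column of the alignment, reversed later
  // codes: 0 match, 1 substitution, 2 insertion (read base), 3 deletion (ref base)
  while (i > 0 || (state != 0 && j > 0)) {
    if (state == 0) {
      unsigned char t = tbH[i * (m + 1) + j];
      if (local && t == 3) break;
      if (i == 0) break; // glocal boundary: free ref prefix
      if (t == 0) {
        int code = (subscore(read[i - 1], ref[j - 1], match, mismatch) == match) ? 0 : 1;
        op_code.push_back(code); op_ref.push_back(j - 1); op_read.push_back(i - 1);
        --i; --j;
      } else if (t == 1) state = 1;
      else state = 2;
    } else if (state == 1) {
      unsigned char t = tbD[i * (m + 1) + j];
      op_code.push_back(3); op_ref.push_back(j - 1); op_read.push_back(i);
      --j;
      if (t == 0) state = 0;
      if (j == 0) state = 0;
    } else {
      unsigned char t = tbI[i * (m + 1) + j];
      op_code.push_back(2); op_ref.push_back(j); op_read.push_back(i - 1);
      --i;
      if (t == 0) state = 0;
    }
  }
  std::reverse(op_code.begin(), op_code.end());
  std::reverse(op_ref.begin(), op_ref.end());
  std::reverse(op_read.begin(), op_read.end());

  // compress into runs
  std::vector<int> r_code, r_refstart, r_readstart, r_len;
  for (size_t k = 0; k < op_code.size(); ++k) {
    if (!r_code.empty() && r_code.back() == op_code[k] &&
        ((op_code[k] == 2 && op_read[k] == r_readstart.back() + r_len.back()) ||
         (op_code[k] == 3 && op_ref[k] == r_refstart.back() + r_len.back()) ||
         (op_code[k] <= 1 && op_ref[k] == r_refstart.back() + r_len.back() &&
          op_read[k] == r_readstart.back() + r_len.back()))) {
      r_len.back()++;
    } else {
      r_code.push_back(op_code[k]);
      r_refstart.push_back(op_ref[k]);
      r_readstart.push_back(op_read[k]);
      r_len.push_back(1);
    }
  }
  int ref_start = m, ref_end = 0, read_start = n, read_end = 0;
  if (!op_code.empty()) {
    read_start = op_read.front();
    read_end = op_read.back() + (op_code.back() == 3 ? 0 : 1);
    ref_start = op_ref.front();
    ref_end = op_ref.back() + (op_code.back() == 2 ? 0 : 1);
    // leading insertion has ref coordinate of following column
    for (size_t k = 0; k < op_code.size(); ++k)
      if (op_code[k] != 2) { ref_start = op_ref[k]; break; }
  } else { ref_start = best_j; ref_end = best_j; read_start = best_i; read_end = best_i; }

  CharacterVector opname(r_code.size());
  for (size_t k = 0; k < r_code.size(); ++k)
    opname[k] = (r_code[k] == 0) ? "match" : (r_code[k] == 1) ? "substitution"
              : (r_code[k] == 2) ? "insertion" : "deletion";

  return List::create(
    _["score"] = best,
    _["ref_start"] = ref_start, _["ref_end"] = ref_end,
    _["read_start"] = read_start, _["read_end"] = read_end,
    _["ops"] = DataFrame::create(
      _["op"] = opname,
      _["ref_start"] = IntegerVector(r_refstart.begin(), r_refstart.end()),
      _["read_start"] = IntegerVector(r_readstart.begin(), r_readstart.end()),
      _["length"] = IntegerVector(r_len.begin(), r_len.end()),
      _["stringsAsFactors"] = false));
}
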