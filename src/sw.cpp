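#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Smith-Waterman local alignment of a position-specific profile against a
// subject sequence, affine gaps (gap of length k costs open + k*ext), full
// traceback. The sequence-sequence case is the profile whose row i is the
// substitution-matrix row of query residue i.
//
// profile: L x A integer matrix, profile(i, a) = score of aligning query
//          position i+1 to alphabet letter a+1.
// subject: integer vector of 0-based alphabet indices.
//
// Tie-break (deterministic): cell choice prefers diagonal, then gap in
// subject (query residue over '-'), then gap in query; the best cell is the
// first maximum in row-major (query-outer) scan order.
//
// Returns score 0 and empty spans when no cell scores > 0.
// [[Rcpp::export(name = ".sw_align")]]
List sw_align(IntegerMatrix profile, IntegerVector subject,
              int gap_open, int gap_ext) {
  const int L = profile.nrow();
  const int N = subject.size();
  const int A = profile.ncol();
  const int NEG = -1073741824;  // -2^30: safe -inf
  const int gof = gap_open + gap_ext;  // first gap column cost

  // H, E (gap in subject: consumes query), F (gap in query: consumes subject)
  std::vector<int> Hprev(N + 1, 0), Hcur(N + 1, 0);
  std::vector<int> Eprev(N + 1, NEG), Ecur(N + 1, NEG);
  // traceback: tb[i][j] packs origin of H (2 bits), E-extend flag, F-extend
  // flag: bits 0-1: 0=stop,1=diag,2=E,3=F; bit 2: E came from E above;
  // bit 3: F came from F left.
  std::vector<unsigned char> tb((size_t)(L + 1) * (N + 1), 0);

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= L; ++i) {
    Hcur[0] = 0; Ecur[0] = NEG;
    int Fval = NEG;
    for (int j = 1; j <= N; ++j) {
      int a = subject[j - 1];
      if (a < 0 || a >= A) stop("subject index out of alphabet range");
      int diag = Hprev[j - 1] + profile(i - 1, a);
      int e_open = Hprev[j] - gof;
      int e_ext = Eprev[j] - gap_ext;
      int Eval = e_open >= e_ext ? e_open : e_ext;
      int f_open = Hcur[j - 1] - gof;
      int f_ext = Fval - gap_ext;
      int Fnew = f_open >= f_ext ? f_open : f_ext;
      Fval = Fnew;
      int h = 0; unsigned char dir = 0;
      if (diag > h) { h = diag; dir = 1; }
      if (Eval > h) { h = Eval; dir = 2; }
      if (Fnew > h) { h = Fnew; dir = 3; }
      unsigned char flags = dir;
      if (e_ext > e_open) flags |= 4;   // strict: tie prefers fresh open
      if (f_ext > f_open) flags |= 8;
      tb[(size_t)i * (N + 1) + j] = flags;
      Hcur[j] = h; Ecur[j] = Eval;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur);
    std::swap(Eprev, Ecur);
  }

  if (best <= 0)
    return List::create(_["score"] = 0, _["q_start"] = NA_INTEGER,
                        _["q_end"] = NA_INTEGER, _["s_start"] = NA_INTEGER,
                        _["s_end"] = NA_INTEGER, _["ops"] = "");

  // traceback from (bi, bj)
  std::string ops;
  int i = bi, j = bj;
  int state = 0;  // 0 = in H, 1 = in E, 2 = in F
  while (true) {
    unsigned char flags = tb[(size_t)i * (N + 1) + j];
    if (state == 0) {
      unsigned char dir = flags & 3;
      if (dir == 0) break;
      if (dir == 1) { ops.push_back('M'); --i; --j; }
      else if (dir == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      ops.push_back('D');  // query residue over subject gap
      bool ext = flags & 4;
      --i;
      if (!ext) state = 0;
    } else {
      ops.push_back('I');  // query gap over subject residue
      bool ext = flags & 8;
      --j;
      if (!ext) state = 0;
    }
  }
  std::reverse(ops.begin(), ops.end());
  return List::create(_["score"] = best, _["q_start"] = i + 1,
                      _["q_end"] = bi, _["s_start"] = j + 1,
                      _["s_end"] = bj, _["ops"] = ops);
}

// Scores of the best local alignment of the profile against each subject in
// a database (no traceback; used for E-value calibration).
// [[Rcpp::export(name = ".sw_score_db")]]
IntegerVector sw_score_db(IntegerMatrix profile, List subjects,
                          int gap_open, int gap_ext) {
  const int L = profile.nrow();
  const int A = profile.ncol();
  const int NEG = -1073741824;
  const int gof = gap_open + gap_ext;
  const int nseq = subjects.size();
  IntegerVector out(nseq);
  for (int k = 0; k < nseq; ++k) {
    IntegerVector subj = subjects[k];
    const int N = subj.size();
    std::vector<int> Hprev(N + 1, 0), Hcur(N + 1, 0);
    std::vector<int> Eprev(N + 1, NEG), Ecur(N + 1, NEG);
    int best = 0;
    for (int i = 1; i <= L; ++i) {
      Hcur[0] = 0; Ecur[0] = NEG;
      int Fval = NEG;
      for (int j = 1; j <= N; ++j) {
        int a = subj[j - 1];
        if (a < 0 || a >= A) stop("subject index out of alphabet range");
        int Eval = std::max(Hprev[j] - gof, Eprev[j] - gap_ext);
        Fval = std::max(Hcur[j - 1] - gof, Fval - gap_ext);
        int h = std::max(0, Hprev[j - 1] + profile(i - 1, a));
        h = std::max(h, std::max(Eval, Fval));
        Hcur[j] = h; Ecur[j] = Eval;
        if (h > best) best = h;
      }
      std::swap(Hprev, Hcur);
      std::swap(Eprev, Ecur);
    }
    out[k] = best;
  }
  return out;
}
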