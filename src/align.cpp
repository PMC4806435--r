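#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Overlap-style alignment of a read against an amplicon reference:
// unaligned read ends are soft-clipped without penalty and reference
// flanks are free, interior operations are match/mismatch (M),
// insertion-in-read (I) and deletion-from-reference (D). Gap cost for a
// run of length L is min(gap_open + gap_ext * L, gap_cap): the ceiling
// keeps a single long deletion cheaper than clipping half the read, which
// is what Cas9-induced large deletions in short amplicons require.
//
// States: 0 = M, 1 = D affine, 2 = D capped, 3 = I affine, 4 = I capped.
// Traceback prefers M > D > I on score ties and, for the end cell, the
// leftmost (smallest reference, then read, coordinate) maximum.

static const double NEG_INF = -1e18;

// [[Rcpp::export(name = ".align_read_cpp")]]
List align_read_cpp(std::string read, std::string ref,
                    double match = 1.0, double mismatch = -2.0,
                    double gap_open = -6.0, double gap_ext = -0.5,
                    double gap_cap = -25.0) {
  const int m = (int)read.size(), n = (int)ref.size();
  if (m == 0 || n == 0) {
    return List::create(_["aligned"] = false);
  }
  const double open1 = gap_open + gap_ext;  // cost of opening a 1-base gap

  // row-major (m+1) x (n+1)
  auto idx = [n](int i, int j) { return (size_t)i * (n + 1) + j; };
  std::vector<double> M((size_t)(m + 1) * (n + 1), NEG_INF),
      D = M, D2 = M, I = M, I2 = M;
  // pointer codes: for M, which predecessor state fed the diagonal
  // (0=M,1=D,2=D2,3=I,4=I2,5=fresh start); for gap states, 0=open from M,
  // 1=extend
  std::vector<unsigned char> pM(M.size(), 5), pD(M.size(), 0),
      pD2(M.size(), 0), pI(M.size(), 0), pI2(M.size(), 0);

  double best = 0.0;  // empty alignment scores 0
  int bi = -1, bj = -1;

  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      const size_t c = idx(i, j), dg = idx(i - 1, j - 1),
                   up = idx(i - 1, j), lf = idx(i, j - 1);
      // M: preference order M > D > D2 > I > I2 > start on ties
      double prev = M[dg];
      unsigned char code = 0;
      if (D[dg] > prev) { prev = D[dg]; code = 1; }
      if (D2[dg] > prev) { prev = D2[dg]; code = 2; }
      if (I[dg] > prev) { prev = I[dg]; code = 3; }
      if (I2[dg] > prev) { prev = I2[dg]; code = 4; }
      if (0.0 > prev) { prev = 0.0; code = 5; }
      const double s = (read[i - 1] == ref[j - 1]) ? match : mismatch;
      M[c] = prev + s;
      pM[c] = code;

      // D: consume reference (horizontal)
      double dopen = M[lf] + open1, dext = D[lf] + gap_ext;
      if (dopen >= dext) { D[c] = dopen; pD[c] = 0; }
      else { D[c] = dext; pD[c] = 1; }
      double d2open = M[lf] + gap_cap, d2ext = D2[lf];
      if (d2open >= d2ext) { D2[c] = d2open; pD2[c] = 0; }
      else { D2[c] = d2ext; pD2[c] = 1; }

      // I: consume read (vertical)
      double iopen = M[up] + open1, iext = I[up] + gap_ext;
      if (iopen >= iext) { I[c] = iopen; pI[c] = 0; }
      else { I[c] = iext; pI[c] = 1; }
      double i2open = M[up] + gap_cap, i2ext = I2[up];
      if (i2open >= i2ext) { I2[c] = i2open; pI2[c] = 0; }
      else { I2[c] = i2ext; pI2[c] = 1; }

      if (M[c] > best) { best = M[c]; bi = i; bj = j; }
    }
  }
  // leftmost tie-break over end cells: smallest j then smallest i
  for (int j = 1; j <= n && bi >= 0; ++j) {
    for (int i = 1; i <= m; ++i) {
      if (M[idx(i, j)] == best) { bi = i; bj = j; j = n + 1; break; }
    }
  }
  if (bi < 0) {
    return List::create(_["aligned"] = false, _["score"] = 0.0);
  }

  // traceback
  std::string ops;
  int i = bi, j = bj, state = 0;
  while (true) {
    const size_t c = idx(i, j);
    if (state == 0) {
      ops.push_back('M');
      const unsigned char code = pM[c];
      --i; --j;
      if (code == 5) break;
      state = code;
    } else if (state == 1 || state == 2) {
      ops.push_back('D');
      const unsigned char code = (state == 1) ? pD[c] : pD2[c];
      --j;
      if (code == 0) state = 0;
    } else {
      ops.push_back('I');
      const unsigned char code = (state == 3) ? pI[c] : pI2[c];
      --i;
      if (code == 0) state = 0;
    }
  }
  std::reverse(ops.begin(), ops.end());

  // run-length encode, with soft clips for unaligned read ends
  std::vector<char> op_out;
  std::vector<int> len_out;
  if (i > 0) { op_out.push_back('S'); len_out.push_back(i); }
  for (size_t k = 0; k < ops.size();) {
    size_t k2 = k;
    while (k2 < ops.size() && ops[k2] == ops[k]) ++k2;
    op_out.push_back(ops[k]);
    len_out.push_back((int)(k2 - k));
    k = k2;
  }
  if (bi < m) { op_out.push_back('S'); len_out.push_back(m - bi); }

  std::string cigar;
  for (size_t k = 0; k < op_out.size(); ++k) {
    cigar += std::to_string(len_out[k]);
    cigar.push_back(op_out[k]);
  }
  return List::create(
      _["aligned"] = true, _["score"] = best, _["cigar"] = cigar,
      _["ref_start"] = j,          // 0-based start on the reference
      _["ref_end"] = bj,           // 0-based half-open end
      _["read_start"] = i, _["read_end"] = bi);
}
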