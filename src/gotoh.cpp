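#include <Rcpp.h>
#include <cstring>
#include <limits>
using namespace Rcpp;

// Global (Needleman-Wunsch/Gotoh) alignment with affine gaps.
// A gap run of length k costs gap_open + k * gap_extend.
// IUPAC-aware: two letters score `match` when their nucleotide state sets
// intersect, `mismatch` otherwise.
// Deterministic tie-breaking, resolved while filling: the diagonal move is
// preferred, then a gap in the read (ref base vs '-'), then a gap in the
// ref. Scores are kept in rolling rows; the traceback is a byte matrix
// (2 bits per state), which keeps the working set small.

static int iupac_mask(char c) {
  switch (c) {
    case 'A': return 1;
    case 'C': return 2;
    case 'G': return 4;
    case 'T': case 'U': return 8;
    case 'R': return 1 | 4;
    case 'Y': return 2 | 8;
    case 'S': return 2 | 4;
    case 'W': return 1 | 8;
    case 'K': return 4 | 8;
    case 'M': return 1 | 2;
    case 'B': return 2 | 4 | 8;
    case 'D': return 1 | 4 | 8;
    case 'H': return 1 | 2 | 8;
    case 'V': return 1 | 2 | 4;
    case 'N': return 15;
    default:  return 0;
  }
}

// state codes: 0 = M (diagonal), 1 = X (gap in read), 2 = Y (gap in ref)
// traceback byte: bits 0-1 predecessor-state of M, bits 2-3 of X (3 =
// extend), bits 4-5 of Y (3 = extend)

// [[Rcpp::export(name = ".gotoh_align")]]
List gotoh_align(std::string ref, std::string read,
                 double match, double mismatch,
                 double gap_open, double gap_extend) {
  const int n = (int) ref.size();   // rows: ref
  const int m = (int) read.size();  // cols: read
  const double NEG = -1e30;

  std::vector<int> rmask(n), cmask(m);
  for (int i = 0; i < n; ++i) rmask[i] = iupac_mask(ref[i]);
  for (int j = 0; j < m; ++j) cmask[j] = iupac_mask(read[j]);

  std::vector<double> pM(m + 1), pX(m + 1), pY(m + 1);
  std::vector<double> cM(m + 1), cX(m + 1), cY(m + 1);
  std::vector<unsigned char> tb((size_t)(n + 1) * (m + 1), 0);

  pM[0] = 0.0; pX[0] = NEG; pY[0] = NEG;
  for (int j = 1; j <= m; ++j) {
    pM[j] = NEG; pX[j] = NEG;
    pY[j] = gap_open + j * gap_extend;
    tb[j] = (unsigned char)((j == 1 ? 0 : 3) << 4);  // Y opened from M / ext
  }

  for (int i = 1; i <= n; ++i) {
    unsigned char *tbrow = &tb[(size_t) i * (m + 1)];
    cM[0] = NEG; cY[0] = NEG;
    cX[0] = gap_open + i * gap_extend;
    tbrow[0] = (unsigned char)((i == 1 ? 0 : 3) << 2);
    const int rm = rmask[i - 1];
    for (int j = 1; j <= m; ++j) {
      // M: diagonal from (i-1, j-1); prefer M, then X, then Y on ties
      double s = (rm & cmask[j - 1]) ? match : mismatch;
      double bM = pM[j - 1]; int predM = 0;
      if (pX[j - 1] > bM) { bM = pX[j - 1]; predM = 1; }
      if (pY[j - 1] > bM) { bM = pY[j - 1]; predM = 2; }
      cM[j] = s + bM;
      // X: consume ref[i], gap in read; open (from M, then Y) beats extend
      double opn = pM[j]; int predX = 0;
      if (pY[j] > opn) { opn = pY[j]; predX = 2; }
      opn += gap_open + gap_extend;
      double ext = pX[j] + gap_extend;
      double vX; int px;
      if (opn >= ext) { vX = opn; px = predX; } else { vX = ext; px = 3; }
      cX[j] = vX;
      // Y: consume read[j], gap in ref; open (from M, then X) beats extend
      double opnY = cM[j - 1]; int predY = 0;
      if (cX[j - 1] > opnY) { opnY = cX[j - 1]; predY = 1; }
      opnY += gap_open + gap_extend;
      double extY = cY[j - 1] + gap_extend;
      double vY; int py;
      if (opnY >= extY) { vY = opnY; py = predY; } else { vY = extY; py = 3; }
      cY[j] = vY;
      tbrow[j] = (unsigned char)(predM | (px << 2) | (py << 4));
    }
    std::swap(pM, cM); std::swap(pX, cX); std::swap(pY, cY);
  }

  double sM = pM[m], sX = pX[m], sY = pY[m];
  double score = sM; int state = 0;
  if (sX > score) { score = sX; state = 1; }
  if (sY > score) { score = sY; state = 2; }

  std::string aref, aread;
  aref.reserve(n + m); aread.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (j == 0) state = 1;
    else if (i == 0) state = 2;
    unsigned char t = tb[(size_t) i * (m + 1) + j];
    if (state == 0) {
      aref.push_back(ref[i - 1]);
      aread.push_back(read[j - 1]);
      --i; --j;
      state = t & 3;
    } else if (state == 1) {
      aref.push_back(ref[i - 1]);
      aread.push_back('-');
      --i;
      int p = (t >> 2) & 3;
      state = (p == 3) ? 1 : p;
    } else {
      aref.push_back('-');
      aread.push_back(read[j - 1]);
      --j;
      int p = (t >> 4) & 3;
      state = (p == 3) ? 2 : p;
    }
  }
  std::reverse(aref.begin(), aref.end());
  std::reverse(aread.begin(), aread.end());
  return List::create(_["aligned_ref"] = aref,
                      _["aligned_read"] = aread,
                      _["score"] = score);
}
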