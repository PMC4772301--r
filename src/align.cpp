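#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap pairwise alignment kernels.  Sequences arrive as 0-based
// integer codes into the substitution matrix.  Gap of length g costs
// gap_open + g * gap_extend (the BLAST convention, so the first gap
// residue costs gap_open + gap_extend).  Traceback ties are broken by
// preferring the diagonal, then the up (gap in sequence 2), then the
// left move, which makes the reported alignment deterministic.

static const double NEG_INF = -1e30;

// [[Rcpp::export]]
List sw_align_cpp(IntegerVector a, IntegerVector b, NumericMatrix sub,
                  double gap_open, double gap_extend) {
  const int m = a.size(), n = b.size();
  const double go = gap_open + gap_extend, ge = gap_extend;
  // DP matrices: M ends in a match, Ix in a gap consuming a (up),
  // Iy in a gap consuming b (left).
  std::vector<double> M((m + 1) * (n + 1), 0.0);
  std::vector<double> Ix((m + 1) * (n + 1), NEG_INF);
  std::vector<double> Iy((m + 1) * (n + 1), NEG_INF);
  auto at = [n](int i, int j) { return i * (n + 1) + j; };
  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      double s = sub(a[i - 1], b[j - 1]);
      double diag = std::max(std::max(M[at(i - 1, j - 1)], Ix[at(i - 1, j - 1)]),
                             std::max(Iy[at(i - 1, j - 1)], 0.0));
      M[at(i, j)] = diag + s;
      if (M[at(i, j)] < 0) M[at(i, j)] = NEG_INF;  // local: restart instead
      Ix[at(i, j)] = std::max(M[at(i - 1, j)] - go, Ix[at(i - 1, j)] - ge);
      Iy[at(i, j)] = std::max(M[at(i, j - 1)] - go, Iy[at(i, j - 1)] - ge);
      if (M[at(i, j)] > best) {  // strict >: earliest cell wins ties
        best = M[at(i, j)];
        bi = i; bj = j;
      }
    }
  }
  // traceback from the best match cell
  std::vector<int> ai, bjv;  // aligned positions, 0 marks a gap
  if (best > 0) {
    int i = bi, j = bj, state = 0;  // 0 = M, 1 = Ix, 2 = Iy
    while (i > 0 || j > 0) {
      if (state == 0) {
        double cur = M[at(i, j)];
        if (cur <= 0) break;
        ai.push_back(i); bjv.push_back(j);
        double diagM = M[at(i - 1, j - 1)];
        double diagIx = Ix[at(i - 1, j - 1)];
        double diagIy = Iy[at(i - 1, j - 1)];
        double s = sub(a[i - 1], b[j - 1]);
        double prev = cur - s;
        --i; --j;
        if (std::abs(diagM - prev) < 1e-9 && diagM > NEG_INF / 2) state = 0;
        else if (std::abs(diagIx - prev) < 1e-9) state = 1;
        else if (std::abs(diagIy - prev) < 1e-9) state = 2;
        else break;  // restarted from 0: local alignment begins here
      } else if (state == 1) {
        ai.push_back(i); bjv.push_back(0);
        double cur = Ix[at(i, j)];
        if (std::abs(M[at(i - 1, j)] - go - cur) < 1e-9) state = 0;
        else state = 1;
        --i;
      } else {
        ai.push_back(0); bjv.push_back(j);
        double cur = Iy[at(i, j)];
        if (std::abs(M[at(i, j - 1)] - go - cur) < 1e-9) state = 0;
        else state = 2;
        --j;
      }
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bjv.begin(), bjv.end());
  return List::create(_["score"] = best,
                      _["a_pos"] = IntegerVector(ai.begin(), ai.end()),
                      _["b_pos"] = IntegerVector(bjv.begin(), bjv.end()));
}

// [[Rcpp::export]]
List nw_align_cpp(IntegerVector a, IntegerVector b, NumericMatrix sub,
                  double gap_open, double gap_extend) {
  const int m = a.size(), n = b.size();
  const double go = gap_open + gap_extend, ge = gap_extend;
  std::vector<double> M((m + 1) * (n + 1), NEG_INF);
  std::vector<double> Ix((m + 1) * (n + 1), NEG_INF);
  std::vector<double> Iy((m + 1) * (n + 1), NEG_INF);
  auto at = [n](int i, int j) { return i * (n + 1) + j; };
  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= m; ++i) Ix[at(i, 0)] = -go - (i - 1) * ge;
  for (int j = 1; j <= n; ++j) Iy[at(0, j)] = -go - (j - 1) * ge;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      double s = sub(a[i - 1], b[j - 1]);
      double diag = std::max(std::max(M[at(i - 1, j - 1)], Ix[at(i - 1, j - 1)]),
                             Iy[at(i - 1, j - 1)]);
      M[at(i, j)] = diag + s;
      Ix[at(i, j)] = std::max(M[at(i - 1, j)] - go, Ix[at(i - 1, j)] - ge);
      Iy[at(i, j)] = std::max(M[at(i, j - 1)] - go, Iy[at(i, j - 1)] - ge);
    }
  }
  double sM = M[at(m, n)], sX = Ix[at(m, n)], sY = Iy[at(m, n)];
  double best = std::max(sM, std::max(sX, sY));
  int state = (sM >= sX && sM >= sY) ? 0 : (sX >= sY ? 1 : 2);
  std::vector<int> ai, bjv;
  int i = m, j = n;
  while (i > 0 || j > 0) {
    if (state == 0 && i > 0 && j > 0) {
      ai.push_back(i); bjv.push_back(j);
      double cur = M[at(i, j)];
      double s = sub(a[i - 1], b[j - 1]);
      double prev = cur - s;
      --i; --j;
      if (std::abs(M[at(i, j)] - prev) < 1e-9) state = 0;
      else if (std::abs(Ix[at(i, j)] - prev) < 1e-9) state = 1;
      else state = 2;
    } else if (state == 1 || (state == 0 && j == 0)) {
      ai.push_back(i); bjv.push_back(0);
      double cur = Ix[at(i, j)];
      if (i > 1 && std::abs(M[at(i - 1, j)] - go - cur) < 1e-9) state = 0;
      else if (i == 1) state = 0;
      else state = 1;
      --i;
    } else {
      ai.push_back(0); bjv.push_back(j);
      double cur = Iy[at(i, j)];
      if (j > 1 && std::abs(M[at(i, j - 1)] - go - cur) < 1e-9) state = 0;
      else if (j == 1) state = 0;
      else state = 2;
      --j;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bjv.begin(), bjv.end());
  return List::create(_["score"] = best,
                      _["a_pos"] = IntegerVector(ai.begin(), ai.end()),
                      _["b_pos"] = IntegerVector(bjv.begin(), bjv.end()));
}
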