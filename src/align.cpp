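#include <Rcpp.h>
using namespace Rcpp;

// Global affine-gap alignment (Gotoh) over a precomputed cell-score matrix.
// S(i, j) is the score of pairing row-item i with column-item j; the caller
// builds S from a substitution matrix (sequence vs sequence), a profile
// product (profile vs profile) or simple match/mismatch (DNA gap filling).
// Gap of length k costs open + ext * (k - 1). Ties in the traceback prefer
// diagonal > up > left so results are deterministic.
//
// Returns list(score, path) where path is a vector of moves walked from the
// top-left: 1 = diagonal (consume one of each), 2 = up (consume a row item,
// gap in the column sequence), 3 = left.
// [[Rcpp::export]]
List nw_dp(NumericMatrix S, double gap_open, double gap_ext) {
  const int n = S.nrow(), m = S.ncol();
  if ((double)n * (double)m > 6e7)
    stop("alignment problem too large (%d x %d)", n, m);
  const double NEG = -1e30;

  // DP over rows with rolling arrays; tracebacks stored as byte matrices.
  std::vector<double> Mprev(m + 1), Xprev(m + 1), Yprev(m + 1);
  std::vector<double> Mcur(m + 1), Xcur(m + 1), Ycur(m + 1);
  // tb*: which state preceded (0=M,1=X,2=Y), indexed [i][j]
  RawMatrix tbM(n + 1, m + 1), tbX(n + 1, m + 1), tbY(n + 1, m + 1);

  Mprev[0] = 0.0; Xprev[0] = NEG; Yprev[0] = NEG;
  for (int j = 1; j <= m; ++j) {
    Mprev[j] = NEG;
    Xprev[j] = NEG;
    Yprev[j] = -gap_open - gap_ext * (j - 1);
    tbY(0, j) = (j == 1) ? 0 : 2;
  }
  for (int i = 1; i <= n; ++i) {
    Mcur[0] = NEG;
    Xcur[0] = -gap_open - gap_ext * (i - 1);
    Ycur[0] = NEG;
    tbX(i, 0) = (i == 1) ? 0 : 1;
    for (int j = 1; j <= m; ++j) {
      // M: diagonal step
      double bm = Mprev[j - 1], bx = Xprev[j - 1], by = Yprev[j - 1];
      int arg = 0; double best = bm;
      if (bx > best) { best = bx; arg = 1; }
      if (by > best) { best = by; arg = 2; }
      Mcur[j] = best + S(i - 1, j - 1);
      tbM(i, j) = (unsigned char)arg;
      // X: gap in column sequence (move up)
      double xo = Mprev[j] - gap_open, xe = Xprev[j] - gap_ext,
             xy = Yprev[j] - gap_open;
      arg = 0; best = xo;
      if (xe > best) { best = xe; arg = 1; }
      if (xy > best) { best = xy; arg = 2; }
      Xcur[j] = best;
      tbX(i, j) = (unsigned char)arg;
      // Y: gap in row sequence (move left)
      double yo = Mcur[j - 1] - gap_open, ye = Ycur[j - 1] - gap_ext,
             yx = Xcur[j - 1] - gap_open;
      arg = 0; best = yo;
      if (yx > best) { best = yx; arg = 1; } // via X
      if (ye > best) { best = ye; arg = 2; }
      Ycur[j] = best;
      tbY(i, j) = (unsigned char)(arg == 1 ? 1 : (arg == 2 ? 2 : 0));
    }
    std::swap(Mprev, Mcur); std::swap(Xprev, Xcur); std::swap(Yprev, Ycur);
  }

  double sM = Mprev[m], sX = Xprev[m], sY = Yprev[m];
  int state = 0; double score = sM;
  if (sX > score) { score = sX; state = 1; }
  if (sY > score) { score = sY; state = 2; }
  if (n == 0 && m == 0) { state = 0; score = 0.0; }

  // Traceback needs the full state choice record; tb matrices hold it.
  std::vector<int> rev;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      rev.push_back(1);
      state = tbM(i, j);
      --i; --j;
    } else if (state == 1) {
      rev.push_back(2);
      state = tbX(i, j);
      --i;
    } else {
      rev.push_back(3);
      state = tbY(i, j);
      --j;
    }
  }
  IntegerVector path(rev.size());
  for (size_t k = 0; k < rev.size(); ++k) path[k] = rev[rev.size() - 1 - k];
  return List::create(_["score"] = score, _["path"] = path);
}

// Positions (0-based) of all shared k-mers between two strings as exact
// anchors; qpos comes from a hash of the query built by the caller in R.
// Kept in R instead: anchor finding is vectorised there.
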