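#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap pairwise alignment on a precomputed cell-score matrix S
// (n1 x n2: score of pairing row-unit i with column-unit j). One kernel
// serves residue-residue (BLOSUM lookups), PSSM-vs-sequence and
// profile-vs-profile alignment; callers build S.
//
// mode: 0 = global (Needleman-Wunsch), 1 = local (Smith-Waterman).
// A gap of length k costs gap_open + k * gap_ext.
//
// Returns list(score, path) where path is a 2-column integer matrix of
// 1-based aligned indices, 0 marking a gap (empty if traceback = false).

// [[Rcpp::export(name = ".affine_align_cpp")]]
List affine_align_cpp(NumericMatrix S, double gap_open, double gap_ext,
                      int mode, bool traceback) {
  const int n1 = S.nrow(), n2 = S.ncol();
  const double NEG = -1e30;
  const double gap_first = gap_open + gap_ext;
  const bool local = (mode == 1);

  NumericMatrix M(n1 + 1, n2 + 1), X(n1 + 1, n2 + 1), Y(n1 + 1, n2 + 1);
  // predecessor matrix codes: 0 = M, 1 = X, 2 = Y, 3 = fresh local start
  IntegerMatrix tM(n1 + 1, n2 + 1), tX(n1 + 1, n2 + 1), tY(n1 + 1, n2 + 1);

  M(0, 0) = local ? 0.0 : 0.0;
  X(0, 0) = NEG; Y(0, 0) = NEG;
  for (int i = 1; i <= n1; ++i) {
    M(i, 0) = NEG;
    X(i, 0) = local ? NEG : -(gap_open + i * gap_ext);
    Y(i, 0) = NEG;
    tX(i, 0) = 1;
  }
  for (int j = 1; j <= n2; ++j) {
    M(0, j) = NEG;
    X(0, j) = NEG;
    Y(0, j) = local ? NEG : -(gap_open + j * gap_ext);
    tY(0, j) = 2;
  }

  double best = 0.0;
  int bi = 0, bj = 0;

  for (int i = 1; i <= n1; ++i) {
    for (int j = 1; j <= n2; ++j) {
      double dM = M(i - 1, j - 1), dX = X(i - 1, j - 1), dY = Y(i - 1, j - 1);
      double dbest = dM; int dfrom = 0;
      if (dX > dbest) { dbest = dX; dfrom = 1; }
      if (dY > dbest) { dbest = dY; dfrom = 2; }
      double m = dbest + S(i - 1, j - 1);
      if (local && m < 0.0) { m = 0.0; dfrom = 3; }
      if (local && dbest < 0.0 && m > 0.0) dfrom = 3;  // start fresh here
      M(i, j) = m; tM(i, j) = dfrom;

      double xo = M(i - 1, j) - gap_first, xe = X(i - 1, j) - gap_ext;
      if (xo >= xe) { X(i, j) = xo; tX(i, j) = 0; }
      else          { X(i, j) = xe; tX(i, j) = 1; }

      double yo = M(i, j - 1) - gap_first, ye = Y(i, j - 1) - gap_ext;
      if (yo >= ye) { Y(i, j) = yo; tY(i, j) = 0; }
      else          { Y(i, j) = ye; tY(i, j) = 2; }

      if (local && M(i, j) > best) { best = M(i, j); bi = i; bj = j; }
    }
  }

  double score;
  int ci, cj, cm;
  if (local) {
    score = best; ci = bi; cj = bj; cm = 0;
  } else {
    double e0 = M(n1, n2), e1 = X(n1, n2), e2 = Y(n1, n2);
    score = e0; cm = 0;
    if (e1 > score) { score = e1; cm = 1; }
    if (e2 > score) { score = e2; cm = 2; }
    ci = n1; cj = n2;
  }

  IntegerMatrix path(0, 2);
  if (traceback && !(local && score <= 0.0)) {
    std::vector<int> pi, pj;
    while (ci > 0 || cj > 0) {
      if (cm == 0) {
        int from = tM(ci, cj);
        pi.push_back(ci); pj.push_back(cj);
        --ci; --cj;
        if (from == 3) break;      // local alignment start
        cm = from;
      } else if (cm == 1) {
        int from = tX(ci, cj);
        pi.push_back(ci); pj.push_back(0);
        --ci;
        cm = (from == 0) ? 0 : 1;
      } else {
        int from = tY(ci, cj);
        pi.push_back(0); pj.push_back(cj);
        --cj;
        cm = (from == 0) ? 0 : 2;
      }
      if (local && cm == 0 && M(ci, cj) <= 0.0) break;
    }
    const int L = (int) pi.size();
    path = IntegerMatrix(L, 2);
    for (int k = 0; k < L; ++k) {
      path(k, 0) = pi[L - 1 - k];
      path(k, 1) = pj[L - 1 - k];
    }
  }

  return List::create(_["score"] = score, _["path"] = path);
}

// Batch Smith-Waterman scores of one row-profile (n1 x n_alphabet score
// matrix, rows = query positions, columns = residue codes) against many
// integer-encoded sequences (1-based codes). Used for database scans and
// Karlin-Altschul calibration where only the optimal score is needed.
// [[Rcpp::export(name = ".batch_local_scores_cpp")]]
NumericVector batch_local_scores_cpp(NumericMatrix prof, List seqs,
                                     double gap_open, double gap_ext) {
  const int n1 = prof.nrow();
  const double NEG = -1e30;
  const double gap_first = gap_open + gap_ext;
  const int nseq = seqs.size();
  NumericVector out(nseq);

  std::vector<double> Hprev(n1 + 1), Eprev(n1 + 1), Hcur(n1 + 1), Ecur(n1 + 1);
  for (int s = 0; s < nseq; ++s) {
    IntegerVector q = seqs[s];
    const int n2 = q.size();
    double best = 0.0;
    std::fill(Hprev.begin(), Hprev.end(), 0.0);
    std::fill(Eprev.begin(), Eprev.end(), NEG);
    for (int j = 1; j <= n2; ++j) {
      const int col = q[j - 1] - 1;
      Hcur[0] = 0.0; Ecur[0] = NEG;
      double f = NEG;
      for (int i = 1; i <= n1; ++i) {
        double e = std::max(Hprev[i] - gap_first, Eprev[i] - gap_ext);
        f = std::max(Hcur[i - 1] - gap_first, f - gap_ext);
        double h = Hprev[i - 1] + prof(i - 1, col);
        if (e > h) h = e;
        if (f > h) h = f;
        if (h < 0.0) h = 0.0;
        Hcur[i] = h; Ecur[i] = e;
        if (h > best) best = h;
      }
      std::swap(Hprev, Hcur);
      std::swap(Eprev, Ecur);
    }
    out[s] = best;
  }
  return out;
}
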