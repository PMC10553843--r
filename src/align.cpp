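#include <Rcpp.h>
#include <vector>
#include <cstring>
using namespace Rcpp;

// Affine-gap Smith-Waterman. Gap of length L costs open + L * ext.
// Substitution matrix comes in with dimnames (e.g. BLOSUM62); characters are
// resolved through a 256-entry lookup built from its row names.

static void build_lookup(const NumericMatrix &submat, int lookup[256]) {
  for (int i = 0; i < 256; ++i) lookup[i] = -1;
  CharacterVector rn = rownames(submat);
  for (int i = 0; i < rn.size(); ++i) {
    const char *s = CHAR(STRING_ELT(rn, i));
    if (std::strlen(s) == 1) lookup[(unsigned char)s[0]] = i;
  }
}

static std::vector<int> index_seq(const std::string &s, const int lookup[256]) {
  std::vector<int> idx(s.size());
  for (size_t k = 0; k < s.size(); ++k) {
    int v = lookup[(unsigned char)s[k]];
    if (v < 0) stop("character not covered by substitution matrix");
    idx[k] = v;
  }
  return idx;
}

// [[Rcpp::export]]
NumericVector sw_scores(std::string query, CharacterVector targets,
                        NumericMatrix submat, double open, double ext) {
  int lookup[256];
  build_lookup(submat, lookup);
  const int nr = submat.nrow();
  std::vector<double> flat(submat.begin(), submat.end()); // column-major
  std::vector<int> qi = index_seq(query, lookup);
  const int m = qi.size();
  const double NEG = -1e30;
  const double oe = open + ext;
  NumericVector out(targets.size());
  std::vector<double> M(m + 1), Ix(m + 1), Iy(m + 1);
  std::vector<double> Mp(m + 1), Ixp(m + 1), Iyp(m + 1);

  for (int t = 0; t < targets.size(); ++t) {
    std::string tg = as<std::string>(targets[t]);
    std::vector<int> ti = index_seq(tg, lookup);
    const int n = ti.size();
    double best = 0.0;
    for (int i = 0; i <= m; ++i) { Mp[i] = 0.0; Ixp[i] = NEG; Iyp[i] = NEG; }
    for (int j = 1; j <= n; ++j) {
      const double *col = flat.data() + (size_t)ti[j - 1] * nr;
      M[0] = 0.0; Ix[0] = NEG; Iy[0] = NEG;
      for (int i = 1; i <= m; ++i) {
        double diag = Mp[i - 1];
        if (Ixp[i - 1] > diag) diag = Ixp[i - 1];
        if (Iyp[i - 1] > diag) diag = Iyp[i - 1];
        double mv = diag + col[qi[i - 1]];
        if (mv < 0.0) mv = 0.0;
        M[i] = mv;
        if (mv > best) best = mv;
        // Ix: gap in target (consumes query, vertical move)
        double a = M[i - 1] - oe;
        double b = Ix[i - 1] - ext;
        Ix[i] = a > b ? a : b;
        // Iy: gap in query (consumes target, horizontal move)
        double c = Mp[i] - oe;
        double d = Iyp[i] - ext;
        Iy[i] = c > d ? c : d;
      }
      std::swap(M, Mp); std::swap(Ix, Ixp); std::swap(Iy, Iyp);
    }
    out[t] = best;
  }
  return out;
}

// [[Rcpp::export]]
List sw_stats(std::string query, CharacterVector targets,
              NumericMatrix submat, double open, double ext) {
  int lookup[256];
  build_lookup(submat, lookup);
  const int nr = submat.nrow();
  std::vector<double> flat(submat.begin(), submat.end());
  std::vector<int> qi = index_seq(query, lookup);
  const int m = qi.size();
  const double NEG = -1e30;
  const double oe = open + ext;
  const int nt = targets.size();
  NumericVector score(nt);
  IntegerVector nmatch(nt), columns(nt), q_aligned(nt);

  for (int t = 0; t < nt; ++t) {
    std::string tg = as<std::string>(targets[t]);
    std::vector<int> ti = index_seq(tg, lookup);
    const int n = ti.size();
    std::vector<double> M((size_t)(m + 1) * (n + 1), 0.0);
    std::vector<double> Ix((size_t)(m + 1) * (n + 1), NEG);
    std::vector<double> Iy((size_t)(m + 1) * (n + 1), NEG);
    auto at = [m](int i, int j) { return (size_t)j * (m + 1) + i; };
    double best = 0.0; int bi = 0, bj = 0;
    for (int j = 1; j <= n; ++j) {
      const double *col = flat.data() + (size_t)ti[j - 1] * nr;
      for (int i = 1; i <= m; ++i) {
        double diag = M[at(i - 1, j - 1)];
        if (Ix[at(i - 1, j - 1)] > diag) diag = Ix[at(i - 1, j - 1)];
        if (Iy[at(i - 1, j - 1)] > diag) diag = Iy[at(i - 1, j - 1)];
        double mv = diag + col[qi[i - 1]];
        if (mv < 0.0) mv = 0.0;
        M[at(i, j)] = mv;
        if (mv > best) { best = mv; bi = i; bj = j; }
        double a = M[at(i - 1, j)] - oe;
        double b = Ix[at(i - 1, j)] - ext;
        Ix[at(i, j)] = a > b ? a : b;
        double c = M[at(i, j - 1)] - oe;
        double d = Iy[at(i, j - 1)] - ext;
        Iy[at(i, j)] = c > d ? c : d;
      }
    }
    int nm = 0, cols = 0, qa = 0;
    if (best > 0.0) {
      // traceback from the best M cell until a zero-valued M cell
      int i = bi, j = bj, state = 0; // 0 = M, 1 = Ix, 2 = Iy
      while (i > 0 && j > 0) {
        if (state == 0) {
          double v = M[at(i, j)];
          if (v <= 0.0) break;
          double s = flat[(size_t)ti[j - 1] * nr + qi[i - 1]];
          ++cols; ++qa;
          if (query[i - 1] == tg[j - 1]) ++nm;
          double prev = v - s;
          if (std::abs(M[at(i - 1, j - 1)] - prev) < 1e-9) state = 0;
          else if (std::abs(Ix[at(i - 1, j - 1)] - prev) < 1e-9) state = 1;
          else if (std::abs(Iy[at(i - 1, j - 1)] - prev) < 1e-9) state = 2;
          else state = 0; // prev == 0: local alignment start
          --i; --j;
          if (state == 0 && M[at(i, j)] <= 0.0) break;
        } else if (state == 1) { // gap in target, consume query
          ++cols; ++qa;
          double v = Ix[at(i, j)];
          if (std::abs(M[at(i - 1, j)] - oe - v) < 1e-9) state = 0;
          --i;
        } else { // gap in query, consume target
          ++cols;
          double v = Iy[at(i, j)];
          if (std::abs(M[at(i, j - 1)] - oe - v) < 1e-9) state = 0;
          --j;
        }
      }
    }
    score[t] = best; nmatch[t] = nm; columns[t] = cols; q_aligned[t] = qa;
  }
  return List::create(_["score"] = score, _["nmatch"] = nmatch,
                      _["columns"] = columns, _["q_aligned"] = q_aligned);
}

// [[Rcpp::export]]
List nw_stats(std::string query, CharacterVector targets,
              NumericMatrix submat, double open, double ext) {
  // global (Needleman-Wunsch) affine alignment with end gaps penalized,
  // same gap convention as the local aligner
  int lookup[256];
  build_lookup(submat, lookup);
  const int nr = submat.nrow();
  std::vector<double> flat(submat.begin(), submat.end());
  std::vector<int> qi = index_seq(query, lookup);
  const int m = qi.size();
  const double NEG = -1e30;
  const double oe = open + ext;
  const int nt = targets.size();
  NumericVector score(nt);
  IntegerVector nmatch(nt), columns(nt);

  for (int t = 0; t < nt; ++t) {
    std::string tg = as<std::string>(targets[t]);
    std::vector<int> ti = index_seq(tg, lookup);
    const int n = ti.size();
    std::vector<double> M((size_t)(m + 1) * (n + 1), NEG);
    std::vector<double> Ix((size_t)(m + 1) * (n + 1), NEG);
    std::vector<double> Iy((size_t)(m + 1) * (n + 1), NEG);
    auto at = [m](int i, int j) { return (size_t)j * (m + 1) + i; };
    M[at(0, 0)] = 0.0;
    for (int i = 1; i <= m; ++i) Ix[at(i, 0)] = -oe - ext * (i - 1);
    for (int j = 1; j <= n; ++j) Iy[at(0, j)] = -oe - ext * (j - 1);
    for (int j = 1; j <= n; ++j) {
      const double *col = flat.data() + (size_t)ti[j - 1] * nr;
      for (int i = 1; i <= m; ++i) {
        double diag = M[at(i - 1, j - 1)];
        if (Ix[at(i - 1, j - 1)] > diag) diag = Ix[at(i - 1, j - 1)];
        if (Iy[at(i - 1, j - 1)] > diag) diag = Iy[at(i - 1, j - 1)];
        M[at(i, j)] = diag + col[qi[i - 1]];
        double a = M[at(i - 1, j)] - oe;
        double b = Ix[at(i - 1, j)] - ext;
        double c = Iy[at(i - 1, j)] - oe; // gap reopening across states
        Ix[at(i, j)] = std::max(a, std::max(b, c));
        double d = M[at(i, j - 1)] - oe;
        double e = Iy[at(i, j - 1)] - ext;
        double f = Ix[at(i, j - 1)] - oe;
        Iy[at(i, j)] = std::max(d, std::max(e, f));
      }
    }
    double fin = M[at(m, n)]; int state = 0;
    if (Ix[at(m, n)] > fin) { fin = Ix[at(m, n)]; state = 1; }
    if (Iy[at(m, n)] > fin) { fin = Iy[at(m, n)]; state = 2; }
    // traceback for match and column counts
    int i = m, j = n, nm = 0, cols = 0;
    while (i > 0 || j > 0) {
      if (state == 0 && i > 0 && j > 0) {
        double v = M[at(i, j)];
        double s = flat[(size_t)ti[j - 1] * nr + qi[i - 1]];
        ++cols;
        if (query[i - 1] == tg[j - 1]) ++nm;
        double prev = v - s;
        if (std::abs(M[at(i - 1, j - 1)] - prev) < 1e-9) state = 0;
        else if (std::abs(Ix[at(i - 1, j - 1)] - prev) < 1e-9) state = 1;
        else state = 2;
        --i; --j;
      } else if ((state == 1 && i > 0) || (state != 2 && j == 0)) {
        double v = Ix[at(i, j)];
        ++cols;
        if (i > 1 || j > 0) {
          if (std::abs(M[at(i - 1, j)] - oe - v) < 1e-9) state = 0;
          else if (std::abs(Iy[at(i - 1, j)] - oe - v) < 1e-9) state = 2;
          else state = 1;
        }
        --i;
      } else {
        double v = Iy[at(i, j)];
        ++cols;
        if (j > 1 || i > 0) {
          if (std::abs(M[at(i, j - 1)] - oe - v) < 1e-9) state = 0;
          else if (std::abs(Ix[at(i, j - 1)] - oe - v) < 1e-9) state = 1;
          else state = 2;
        }
        --j;
      }
    }
    score[t] = fin; nmatch[t] = nm; columns[t] = cols;
  }
  return List::create(_["score"] = score, _["nmatch"] = nmatch,
                      _["columns"] = columns);
}
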