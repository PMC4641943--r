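#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Affine-gap pairwise alignment kernels (Gotoh three-state recursion).
// A gap of length L costs go + L * ge, i.e. the first gap residue costs
// go + ge. Local scores floor at 0 (empty alignment allowed).

static const double NEG = -1e30;

// Build a 256-entry lookup from residue character to substitution-matrix row.
static std::vector<int> residue_lut(const NumericMatrix& mat) {
  std::vector<int> lut(256, -1);
  CharacterVector rn = rownames(mat);
  for (int i = 0; i < rn.size(); ++i) {
    std::string r = as<std::string>(rn[i]);
    if (r.size() == 1) lut[(unsigned char)r[0]] = i;
  }
  return lut;
}

static std::vector<int> encode(const std::string& s, const std::vector<int>& lut) {
  std::vector<int> out(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    int code = lut[(unsigned char)s[i]];
    if (code < 0)
      stop("residue '%s' absent from substitution matrix",
           std::string(1, s[i]).c_str());
    out[i] = code;
  }
  return out;
}

// Score-only Gotoh, rolling rows. local: Smith-Waterman (floor 0);
// otherwise Needleman-Wunsch with penalized end gaps.
static double gotoh_score(const std::vector<int>& x, const std::vector<int>& y,
                          const NumericMatrix& mat, double go, double ge,
                          bool local) {
  int n = x.size(), m = y.size();
  std::vector<double> Mp(m + 1), Xp(m + 1), Yp(m + 1);
  std::vector<double> Mc(m + 1), Xc(m + 1), Yc(m + 1);
  Mp[0] = 0.0; Xp[0] = NEG; Yp[0] = NEG;
  for (int j = 1; j <= m; ++j) {
    Mp[j] = local ? 0.0 : NEG;
    Xp[j] = NEG;
    Yp[j] = -(go + j * ge);
  }
  double best = 0.0;
  for (int i = 1; i <= n; ++i) {
    Mc[0] = local ? 0.0 : NEG;
    Xc[0] = -(go + i * ge);
    Yc[0] = NEG;
    for (int j = 1; j <= m; ++j) {
      double s = mat(x[i - 1], y[j - 1]);
      double dia = std::max(Mp[j - 1], std::max(Xp[j - 1], Yp[j - 1]));
      double mv = dia + s;
      if (local && s > mv) mv = s;  // fresh start from 0
      Mc[j] = mv;
      Xc[j] = std::max(Mp[j] - go - ge, Xp[j] - ge);
      Yc[j] = std::max(Mc[j - 1] - go - ge, Yc[j - 1] - ge);
      if (local && mv > best) best = mv;
    }
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
  }
  if (local) return best;
  return std::max(Mp[m], std::max(Xp[m], Yp[m]));
}

// [[Rcpp::export(name = ".aln_cross_scores")]]
NumericMatrix aln_cross_scores(CharacterVector xs, CharacterVector ys,
                               NumericMatrix mat, double go, double ge,
                               bool local) {
  std::vector<int> lut = residue_lut(mat);
  int n = xs.size(), m = ys.size();
  std::vector<std::vector<int> > ex(n), ey(m);
  for (int i = 0; i < n; ++i) ex[i] = encode(as<std::string>(xs[i]), lut);
  for (int j = 0; j < m; ++j) ey[j] = encode(as<std::string>(ys[j]), lut);
  NumericMatrix out(n, m);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j)
      out(i, j) = gotoh_score(ex[i], ey[j], mat, go, ge, local);
  return out;
}

// Global alignment with traceback. Ties broken preferring the diagonal
// (match state), then up (gap in y), then left (gap in x), so aligned
// strings are deterministic.
// [[Rcpp::export(name = ".aln_global_traceback")]]
List aln_global_traceback(std::string xs, std::string ys, NumericMatrix mat,
                          double go, double ge) {
  std::vector<int> lut = residue_lut(mat);
  std::vector<int> x = encode(xs, lut), y = encode(ys, lut);
  int n = x.size(), m = y.size();
  int W = m + 1;
  std::vector<double> M((n + 1) * W, NEG), X((n + 1) * W, NEG),
      Y((n + 1) * W, NEG);
  M[0] = 0.0;
  for (int j = 1; j <= m; ++j) Y[j] = -(go + j * ge);
  for (int i = 1; i <= n; ++i) X[i * W] = -(go + i * ge);
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = mat(x[i - 1], y[j - 1]);
      int p = (i - 1) * W + (j - 1);
      M[i * W + j] = std::max(M[p], std::max(X[p], Y[p])) + s;
      X[i * W + j] = std::max(M[(i - 1) * W + j] - go - ge,
                              X[(i - 1) * W + j] - ge);
      Y[i * W + j] = std::max(M[i * W + j - 1] - go - ge,
                              Y[i * W + j - 1] - ge);
    }
  }
  int i = n, j = m;
  double sM = M[i * W + j], sX = X[i * W + j], sY = Y[i * W + j];
  double sc = std::max(sM, std::max(sX, sY));
  int state = (sM >= sX && sM >= sY) ? 0 : (sX >= sY ? 1 : 2);
  std::string ax, ay;
  while (i > 0 || j > 0) {
    if (state == 0) {
      ax.push_back(xs[i - 1]); ay.push_back(ys[j - 1]);
      int p = (i - 1) * W + (j - 1);
      double pm = M[p], px = X[p], py = Y[p];
      state = (pm >= px && pm >= py) ? 0 : (px >= py ? 1 : 2);
      --i; --j;
    } else if (state == 1) {
      ax.push_back(xs[i - 1]); ay.push_back('-');
      int p = (i - 1) * W + j;
      state = (M[p] - go - ge >= X[p] - ge) ? 0 : 1;
      --i;
    } else {
      ax.push_back('-'); ay.push_back(ys[j - 1]);
      int p = i * W + (j - 1);
      state = (M[p] - go - ge >= Y[p] - ge) ? 0 : 2;
      --j;
    }
  }
  std::reverse(ax.begin(), ax.end());
  std::reverse(ay.begin(), ay.end());
  return List::create(_["score"] = sc, _["aligned_x"] = ax,
                      _["aligned_y"] = ay);
}
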