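#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

// Gotoh affine-gap global alignment.
//
// A gap of length k scores gap_open + k * gap_extend (both <= 0).
// Traceback tie-breaking is fixed: diagonal > up (gap in b) > left (gap in a),
// and within a gap state, opening (from the match state) is preferred over
// extending on ties. This makes the reported alignment deterministic across
// platforms; the score is optimal regardless.
//
// score_mat is indexed by the position of each character in `alphabet`.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// [[Rcpp::export]]
List nw_align_cpp(std::string a, std::string b,
                  NumericMatrix score_mat, std::string alphabet,
                  double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("empty sequence");

  std::vector<int> lut(256, -1);
  for (size_t k = 0; k < alphabet.size(); ++k)
    lut[(unsigned char)alphabet[k]] = (int)k;
  std::vector<int> ai(n), bi(m);
  for (int i = 0; i < n; ++i) {
    ai[i] = lut[(unsigned char)a[i]];
    if (ai[i] < 0) stop("character '%s' not in alphabet", std::string(1, a[i]));
  }
  for (int j = 0; j < m; ++j) {
    bi[j] = lut[(unsigned char)b[j]];
    if (bi[j] < 0) stop("character '%s' not in alphabet", std::string(1, b[j]));
  }

  // M: a[i] aligned to b[j]; X: gap in b (consumes a, "up"); Y: gap in a ("left").
  const int W = m + 1;
  std::vector<double> M((n + 1) * W, NEG_INF), X((n + 1) * W, NEG_INF),
      Y((n + 1) * W, NEG_INF);
  // traceback: which state each cell's max came from (0=M,1=X,2=Y; -1 none)
  std::vector<signed char> tM((n + 1) * W, -1), tX((n + 1) * W, -1),
      tY((n + 1) * W, -1);

  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[i * W] = gap_open + i * gap_extend;
    tX[i * W] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    Y[j] = gap_open + j * gap_extend;
    tY[j] = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int c = i * W + j, d = (i - 1) * W + (j - 1),
                u = (i - 1) * W + j, l = i * W + (j - 1);
      // M from best of previous states at (i-1, j-1); prefer M > X > Y on ties
      double best = M[d]; signed char from = 0;
      if (X[d] > best) { best = X[d]; from = 1; }
      if (Y[d] > best) { best = Y[d]; from = 2; }
      if (best > NEG_INF) {
        M[c] = best + score_mat(ai[i - 1], bi[j - 1]);
        tM[c] = from;
      }
      // X: gap in b; open from M or extend X
      double open_x = (M[u] > NEG_INF) ? M[u] + gap_open + gap_extend : NEG_INF;
      double ext_x  = (X[u] > NEG_INF) ? X[u] + gap_extend : NEG_INF;
      if (open_x >= ext_x) { X[c] = open_x; if (open_x > NEG_INF) tX[c] = 0; }
      else                 { X[c] = ext_x;  tX[c] = 1; }
      // Y: gap in a; open from M or extend Y
      double open_y = (M[l] > NEG_INF) ? M[l] + gap_open + gap_extend : NEG_INF;
      double ext_y  = (Y[l] > NEG_INF) ? Y[l] + gap_extend : NEG_INF;
      if (open_y >= ext_y) { Y[c] = open_y; if (open_y > NEG_INF) tY[c] = 0; }
      else                 { Y[c] = ext_y;  tY[c] = 2; }
    }
  }

  const int end = n * W + m;
  int state = 0; double score = M[end];
  if (X[end] > score) { score = X[end]; state = 1; }
  if (Y[end] > score) { score = Y[end]; state = 2; }

  std::string ra, rb;
  ra.reserve(n + m); rb.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const int c = i * W + j;
    if (state == 0) {
      signed char from = tM[c];
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      --i; --j; state = from;
    } else if (state == 1) {
      signed char from = tX[c];
      ra.push_back(a[i - 1]); rb.push_back('-');
      --i; state = from;
    } else {
      signed char from = tY[c];
      ra.push_back('-'); rb.push_back(b[j - 1]);
      --j; state = from;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());

  return List::create(_["aligned_a"] = ra, _["aligned_b"] = rb,
                      _["score"] = score);
}

namespace {

struct PairStats { double score; int N; int M; };

// affine NW on pre-encoded sequences; returns gap-free column count (N) and
// mismatch count (M) from the traceback, without building strings.
// Buffers are caller-owned and resized as needed so batch scans reuse them.
PairStats nw_stats(const std::vector<int>& ai, const std::vector<int>& bi,
                   const std::vector<double>& smat, int nalpha,
                   double gap_open, double gap_extend,
                   std::vector<double>& M, std::vector<double>& X,
                   std::vector<double>& Y, std::vector<signed char>& tM,
                   std::vector<signed char>& tX, std::vector<signed char>& tY) {
  const int n = ai.size(), m = bi.size();
  const int W = m + 1;
  const size_t sz = (size_t)(n + 1) * W;
  M.assign(sz, NEG_INF); X.assign(sz, NEG_INF); Y.assign(sz, NEG_INF);
  tM.assign(sz, -1); tX.assign(sz, -1); tY.assign(sz, -1);
  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[(size_t)i * W] = gap_open + i * gap_extend;
    tX[(size_t)i * W] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    Y[j] = gap_open + j * gap_extend;
    tY[j] = (j == 1) ? 0 : 2;
  }
  for (int i = 1; i <= n; ++i) {
    const size_t row = (size_t)i * W, prow = (size_t)(i - 1) * W;
    for (int j = 1; j <= m; ++j) {
      const size_t c = row + j, d = prow + (j - 1), u = prow + j,
                   l = row + (j - 1);
      double best = M[d]; signed char from = 0;
      if (X[d] > best) { best = X[d]; from = 1; }
      if (Y[d] > best) { best = Y[d]; from = 2; }
      if (best > NEG_INF) {
        M[c] = best + smat[ai[i - 1] * nalpha + bi[j - 1]];
        tM[c] = from;
      }
      double open_x = (M[u] > NEG_INF) ? M[u] + gap_open + gap_extend : NEG_INF;
      double ext_x  = (X[u] > NEG_INF) ? X[u] + gap_extend : NEG_INF;
      if (open_x >= ext_x) { X[c] = open_x; if (open_x > NEG_INF) tX[c] = 0; }
      else                 { X[c] = ext_x;  tX[c] = 1; }
      double open_y = (M[l] > NEG_INF) ? M[l] + gap_open + gap_extend : NEG_INF;
      double ext_y  = (Y[l] > NEG_INF) ? Y[l] + gap_extend : NEG_INF;
      if (open_y >= ext_y) { Y[c] = open_y; if (open_y > NEG_INF) tY[c] = 0; }
      else                 { Y[c] = ext_y;  tY[c] = 2; }
    }
  }
  const size_t end = (size_t)n * W + m;
  int state = 0; double score = M[end];
  if (X[end] > score) { score = X[end]; state = 1; }
  if (Y[end] > score) { score = Y[end]; state = 2; }
  int i = n, j = m, Ncol = 0, Mcol = 0;
  while (i > 0 || j > 0) {
    const size_t c = (size_t)i * W + j;
    if (state == 0) {
      ++Ncol;
      if (ai[i - 1] != bi[j - 1]) ++Mcol;
      state = tM[c]; --i; --j;
    } else if (state == 1) {
      state = tX[c]; --i;
    } else {
      state = tY[c]; --j;
    }
  }
  PairStats out; out.score = score; out.N = Ncol; out.M = Mcol;
  return out;
}

std::vector<int> encode_seq(const std::string& s,
                            const std::vector<int>& lut) {
  std::vector<int> v(s.size());
  for (size_t k = 0; k < s.size(); ++k) {
    v[k] = lut[(unsigned char)s[k]];
    if (v[k] < 0)
      stop("character '%s' not in alphabet", std::string(1, s[k]));
  }
  return v;
}

} // namespace

// Batch gap-excluded identities: for every query x reference pair, the
// identity 1 - M/N over gap-free columns of the optimal global alignment,
// and the coverage N / min(length). Used by the synteny scan, which needs
// thousands of pairwise alignments per neighborhood comparison.
// [[Rcpp::export]]
List batch_identity_cpp(CharacterVector queries, CharacterVector refs,
                        NumericMatrix score_mat, std::string alphabet,
                        double gap_open, double gap_extend) {
  const int nq = queries.size(), nr = refs.size();
  const int nalpha = alphabet.size();
  std::vector<int> lut(256, -1);
  for (int k = 0; k < nalpha; ++k)
    lut[(unsigned char)alphabet[k]] = k;
  std::vector<double> smat(nalpha * nalpha);
  for (int a = 0; a < nalpha; ++a)
    for (int b = 0; b < nalpha; ++b)
      smat[a * nalpha + b] = score_mat(a, b);
  std::vector<std::vector<int> > qv(nq), rv(nr);
  for (int i = 0; i < nq; ++i)
    qv[i] = encode_seq(as<std::string>(queries[i]), lut);
  for (int j = 0; j < nr; ++j)
    rv[j] = encode_seq(as<std::string>(refs[j]), lut);

  NumericMatrix identity(nq, nr), coverage(nq, nr), score(nq, nr);
  std::vector<double> Mb, Xb, Yb;
  std::vector<signed char> tM, tX, tY;
  for (int i = 0; i < nq; ++i) {
    for (int j = 0; j < nr; ++j) {
      PairStats st = nw_stats(qv[i], rv[j], smat, nalpha, gap_open,
                              gap_extend, Mb, Xb, Yb, tM, tX, tY);
      identity(i, j) = st.N > 0 ? 1.0 - (double)st.M / st.N : 0.0;
      coverage(i, j) = (double)st.N /
        (double)std::min(qv[i].size(), rv[j].size());
      score(i, j) = st.score;
    }
  }
  return List::create(_["identity"] = identity, _["coverage"] = coverage,
                      _["score"] = score);
}

// Gap-excluded identity over an alignment: 1 - M/N with M the mismatches and
// N the columns where neither row has a gap. Returns c(N, M) for the caller.
// [[Rcpp::export]]
IntegerVector gapfree_mismatch_cpp(std::string a, std::string b) {
  if (a.size() != b.size()) stop("aligned rows differ in length");
  int N = 0, M = 0;
  for (size_t k = 0; k < a.size(); ++k) {
    if (a[k] == '-' || b[k] == '-') continue;
    ++N;
    if (a[k] != b[k]) ++M;
  }
  return IntegerVector::create(N, M);
}
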