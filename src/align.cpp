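// Affine-gap pairwise alignment (Gotoh three-state DP) with deterministic
// traceback. A gap of length k costs open + k * extend (BLAST convention).
// Tie-break order: diagonal (match state) > up (gap in subject) > left.
#include <Rcpp.h>
#include <vector>
#include <string>
#include <climits>
using namespace Rcpp;

static const int NEG = INT_MIN / 4;

enum { ST_M = 0, ST_X = 1, ST_Y = 2, ST_NONE = 3 };

struct AlnOut {
  int score = 0;
  int matches = 0;       // identical aligned residue pairs
  int columns = 0;       // alignment columns including gaps
  int qstart = 0, qend = 0;  // 1-based inclusive span on a; 0 if empty
  int sstart = 0, send = 0;
};

static std::vector<int> make_lut(const IntegerMatrix& mat) {
  std::vector<int> lut(256, -1);
  CharacterVector rn = rownames(mat);
  for (int i = 0; i < rn.size(); ++i) {
    std::string r = as<std::string>(rn[i]);
    if (r.size() == 1) lut[(unsigned char)r[0]] = i;
  }
  return lut;
}

static std::vector<int> encode(const std::string& s, const std::vector<int>& lut) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    int code = lut[(unsigned char)s[i]];
    if (code < 0)
      stop("residue '%s' not covered by the substitution matrix",
           std::string(1, s[i]).c_str());
    v[i] = code;
  }
  return v;
}

// pick best of (m, x, y) with preference M > X > Y on ties
static inline int argmax3(int m, int x, int y, int& val) {
  val = m; int st = ST_M;
  if (x > val) { val = x; st = ST_X; }
  if (y > val) { val = y; st = ST_Y; }
  return st;
}

static AlnOut gotoh(const std::vector<int>& A, const std::vector<int>& B,
                    const IntegerMatrix& mat, int open, int ext, bool global) {
  const int n = A.size(), m = B.size(), W = m + 1;
  std::vector<int> M((n + 1) * W, NEG), X((n + 1) * W, NEG), Y((n + 1) * W, NEG);
  std::vector<unsigned char> tM((n + 1) * W, ST_NONE), tX((n + 1) * W, ST_NONE),
      tY((n + 1) * W, ST_NONE);

  M[0] = 0;
  if (global) {
    for (int i = 1; i <= n; ++i) { X[i * W] = -(open + i * ext); tX[i * W] = (i == 1) ? ST_M : ST_X; }
    for (int j = 1; j <= m; ++j) { Y[j] = -(open + j * ext); tY[j] = (j == 1) ? ST_M : ST_Y; }
  } else {
    for (int i = 1; i <= n; ++i) M[i * W] = 0;
    for (int j = 1; j <= m; ++j) M[j] = 0;
  }

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int idx = i * W + j, diag = idx - W - 1, up = idx - W, left = idx - 1;
      const int s = mat(A[i - 1], B[j - 1]);
      int v;
      int st = argmax3(M[diag], X[diag], Y[diag], v);
      if (v > NEG) { M[idx] = v + s; tM[idx] = st; }
      if (!global && M[idx] < 0) { M[idx] = 0; tM[idx] = ST_NONE; }
      // gap in subject (consume a[i]); may open from M or Y, extend from X
      int xopen = std::max(M[up], Y[up]), xext = X[up];
      int xo = (xopen > NEG) ? xopen - open - ext : NEG;
      int xe = (xext > NEG) ? xext - ext : NEG;
      if (xo >= xe) { if (xo > NEG) { X[idx] = xo; tX[idx] = (M[up] >= Y[up]) ? ST_M : ST_Y; } }
      else { X[idx] = xe; tX[idx] = ST_X; }
      // gap in query (consume b[j])
      int yopen = std::max(M[left], X[left]), yext = Y[left];
      int yo = (yopen > NEG) ? yopen - open - ext : NEG;
      int ye = (yext > NEG) ? yext - ext : NEG;
      if (yo >= ye) { if (yo > NEG) { Y[idx] = yo; tY[idx] = (M[left] >= X[left]) ? ST_M : ST_X; } }
      else { Y[idx] = ye; tY[idx] = ST_Y; }
      // local best: first (row-major) strict maximum wins -> deterministic
      if (!global && M[idx] > best) { best = M[idx]; bi = i; bj = j; }
    }
  }

  AlnOut out;
  int state;
  if (global) {
    const int idx = n * W + m;
    state = argmax3(M[idx], X[idx], Y[idx], best);
    bi = n; bj = m;
  } else {
    if (best <= 0) return out;  // empty local alignment
    state = ST_M;  // an optimal local alignment never ends in a gap
  }
  out.score = best;

  int i = bi, j = bj;
  bool first = true;
  while (i > 0 || j > 0) {
    const int idx = i * W + j;
    if (!global && state == ST_M && M[idx] == 0) break;  // local start reached
    if (first) { out.qend = i; out.send = j; first = false; }
    out.columns++;
    if (state == ST_M) {
      if (A[i - 1] == B[j - 1]) out.matches++;
      out.qstart = i; out.sstart = j;
      state = tM[idx]; --i; --j;
    } else if (state == ST_X) {
      out.qstart = i;
      state = tX[idx]; --i;
    } else {
      out.sstart = j;
      state = tY[idx]; --j;
    }
  }
  if (global) { out.qstart = 1; out.sstart = 1; out.qend = n; out.send = m; }
  return out;
}

static void fill_row(NumericMatrix& out, int k, const AlnOut& r, size_t la,
                     size_t lb, bool global) {
  double identity = (r.columns > 0) ? 100.0 * r.matches / r.columns : 0.0;
  double qcov = (r.columns > 0) ? 100.0 * (r.qend - r.qstart + 1) / (double)la : 0.0;
  double scov = (r.columns > 0) ? 100.0 * (r.send - r.sstart + 1) / (double)lb : 0.0;
  if (global) { qcov = 100.0; scov = 100.0; }
  out(k, 0) = r.score; out(k, 1) = r.matches; out(k, 2) = r.columns;
  out(k, 3) = identity; out(k, 4) = qcov; out(k, 5) = scov;
  out(k, 6) = r.qstart; out(k, 7) = r.qend; out(k, 8) = r.sstart;
  out(k, 9) = r.send;
}

static CharacterVector result_cols() {
  return CharacterVector::create(
      "raw_score", "matches", "aligned_cols", "identity_pct",
      "query_cover_pct", "subject_cover_pct", "qstart", "qend", "sstart",
      "send");
}

// [[Rcpp::export(name = ".cpp_pairwise_align")]]
NumericVector cpp_pairwise_align(std::string a, std::string b,
                                 IntegerMatrix mat, int gap_open,
                                 int gap_extend, bool global) {
  if (a.empty() || b.empty()) stop("sequences must be non-empty");
  if (gap_open <= 0 || gap_extend <= 0) stop("gap penalties must be positive");
  std::vector<int> lut = make_lut(mat);
  std::vector<int> A = encode(a, lut), B = encode(b, lut);
  AlnOut r = gotoh(A, B, mat, gap_open, gap_extend, global);
  NumericMatrix tmp(1, 10);
  fill_row(tmp, 0, r, a.size(), b.size(), global);
  NumericVector out = tmp(0, _);
  out.attr("names") = result_cols();
  return out;
}

// One query against many subjects; avoids R-loop overhead in proteome scans.
// [[Rcpp::export(name = ".cpp_align_many")]]
NumericMatrix cpp_align_many(std::string a, CharacterVector subjects,
                             IntegerMatrix mat, int gap_open, int gap_extend) {
  if (a.empty()) stop("sequences must be non-empty");
  if (gap_open <= 0 || gap_extend <= 0) stop("gap penalties must be positive");
  std::vector<int> lut = make_lut(mat);
  std::vector<int> A = encode(a, lut);
  const int ns = subjects.size();
  NumericMatrix out(ns, 10);
  colnames(out) = result_cols();
  for (int k = 0; k < ns; ++k) {
    std::string b = as<std::string>(subjects[k]);
    if (b.empty()) stop("sequences must be non-empty");
    std::vector<int> B = encode(b, lut);
    AlnOut r = gotoh(A, B, mat, gap_open, gap_extend, false);
    fill_row(out, k, r, a.size(), b.size(), false);
  }
  return out;
}
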