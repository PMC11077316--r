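#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Residue encoding: the 20 canonical amino acids map to 0..19 in the order
// ARNDCQEGHILKMFPSTWYV; anything else (X, B, Z, U, ...) maps to 20 and is
// scored through row/column 20 of the substitution matrix.
static const char AA_ORDER[] = "ARNDCQEGHILKMFPSTWYV";

static inline void build_lut(int lut[256]) {
  for (int i = 0; i < 256; ++i) lut[i] = 20;
  for (int i = 0; i < 20; ++i) lut[(unsigned char)AA_ORDER[i]] = i;
}

static void encode_seq(const char *s, int n, const int lut[256], std::vector<int> &out) {
  out.resize(n);
  for (int i = 0; i < n; ++i) out[i] = lut[(unsigned char)s[i]];
}

// Smith-Waterman local alignment score with affine gaps.
// A gap of length L costs gap_open + L * gap_extend.
static int sw_score_core(const std::vector<int> &a, const std::vector<int> &b,
                         const int *sub, int nsub, int go, int ge) {
  const int m = (int)a.size(), n = (int)b.size();
  if (m == 0 || n == 0) return 0;
  std::vector<int> H(n + 1, 0), E(n + 1, 0);
  int best = 0;
  const int open_cost = go + ge;
  for (int i = 1; i <= m; ++i) {
    int Hdiag = 0;   // H[i-1][j-1]
    int F = 0;
    const int *srow = sub + (size_t)a[i - 1] * nsub;
    for (int j = 1; j <= n; ++j) {
      int Hup = H[j]; // H[i-1][j]
      int e = E[j] - ge;
      int eo = Hup - open_cost;
      if (eo > e) e = eo;
      if (e < 0) e = 0;
      E[j] = e;
      int f = F - ge;
      int fo = H[j - 1] - open_cost;
      if (fo > f) f = fo;
      if (f < 0) f = 0;
      F = f;
      int h = Hdiag + srow[b[j - 1]];
      if (e > h) h = e;
      if (f > h) h = f;
      if (h < 0) h = 0;
      H[j] = h;
      if (h > best) best = h;
      Hdiag = Hup;
    }
  }
  return best;
}

// [[Rcpp::export(name = ".sw_score_pair_cpp")]]
int sw_score_pair_cpp(std::string a, std::string b, IntegerMatrix sub,
                      int gap_open, int gap_extend) {
  int lut[256];
  build_lut(lut);
  std::vector<int> ea, eb;
  encode_seq(a.c_str(), (int)a.size(), lut, ea);
  encode_seq(b.c_str(), (int)b.size(), lut, eb);
  std::vector<int> S(sub.begin(), sub.end());
  // IntegerMatrix is column-major; sub is symmetric so layout does not matter,
  // but copy into row-major explicitly for clarity.
  int ns = sub.nrow();
  std::vector<int> Srm((size_t)ns * ns);
  for (int i = 0; i < ns; ++i)
    for (int j = 0; j < ns; ++j) Srm[(size_t)i * ns + j] = sub(i, j);
  return sw_score_core(ea, eb, Srm.data(), ns, gap_open, gap_extend);
}

// All-vs-all score matrix between two sets of sequences.
// [[Rcpp::export(name = ".sw_score_matrix_cpp")]]
IntegerMatrix sw_score_matrix_cpp(CharacterVector qs, CharacterVector ss,
                                  IntegerMatrix sub, int gap_open, int gap_extend) {
  int lut[256];
  build_lut(lut);
  int nq = qs.size(), nsub = ss.size();
  int ns = sub.nrow();
  std::vector<int> Srm((size_t)ns * ns);
  for (int i = 0; i < ns; ++i)
    for (int j = 0; j < ns; ++j) Srm[(size_t)i * ns + j] = sub(i, j);
  std::vector< std::vector<int> > eq(nq), es(nsub);
  for (int i = 0; i < nq; ++i) {
    const char *p = CHAR(STRING_ELT(qs, i));
    encode_seq(p, (int)LENGTH(STRING_ELT(qs, i)), lut, eq[i]);
  }
  for (int j = 0; j < nsub; ++j) {
    const char *p = CHAR(STRING_ELT(ss, j));
    encode_seq(p, (int)LENGTH(STRING_ELT(ss, j)), lut, es[j]);
  }
  IntegerMatrix out(nq, nsub);
  for (int i = 0; i < nq; ++i) {
    for (int j = 0; j < nsub; ++j) {
      out(i, j) = sw_score_core(eq[i], es[j], Srm.data(), ns, gap_open, gap_extend);
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}

// Scan subjects in the given order and return the first whose local alignment
// score with the query reaches min_score (1-based index; 0 if none).
// [[Rcpp::export(name = ".sw_first_hit_cpp")]]
List sw_first_hit_cpp(std::string q, CharacterVector ss, double min_score,
                      IntegerMatrix sub, int gap_open, int gap_extend) {
  int lut[256];
  build_lut(lut);
  int ns = sub.nrow();
  std::vector<int> Srm((size_t)ns * ns);
  for (int i = 0; i < ns; ++i)
    for (int j = 0; j < ns; ++j) Srm[(size_t)i * ns + j] = sub(i, j);
  std::vector<int> eq, es;
  encode_seq(q.c_str(), (int)q.size(), lut, eq);
  for (int j = 0; j < ss.size(); ++j) {
    const char *p = CHAR(STRING_ELT(ss, j));
    encode_seq(p, (int)LENGTH(STRING_ELT(ss, j)), lut, es);
    int sc = sw_score_core(eq, es, Srm.data(), ns, gap_open, gap_extend);
    if ((double)sc >= min_score)
      return List::create(_["index"] = j + 1, _["score"] = sc);
  }
  return List::create(_["index"] = 0, _["score"] = NA_INTEGER);
}

// Global (Needleman-Wunsch) affine-gap alignment over a precomputed
// column-similarity matrix C (rows = columns of profile A, cols = profile B).
// Returns a path of codes: 3 = consume one column from each profile,
// 1 = consume a column of A (gap in B), 2 = consume a column of B (gap in A).
// End gaps are penalized. Ties resolve match > gap-in-B > gap-in-A.
// [[Rcpp::export(name = ".nw_profile_path_cpp")]]
IntegerVector nw_profile_path_cpp(NumericMatrix C, double gap_open, double gap_extend) {
  const int m = C.nrow(), n = C.ncol();
  const double NEG = -1e100;
  const double open_cost = gap_open + gap_extend;
  // M: aligned; E: gap in B (consumes A rows); F: gap in A (consumes B cols)
  std::vector<double> M((size_t)(m + 1) * (n + 1), NEG);
  std::vector<double> E((size_t)(m + 1) * (n + 1), NEG);
  std::vector<double> F((size_t)(m + 1) * (n + 1), NEG);
  const size_t W = (size_t)n + 1;
  M[0] = 0.0;
  for (int i = 1; i <= m; ++i)
    E[(size_t)i * W] = -open_cost - (i - 1) * gap_extend;
  for (int j = 1; j <= n; ++j)
    F[(size_t)j] = -open_cost - (j - 1) * gap_extend;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      size_t cur = (size_t)i * W + j;
      size_t diag = (size_t)(i - 1) * W + (j - 1);
      size_t up = (size_t)(i - 1) * W + j;
      size_t left = cur - 1;
      double bd = M[diag];
      if (E[diag] > bd) bd = E[diag];
      if (F[diag] > bd) bd = F[diag];
      M[cur] = bd + C(i - 1, j - 1);
      double eb = M[up] - open_cost;
      double ec = E[up] - gap_extend;
      double ef = F[up] - open_cost;
      double e = eb;
      if (ec > e) e = ec;
      if (ef > e) e = ef;
      E[cur] = e;
      double fb = M[left] - open_cost;
      double fc = F[left] - gap_extend;
      double fe = E[left] - open_cost;
      double f = fb;
      if (fc > f) f = fc;
      if (fe > f) f = fe;
      F[cur] = f;
    }
  }
  // traceback
  std::vector<int> rev;
  rev.reserve(m + n);
  int i = m, j = n;
  size_t cur = (size_t)m * W + n;
  int state; // 0=M, 1=E, 2=F
  if (M[cur] >= E[cur] && M[cur] >= F[cur]) state = 0;
  else if (E[cur] >= F[cur]) state = 1;
  else state = 2;
  while (i > 0 || j > 0) {
    cur = (size_t)i * W + j;
    if (i == 0) { rev.push_back(2); --j; continue; }
    if (j == 0) { rev.push_back(1); --i; continue; }
    if (state == 0) {
      rev.push_back(3);
      size_t diag = (size_t)(i - 1) * W + (j - 1);
      double bd = M[diag];
      int ns = 0;
      if (E[diag] > bd) { bd = E[diag]; ns = 1; }
      if (F[diag] > bd) { bd = F[diag]; ns = 2; }
      --i; --j; state = ns;
    } else if (state == 1) {
      rev.push_back(1);
      size_t up = (size_t)(i - 1) * W + j;
      double val = E[cur];
      // which predecessor produced E[cur]?
      if (M[up] - open_cost >= val - 1e-9 && M[up] - open_cost >= E[up] - gap_extend &&
          M[up] - open_cost >= F[up] - open_cost) state = 0;
      else if (E[up] - gap_extend >= F[up] - open_cost) state = 1;
      else state = 2;
      --i;
    } else {
      rev.push_back(2);
      size_t left = cur - 1;
      double val = F[cur];
      if (M[left] - open_cost >= val - 1e-9 && M[left] - open_cost >= F[left] - gap_extend &&
          M[left] - open_cost >= E[left] - open_cost) state = 0;
      else if (F[left] - gap_extend >= E[left] - open_cost) state = 2;
      else state = 1;
      --j;
    }
  }
  IntegerVector out(rev.size());
  for (size_t k = 0; k < rev.size(); ++k) out[k] = rev[rev.size() - 1 - k];
  return out;
}

// PWM scan of one nucleotide sequence on both strands.
// lo is a 5 x w log-odds matrix, rows A,C,G,T,N (N row should be zeros).
// Returns 0-based window start positions on the given (forward) sequence.
// [[Rcpp::export(name = ".pwm_scan_cpp")]]
DataFrame pwm_scan_cpp(std::string seq, NumericMatrix lo, double threshold) {
  const int w = lo.ncol();
  const int n = (int)seq.size();
  std::vector<int> enc(n);
  for (int i = 0; i < n; ++i) {
    switch (seq[i]) {
      case 'A': case 'a': enc[i] = 0; break;
      case 'C': case 'c': enc[i] = 1; break;
      case 'G': case 'g': enc[i] = 2; break;
      case 'T': case 't': enc[i] = 3; break;
      default: enc[i] = 4;
    }
  }
  std::vector<int> pos;
  std::vector<double> sc;
  std::vector<int> str; // 1 = forward, -1 = reverse
  if (n >= w) {
    for (int p = 0; p + w <= n; ++p) {
      double sf = 0.0, sr = 0.0;
      for (int k = 0; k < w; ++k) {
        int bf = enc[p + k];
        sf += lo(bf, k);
        // reverse strand: complement of base at p + w - 1 - k aligns column k
        int bb = enc[p + w - 1 - k];
        int bc = (bb < 4) ? 3 - bb : 4;
        sr += lo(bc, k);
      }
      if (sf >= threshold) { pos.push_back(p); sc.push_back(sf); str.push_back(1); }
      if (sr >= threshold) { pos.push_back(p); sc.push_back(sr); str.push_back(-1); }
    }
  }
  return DataFrame::create(_["position"] = pos, _["strand"] = str, _["score"] = sc);
}

// For each sequence, does the PWM hit anywhere (either strand)?
// [[Rcpp::export(name = ".pwm_any_hit_cpp")]]
LogicalVector pwm_any_hit_cpp(CharacterVector seqs, NumericMatrix lo, double threshold) {
  const int w = lo.ncol();
  int nseq = seqs.size();
  LogicalVector out(nseq);
  for (int s = 0; s < nseq; ++s) {
    const char *cs = CHAR(STRING_ELT(seqs, s));
    int n = (int)LENGTH(STRING_ELT(seqs, s));
    bool hit = false;
    std::vector<int> enc(n);
    for (int i = 0; i < n; ++i) {
      switch (cs[i]) {
        case 'A': case 'a': enc[i] = 0; break;
        case 'C': case 'c': enc[i] = 1; break;
        case 'G': case 'g': enc[i] = 2; break;
        case 'T': case 't': enc[i] = 3; break;
        default: enc[i] = 4;
      }
    }
    for (int p = 0; p + w <= n && !hit; ++p) {
      double sf = 0.0, sr = 0.0;
      for (int k = 0; k < w; ++k) {
        sf += lo(enc[p + k], k);
        int bb = enc[p + w - 1 - k];
        sr += lo((bb < 4) ? 3 - bb : 4, k);
      }
      hit = (sf >= threshold) || (sr >= threshold);
    }
    out[s] = hit;
  }
  return out;
}
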