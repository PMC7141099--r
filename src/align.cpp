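#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
#include <cstring>

using namespace Rcpp;

// Affine-gap local/global peptide alignment used by the translated search,
// the profile (PSSM) search and the star multiple alignment.
//
// Conventions:
//  - substitution matrix is passed as a 128x128 row-major lookup indexed by
//    ASCII code (query x subject);
//  - gap of length L costs gap_open + L * gap_extend (Biostrings convention);
//  - gap runs are capped at gap_cap residues, and paths are pruned when
//    their score falls more than xdrop below the running maximum along the
//    path (X-drop termination, as in gapped BLAST): together these stop
//    local alignments from bridging long unrelated stretches such as
//    translated introns by chaining capped gaps with mismatch columns;
//  - coordinates in results are 0-based half-open.

static const double NEG = -1e15;

struct Hit {
  double score;
  int qs, qe, ss, se; // 0-based half-open
  int nid, ncol;
};

// One best local alignment of query (or PSSM columns) against subject window
// [w0, w1). smat != nullptr -> sequence mode; pssm != nullptr -> profile mode
// (pssm is m x 128 row-major, cons is the consensus used for identity).
static bool local_align_window(const char* q, int m,
                               const char* s, int w0, int w1,
                               const std::vector<char>& masked,
                               const double* smat,
                               const double* pssm, const char* cons,
                               double go, double ge, int gap_cap,
                               double xdrop, Hit& out) {
  int n = w1 - w0;
  if (m <= 0 || n <= 0) return false;
  size_t W = (size_t)n + 1;
  size_t sz = (size_t)(m + 1) * W;
  std::vector<double> M(sz, NEG), X(sz, NEG), Y(sz, NEG);
  // tb bits: 0-1 M source (0 start, 1 M, 2 X, 3 Y); 2: X opened from M;
  // 3: Y opened from M
  std::vector<unsigned char> tb(sz, 0);
  std::vector<unsigned short> xr(sz, 0), yr(sz, 0); // gap run lengths
  // running deficit below the path's max score (X-drop state), capped
  const double DCAP = 60000.0;
  std::vector<float> defM(sz, 0.0f), defX(sz, 0.0f), defY(sz, 0.0f);
  double gopen = go + ge;

  double best = 0.0;
  int bi = -1, bj = -1;

  for (int i = 1; i <= m; ++i) {
    size_t r = (size_t)i * W, rp = r - W;
    unsigned char qc = (unsigned char)q[i - 1];
    const double* srow = smat ? (smat + (size_t)qc * 128)
                              : (pssm + (size_t)(i - 1) * 128);
    for (int j = 1; j <= n; ++j) {
      int sj = w0 + j - 1;
      bool msk = masked[sj] != 0;
      unsigned char sc = (unsigned char)s[sj];
      double sub = msk ? NEG : srow[sc];
      // M
      double dM = M[rp + j - 1], dX = X[rp + j - 1], dY = Y[rp + j - 1];
      double prev = 0.0; unsigned char src = 0;
      if (dM > prev) { prev = dM; src = 1; }
      if (dX > prev) { prev = dX; src = 2; }
      if (dY > prev) { prev = dY; src = 3; }
      double dprev = (src == 1) ? defM[rp + j - 1]
                   : (src == 2) ? defX[rp + j - 1]
                   : (src == 3) ? defY[rp + j - 1] : 0.0;
      double nd = dprev - sub;
      if (nd < 0.0) nd = 0.0; else if (nd > DCAP) nd = DCAP;
      if (nd > xdrop && src != 0) {
        // prune: restart the local path at this cell instead
        prev = 0.0; src = 0;
        nd = sub < 0.0 ? -sub : 0.0;
      }
      double mv = prev + sub;
      M[r + j] = mv;
      defM[r + j] = (float)nd;
      unsigned char t = src;
      // X: gap in subject (consume query residue i)
      double xo = M[rp + j] - gopen;
      double xe = (xr[rp + j] < gap_cap) ? X[rp + j] - ge : NEG;
      double dxn;
      if (xo >= xe) { X[r + j] = xo; t |= 4; xr[r + j] = 1;
                      dxn = defM[rp + j] + gopen; }
      else { X[r + j] = xe; xr[r + j] = xr[rp + j] + 1;
             dxn = defX[rp + j] + ge; }
      if (dxn > xdrop) { X[r + j] = NEG; dxn = 0.0; }
      defX[r + j] = (float)(dxn > DCAP ? DCAP : dxn);
      // Y: gap in query (consume subject residue j)
      double yo = M[r + j - 1] - gopen;
      double ye = (yr[r + j - 1] < gap_cap) ? Y[r + j - 1] - ge : NEG;
      double dyn;
      if (yo >= ye) { Y[r + j] = yo; t |= 8; yr[r + j] = 1;
                      dyn = defM[r + j - 1] + gopen; }
      else { Y[r + j] = ye; yr[r + j] = yr[r + j - 1] + 1;
             dyn = defY[r + j - 1] + ge; }
      if (dyn > xdrop) { Y[r + j] = NEG; dyn = 0.0; }
      defY[r + j] = (float)(dyn > DCAP ? DCAP : dyn);
      tb[r + j] = t;
      if (mv > best) { best = mv; bi = i; bj = j; }
    }
  }
  if (bi < 0 || best <= 0.0) return false;

  // traceback from (bi, bj), state M
  int i = bi, j = bj, state = 1; // 1 = M, 2 = X, 3 = Y
  int nid = 0, ncol = 0;
  int qe = bi, se = w0 + bj;
  while (true) {
    size_t r = (size_t)i * W;
    if (state == 1) {
      unsigned char src = tb[r + j] & 3;
      char qc = q[i - 1];
      char sc = s[w0 + j - 1];
      bool ident = smat ? (qc == sc) : (cons[i - 1] == sc);
      ncol++; if (ident) nid++;
      i--; j--;
      if (src == 0) break;
      state = src;
    } else if (state == 2) {
      state = (tb[r + j] & 4) ? 1 : 2;
      ncol++;
      i--;
    } else {
      state = (tb[r + j] & 8) ? 1 : 3;
      ncol++;
      j--;
    }
  }
  out.score = best;
  out.qs = i; out.qe = qe;
  out.ss = w0 + j; out.se = se;
  out.nid = nid; out.ncol = ncol;
  return true;
}

// Exact k-mer seed windows of query/consensus vs subject. Seeds are clustered
// by diagonal band and subject position; clusters with >= min_seeds seeds
// define extension windows.
static void seed_windows(const std::string& q, const std::string& s,
                         int k, int min_seeds,
                         std::vector<std::pair<int,int> >& windows) {
  int m = (int)q.size(), n = (int)s.size();
  if (m < k || n < k) return;
  const int BASE = 26;
  // index query k-mers
  long span = 1;
  for (int i = 0; i < k; ++i) span *= BASE;
  std::vector<std::vector<int> > idx((size_t)span);
  long code = 0, mul = 1;
  for (int i = 0; i < k - 1; ++i) mul *= BASE;
  int run = 0;
  for (int i = 0; i < m; ++i) {
    int c = q[i] - 'A';
    if (c < 0 || c >= BASE) { run = 0; code = 0; continue; }
    code = (code % mul) * BASE + c;
    run++;
    if (run >= k) {
      std::vector<int>& v = idx[(size_t)code];
      if ((int)v.size() < 16) v.push_back(i - k + 1); // low-complexity cap
    }
  }
  // scan subject
  std::vector<std::pair<int,int> > seeds; // (diag, spos)
  code = 0; run = 0;
  for (int j = 0; j < n; ++j) {
    int c = s[j] - 'A';
    if (c < 0 || c >= BASE) { run = 0; code = 0; continue; }
    code = (code % mul) * BASE + c;
    run++;
    if (run >= k) {
      const std::vector<int>& v = idx[(size_t)code];
      int sp = j - k + 1;
      for (size_t t = 0; t < v.size(); ++t)
        seeds.push_back(std::make_pair(sp - v[t], sp));
    }
  }
  if (seeds.empty()) return;
  std::sort(seeds.begin(), seeds.end());
  const int band = 48;
  int split = std::max(200, m);
  size_t b0 = 0;
  std::vector<std::pair<int,int> > raw;
  for (size_t t = 1; t <= seeds.size(); ++t) {
    if (t == seeds.size() || seeds[t].first - seeds[t - 1].first > band) {
      // one diagonal band: cluster by subject position
      std::vector<int> sp;
      for (size_t u = b0; u < t; ++u) sp.push_back(seeds[u].second);
      std::sort(sp.begin(), sp.end());
      size_t c0 = 0;
      for (size_t u = 1; u <= sp.size(); ++u) {
        if (u == sp.size() || sp[u] - sp[u - 1] > split) {
          if ((int)(u - c0) >= min_seeds) {
            int pad = m + 60;
            int w0 = std::max(0, sp[c0] - pad);
            int w1 = std::min(n, sp[u - 1] + k + pad);
            raw.push_back(std::make_pair(w0, w1));
          }
          c0 = u;
        }
      }
      b0 = t;
    }
  }
  if (raw.empty()) return;
  std::sort(raw.begin(), raw.end());
  // merge overlapping windows
  int cs = raw[0].first, ce = raw[0].second;
  for (size_t t = 1; t < raw.size(); ++t) {
    if (raw[t].first <= ce) { ce = std::max(ce, raw[t].second); }
    else { windows.push_back(std::make_pair(cs, ce)); cs = raw[t].first; ce = raw[t].second; }
  }
  windows.push_back(std::make_pair(cs, ce));
  // chunk very long windows (tandem arrays) to bound DP memory
  std::vector<std::pair<int,int> > out;
  int chunk = std::max(4 * m, 1200), ov = m + 60;
  for (size_t t = 0; t < windows.size(); ++t) {
    int a = windows[t].first, b = windows[t].second;
    if (b - a <= chunk + ov) { out.push_back(windows[t]); continue; }
    for (int p = a; p < b; p += chunk) {
      int e = std::min(b, p + chunk + ov);
      out.push_back(std::make_pair(p, e));
      if (e == b) break;
    }
  }
  windows.swap(out);
}

static DataFrame hits_frame(const std::vector<Hit>& hits) {
  int nh = (int)hits.size();
  NumericVector score(nh);
  IntegerVector qs(nh), qe(nh), ss(nh), se(nh), nid(nh), ncol(nh);
  for (int i = 0; i < nh; ++i) {
    score[i] = hits[i].score;
    qs[i] = hits[i].qs; qe[i] = hits[i].qe;
    ss[i] = hits[i].ss; se[i] = hits[i].se;
    nid[i] = hits[i].nid; ncol[i] = hits[i].ncol;
  }
  return DataFrame::create(_["score"] = score, _["q_start"] = qs,
                           _["q_end"] = qe, _["s_start"] = ss,
                           _["s_end"] = se, _["n_ident"] = nid,
                           _["aln_cols"] = ncol);
}

static DataFrame search_impl(const std::string& q, const std::string& cons,
                             const std::string& s,
                             const double* smat, const double* pssm,
                             double go, double ge, int gap_cap,
                             double xdrop, double min_score, int k,
                             int min_seeds, bool full, int max_hits) {
  int m = smat ? (int)q.size() : (int)cons.size();
  int n = (int)s.size();
  std::vector<std::pair<int,int> > windows;
  if (full) {
    if ((double)m * (double)n > 6e7)
      stop("full DP mode restricted to query x subject <= 6e7 cells; use seeded mode");
    windows.push_back(std::make_pair(0, n));
  } else {
    seed_windows(smat ? q : cons, s, k, min_seeds, windows);
  }
  std::vector<char> masked((size_t)n, 0);
  std::vector<Hit> hits;
  const char* qp = smat ? q.c_str() : cons.c_str();
  for (size_t w = 0; w < windows.size(); ++w) {
    int iter = 0;
    while (iter++ < max_hits) {
      Hit h;
      bool ok = local_align_window(qp, m, s.c_str(),
                                   windows[w].first, windows[w].second,
                                   masked, smat, pssm,
                                   smat ? (const char*)nullptr : cons.c_str(),
                                   go, ge, gap_cap, xdrop, h);
      if (!ok || h.score < min_score) break;
      hits.push_back(h);
      for (int p = h.ss; p < h.se; ++p) masked[p] = 1;
    }
  }
  // dedupe identical hits found in overlapping window chunks
  std::sort(hits.begin(), hits.end(), [](const Hit& a, const Hit& b) {
    if (a.ss != b.ss) return a.ss < b.ss;
    if (a.se != b.se) return a.se < b.se;
    return a.qs < b.qs;
  });
  hits.erase(std::unique(hits.begin(), hits.end(), [](const Hit& a, const Hit& b) {
    return a.ss == b.ss && a.se == b.se && a.qs == b.qs && a.qe == b.qe;
  }), hits.end());
  return hits_frame(hits);
}

// [[Rcpp::export]]
DataFrame cpp_search(std::string query, std::string subject,
                     NumericMatrix smat128, double gap_open,
                     double gap_extend, int gap_cap, double x_drop,
                     double min_score, int k, int min_seeds, bool full,
                     int max_hits) {
  return search_impl(query, std::string(), subject, REAL(smat128), nullptr,
                     gap_open, gap_extend, gap_cap, x_drop, min_score,
                     k, min_seeds, full, max_hits);
}

// [[Rcpp::export]]
DataFrame cpp_search_pssm(NumericMatrix pssm128, std::string consensus,
                          std::string subject, double gap_open,
                          double gap_extend, int gap_cap, double x_drop,
                          double min_score, int k, int min_seeds, bool full,
                          int max_hits) {
  // pssm128 arrives column-major ncol(profile) x 128; transpose to row-major
  int m = pssm128.nrow();
  std::vector<double> rowmaj((size_t)m * 128);
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < 128; ++j)
      rowmaj[(size_t)i * 128 + j] = pssm128(i, j);
  return search_impl(std::string(), consensus, subject, nullptr, rowmaj.data(),
                     gap_open, gap_extend, gap_cap, x_drop, min_score,
                     k, min_seeds, full, max_hits);
}

// Global (Needleman-Wunsch) affine alignment with end gaps penalized;
// used by the star multiple alignment. Returns gapped strings.
// [[Rcpp::export]]
List cpp_global_align(std::string a, std::string b, NumericMatrix smat128,
                      double gap_open, double gap_extend) {
  int m = (int)a.size(), n = (int)b.size();
  const double* smat = REAL(smat128);
  double gopen = gap_open + gap_extend, ge = gap_extend;
  size_t W = (size_t)n + 1;
  std::vector<double> M((size_t)(m + 1) * W, NEG), X((size_t)(m + 1) * W, NEG),
      Y((size_t)(m + 1) * W, NEG);
  std::vector<unsigned char> tb((size_t)(m + 1) * W, 0);
  M[0] = 0.0;
  for (int j = 1; j <= n; ++j) Y[j] = -gopen - ge * (j - 1);
  for (int i = 1; i <= m; ++i) X[(size_t)i * W] = -gopen - ge * (i - 1);
  for (int i = 1; i <= m; ++i) {
    size_t r = (size_t)i * W, rp = r - W;
    const double* srow = smat + (size_t)(unsigned char)a[i - 1] * 128;
    for (int j = 1; j <= n; ++j) {
      double sub = srow[(unsigned char)b[j - 1]];
      double dM = M[rp + j - 1], dX = X[rp + j - 1], dY = Y[rp + j - 1];
      double prev = dM; unsigned char src = 1;
      if (dX > prev) { prev = dX; src = 2; }
      if (dY > prev) { prev = dY; src = 3; }
      M[r + j] = prev + sub;
      unsigned char t = src;
      double xo = M[rp + j] - gopen, xe = X[rp + j] - ge;
      if (xo >= xe) { X[r + j] = xo; t |= 4; } else X[r + j] = xe;
      double yo = M[r + j - 1] - gopen, ye = Y[r + j - 1] - ge;
      if (yo >= ye) { Y[r + j] = yo; t |= 8; } else Y[r + j] = ye;
      tb[r + j] = t;
    }
  }
  size_t last = (size_t)m * W + n;
  double sM = M[last], sX = X[last], sY = Y[last];
  int state = 1; double sc = sM;
  if (sX > sc) { sc = sX; state = 2; }
  if (sY > sc) { sc = sY; state = 3; }
  std::string ra, rb;
  int i = m, j = n;
  while (i > 0 || j > 0) {
    size_t r = (size_t)i * W;
    if (i == 0) { ra.push_back('-'); rb.push_back(b[j - 1]); j--; continue; }
    if (j == 0) { ra.push_back(a[i - 1]); rb.push_back('-'); i--; continue; }
    if (state == 1) {
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      unsigned char src = tb[r + j] & 3;
      i--; j--;
      state = src;
    } else if (state == 2) {
      ra.push_back(a[i - 1]); rb.push_back('-');
      state = (tb[r + j] & 4) ? 1 : 2;
      i--;
    } else {
      ra.push_back('-'); rb.push_back(b[j - 1]);
      state = (tb[r + j] & 8) ? 1 : 3;
      j--;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["score"] = sc, _["a"] = ra, _["b"] = rb);
}

// Score-only global alignment (centre selection in the star MSA).
// [[Rcpp::export]]
double cpp_global_score(std::string a, std::string b, NumericMatrix smat128,
                        double gap_open, double gap_extend) {
  int m = (int)a.size(), n = (int)b.size();
  const double* smat = REAL(smat128);
  double gopen = gap_open + gap_extend, ge = gap_extend;
  std::vector<double> M(n + 1, NEG), X(n + 1, NEG), Y(n + 1, NEG);
  std::vector<double> pM(n + 1), pX(n + 1), pY(n + 1);
  M[0] = 0.0;
  for (int j = 1; j <= n; ++j) Y[j] = -gopen - ge * (j - 1);
  for (int i = 1; i <= m; ++i) {
    pM = M; pX = X; pY = Y;
    M[0] = NEG; X[0] = -gopen - ge * (i - 1); Y[0] = NEG;
    const double* srow = smat + (size_t)(unsigned char)a[i - 1] * 128;
    for (int j = 1; j <= n; ++j) {
      double sub = srow[(unsigned char)b[j - 1]];
      M[j] = std::max(pM[j - 1], std::max(pX[j - 1], pY[j - 1])) + sub;
      X[j] = std::max(pM[j] - gopen, pX[j] - ge);
      Y[j] = std::max(M[j - 1] - gopen, Y[j - 1] - ge);
    }
  }
  return std::max(M[n], std::max(X[n], Y[n]));
}
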