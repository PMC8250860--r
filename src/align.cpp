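// Pairwise protein alignment kernel: global alignment with affine gap
// penalties (Gotoh) and free terminal gaps, the stand-in for blastp in the
// pan-genome pipeline. Percent identity is computed over aligned columns of
// the core region (terminal gap columns excluded); coverage is the fraction
// of each sequence's residues inside that core region.
//
// Tie-breaking is pinned for reproducibility: at equal score the traceback
// prefers diagonal > up (gap in subject) > left (gap in query), and prefers
// closing a gap over extending it.
#include <Rcpp.h>
#include <cstdint>
#include <algorithm>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

static const double NEG = -1e30;

struct Encoder {
  int idx[256];
  int x_idx;
  bool standard[256];
  Encoder(const NumericMatrix& sub) {
    CharacterVector rn = rownames(sub);
    for (int i = 0; i < 256; ++i) { idx[i] = -1; standard[i] = false; }
    x_idx = -1;
    for (int i = 0; i < rn.size(); ++i) {
      std::string s = as<std::string>(rn[i]);
      if (s.size() == 1) {
        unsigned char c = toupper(s[0]);
        idx[c] = i;
        if (c == 'X') x_idx = i;
      }
    }
    if (x_idx < 0) stop("substitution matrix must contain an 'X' row/column");
    const std::string std20 = "ACDEFGHIKLMNPQRSTVWY";
    for (char c : std20) standard[(unsigned char)c] = true;
  }
  // non-standard letters (B, Z, J, U, O, ...) are mapped to X and scored as
  // mismatch; they never count as identities
  int encode(unsigned char c) const {
    c = toupper(c);
    int i = idx[c];
    if (i < 0 || !standard[c]) return x_idx;
    return i;
  }
};

struct AlnStats {
  double score;
  int n_ident, cols, q_res, s_res;
  std::string aln_a, aln_b;
};

static AlnStats align_core(const std::vector<int>& ea, const std::vector<int>& eb,
                           const std::string& a, const std::string& b,
                           const NumericMatrix& sub, int x_idx,
                           double open, double ext, bool keep_aln) {
  const int n = (int)ea.size(), m = (int)eb.size();
  // pointer bits: 0-1 H choice (0 diag, 1 up/F, 2 left/E); 2 F closes; 3 E closes
  std::vector<uint8_t> ptr((size_t)(n + 1) * (m + 1), 0);
  std::vector<double> Hprev(m + 1, 0.0), Hcur(m + 1, 0.0), Fcol(m + 1, NEG);
  std::vector<double> HlastCol(n + 1, 0.0), HlastRow(m + 1, 0.0);
  HlastCol[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    Hcur[0] = 0.0;
    double Ecur = NEG;
    const double* srow = &sub(ea[i - 1], 0);
    size_t off = (size_t)i * (m + 1);
    for (int j = 1; j <= m; ++j) {
      double eOpen = Hcur[j - 1] - open - ext;
      double eExt = Ecur - ext;
      bool eClose = eOpen >= eExt;
      Ecur = eClose ? eOpen : eExt;
      double fOpen = Hprev[j] - open - ext;
      double fExt = Fcol[j] - ext;
      bool fClose = fOpen >= fExt;
      Fcol[j] = fClose ? fOpen : fExt;
      double diag = Hprev[j - 1] + srow[(size_t)eb[j - 1] * sub.nrow()];
      double h; uint8_t hc;
      if (diag >= Fcol[j] && diag >= Ecur) { h = diag; hc = 0; }
      else if (Fcol[j] >= Ecur) { h = Fcol[j]; hc = 1; }
      else { h = Ecur; hc = 2; }
      Hcur[j] = h;
      ptr[off + j] = (uint8_t)(hc | (fClose ? 4 : 0) | (eClose ? 8 : 0));
    }
    HlastCol[i] = Hcur[m];
    std::swap(Hprev, Hcur);
  }
  for (int j = 0; j <= m; ++j) HlastRow[j] = Hprev[j];

  // end cell: free trailing gaps -> best over last row / last column.
  // preference: corner, then last row right-to-left, then last column bottom-up
  int bi = n, bj = m;
  double best = HlastRow[m];
  for (int j = m - 1; j >= 1; --j)
    if (HlastRow[j] > best) { best = HlastRow[j]; bi = n; bj = j; }
  for (int i = n - 1; i >= 1; --i)
    if (HlastCol[i] > best) { best = HlastCol[i]; bi = i; bj = m; }

  AlnStats st; st.score = best;
  st.n_ident = 0; st.cols = 0; st.q_res = 0; st.s_res = 0;

  std::string ra, rb; // built in reverse
  if (keep_aln) { // trailing unaligned residues, padded against gaps
    for (int j = m; j > bj; --j) { ra.push_back('-'); rb.push_back(b[j - 1]); }
    for (int i = n; i > bi; --i) { ra.push_back(a[i - 1]); rb.push_back('-'); }
  }
  int i = bi, j = bj, state = 0; // 0 = H, 1 = F(up), 2 = E(left)
  while (true) {
    if (state == 0) {
      if (i == 0 || j == 0) break;
      uint8_t p = ptr[(size_t)i * (m + 1) + j];
      int hc = p & 3;
      if (hc == 0) {
        st.cols++; st.q_res++; st.s_res++;
        if (ea[i - 1] == eb[j - 1] && ea[i - 1] != x_idx) st.n_ident++;
        if (keep_aln) { ra.push_back(a[i - 1]); rb.push_back(b[j - 1]); }
        --i; --j;
      } else state = hc;
    } else if (state == 1) { // gap in b, consume a
      uint8_t p = ptr[(size_t)i * (m + 1) + j];
      st.cols++; st.q_res++;
      if (keep_aln) { ra.push_back(a[i - 1]); rb.push_back('-'); }
      --i;
      if (p & 4) state = 0;
    } else { // gap in a, consume b
      uint8_t p = ptr[(size_t)i * (m + 1) + j];
      st.cols++; st.s_res++;
      if (keep_aln) { ra.push_back('-'); rb.push_back(b[j - 1]); }
      --j;
      if (p & 8) state = 0;
    }
  }
  if (keep_aln) { // leading unaligned residues
    for (; i > 0; --i) { ra.push_back(a[i - 1]); rb.push_back('-'); }
    for (; j > 0; --j) { ra.push_back('-'); rb.push_back(b[j - 1]); }
    std::reverse(ra.begin(), ra.end());
    std::reverse(rb.begin(), rb.end());
    st.aln_a = ra; st.aln_b = rb;
  }
  return st;
}

// [[Rcpp::export]]
List align_pair_cpp(std::string a, std::string b, NumericMatrix sub,
                    double gap_open, double gap_ext, bool keep_alignment) {
  if (a.empty() || b.empty()) stop("sequences must be non-empty");
  Encoder enc(sub);
  std::vector<int> ea(a.size()), eb(b.size());
  for (size_t i = 0; i < a.size(); ++i) ea[i] = enc.encode(a[i]);
  for (size_t i = 0; i < b.size(); ++i) eb[i] = enc.encode(b[i]);
  AlnStats st = align_core(ea, eb, a, b, sub, enc.x_idx, gap_open, gap_ext, keep_alignment);
  List out = List::create(
    _["score"] = st.score,
    _["pid"] = st.cols > 0 ? 100.0 * st.n_ident / st.cols : NA_REAL,
    _["query_cov"] = 100.0 * st.q_res / (double)a.size(),
    _["subject_cov"] = 100.0 * st.s_res / (double)b.size(),
    _["aligned_cols"] = st.cols,
    _["n_ident"] = st.n_ident);
  if (keep_alignment) {
    out.push_back(st.aln_a, "aln_a");
    out.push_back(st.aln_b, "aln_b");
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix align_stats_batch_cpp(CharacterVector seqs, IntegerVector ai,
                                    IntegerVector bi, NumericMatrix sub,
                                    double gap_open, double gap_ext) {
  if (ai.size() != bi.size()) stop("index vectors differ in length");
  Encoder enc(sub);
  int ns = seqs.size();
  std::vector<std::vector<int>> encs(ns);
  std::vector<std::string> raw(ns);
  for (int i = 0; i < ns; ++i) {
    raw[i] = as<std::string>(seqs[i]);
    encs[i].resize(raw[i].size());
    for (size_t p = 0; p < raw[i].size(); ++p) encs[i][p] = enc.encode(raw[i][p]);
  }
  int np = ai.size();
  NumericMatrix out(np, 6);
  colnames(out) = CharacterVector::create("score", "pid", "query_cov",
                                          "subject_cov", "aligned_cols", "n_ident");
  for (int p = 0; p < np; ++p) {
    int u = ai[p] - 1, v = bi[p] - 1;
    if (u < 0 || v < 0 || u >= ns || v >= ns) stop("pair index out of range");
    if (encs[u].empty() || encs[v].empty()) stop("sequences must be non-empty");
    AlnStats st = align_core(encs[u], encs[v], raw[u], raw[v], sub, enc.x_idx,
                             gap_open, gap_ext, false);
    out(p, 0) = st.score;
    out(p, 1) = st.cols > 0 ? 100.0 * st.n_ident / st.cols : NA_REAL;
    out(p, 2) = 100.0 * st.q_res / (double)raw[u].size();
    out(p, 3) = 100.0 * st.s_res / (double)raw[v].size();
    out(p, 4) = st.cols;
    out(p, 5) = st.n_ident;
    if (p % 1024 == 0) checkUserInterrupt();
  }
  return out;
}

static void unique_kmers(const std::string& s, int k, std::vector<uint64_t>& out) {
  out.clear();
  int n = (int)s.size();
  if (n < k) return;
  uint64_t mask = (k * 5 >= 64) ? ~0ULL : ((1ULL << (5 * k)) - 1);
  uint64_t cur = 0;
  for (int i = 0; i < n; ++i) {
    unsigned char c = toupper(s[i]);
    uint64_t code = (c >= 'A' && c <= 'Z') ? (uint64_t)(c - 'A') : 26ULL;
    cur = ((cur << 5) | code) & mask;
    if (i >= k - 1) out.push_back(cur);
  }
  std::sort(out.begin(), out.end());
  out.erase(std::unique(out.begin(), out.end()), out.end());
}

// All pairs of sequences sharing at least min_shared distinct k-mers,
// found by a single inverted-index pass (the CD-HIT/blast-style prescreen).
// [[Rcpp::export]]
IntegerMatrix kmer_candidate_pairs_cpp(CharacterVector seqs, int k, int min_shared) {
  if (k < 3) stop("k must be >= 3");
  int ns = seqs.size();
  std::vector<std::pair<uint64_t, int>> post;
  std::vector<uint64_t> buf;
  for (int i = 0; i < ns; ++i) {
    unique_kmers(as<std::string>(seqs[i]), k, buf);
    for (uint64_t km : buf) post.emplace_back(km, i);
  }
  std::sort(post.begin(), post.end());
  std::unordered_map<uint64_t, int> counts;
  size_t p = 0;
  while (p < post.size()) {
    size_t q = p;
    while (q < post.size() && post[q].first == post[p].first) ++q;
    for (size_t x = p; x < q; ++x)
      for (size_t y = x + 1; y < q; ++y) {
        uint64_t key = ((uint64_t)post[x].second << 32) | (uint32_t)post[y].second;
        counts[key]++;
      }
    p = q;
  }
  std::vector<std::pair<uint64_t, int>> keep;
  for (auto& kv : counts)
    if (kv.second >= min_shared) keep.push_back(kv);
  std::sort(keep.begin(), keep.end());
  IntegerMatrix out((int)keep.size(), 3);
  colnames(out) = CharacterVector::create("i", "j", "shared");
  for (size_t r = 0; r < keep.size(); ++r) {
    out(r, 0) = (int)(keep[r].first >> 32) + 1;
    out(r, 1) = (int)(keep[r].first & 0xffffffffULL) + 1;
    out(r, 2) = keep[r].second;
  }
  return out;
}

static void all_kmers(const std::string& s, int k, std::vector<uint64_t>& out) {
  out.clear();
  int n = (int)s.size();
  if (n < k) return;
  uint64_t mask = (k * 5 >= 64) ? ~0ULL : ((1ULL << (5 * k)) - 1);
  uint64_t cur = 0;
  for (int i = 0; i < n; ++i) {
    unsigned char c = toupper(s[i]);
    uint64_t code = (c >= 'A' && c <= 'Z') ? (uint64_t)(c - 'A') : 26ULL;
    cur = ((cur << 5) | code) & mask;
    if (i >= k - 1) out.push_back(cur);
  }
  std::sort(out.begin(), out.end());
}

// Multiplicity-aware shared k-mer count (sum over k-mers of the minimum of
// the two occurrence counts), so identical sequences of length L always
// share exactly L - k + 1 k-mers, repeats included.
// [[Rcpp::export]]
int shared_kmer_count_cpp(std::string a, std::string b, int k) {
  if (k < 3) stop("k must be >= 3");
  std::vector<uint64_t> ka, kb;
  all_kmers(a, k, ka);
  all_kmers(b, k, kb);
  int shared = 0;
  size_t i = 0, j = 0;
  while (i < ka.size() && j < kb.size()) {
    if (ka[i] == kb[j]) { ++shared; ++i; ++j; }
    else if (ka[i] < kb[j]) ++i;
    else ++j;
  }
  return shared;
}

// Ungapped percent identity of two equal-length sequences (truth-ledger recount)
// [[Rcpp::export]]
double hamming_pid_cpp(std::string a, std::string b) {
  if (a.size() != b.size()) stop("sequences differ in length");
  if (a.empty()) stop("sequences must be non-empty");
  int id = 0;
  for (size_t i = 0; i < a.size(); ++i)
    if (toupper(a[i]) == toupper(b[i])) ++id;
  return 100.0 * id / (double)a.size();
}
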