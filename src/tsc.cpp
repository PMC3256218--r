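#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Scoring model
//
// A gap run of length L costs g + (L-1)*ext, terminal runs included; the
// platform sets the extension value (Illumina: e per column, 454: 0, so a
// 454 run costs the opening penalty once -- a single indel however long).
// The x flag excludes end gaps from the *distance*: terminal gap columns
// are trimmed before differences are counted and from the denominator.
// ---------------------------------------------------------------------------

struct AlnParams {
  double a;     // match score
  double b;     // mismatch score
  double g;     // gap open
  double e;     // gap extend
  bool   x;     // exclude end gaps from the distance (trim terminal columns)
  bool   r454;  // 454 gap model
  double gext() const { return r454 ? 0.0 : e; }
};

static AlnParams make_params(double a, double b, double g, double e,
                             bool x, bool r454) {
  AlnParams p; p.a = a; p.b = b; p.g = g; p.e = e; p.x = x; p.r454 = r454;
  return p;
}

static inline bool is_acgt(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

// ambiguity codes never match, even to themselves
static inline double subscore(char c1, char c2, const AlnParams& p) {
  return (c1 == c2 && is_acgt(c1)) ? p.a : p.b;
}

// ---------------------------------------------------------------------------
// Gotoh global alignment with affine gaps, end-gap conventions and a
// deterministic traceback (prefer substitution column, then gap in the
// second sequence, then gap in the first).
//
// States: 0 = M (substitution column), 1 = E (gap in s1, consumes s2),
//         2 = F (gap in s2, consumes s1).
// ---------------------------------------------------------------------------

static const double NEG = -1e18;

struct AlnResult {
  std::string a1, a2;
  double score;
};

// preference M(0) > F(2) > E(1) on ties
static inline int pick3(double m, double e, double f, double& best) {
  best = m; int st = 0;
  if (f > best) { best = f; st = 2; }
  if (e > best) { best = e; st = 1; }
  return st;
}

static AlnResult nw_core(const std::string& s1, const std::string& s2,
                         const AlnParams& p) {
  const int n = (int) s1.size(), m = (int) s2.size();
  if (n == 0 || m == 0) stop("sequences must be non-empty");
  const int W = m + 1;
  std::vector<double> M((n + 1) * W, NEG), E((n + 1) * W, NEG),
      F((n + 1) * W, NEG);
  std::vector<unsigned char> tbM((n + 1) * W), tbE((n + 1) * W),
      tbF((n + 1) * W);
  const double ge = p.gext();

  M[0] = 0.0;
  for (int j = 1; j <= m; ++j) {           // leading gap in s1
    E[j] = p.g + ge * (j - 1);
    tbE[j] = (j == 1) ? 0 : 1;
  }
  for (int i = 1; i <= n; ++i) {           // leading gap in s2
    F[i * W] = p.g + ge * (i - 1);
    tbF[i * W] = (i == 1) ? 0 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int c = i * W + j, d = (i - 1) * W + (j - 1),
                u = (i - 1) * W + j, l = i * W + (j - 1);
      double best;
      // M: substitution column
      int st = pick3(M[d], E[d], F[d], best);
      M[c] = best + subscore(s1[i - 1], s2[j - 1], p);
      tbM[c] = (unsigned char) st;
      // E: gap in s1, consumes s2[j-1]
      {
        double vm = M[l] + p.g, ve = E[l] + ge, vf = F[l] + p.g;
        st = pick3(vm, ve, vf, best);
        E[c] = best; tbE[c] = (unsigned char) st;
      }
      // F: gap in s2, consumes s1[i-1]
      {
        double vm = M[u] + p.g, ve = E[u] + p.g, vf = F[u] + ge;
        st = pick3(vm, ve, vf, best);
        F[c] = best; tbF[c] = (unsigned char) st;
      }
    }
  }

  double best;
  int st = pick3(M[n * W + m], E[n * W + m], F[n * W + m], best);

  AlnResult res; res.score = best;
  std::string r1, r2;
  r1.reserve(n + m); r2.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const int c = i * W + j;
    if (st == 0) {
      r1.push_back(s1[i - 1]); r2.push_back(s2[j - 1]);
      st = tbM[c]; --i; --j;
    } else if (st == 1) {
      r1.push_back('-'); r2.push_back(s2[j - 1]);
      st = tbE[c]; --j;
    } else {
      r1.push_back(s1[i - 1]); r2.push_back('-');
      st = tbF[c]; --i;
    }
  }
  std::reverse(r1.begin(), r1.end());
  std::reverse(r2.begin(), r2.end());
  res.a1 = r1; res.a2 = r2;
  return res;
}

// [[Rcpp::export]]
List nw_align_cpp(std::string s1, std::string s2, double a, double b,
                  double g, double e, bool x, bool r454) {
  AlnParams p = make_params(a, b, g, e, x, r454);
  AlnResult r = nw_core(s1, s2, p);
  return List::create(_["a1"] = r.a1, _["a2"] = r.a2, _["score"] = r.score);
}

// ---------------------------------------------------------------------------
// Distance from an aligned pair
// ---------------------------------------------------------------------------

struct AlnStats { int mismatches, gap_cols, gap_runs, length; };

static AlnStats aln_stats(const std::string& a1, const std::string& a2,
                          bool trim) {
  if (a1.size() != a2.size())
    stop("aligned sequences must have equal length");
  int L = (int) a1.size();
  int s = 0, t = L - 1;
  if (trim) {
    while (s < L && (a1[s] == '-' || a2[s] == '-')) ++s;
    while (t >= s && (a1[t] == '-' || a2[t] == '-')) --t;
  }
  AlnStats st; st.mismatches = 0; st.gap_cols = 0; st.gap_runs = 0;
  st.length = (t >= s) ? (t - s + 1) : 0;
  int prev = 0;  // 0 none, 1 gap in a1, 2 gap in a2
  for (int i = s; i <= t; ++i) {
    bool g1 = a1[i] == '-', g2 = a2[i] == '-';
    if (g1 && g2) stop("column %d has gaps in both sequences", i + 1);
    if (g1 || g2) {
      ++st.gap_cols;
      int cur = g1 ? 1 : 2;
      if (cur != prev) ++st.gap_runs;
      prev = cur;
    } else {
      prev = 0;
      if (!(a1[i] == a2[i] && is_acgt(a1[i]))) ++st.mismatches;
    }
  }
  return st;
}

// [[Rcpp::export]]
List aln_stats_cpp(std::string a1, std::string a2, bool trim) {
  AlnStats st = aln_stats(a1, a2, trim);
  return List::create(_["mismatches"] = st.mismatches,
                      _["gap_cols"] = st.gap_cols,
                      _["gap_runs"] = st.gap_runs,
                      _["length"] = st.length);
}

static double dist_from_aln(const std::string& a1, const std::string& a2,
                            const AlnParams& p) {
  AlnStats st = aln_stats(a1, a2, p.x);
  if (st.length == 0) return 1.0;  // alignment entirely end gaps
  double diff = st.mismatches + (p.r454 ? st.gap_runs : st.gap_cols);
  return diff / st.length;
}

// [[Rcpp::export]]
double aln_distance_cpp(std::string a1, std::string a2, double a, double b,
                        double g, double e, bool x, bool r454) {
  AlnParams p = make_params(a, b, g, e, x, r454);
  return dist_from_aln(a1, a2, p);
}

// [[Rcpp::export]]
double nw_pair_distance_cpp(std::string s1, std::string s2, double a,
                            double b, double g, double e, bool x, bool r454) {
  AlnParams p = make_params(a, b, g, e, x, r454);
  AlnResult r = nw_core(s1, s2, p);
  return dist_from_aln(r.a1, r.a2, p);
}

// [[Rcpp::export]]
NumericVector nw_distance_many_cpp(std::string q, CharacterVector targets,
                                   double a, double b, double g, double e,
                                   bool x, bool r454) {
  AlnParams p = make_params(a, b, g, e, x, r454);
  NumericVector out(targets.size());
  for (int i = 0; i < targets.size(); ++i) {
    std::string t = as<std::string>(targets[i]);
    AlnResult r = nw_core(q, t, p);
    out[i] = dist_from_aln(r.a1, r.a2, p);
  }
  return out;
}

// ---------------------------------------------------------------------------
// k-mer word profiles and k-mer distance
//
// d = 1 - sum_w min(c1(w), c2(w)) / (min(|s1|, |s2|) - k + 1)
// over overlapping forward-strand words; words containing non-ACGT
// characters are skipped.
// ---------------------------------------------------------------------------

static void profile_of(const std::string& s, int k,
                       std::vector<int>& codes, std::vector<int>& counts) {
  codes.clear(); counts.clear();
  const int L = (int) s.size();
  if (L < k) return;
  std::vector<int> raw;
  raw.reserve(L - k + 1);
  for (int i = 0; i + k <= L; ++i) {
    int code = 0; bool ok = true;
    for (int j = 0; j < k; ++j) {
      int v;
      switch (s[i + j]) {
        case 'A': v = 0; break; case 'C': v = 1; break;
        case 'G': v = 2; break; case 'T': v = 3; break;
        default: v = 0; ok = false;
      }
      code = (code << 2) | v;
    }
    if (ok) raw.push_back(code);
  }
  std::sort(raw.begin(), raw.end());
  for (size_t i = 0; i < raw.size();) {
    size_t j = i;
    while (j < raw.size() && raw[j] == raw[i]) ++j;
    codes.push_back(raw[i]);
    counts.push_back((int) (j - i));
    i = j;
  }
}

static int shared_words(const int* c1, const int* n1, int l1,
                        const int* c2, const int* n2, int l2) {
  int i = 0, j = 0, sh = 0;
  while (i < l1 && j < l2) {
    if (c1[i] < c2[j]) ++i;
    else if (c1[i] > c2[j]) ++j;
    else { sh += std::min(n1[i], n2[j]); ++i; ++j; }
  }
  return sh;
}

// [[Rcpp::export]]
double kmer_distance_cpp(std::string s1, std::string s2, int k) {
  if ((int) s1.size() < k || (int) s2.size() < k)
    stop("sequences must be at least k bases long");
  std::vector<int> c1, n1, c2, n2;
  profile_of(s1, k, c1, n1);
  profile_of(s2, k, c2, n2);
  int sh = shared_words(c1.data(), n1.data(), (int) c1.size(),
                        c2.data(), n2.data(), (int) c2.size());
  double denom = (double) std::min(s1.size(), s2.size()) - k + 1;
  return 1.0 - sh / denom;
}

// Flat profile store over a fixed tag set (built once, queried many times)
// [[Rcpp::export]]
List kmer_profiles_cpp(CharacterVector seqs, int k) {
  const int n = seqs.size();
  std::vector<int> codes, counts, offs(n + 1, 0), lens(n);
  std::vector<int> c, cn;
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    lens[i] = (int) s.size();
    if (lens[i] < k) stop("sequence %d shorter than k", i + 1);
    profile_of(s, k, c, cn);
    codes.insert(codes.end(), c.begin(), c.end());
    counts.insert(counts.end(), cn.begin(), cn.end());
    offs[i + 1] = (int) codes.size();
  }
  return List::create(_["codes"] = wrap(codes), _["counts"] = wrap(counts),
                      _["offsets"] = wrap(offs), _["lens"] = wrap(lens),
                      _["k"] = k);
}

// k-mer distances of tag `qi` against tags `cand` (both 1-based)
// [[Rcpp::export]]
NumericVector kmer_query_cpp(List prof, int qi, IntegerVector cand) {
  IntegerVector codes = prof["codes"], counts = prof["counts"],
                offs = prof["offsets"], lens = prof["lens"];
  int k = as<int>(prof["k"]);
  const int* C = INTEGER(codes);
  const int* N = INTEGER(counts);
  const int* O = INTEGER(offs);
  const int* L = INTEGER(lens);
  int q = qi - 1;
  NumericVector out(cand.size());
  for (int t = 0; t < cand.size(); ++t) {
    int j = cand[t] - 1;
    int sh = shared_words(C + O[q], N + O[q], O[q + 1] - O[q],
                          C + O[j], N + O[j], O[j + 1] - O[j]);
    double denom = (double) std::min(L[q], L[j]) - k + 1;
    out[t] = 1.0 - sh / denom;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Sparse all-vs-all NW distances with k-mer prescreening
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List sparse_pairs_cpp(CharacterVector seqs, int k, double fmax, double a,
                      double b, double g, double e, bool x, bool r454,
                      double cap) {
  AlnParams p = make_params(a, b, g, e, x, r454);
  const int n = seqs.size();
  std::vector<std::string> S(n);
  std::vector<std::vector<int> > codes(n), counts(n);
  for (int i = 0; i < n; ++i) {
    S[i] = as<std::string>(seqs[i]);
    if ((int) S[i].size() < k) stop("sequence %d shorter than k", i + 1);
    profile_of(S[i], k, codes[i], counts[i]);
  }
  std::vector<int> vi, vj;
  std::vector<double> vd;
  long long n_align = 0, n_pass = 0;
  const long long n_pairs = (long long) n * (n - 1) / 2;
  for (int i = 0; i < n; ++i) {
    Rcpp::checkUserInterrupt();
    for (int j = i + 1; j < n; ++j) {
      int sh = shared_words(codes[i].data(), counts[i].data(),
                            (int) codes[i].size(), codes[j].data(),
                            counts[j].data(), (int) codes[j].size());
      double denom = (double) std::min(S[i].size(), S[j].size()) - k + 1;
      double kd = 1.0 - sh / denom;
      if (kd > fmax) continue;
      ++n_pass;
      AlnResult r = nw_core(S[i], S[j], p);
      ++n_align;
      double d = dist_from_aln(r.a1, r.a2, p);
      if (d <= cap) {
        vi.push_back(i + 1); vj.push_back(j + 1); vd.push_back(d);
      }
    }
  }
  return List::create(_["i"] = wrap(vi), _["j"] = wrap(vj),
                      _["d"] = wrap(vd),
                      _["n_alignments"] = (double) n_align,
                      _["n_pairs"] = (double) n_pairs,
                      _["n_prescreen_pass"] = (double) n_pass);
}

// ---------------------------------------------------------------------------
// Alignment-free direct comparison (precluster 2): walk 5' to 3' one base
// at a time; unequal lengths add the length difference as mismatches;
// denominator is the longer length.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
double direct_distance_cpp(std::string s1, std::string s2) {
  size_t l1 = s1.size(), l2 = s2.size(), lm = std::min(l1, l2);
  if (lm == 0) stop("sequences must be non-empty");
  int mm = 0;
  for (size_t i = 0; i < lm; ++i)
    if (!(s1[i] == s2[i] && is_acgt(s1[i]))) ++mm;
  double diff = mm + (double) (std::max(l1, l2) - lm);
  return diff / std::max(l1, l2);
}

// first index (1-based) in `reps` with direct distance strictly below d,
// scanned in order; 0 when none qualifies
// [[Rcpp::export]]
int direct_scan_cpp(std::string q, CharacterVector reps, double d) {
  for (int i = 0; i < reps.size(); ++i) {
    std::string r = as<std::string>(reps[i]);
    if (direct_distance_cpp(q, r) < d) return i + 1;
  }
  return 0;
}

// ---------------------------------------------------------------------------
// Brute-force oracle: enumerate every global alignment and score it with a
// standalone run-based scorer.  Independent of the DP above; used in tests.
// ---------------------------------------------------------------------------

static double score_alignment(const std::string& a1, const std::string& a2,
                              const AlnParams& p) {
  const int L = (int) a1.size();
  double sc = 0.0;
  int i = 0;
  while (i < L) {
    bool g1 = a1[i] == '-', g2 = a2[i] == '-';
    if (g1 && g2) stop("column %d has gaps in both sequences", i + 1);
    if (g1 || g2) {
      bool in1 = g1;
      int j = i;
      while (j < L && (in1 ? a1[j] : a2[j]) == '-') ++j;
      int len = j - i;
      sc += p.g + p.gext() * (len - 1);
      i = j;
    } else {
      sc += subscore(a1[i], a2[i], p);
      ++i;
    }
  }
  return sc;
}

// [[Rcpp::export]]
double score_alignment_cpp(std::string a1, std::string a2, double a, double b,
                           double g, double e, bool x, bool r454) {
  AlnParams p = make_params(a, b, g, e, x, r454);
  return score_alignment(a1, a2, p);
}

static void enum_rec(const std::string& s1, const std::string& s2, size_t i,
                     size_t j, std::string& a1, std::string& a2,
                     const AlnParams& p, double& best) {
  if (i == s1.size() && j == s2.size()) {
    double sc = score_alignment(a1, a2, p);
    if (sc > best) best = sc;
    return;
  }
  if (i < s1.size() && j < s2.size()) {
    a1.push_back(s1[i]); a2.push_back(s2[j]);
    enum_rec(s1, s2, i + 1, j + 1, a1, a2, p, best);
    a1.pop_back(); a2.pop_back();
  }
  if (i < s1.size()) {
    a1.push_back(s1[i]); a2.push_back('-');
    enum_rec(s1, s2, i + 1, j, a1, a2, p, best);
    a1.pop_back(); a2.pop_back();
  }
  if (j < s2.size()) {
    a1.push_back('-'); a2.push_back(s2[j]);
    enum_rec(s1, s2, i, j + 1, a1, a2, p, best);
    a1.pop_back(); a2.pop_back();
  }
}

// [[Rcpp::export]]
double enum_best_score_cpp(std::string s1, std::string s2, double a, double b,
                           double g, double e, bool x, bool r454) {
  AlnParams p = make_params(a, b, g, e, x, r454);
  double best = NEG;
  std::string a1, a2;
  enum_rec(s1, s2, 0, 0, a1, a2, p, best);
  return best;
}

// max |DP score - enumerated score| over paired sequence vectors
// [[Rcpp::export]]
double max_score_gap_cpp(CharacterVector s1, CharacterVector s2, double a,
                         double b, double g, double e, bool x, bool r454) {
  AlnParams p = make_params(a, b, g, e, x, r454);
  double worst = 0.0;
  for (int t = 0; t < s1.size(); ++t) {
    std::string u = as<std::string>(s1[t]), v = as<std::string>(s2[t]);
    AlnResult r = nw_core(u, v, p);
    double best = NEG;
    std::string a1, a2;
    enum_rec(u, v, 0, 0, a1, a2, p, best);
    double gap = std::abs(r.score - best);
    if (gap > worst) worst = gap;
    if (t % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return worst;
}

// ---------------------------------------------------------------------------
// Mock-library read mutation with a bounded-distance screen: each read copies
// its template, applies per-base deletion/substitution/insertion, and is
// resampled until its NW distance to the parent is at most max_dist
// (emulating a "97up"-style screen).  Uses R's RNG.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List mutate_reads_cpp(CharacterVector templates, IntegerVector parent,
                      double sub_rate, double ins_rate, double del_rate,
                      double a, double b, double g, double e, bool x,
                      bool r454, double max_dist, int max_retry) {
  AlnParams p = make_params(a, b, g, e, x, r454);
  const char BASES[4] = {'A', 'C', 'G', 'T'};
  const int n = parent.size();
  CharacterVector reads(n);
  long long resampled = 0, fallback = 0;
  bool mutating = sub_rate > 0 || ins_rate > 0 || del_rate > 0;
  for (int r = 0; r < n; ++r) {
    const std::string tmpl = as<std::string>(templates[parent[r] - 1]);
    if (!mutating) { reads[r] = tmpl; continue; }
    std::string read;
    bool ok = false;
    for (int attempt = 0; attempt < max_retry && !ok; ++attempt) {
      read.clear();
      read.reserve(tmpl.size() + 4);
      bool changed = false;
      for (size_t i = 0; i < tmpl.size(); ++i) {
        if (del_rate > 0 && R::unif_rand() < del_rate) { changed = true; }
        else {
          char c = tmpl[i];
          if (sub_rate > 0 && R::unif_rand() < sub_rate) {
            int v = (int) (R::unif_rand() * 3);
            if (v > 2) v = 2;
            int cur = (c == 'A') ? 0 : (c == 'C') ? 1 : (c == 'G') ? 2 : 3;
            c = BASES[(cur + 1 + v) % 4];
            changed = true;
          }
          read.push_back(c);
        }
        if (ins_rate > 0 && R::unif_rand() < ins_rate) {
          int v = (int) (R::unif_rand() * 4);
          if (v > 3) v = 3;
          read.push_back(BASES[v]);
          changed = true;
        }
      }
      if (!changed || read.empty()) { read = tmpl; ok = true; break; }
      AlnResult al = nw_core(read, tmpl, p);
      ok = dist_from_aln(al.a1, al.a2, p) <= max_dist;
      if (!ok) ++resampled;
    }
    if (!ok) { read = tmpl; ++fallback; }
    reads[r] = read;
    if (r % 1024 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["reads"] = reads, _["resampled"] = (double) resampled,
                      _["fallback"] = (double) fallback);
}
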