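#include <Rcpp.h>
#include <unordered_map>
#include <string>
#include <vector>
using namespace Rcpp;

// Standard genetic code indexed by 16*b1 + 4*b2 + b3 with T=0, C=1, A=2, G=3.
static const char CODON_TABLE[] =
    "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG";

static inline int base_index(char c) {
  switch (c) {
    case 'T': case 't': return 0;
    case 'C': case 'c': return 1;
    case 'A': case 'a': return 2;
    case 'G': case 'g': return 3;
    default: return -1;  // N or other ambiguity
  }
}

// [[Rcpp::export]]
std::string cpp_translate(const std::string& dna, int offset) {
  int n = (int) dna.size();
  int naa = (n - offset) / 3;
  if (naa < 0) naa = 0;
  std::string aa(naa, 'X');
  for (int i = 0; i < naa; ++i) {
    int p = offset + 3 * i;
    int b1 = base_index(dna[p]), b2 = base_index(dna[p + 1]),
        b3 = base_index(dna[p + 2]);
    aa[i] = (b1 < 0 || b2 < 0 || b3 < 0) ? 'X'
                                         : CODON_TABLE[16 * b1 + 4 * b2 + b3];
  }
  return aa;
}

// [[Rcpp::export]]
std::string cpp_revcomp(const std::string& dna) {
  int n = (int) dna.size();
  std::string rc(n, 'N');
  for (int i = 0; i < n; ++i) {
    char c = dna[n - 1 - i], o;
    switch (c) {
      case 'A': o = 'T'; break; case 'a': o = 'T'; break;
      case 'C': o = 'G'; break; case 'c': o = 'G'; break;
      case 'G': o = 'C'; break; case 'g': o = 'C'; break;
      case 'T': o = 'A'; break; case 't': o = 'A'; break;
      default:  o = 'N';
    }
    rc[i] = o;
  }
  return rc;
}

// Affine-gap Smith-Waterman with full traceback.
// q, t: residue strings; lookup: 256-long map char -> row index of S (-1 bad).
// Gap of length L costs gap_open + L * gap_extend.
// [[Rcpp::export]]
List cpp_local_align(const std::string& q, const std::string& t,
                     const IntegerMatrix& S, const IntegerVector& lookup,
                     int gap_open, int gap_extend) {
  const int n = (int) q.size(), m = (int) t.size();
  const int NEG = -1000000000;
  std::vector<int> qi(n), ti(m);
  for (int i = 0; i < n; ++i) {
    qi[i] = lookup[(unsigned char) q[i]];
    if (qi[i] < 0) stop("residue not in substitution matrix: %c", q[i]);
  }
  for (int j = 0; j < m; ++j) {
    ti[j] = lookup[(unsigned char) t[j]];
    if (ti[j] < 0) stop("residue not in substitution matrix: %c", t[j]);
  }
  // DP matrices (n+1) x (m+1); H local, E gap in query (left), F gap in target.
  std::vector<int> H((n + 1) * (m + 1), 0), E((n + 1) * (m + 1), NEG),
      F((n + 1) * (m + 1), NEG);
  // pointers: ph 0=start,1=diag,2=E,3=F ; pe/pf 0=open,1=extend
  std::vector<unsigned char> ph((n + 1) * (m + 1), 0),
      pe((n + 1) * (m + 1), 0), pf((n + 1) * (m + 1), 0);
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int idx = i * (m + 1) + j;
      int left = i * (m + 1) + (j - 1);
      int up = (i - 1) * (m + 1) + j;
      int diag = (i - 1) * (m + 1) + (j - 1);
      int e_open = H[left] - gap_open - gap_extend;
      int e_ext = E[left] - gap_extend;
      E[idx] = (e_ext > e_open) ? e_ext : e_open;
      pe[idx] = (e_ext > e_open) ? 1 : 0;
      int f_open = H[up] - gap_open - gap_extend;
      int f_ext = F[up] - gap_extend;
      F[idx] = (f_ext > f_open) ? f_ext : f_open;
      pf[idx] = (f_ext > f_open) ? 1 : 0;
      int d = H[diag] + S(qi[i - 1], ti[j - 1]);
      int h = 0; unsigned char p = 0;
      if (d > h) { h = d; p = 1; }
      if (E[idx] > h) { h = E[idx]; p = 2; }
      if (F[idx] > h) { h = F[idx]; p = 3; }
      H[idx] = h; ph[idx] = p;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  std::string qa, ta;
  int i = bi, j = bj, n_match = 0, n_both = 0;
  int state = 0;  // 0 = in H, 2 = in E, 3 = in F
  if (best > 0) state = 0;
  while (best > 0) {
    int idx = i * (m + 1) + j;
    if (state == 0) {
      unsigned char p = ph[idx];
      if (p == 0) break;
      if (p == 1) {
        qa.push_back(q[i - 1]); ta.push_back(t[j - 1]);
        ++n_both;
        if (q[i - 1] == t[j - 1]) ++n_match;
        --i; --j;
      } else {
        state = p;
      }
    } else if (state == 2) {  // gap in query: consume target
      qa.push_back('-'); ta.push_back(t[j - 1]);
      if (pe[idx] == 0) state = 0;
      --j;
    } else {  // gap in target: consume query
      qa.push_back(q[i - 1]); ta.push_back('-');
      if (pf[idx] == 0) state = 0;
      --i;
    }
  }
  std::reverse(qa.begin(), qa.end());
  std::reverse(ta.begin(), ta.end());
  double ident = n_both > 0 ? 100.0 * n_match / n_both : NA_REAL;
  return List::create(
      _["score"] = best, _["q_start"] = i, _["q_end"] = bi,
      _["t_start"] = j, _["t_end"] = bj, _["q_aln"] = qa, _["t_aln"] = ta,
      _["n_match"] = n_match, _["n_both"] = n_both,
      _["identity_pct"] = ident);
}

// Positions (0-based) in `target` where any exact k-mer of each query occurs.
// Returns one sorted unique integer vector per query.
// [[Rcpp::export]]
List cpp_seed_positions(const std::string& target,
                        const std::vector<std::string>& queries, int k) {
  std::unordered_map<std::string, std::vector<int> > kmap;
  int nq = (int) queries.size();
  for (int qidx = 0; qidx < nq; ++qidx) {
    const std::string& q = queries[qidx];
    int nk = (int) q.size() - k + 1;
    for (int p = 0; p < nk; ++p) {
      std::string km = q.substr(p, k);
      if (km.find('X') != std::string::npos ||
          km.find('*') != std::string::npos)
        continue;
      std::vector<int>& v = kmap[km];
      if (v.empty() || v.back() != qidx) v.push_back(qidx);
    }
  }
  std::vector<std::vector<int> > out(nq);
  int nt = (int) target.size() - k + 1;
  for (int p = 0; p < nt; ++p) {
    auto it = kmap.find(target.substr(p, k));
    if (it == kmap.end()) continue;
    for (int qidx : it->second) out[qidx].push_back(p);
  }
  List res(nq);
  for (int qidx = 0; qidx < nq; ++qidx) res[qidx] = wrap(out[qidx]);
  return res;
}
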