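#include <Rcpp.h>
#include <cstdint>
#include <climits>
#include <unordered_map>
#include <vector>
#include <string>

using namespace Rcpp;

// Affine-gap local alignment (Smith-Waterman, Gotoh three-state recursion)
// with integer scoring. A gap of length k costs gap_open + k * gap_ext.
// Traceback is stored as one byte per cell: bits 0-1 main-state move
// (0 stop, 1 diag, 2 up, 3 left), bit 2 up-state extension, bit 3
// left-state extension.
//
// Tie-break on the optimum cell: smaller subject end, then smaller query
// end; traceback prefers diagonal moves, giving a deterministic alignment.

static const int NEG = INT_MIN / 4;

static inline int subst_score(char a, char b, int match, int mismatch) {
  if (a == 'N' || b == 'N') return mismatch;
  return (a == b) ? match : mismatch;
}

// [[Rcpp::export]]
List sw_align_cpp(std::string query, std::string subject,
                  int match, int mismatch, int gap_open, int gap_ext) {
  const size_t m = query.size(), n = subject.size();
  if (m == 0 || n == 0) stop("empty sequence");
  if ((double)(m + 1) * (double)(n + 1) > 2.6e8)
    stop("sequences too large for exact alignment (limit ~2.5e8 cells)");

  std::vector<int> Hprev(n + 1, 0), Hcur(n + 1, 0);
  std::vector<int> Pprev(n + 1, NEG), Pcur(n + 1, NEG);
  std::vector<int> Qcur(n + 1, NEG);
  std::vector<uint8_t> tb((m + 1) * (n + 1), 0);

  const int go = gap_open + gap_ext;  // cost of opening a 1 bp gap
  int best = 0;
  size_t bi = 0, bj = 0;

  for (size_t i = 1; i <= m; ++i) {
    Hcur[0] = 0; Qcur[0] = NEG;
    uint8_t *tbrow = &tb[i * (n + 1)];
    const char qi = query[i - 1];
    for (size_t j = 1; j <= n; ++j) {
      uint8_t cell = 0;
      int p_open = Hprev[j] - go, p_ext = Pprev[j] - gap_ext;
      int P = p_open;
      if (p_ext > p_open) { P = p_ext; cell |= 4; }
      Pcur[j] = P;
      int q_open = Hcur[j - 1] - go, q_ext = Qcur[j - 1] - gap_ext;
      int Q = q_open;
      if (q_ext > q_open) { Q = q_ext; cell |= 8; }
      Qcur[j] = Q;
      int D = Hprev[j - 1] + subst_score(qi, subject[j - 1], match, mismatch);
      int H = 0; uint8_t mv = 0;
      if (D > H) { H = D; mv = 1; }
      if (P > H) { H = P; mv = 2; }
      if (Q > H) { H = Q; mv = 3; }
      Hcur[j] = H;
      tbrow[j] = cell | mv;
      if (H > best) { best = H; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur);
    std::swap(Pprev, Pcur);
  }

  if (best <= 0)
    return List::create(Named("score") = 0.0);

  std::string qa, sa;
  size_t i = bi, j = bj;
  int state = 0;  // 0 = H, 1 = P(up), 2 = Q(left)
  while (true) {
    uint8_t cell = tb[i * (n + 1) + j];
    if (state == 0) {
      uint8_t mv = cell & 3;
      if (mv == 0) break;
      if (mv == 1) {
        qa.push_back(query[i - 1]); sa.push_back(subject[j - 1]);
        --i; --j;
      } else if (mv == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      qa.push_back(query[i - 1]); sa.push_back('-');
      bool ext = cell & 4;
      --i;
      if (!ext) state = 0;
    } else {
      qa.push_back('-'); sa.push_back(subject[j - 1]);
      bool ext = cell & 8;
      --j;
      if (!ext) state = 0;
    }
  }
  std::reverse(qa.begin(), qa.end());
  std::reverse(sa.begin(), sa.end());

  int matches = 0, nn_cols = 0;
  for (size_t k = 0; k < qa.size(); ++k) {
    char a = qa[k], b = sa[k];
    if (a == '-' || b == '-') { ++nn_cols; continue; }
    if (a == 'N' || b == 'N') continue;
    ++nn_cols;
    if (a == b) ++matches;
  }

  return List::create(
    Named("score") = (double)best,
    Named("q_start") = (double)i,        // 0-based half-open
    Named("q_end") = (double)bi,
    Named("s_start") = (double)j,
    Named("s_end") = (double)bj,
    Named("aligned_len") = (double)qa.size(),
    Named("matches") = (double)matches,
    Named("identity") = nn_cols > 0 ? (double)matches / nn_cols : 0.0,
    Named("q_gapped") = qa,
    Named("s_gapped") = sa);
}

static inline int base2bits(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

// Seed-and-filter scan: exact-match word seeds, then ungapped X-drop
// extension; a seed survives when its ungapped HSP score reaches
// min_ungapped. Seeds landing inside an already-extended HSP on the same
// diagonal are skipped. Returns a matrix with one row per surviving HSP:
// (qpos, spos, score, s_lo, s_hi), 0-based, s interval half-open.
// [[Rcpp::export]]
IntegerMatrix seed_scan_cpp(std::string query, std::string subject,
                            int word, int match, int mismatch,
                            int xdrop, int min_ungapped) {
  const int m = query.size(), n = subject.size();
  std::vector<int> out;
  if (m < word || n < word) return IntegerMatrix(0, 5);
  if (word < 4 || word > 15) stop("word size must be in [4, 15]");

  std::unordered_map<uint32_t, std::vector<int>> index;
  const uint32_t mask = (1u << (2 * word)) - 1u;
  uint32_t key = 0; int run = 0;
  for (int i = 0; i < m; ++i) {
    int b = base2bits(query[i]);
    if (b < 0) { run = 0; key = 0; continue; }
    key = ((key << 2) | b) & mask;
    if (++run >= word) index[key].push_back(i - word + 1);
  }

  std::unordered_map<int, int> diag_end;  // diagonal -> subject end reached
  int n_hsp = 0;
  key = 0; run = 0;
  for (int j = 0; j < n; ++j) {
    int b = base2bits(subject[j]);
    if (b < 0) { run = 0; key = 0; continue; }
    key = ((key << 2) | b) & mask;
    if (run + 1 < word) { ++run; continue; }
    ++run;
    auto it = index.find(key);
    if (it == index.end()) continue;
    int sj = j - word + 1;
    for (int q : it->second) {
      int diag = sj - q;
      auto de = diag_end.find(diag);
      if (de != diag_end.end() && sj < de->second) continue;
      // ungapped extension with X-drop
      int score = word * match;
      int best = score;
      int qi = q + word, si = sj + word;
      int s_hi = si;
      while (qi < m && si < n) {
        score += subst_score(query[qi], subject[si], match, mismatch);
        ++qi; ++si;
        if (score > best) { best = score; s_hi = si; }
        else if (best - score > xdrop) break;
      }
      int right_best = best;
      score = right_best;
      best = right_best;
      qi = q - 1; si = sj - 1;
      int s_lo = sj;
      while (qi >= 0 && si >= 0) {
        score += subst_score(query[qi], subject[si], match, mismatch);
        if (score > best) { best = score; s_lo = si; }
        else if (best - score > xdrop) break;
        --qi; --si;
      }
      diag_end[diag] = s_hi;
      if (best < min_ungapped) continue;
      out.push_back(q); out.push_back(sj); out.push_back(best);
      out.push_back(s_lo); out.push_back(s_hi);
      if (++n_hsp > 500000)
        stop("seed HSP count exceeded 5e5; sequences too repetitive");
    }
  }
  int rows = out.size() / 5;
  IntegerMatrix res(rows, 5);
  for (int r = 0; r < rows; ++r)
    for (int c = 0; c < 5; ++c) res(r, c) = out[5 * r + c];
  colnames(res) = CharacterVector::create("qpos", "spos", "score",
                                          "s_lo", "s_hi");
  return res;
}
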