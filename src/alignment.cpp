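#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Affine-gap local alignment (Smith-Waterman). Gap of length L costs
// gap_open + L * gap_ext (BLAST convention). Sequences are integer-encoded
// indices into the substitution matrix. Returns the optimal score and the
// end cell; the start is recovered by a second pass on reversed prefixes.

struct SWResult {
  int score;
  int q_end; // 0-based exclusive
  int s_end;
};

// substitution matrix flattened to a plain array (row-major, nr rows) so the
// inner loop avoids Rcpp's bounds-checked element access
static SWResult sw_core2(const std::vector<int>& q, const std::vector<int>& s,
                         const int* sub, int nr, int gap_open, int gap_ext) {
  const int m = q.size(), n = s.size();
  const int NEG = -1000000000;
  const int gi = gap_open + gap_ext;
  std::vector<int> Hprev(n + 1, 0), Hcur(n + 1, 0), Eprev(n + 1, NEG),
      Ecur(n + 1, NEG);
  SWResult best = {0, 0, 0};
  for (int i = 1; i <= m; ++i) {
    Hcur[0] = 0;
    int F = NEG;
    const int* row = sub + (long long)q[i - 1] * nr;
    for (int j = 1; j <= n; ++j) {
      Ecur[j] = std::max(Hprev[j] - gi, Eprev[j] - gap_ext);
      F = std::max(Hcur[j - 1] - gi, F - gap_ext);
      int h = Hprev[j - 1] + row[s[j - 1]];
      h = std::max(h, std::max(Ecur[j], F));
      h = std::max(h, 0);
      Hcur[j] = h;
      if (h > best.score) { best.score = h; best.q_end = i; best.s_end = j; }
    }
    std::swap(Hprev, Hcur);
    std::swap(Eprev, Ecur);
  }
  return best;
}

// row-major copy of the (symmetric) substitution matrix
static std::vector<int> flatten_sub(const IntegerMatrix& sub) {
  const int nr = sub.nrow(), nc = sub.ncol();
  std::vector<int> flat((size_t)nr * nc);
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j) flat[(size_t)i * nc + j] = sub(i, j);
  return flat;
}

static std::vector<int> as_vec(const IntegerVector& x) {
  return std::vector<int>(x.begin(), x.end());
}

// full local alignment with aligned ranges (0-based half-open)
// [[Rcpp::export]]
List sw_align_cpp(IntegerVector query, IntegerVector subject,
                  IntegerMatrix sub, int gap_open, int gap_ext) {
  std::vector<int> q = as_vec(query), s = as_vec(subject);
  std::vector<int> flat = flatten_sub(sub);
  const int na = sub.ncol();
  SWResult fwd = sw_core2(q, s, flat.data(), na, gap_open, gap_ext);
  if (fwd.score <= 0)
    return List::create(_["score"] = 0, _["q_start"] = 0, _["q_end"] = 0,
                        _["s_start"] = 0, _["s_end"] = 0);
  std::vector<int> qr(q.begin(), q.begin() + fwd.q_end);
  std::vector<int> sr(s.begin(), s.begin() + fwd.s_end);
  std::reverse(qr.begin(), qr.end());
  std::reverse(sr.begin(), sr.end());
  SWResult rev = sw_core2(qr, sr, flat.data(), na, gap_open, gap_ext);
  return List::create(_["score"] = fwd.score,
                      _["q_start"] = fwd.q_end - rev.q_end,
                      _["q_end"] = fwd.q_end,
                      _["s_start"] = fwd.s_end - rev.s_end,
                      _["s_end"] = fwd.s_end);
}

// Seed-and-extend search of integer-encoded queries against subjects.
// k-mer seeds (letters >= alpha_size never seed), grouped into clusters of
// nearby diagonals; clusters with >= min_seeds seeds are extended by exact
// Smith-Waterman on a subject window around the cluster. Reports the best
// score per (query, subject) pair with aligned ranges.
// [[Rcpp::export]]
DataFrame seeded_search_cpp(List queries, List subjects, int k,
                            int alpha_size, IntegerMatrix sub, int gap_open,
                            int gap_ext, int min_seeds, int diag_band,
                            int window_margin) {
  const int nq = queries.size(), ns = subjects.size();
  std::vector<int> flat = flatten_sub(sub);
  const int na = sub.ncol();
  std::vector<int> out_q, out_s, out_score, out_qs, out_qe, out_ss, out_se;
  std::vector<std::vector<int>> Q(nq);
  for (int i = 0; i < nq; ++i) Q[i] = as_vec(queries[i]);

  long long mod = 1;
  for (int i = 0; i < k - 1; ++i) mod *= alpha_size;

  // index all query k-mers once: key -> (query, query position); each
  // subject is then streamed through the index a single time
  std::unordered_map<long long, std::vector<std::pair<int, int>>> qindex;
  for (int qi = 0; qi < nq; ++qi) {
    const std::vector<int>& q = Q[qi];
    long long qkey = 0;
    int qvalid = 0;
    for (int i = 0; i < (int)q.size(); ++i) {
      if (q[i] >= alpha_size || q[i] < 0) { qvalid = 0; qkey = 0; continue; }
      qkey = (qkey % mod) * alpha_size + q[i];
      if (++qvalid >= k)
        qindex[qkey].push_back(std::make_pair(qi, i - k + 1));
    }
  }

  // per-query hit lists, reused across subjects (only touched entries
  // are cleared)
  std::vector<std::vector<std::pair<int, int>>> qhits(nq);
  std::vector<int> touched;

  for (int sj = 0; sj < ns; ++sj) {
    std::vector<int> S = as_vec(subjects[sj]);
    const int n = S.size();
    if (n < k) continue;
    for (int t : touched) qhits[t].clear();
    touched.clear();
    long long key = 0;
    int valid = 0;
    for (int i = 0; i < n; ++i) {
      if (S[i] >= alpha_size || S[i] < 0) { valid = 0; key = 0; continue; }
      key = (key % mod) * alpha_size + S[i];
      if (++valid >= k) {
        auto it = qindex.find(key);
        if (it != qindex.end()) {
          int spos = i - k + 1;
          for (const std::pair<int, int>& qp : it->second) {
            if (qhits[qp.first].empty()) touched.push_back(qp.first);
            qhits[qp.first].push_back(
                std::make_pair(qp.second - spos, spos));
          }
        }
      }
    }
    std::sort(touched.begin(), touched.end());
    for (int qi : touched) {
      const std::vector<int>& q = Q[qi];
      const int m = q.size();
      std::vector<std::pair<int, int>>& hits = qhits[qi];
      if ((int)hits.size() < min_seeds) continue;
      std::sort(hits.begin(), hits.end());
      // cluster by diagonal proximity
      int best_score = 0, best_qs = 0, best_qe = 0, best_ss = 0, best_se = 0;
      size_t i0 = 0;
      while (i0 < hits.size()) {
        size_t i1 = i0 + 1;
        int s_lo = hits[i0].second, s_hi = hits[i0].second;
        // chain while diagonals stay within the band AND the subject
        // position stays within one query length of the cluster, so two
        // far-apart seeds on the same diagonal never form one huge window
        while (i1 < hits.size() &&
               hits[i1].first - hits[i1 - 1].first <= diag_band &&
               hits[i1].second <= s_hi + m + window_margin &&
               hits[i1].second >= s_lo - m - window_margin) {
          s_lo = std::min(s_lo, hits[i1].second);
          s_hi = std::max(s_hi, hits[i1].second);
          ++i1;
        }
        if ((int)(i1 - i0) >= min_seeds) {
          // an alignment through any cluster seed starts no earlier in the
          // subject than spos - qpos = -diag (minus gap slack) and ends no
          // later than spos + (m - qpos) = m - diag (plus gap slack), so
          // the window needs only the diagonal range plus gap allowance,
          // not a blanket +/- query length
          int d_lo = hits[i0].first, d_hi = hits[i1 - 1].first;
          int slack = window_margin + diag_band;
          int w_lo = std::max(0, std::max(-d_hi - slack, s_lo - m - window_margin));
          int w_hi = std::min(n, std::min(m - d_lo + slack, s_hi + k + m + window_margin));
          std::vector<int> win(S.begin() + w_lo, S.begin() + w_hi);
          SWResult fwd = sw_core2(q, win, flat.data(), na, gap_open, gap_ext);
          if (fwd.score > best_score) {
            std::vector<int> qr(q.begin(), q.begin() + fwd.q_end);
            std::vector<int> wr(win.begin(), win.begin() + fwd.s_end);
            std::reverse(qr.begin(), qr.end());
            std::reverse(wr.begin(), wr.end());
            SWResult rev = sw_core2(qr, wr, flat.data(), na, gap_open, gap_ext);
            best_score = fwd.score;
            best_qs = fwd.q_end - rev.q_end;
            best_qe = fwd.q_end;
            best_ss = w_lo + fwd.s_end - rev.s_end;
            best_se = w_lo + fwd.s_end;
          }
        }
        i0 = i1;
      }
      if (best_score > 0) {
        out_q.push_back(qi + 1);
        out_s.push_back(sj + 1);
        out_score.push_back(best_score);
        out_qs.push_back(best_qs);
        out_qe.push_back(best_qe);
        out_ss.push_back(best_ss);
        out_se.push_back(best_se);
      }
    }
  }
  return DataFrame::create(_["query"] = out_q, _["subject"] = out_s,
                           _["score"] = out_score, _["q_start"] = out_qs,
                           _["q_end"] = out_qe, _["s_start"] = out_ss,
                           _["s_end"] = out_se);
}
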