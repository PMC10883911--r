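#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Seed-weighted local complementarity alignment (Gotoh affine-gap DP) of a
// 3'->5' reversed miRNA against a 5'->3' target window.
//
// States: M = paired/mismatch column (consumes one base of each sequence),
//         X = gap in target (miRNA base unpaired),
//         Y = gap in miRNA (target base unpaired).
// X is reachable from {M, X}, Y from {M, Y}: opposite-sign gap columns are
// never adjacent (two opens always score worse than a mismatch column here,
// and fixing the transition set keeps the recurrence well-defined for the
// brute-force cross-check).
//
// Column weights: every column that consumes a miRNA base whose ORIGINAL
// 1-based position (5'->3') lies in [seed_lo, seed_hi] has its score --
// substitution or gap penalty -- multiplied by seed_scale.

static inline double pair_score(char q, char t, double match, double wobble,
                                double mismatch) {
  // complementarity scoring on RNA alphabet (A,C,G,U)
  if ((q == 'A' && t == 'U') || (q == 'U' && t == 'A') ||
      (q == 'G' && t == 'C') || (q == 'C' && t == 'G'))
    return match;
  if ((q == 'G' && t == 'U') || (q == 'U' && t == 'G')) return wobble;
  return mismatch;
}

struct AlnResult {
  double score;
  std::string trace;
  int q_start, q_end, t_start, t_end;
};

static AlnResult sw_align(const std::string& q_rev, const std::string& target,
                          double match, double wobble, double mismatch,
                          double gap_open, double gap_extend,
                          double seed_scale, int seed_lo, int seed_hi) {
  const int m = (int)q_rev.size();
  const int n = (int)target.size();
  const double NEG = -1e18;

  std::vector<double> w(m + 1, 1.0);
  for (int i = 1; i <= m; ++i) {
    int orig = m - i + 1;  // original miRNA position of q_rev[i-1]
    if (orig >= seed_lo && orig <= seed_hi) w[i] = seed_scale;
  }

  auto idx = [n](int i, int j) { return i * (n + 1) + j; };
  std::vector<double> M((m + 1) * (n + 1), NEG), X((m + 1) * (n + 1), NEG),
      Y((m + 1) * (n + 1), NEG);
  std::vector<signed char> fromM((m + 1) * (n + 1), 0),
      fromX((m + 1) * (n + 1), 0), fromY((m + 1) * (n + 1), 0);

  double best = 0.0;
  int bi = 0, bj = 0;

  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      double sM = M[idx(i - 1, j - 1)], sX = X[idx(i - 1, j - 1)],
             sY = Y[idx(i - 1, j - 1)];
      double pre = 0.0;  // fresh local start
      signed char who = 0;
      if (sM > pre) { pre = sM; who = 1; }
      if (sX > pre) { pre = sX; who = 2; }
      if (sY > pre) { pre = sY; who = 3; }
      double col =
          w[i] * pair_score(q_rev[i - 1], target[j - 1], match, wobble, mismatch);
      M[idx(i, j)] = pre + col;
      fromM[idx(i, j)] = who;

      double xo = M[idx(i - 1, j)] + w[i] * gap_open;
      double xe = X[idx(i - 1, j)] + w[i] * gap_extend;
      if (xo >= xe) { X[idx(i, j)] = xo; fromX[idx(i, j)] = 1; }
      else          { X[idx(i, j)] = xe; fromX[idx(i, j)] = 2; }

      double yo = M[idx(i, j - 1)] + gap_open;
      double ye = Y[idx(i, j - 1)] + gap_extend;
      if (yo >= ye) { Y[idx(i, j)] = yo; fromY[idx(i, j)] = 1; }
      else          { Y[idx(i, j)] = ye; fromY[idx(i, j)] = 3; }

      if (M[idx(i, j)] > best) { best = M[idx(i, j)]; bi = i; bj = j; }
    }
  }

  AlnResult res;
  res.score = best;
  res.q_start = res.q_end = res.t_start = res.t_end = 0;
  if (best > 0.0) {
    int i = bi, j = bj, state = 1;
    res.q_end = bi;
    res.t_end = bj;
    std::string trace;
    while (state != 0 && i >= 0 && j >= 0) {
      if (state == 1) {
        char q = q_rev[i - 1], t = target[j - 1];
        double ps = pair_score(q, t, match, wobble, mismatch);
        char c = (ps == match) ? '|' : (ps == wobble ? ':' : '.');
        trace.push_back(c);
        state = fromM[idx(i, j)];
        --i; --j;
      } else if (state == 2) {
        trace.push_back('-');
        state = fromX[idx(i, j)];
        --i;
      } else {
        trace.push_back('^');
        state = fromY[idx(i, j)];
        --j;
      }
    }
    res.q_start = i;  // consumed q_rev[(q_start+1)..q_end], target likewise
    res.t_start = j;
    std::reverse(trace.begin(), trace.end());
    res.trace = trace;
  }
  return res;
}

// [[Rcpp::export]]
List duplex_align_cpp(std::string q_rev, std::string target, double match,
                      double wobble, double mismatch, double gap_open,
                      double gap_extend, double seed_scale, int seed_lo,
                      int seed_hi) {
  AlnResult r = sw_align(q_rev, target, match, wobble, mismatch, gap_open,
                         gap_extend, seed_scale, seed_lo, seed_hi);
  return List::create(_["score"] = r.score, _["trace"] = r.trace,
                      _["q_start"] = r.q_start, _["q_end"] = r.q_end,
                      _["t_start"] = r.t_start, _["t_end"] = r.t_end);
}

// Slide fixed-size windows (given step) over the target, align into each
// window, and return per-window best alignments with coordinates lifted to
// the full target. Filtering, energy evaluation and interval deduplication
// happen on the R side.
// [[Rcpp::export]]
DataFrame scan_windows_cpp(std::string q_rev, std::string target, int win,
                           int step, double match, double wobble,
                           double mismatch, double gap_open,
                           double gap_extend, double seed_scale, int seed_lo,
                           int seed_hi, double score_min) {
  const int n = (int)target.size();
  std::vector<int> starts;
  int last = std::max(0, n - win);
  for (int s = 0; s <= last; s += step) starts.push_back(s);
  if (starts.empty() || starts.back() != last) starts.push_back(last);

  std::vector<double> scores;
  std::vector<std::string> traces;
  std::vector<int> qs, ts, te;
  for (int s : starts) {
    std::string wseq = target.substr(s, win);
    AlnResult r = sw_align(q_rev, wseq, match, wobble, mismatch, gap_open,
                           gap_extend, seed_scale, seed_lo, seed_hi);
    if (r.score < score_min) continue;
    scores.push_back(r.score);
    traces.push_back(r.trace);
    qs.push_back(r.q_start);
    ts.push_back(r.t_start + s);
    te.push_back(r.t_end + s);
  }
  return DataFrame::create(_["score"] = scores, _["trace"] = traces,
                           _["q_start"] = qs, _["target_start"] = ts,
                           _["target_end"] = te,
                           _["stringsAsFactors"] = false);
}
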