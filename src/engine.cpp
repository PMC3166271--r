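#include <Rcpp.h>
#include <vector>
#include <cstdint>

using namespace Rcpp;

static const int SAT_MAX = 65535;  // 16-bit score ceiling
static const int CODE_SEQ_TERM = 23;
static const int CODE_GROUP_TERM = 24;
static const int CODE_PAD = 25;

// Full-matrix affine-gap local alignment (Gotoh), zero boundary, max over
// all cells. Reference oracle: keeps the complete H/E/D matrices and shares
// no state with the streaming engine below.
// [[Rcpp::export]]
List cpp_sw_full_matrix(IntegerVector a, IntegerVector b,
                        IntegerMatrix scores, int open_cost,
                        int extend_cost) {
  const int m = a.size(), n = b.size();
  bool saturated = false;
  int best = 0;
  std::vector<std::vector<int>> H(m + 1, std::vector<int>(n + 1, 0));
  std::vector<std::vector<int>> E(m + 1, std::vector<int>(n + 1, 0));
  std::vector<std::vector<int>> D(m + 1, std::vector<int>(n + 1, 0));
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      int e = std::max(H[i][j - 1] - open_cost, E[i][j - 1] - extend_cost);
      if (e < 0) e = 0;
      int d = std::max(H[i - 1][j] - open_cost, D[i - 1][j] - extend_cost);
      if (d < 0) d = 0;
      int h = H[i - 1][j - 1] + scores(a[i - 1], b[j - 1]);
      if (h < 0) h = 0;
      if (e > h) h = e;
      if (d > h) h = d;
      if (h > SAT_MAX) { h = SAT_MAX; saturated = true; }
      E[i][j] = e;
      D[i][j] = d;
      H[i][j] = h;
      if (h > best) best = h;
    }
  }
  return List::create(_["score"] = best, _["saturated"] = saturated);
}

// Streaming engine over one interlaced sequence set. Lanes advance in
// lock-step over subset windows (the stream's storage order). Per lane the
// only DP state is the previous position's H and D columns, the running E
// and upper-left H of the current sweep, and the best score since the last
// sequence start. Terminator codes emit the finished score and reset the
// lane; PAD is a no-op. Emitted scores are returned lane-major, in stream
// order within each lane; `counts` gives the expected emissions per lane.
// [[Rcpp::export]]
List cpp_scan_set(IntegerVector stream, int lanes, int subset,
                  IntegerMatrix profile, int open_cost, int extend_cost,
                  IntegerVector counts) {
  const int M = profile.nrow();
  const R_xlen_t n = stream.size();
  if (counts.size() != lanes)
    stop("counts must have one entry per lane");

  std::vector<std::vector<uint16_t>> Hcol(lanes,
                                          std::vector<uint16_t>(M, 0));
  std::vector<std::vector<uint16_t>> Dcol(lanes,
                                          std::vector<uint16_t>(M, 0));
  std::vector<int> bestv(lanes, 0);
  std::vector<char> satv(lanes, 0);
  std::vector<std::vector<int>> emitted(lanes);
  std::vector<std::vector<char>> emitted_sat(lanes);

  const int window = lanes * subset;
  for (R_xlen_t p = 0; p < n; ++p) {
    const int lane = (int)((p % window) / subset);
    const int code = stream[p];
    if (code == CODE_PAD) continue;
    if (code == CODE_SEQ_TERM || code == CODE_GROUP_TERM) {
      if ((int)emitted[lane].size() >= counts[lane])
        stop("packing inconsistency: lane %d of this set emits more sequences than its index entries",
             lane + 1);
      emitted[lane].push_back(bestv[lane]);
      emitted_sat[lane].push_back(satv[lane]);
      std::fill(Hcol[lane].begin(), Hcol[lane].end(), 0);
      std::fill(Dcol[lane].begin(), Dcol[lane].end(), 0);
      bestv[lane] = 0;
      satv[lane] = 0;
      continue;
    }
    if (code < 0 || code > 22)
      stop("invalid stream code %d at position %ld", code, (long)(p + 1));

    uint16_t* Hc = Hcol[lane].data();
    uint16_t* Dc = Dcol[lane].data();
    int e = 0, h_diag = 0, h_left = 0;
    int best = bestv[lane];
    bool sat = satv[lane] != 0;
    for (int j = 0; j < M; ++j) {
      int d = std::max((int)Hc[j] - open_cost, (int)Dc[j] - extend_cost);
      if (d < 0) d = 0;
      e = std::max(h_left - open_cost, e - extend_cost);
      if (e < 0) e = 0;
      int h = h_diag + profile(j, code);
      if (h < 0) h = 0;
      if (e > h) h = e;
      if (d > h) h = d;
      if (h > SAT_MAX) { h = SAT_MAX; sat = true; }
      h_diag = Hc[j];
      Hc[j] = (uint16_t)h;
      Dc[j] = (uint16_t)d;
      h_left = h;
      if (h > best) best = h;
    }
    bestv[lane] = best;
    satv[lane] = sat ? 1 : 0;
  }

  R_xlen_t total = 0;
  for (int g = 0; g < lanes; ++g) {
    if ((int)emitted[g].size() != counts[g])
      stop("packing inconsistency: lane %d emitted %d sequences, index expects %d",
           g + 1, (int)emitted[g].size(), counts[g]);
    total += emitted[g].size();
  }
  IntegerVector out_scores(total);
  LogicalVector out_sat(total);
  R_xlen_t k = 0;
  for (int g = 0; g < lanes; ++g)
    for (size_t i = 0; i < emitted[g].size(); ++i, ++k) {
      out_scores[k] = emitted[g][i];
      out_sat[k] = emitted_sat[g][i] != 0;
    }
  return List::create(_["scores"] = out_scores, _["saturated"] = out_sat);
}
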