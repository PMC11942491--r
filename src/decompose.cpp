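#include <Rcpp.h>
using namespace Rcpp;

// Exact segmentation of a repeat-region sequence into motif runs and
// interruption stretches, minimizing
//   interruption_penalty * (# interruption bases) +
//   switch_penalty * (# changes of motif between consecutive motif units).
// A motif unit is consumed only on an exact match. DP state: (position,
// last emitted motif). Interruption bases do not reset the last motif, so a
// run of the same motif resumed after an interruption costs no switch.
// Deterministic tie-break when reconstructing an optimal segmentation:
// (1) continue the current motif, (2) lexicographically smallest motif,
// (3) an interruption base.

// [[Rcpp::export(name = ".decompose_cpp")]]
List decompose_cpp(std::string seq, CharacterVector motifs,
                   double interruption_penalty, double switch_penalty) {
  const int n = (int) seq.size();
  const int M = motifs.size();
  std::vector<std::string> mot(M);
  for (int j = 0; j < M; ++j) mot[j] = as<std::string>(motifs[j]);
  // motifs are assumed sorted lexicographically by the R wrapper

  std::vector<int> len(M);
  for (int j = 0; j < M; ++j) len[j] = (int) mot[j].size();

  // match[j*(n+1)+pos] : motif j matches exactly at pos
  std::vector<char> match((size_t)M * (n + 1), 0);
  for (int j = 0; j < M; ++j)
    for (int pos = 0; pos + len[j] <= n; ++pos)
      if (seq.compare(pos, len[j], mot[j]) == 0)
        match[(size_t)j * (n + 1) + pos] = 1;

  const double INF = std::numeric_limits<double>::infinity();
  const int S = M + 1;               // last-motif states; M = none yet
  std::vector<double> dp((size_t)(n + 1) * S, INF);
  for (int m = 0; m < S; ++m) dp[(size_t)n * S + m] = 0.0;

  for (int pos = n - 1; pos >= 0; --pos) {
    for (int m = 0; m < S; ++m) {
      double best = interruption_penalty + dp[(size_t)(pos + 1) * S + m];
      for (int j = 0; j < M; ++j) {
        if (!match[(size_t)j * (n + 1) + pos]) continue;
        double sw = (m < M && m != j) ? switch_penalty : 0.0;
        double c = sw + dp[(size_t)(pos + len[j]) * S + j];
        if (c < best) best = c;
      }
      dp[(size_t)pos * S + m] = best;
    }
  }

  // reconstruct
  std::vector<std::string> seg_type;
  std::vector<std::string> seg_motif;
  std::vector<int> seg_start, seg_end, seg_units;
  std::vector<std::string> seg_seq;

  int pos = 0, m = M;
  const double eps = 1e-9;
  while (pos < n) {
    double best = dp[(size_t)pos * S + m];
    int chosen = -1;  // -1 interruption, else motif index
    // (1) continue current motif
    if (m < M && match[(size_t)m * (n + 1) + pos] &&
        dp[(size_t)(pos + len[m]) * S + m] <= best + eps) {
      chosen = m;
    } else {
      // (2) lexicographically smallest optimal motif
      for (int j = 0; j < M && chosen < 0; ++j) {
        if (!match[(size_t)j * (n + 1) + pos]) continue;
        double sw = (m < M && m != j) ? switch_penalty : 0.0;
        if (sw + dp[(size_t)(pos + len[j]) * S + j] <= best + eps) chosen = j;
      }
      // (3) interruption base (always feasible if nothing else was optimal)
    }
    if (chosen >= 0) {
      int j = chosen;
      if (!seg_type.empty() && seg_type.back() == "motif" &&
          seg_motif.back() == mot[j] && seg_end.back() == pos) {
        seg_units.back() += 1;
        seg_end.back() = pos + len[j];
      } else {
        seg_type.push_back("motif");
        seg_motif.push_back(mot[j]);
        seg_start.push_back(pos);
        seg_end.push_back(pos + len[j]);
        seg_units.push_back(1);
        seg_seq.push_back("");
      }
      pos += len[j];
      m = j;
    } else {
      if (!seg_type.empty() && seg_type.back() == "interruption" &&
          seg_end.back() == pos) {
        seg_end.back() = pos + 1;
        seg_seq.back() += seq[pos];
      } else {
        seg_type.push_back("interruption");
        seg_motif.push_back("");
        seg_start.push_back(pos);
        seg_end.push_back(pos + 1);
        seg_units.push_back(NA_INTEGER);
        seg_seq.push_back(std::string(1, seq[pos]));
      }
      pos += 1;
    }
  }

  int K = (int) seg_type.size();
  CharacterVector type(K), motif(K), sseq(K);
  IntegerVector start(K), end(K), units(K);
  for (int k = 0; k < K; ++k) {
    type[k] = seg_type[k];
    motif[k] = seg_type[k] == "motif" ? String(seg_motif[k]) : String(NA_STRING);
    sseq[k] = seg_type[k] == "interruption" ? String(seg_seq[k]) : String(NA_STRING);
    start[k] = seg_start[k];
    end[k] = seg_end[k];
    units[k] = seg_units[k];
  }
  DataFrame segs = DataFrame::create(
      _["type"] = type, _["motif"] = motif, _["start"] = start,
      _["end"] = end, _["unit_count"] = units, _["sequence"] = sseq,
      _["stringsAsFactors"] = false);
  return List::create(_["segments"] = segs,
                      _["cost"] = dp[(size_t)0 * S + M],
                      _["region_length"] = n);
}
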