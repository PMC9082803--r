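#include <Rcpp.h>
using namespace Rcpp;

// Weighted pair enumeration for concordance estimation.
//
// Each pair is anchored by the subject with the earlier cause-1 event
// (status == 1). A pair is examinable when the anchor's partner is known to
// be event-free at the anchor's time: a later follow-up time, an
// "infinite" follow-up (competing event retained in the risk set forever),
// or a censoring tied with the anchor's event time (events are processed
// before censorings). Tied event times between two cause-1 events are not
// examinable. In IPCW mode the partner rule is instead (T_j > T_i) or
// (j had a competing event), and each pair carries the anchor's weight.
//
// [[Rcpp::export]]
List concordance_pairs(NumericVector time, IntegerVector status,
                       LogicalVector inf_flag, NumericVector risk,
                       double tau, NumericVector anchor_weight,
                       bool ipcw, IntegerVector competing) {
  const int n = time.size();
  double conc = 0.0, disc = 0.0, tied = 0.0;
  double npairs = 0.0;
  for (int i = 0; i < n; ++i) {
    if (status[i] != 1 || inf_flag[i]) continue;
    if (time[i] > tau) continue;
    const double ti = time[i];
    const double ri = risk[i];
    const double w = anchor_weight[i];
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      bool ok;
      if (ipcw) {
        ok = (time[j] > ti) || (competing[j] == 1 && time[j] < ti) ||
             (competing[j] == 1 && time[j] == ti);
      } else {
        ok = inf_flag[j] || (time[j] > ti) ||
             (time[j] == ti && status[j] == 0 && !inf_flag[j]);
      }
      if (!ok) continue;
      npairs += 1.0;
      if (ri > risk[j]) conc += w;
      else if (ri < risk[j]) disc += w;
      else tied += w;
    }
  }
  return List::create(_["concordant"] = conc, _["discordant"] = disc,
                      _["tied"] = tied, _["n_pairs"] = npairs);
}
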