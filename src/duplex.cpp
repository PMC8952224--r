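#include <Rcpp.h>
using namespace Rcpp;

// Antiparallel duplex scan between two RNA strands.
//
// Bases are encoded 1=A, 2=C, 3=G, 4=U (0 = unknown, never pairs).
// pair_type[b1-1][b2-1] gives 0 (no pair) or the 1-based index of the
// (top, bottom) pair among CG, GC, GU, UG, AU, UA. stack(p1, p2) is the
// free-energy increment (kcal/mol) of stacking pair p2 on pair p1.
//
// The scan slides strand a (5'->3') along the reverse of strand b and,
// for every offset, walks the maximal contiguous complementary runs.
// Each run of paired length >= min_pair is scored as
//   dG = init + sum of stack terms over adjacent pairs in the run
// and the run minimizing ndG = dG / length is reported.
// [[Rcpp::export]]
List cpp_duplex_scan(IntegerVector a, IntegerVector b_rev,
                     IntegerMatrix pair_type, NumericMatrix stack,
                     double init, int min_pair) {
  int la = a.size(), lb = b_rev.size();
  double best_ndg = 0.0, best_dg = 0.0;
  int best_len = 0, best_ai = 0, best_bi = 0;
  // offset k: a[i] aligns with b_rev[i + k], k in [-(la-1), lb-1]
  for (int k = -(la - 1); k <= lb - 1; ++k) {
    int i0 = std::max(0, -k);
    int i1 = std::min(la - 1, lb - 1 - k);
    int run_start = -1;
    double run_dg = 0.0;
    int prev_pair = 0;
    for (int i = i0; i <= i1 + 1; ++i) {
      int pt = 0;
      if (i <= i1) {
        int ba = a[i], bb = b_rev[i + k];
        if (ba > 0 && bb > 0) pt = pair_type(ba - 1, bb - 1);
      }
      if (pt > 0) {
        if (run_start < 0) {
          run_start = i;
          run_dg = init;
        } else {
          run_dg += stack(prev_pair - 1, pt - 1);
        }
        prev_pair = pt;
      } else if (run_start >= 0) {
        int len = i - run_start;
        if (len >= min_pair) {
          double ndg = run_dg / len;
          if (best_len == 0 || ndg < best_ndg ||
              (ndg == best_ndg && run_dg < best_dg)) {
            best_ndg = ndg;
            best_dg = run_dg;
            best_len = len;
            best_ai = run_start;          // 0-based start in a
            best_bi = run_start + k;      // 0-based start in b_rev
          }
        }
        run_start = -1;
      }
    }
  }
  return List::create(_["dg"] = best_dg, _["ndg"] = best_ndg,
                      _["paired_length"] = best_len,
                      _["a_start0"] = best_ai, _["b_rev_start0"] = best_bi);
}
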