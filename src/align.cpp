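#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstring>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with affine gap penalties (Gotoh):
// a gap of length L costs gap_open + gap_ext * L. Tie-breaking is
// deterministic: substitution preferred over gaps, gap-in-query preferred
// over gap-in-reference.
//
// States: M = query base vs reference base; X = gap in query (reference
// base consumed); Y = gap in reference (query base consumed). Score rows are
// rolled; the traceback keeps one packed byte per cell
// (bits 0-1: M's predecessor, 2-3: X's, 4-5: Y's).

// [[Rcpp::export]]
List align_affine_cpp(CharacterVector queries, std::string ref,
                      double match, double mismatch,
                      double gap_open, double gap_ext) {
  const int m = (int)ref.size();
  const double NEG = -1e30;
  const double open_step = gap_open + gap_ext;
  const char *rf = ref.data();

  int nq = queries.size();
  CharacterVector out_q(nq), out_r(nq);
  NumericVector out_score(nq);

  std::vector<double> Mp(m + 1), Xp(m + 1), Yp(m + 1);
  std::vector<double> Mc(m + 1), Xc(m + 1), Yc(m + 1);
  std::vector<unsigned char> tb;
  std::string aq, ar;

  for (int qi = 0; qi < nq; ++qi) {
    const char *q = CHAR(STRING_ELT(queries, qi));
    const int n = (int)std::strlen(q);
    tb.assign((size_t)(n + 1) * (m + 1), 0);

    // row 0
    Mp[0] = 0.0;
    Xp[0] = Yp[0] = NEG;
    for (int j = 1; j <= m; ++j) {
      Mp[j] = NEG;
      Yp[j] = NEG;
      Xp[j] = -(gap_open + gap_ext * j);
      tb[j] = (unsigned char)((j == 1 ? 0 : 1) << 2);
    }

    for (int i = 1; i <= n; ++i) {
      unsigned char *tbrow = &tb[(size_t)i * (m + 1)];
      Mc[0] = NEG;
      Xc[0] = NEG;
      Yc[0] = -(gap_open + gap_ext * i);
      tbrow[0] = (unsigned char)((i == 1 ? 0 : 2) << 4);
      const char qc = q[i - 1];
      for (int j = 1; j <= m; ++j) {
        // M: preference M > X > Y on ties
        double best = Mp[j - 1];
        unsigned char t = 0;
        if (Xp[j - 1] > best) { best = Xp[j - 1]; t = 1; }
        if (Yp[j - 1] > best) { best = Yp[j - 1]; t = 2; }
        double s = (qc == 'N' || rf[j - 1] == 'N')
                       ? mismatch
                       : (qc == rf[j - 1] ? match : mismatch);
        Mc[j] = best + s;
        unsigned char packed = t;
        // X: gap in query, consumes ref[j-1]
        best = Mc[j - 1] - open_step; t = 0;
        if (Xc[j - 1] - gap_ext > best) { best = Xc[j - 1] - gap_ext; t = 1; }
        if (Yc[j - 1] - open_step > best) { best = Yc[j - 1] - open_step; t = 2; }
        Xc[j] = best;
        packed |= (unsigned char)(t << 2);
        // Y: gap in reference, consumes q[i-1]
        best = Mp[j] - open_step; t = 0;
        if (Xp[j] - open_step > best) { best = Xp[j] - open_step; t = 1; }
        if (Yp[j] - gap_ext > best) { best = Yp[j] - gap_ext; t = 2; }
        Yc[j] = best;
        packed |= (unsigned char)(t << 4);
        tbrow[j] = packed;
      }
      Mp.swap(Mc); Xp.swap(Xc); Yp.swap(Yc);
    }

    int state = 0;
    double sc = Mp[m];
    if (Xp[m] > sc) { sc = Xp[m]; state = 1; }
    if (Yp[m] > sc) { sc = Yp[m]; state = 2; }

    aq.clear(); ar.clear();
    aq.reserve(n + m); ar.reserve(n + m);
    int i = n, j = m;
    while (i > 0 || j > 0) {
      unsigned char packed = tb[(size_t)i * (m + 1) + j];
      if (state == 0) {
        aq.push_back(q[i - 1]); ar.push_back(rf[j - 1]);
        --i; --j; state = packed & 3;
      } else if (state == 1) {
        aq.push_back('-'); ar.push_back(rf[j - 1]);
        --j; state = (packed >> 2) & 3;
      } else {
        aq.push_back(q[i - 1]); ar.push_back('-');
        --i; state = (packed >> 4) & 3;
      }
    }
    std::reverse(aq.begin(), aq.end());
    std::reverse(ar.begin(), ar.end());
    out_q[qi] = aq; out_r[qi] = ar; out_score[qi] = sc;
  }
  return List::create(_["ref"] = out_r, _["query"] = out_q,
                      _["score"] = out_score);
}
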