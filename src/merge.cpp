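#include <Rcpp.h>
using namespace Rcpp;

// Overlap scan for paired-read merging. r2rc must already be
// reverse-complemented (and q2r reversed). For each pair the largest overlap
// o in [min_overlap, min(len1, len2)] whose mismatch density is at most
// max_density wins; in the overlap each base is taken from the mate with the
// higher quality (ties go to read 1).
// [[Rcpp::export]]
List merge_scan_cpp(CharacterVector r1, CharacterVector r2rc,
                    CharacterVector q1, CharacterVector q2r,
                    int min_overlap, double max_density) {
  int n = r1.size();
  CharacterVector seq(n);
  IntegerVector overlap(n);
  IntegerVector mism(n);
  LogicalVector merged(n);

  for (int i = 0; i < n; ++i) {
    std::string s1 = as<std::string>(r1[i]);
    std::string s2 = as<std::string>(r2rc[i]);
    int len1 = s1.size(), len2 = s2.size();
    int omax = std::min(len1, len2);
    merged[i] = false;
    overlap[i] = 0;
    mism[i] = NA_INTEGER;
    seq[i] = NA_STRING;
    if (len1 == 0 || len2 == 0 || omax < min_overlap) continue;

    for (int o = omax; o >= min_overlap; --o) {
      int allowed = (int)std::floor(max_density * o);
      int mm = 0;
      const char *a = s1.data() + (len1 - o);
      const char *b = s2.data();
      bool ok = true;
      for (int j = 0; j < o; ++j) {
        if (a[j] != b[j]) {
          if (++mm > allowed) { ok = false; break; }
        }
      }
      if (!ok) continue;

      std::string qa = as<std::string>(q1[i]);
      std::string qb = as<std::string>(q2r[i]);
      std::string out;
      out.reserve(len1 + len2 - o);
      out.append(s1, 0, len1 - o);
      for (int j = 0; j < o; ++j) {
        char c1 = s1[len1 - o + j], c2 = s2[j];
        if (c1 == c2) {
          out.push_back(c1);
        } else {
          char e1 = (len1 - o + j) < (int)qa.size() ? qa[len1 - o + j] : '!';
          char e2 = j < (int)qb.size() ? qb[j] : '!';
          out.push_back(e1 >= e2 ? c1 : c2);
        }
      }
      out.append(s2, o, len2 - o);
      seq[i] = out;
      overlap[i] = o;
      mism[i] = mm;
      merged[i] = true;
      break;
    }
  }
  return List::create(_["merged"] = merged, _["seq"] = seq,
                      _["overlap_len"] = overlap,
                      _["n_overlap_mismatches"] = mism);
}
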