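#include <Rcpp.h>
using namespace Rcpp;

// Earliest position (0-based) in `read` where `adapter` starts, allowing
// a per-overlap mismatch rate, including partial adapter at the read's 3'
// end as long as the overlap is at least `min_overlap`. Returns -1 when
// no acceptable occurrence exists. Substitution errors only: indel
// tolerance is not needed for base-called amplicon reads at the error
// rates this trimmer targets.
// [[Rcpp::export(name = ".find_adapter_cpp")]]
int find_adapter_cpp(std::string read, std::string adapter,
                     double max_error_rate = 0.1, int min_overlap = 5) {
  const int n = (int)read.size(), a = (int)adapter.size();
  for (int p = 0; p <= n - min_overlap; ++p) {
    const int ov = std::min(a, n - p);
    if (ov < min_overlap) break;
    const int allowed = (int)(max_error_rate * ov);
    int mm = 0;
    for (int k = 0; k < ov && mm <= allowed; ++k) {
      if (read[p + k] != adapter[k]) ++mm;
    }
    if (mm <= allowed) return p;
  }
  return -1;
}

// Mismatches between `read`'s prefix and `probe`, over the first
// min(len(read), len(probe)) bases; used for 5' scaffold matching.
// [[Rcpp::export(name = ".prefix_mismatches_cpp")]]
IntegerVector prefix_mismatches_cpp(CharacterVector reads, std::string probe) {
  const int a = (int)probe.size();
  IntegerVector out(reads.size());
  for (int r = 0; r < reads.size(); ++r) {
    std::string rd = as<std::string>(reads[r]);
    const int ov = std::min((int)rd.size(), a);
    int mm = a - ov;  // short reads count missing bases as mismatches
    for (int k = 0; k < ov; ++k)
      if (rd[k] != probe[k]) ++mm;
    out[r] = mm;
  }
  return out;
}
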