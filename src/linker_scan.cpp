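#include <Rcpp.h>
using namespace Rcpp;

// Typed single-edit substring scan for a fixed linker inside Read 1.
//
// At every candidate start every interpretation within the edit budget is
// emitted (they differ in span): exact or substitution hits span
// len(linker) read bases, a "deletion" hit spans len(linker)-1 (one linker
// base missing from the read), an "insertion" hit len(linker)+1 (one extra
// read base).  'N' never matches any base.  Hits are returned ordered by
// (edit distance, start, exact/substitution > deletion > insertion).

// edit type codes: 0 exact, 1 substitution, 2 deletion, 3 insertion

struct Hit {
  int start;  // 0-based
  int span;
  int dist;
  int type;
};

static inline bool base_eq(char a, char b) {
  // linkers are A/C/G/T; any 'N' (or other ambiguity code) in the read is a
  // mismatch by definition
  return a == b && a != 'N';
}

static void scan_one(const std::string& seq, const std::string& linker,
                     int max_edits, std::vector<Hit>& out) {
  const int n = (int)seq.size();
  const int L = (int)linker.size();
  for (int s = 0; s < n; ++s) {
    if (s + L <= n) {  // exact / substitution, span L
      int mm = 0;
      for (int i = 0; i < L && mm <= max_edits; ++i)
        if (!base_eq(seq[s + i], linker[i])) ++mm;
      if (mm <= max_edits) {
        Hit h; h.start = s; h.span = L; h.dist = mm; h.type = mm == 0 ? 0 : 1;
        out.push_back(h);
      }
    }
    if (max_edits >= 1) {
      // deletion: window of span L-1 equals the linker minus one base
      // (greedy first-mismatch skip is exact for single-deletion tests)
      if (s + L - 1 <= n) {
        int i = 0;
        while (i < L - 1 && base_eq(seq[s + i], linker[i])) ++i;
        bool ok = true;
        for (int j = i; j < L - 1; ++j)
          if (!base_eq(seq[s + j], linker[j + 1])) { ok = false; break; }
        if (ok) {
          Hit h; h.start = s; h.span = L - 1; h.dist = 1; h.type = 2;
          out.push_back(h);
        }
      }
      // insertion: window of span L+1 equals the linker plus one read base
      if (s + L + 1 <= n) {
        int i = 0;
        while (i < L && base_eq(seq[s + i], linker[i])) ++i;
        bool ok = true;
        for (int j = i; j < L; ++j)
          if (!base_eq(seq[s + j + 1], linker[j])) { ok = false; break; }
        if (ok) {
          Hit h; h.start = s; h.span = L + 1; h.dist = 1; h.type = 3;
          out.push_back(h);
        }
      }
    }
  }
  // per-start emission order already follows the type priority; the stable
  // sort keeps it as the tie-break after (distance, start)
  std::stable_sort(out.begin(), out.end(), [](const Hit& a, const Hit& b) {
    if (a.dist != b.dist) return a.dist < b.dist;
    return a.start < b.start;
  });
}

// [[Rcpp::export(name = ".scan_linker_batch")]]
List scan_linker_batch(CharacterVector seqs, std::string linker, int max_edits) {
  std::vector<int> idx, start, span, dist, type;
  std::vector<Hit> hits;
  for (int k = 0; k < seqs.size(); ++k) {
    hits.clear();
    scan_one(as<std::string>(seqs[k]), linker, max_edits, hits);
    for (const Hit& h : hits) {
      idx.push_back(k + 1);
      start.push_back(h.start + 1);  // 1-based for R
      span.push_back(h.span);
      dist.push_back(h.dist);
      type.push_back(h.type);
    }
  }
  return List::create(_["seq"] = wrap(idx), _["start"] = wrap(start),
                      _["width"] = wrap(span), _["edit_distance"] = wrap(dist),
                      _["type_code"] = wrap(type));
}
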