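#include <Rcpp.h>
using namespace Rcpp;

// Glocal (semi-global) alignment: the query is aligned end-to-end, end gaps
// on the reference are free. Unit-cost edits (substitution = insertion =
// deletion = 1). Among minimum-edit alignments those with fewer internal
// gaps are preferred (a terminal mismatch is scored as a substitution, never
// dodged by gapping the reference), and among those the number of matched
// positions is maximized. 'N' never matches anything.
//
// Returns c(edits, matches).

struct GCell { int e, g, m; };

static inline bool better(const GCell &a, const GCell &b) {
    if (a.e != b.e) return a.e < b.e;
    if (a.g != b.g) return a.g < b.g;
    return a.m > b.m;
}

// [[Rcpp::export(name = ".glocal_align_cpp")]]
IntegerVector glocal_align_cpp(std::string query, std::string ref) {
    const int m = query.size(), n = ref.size();
    if (m == 0 || n == 0) stop("empty sequence");
    std::vector<GCell> prev(n + 1), cur(n + 1);
    for (int j = 0; j <= n; ++j) prev[j] = {0, 0, 0}; // free leading ref
    for (int i = 1; i <= m; ++i) {
        cur[0] = {i, i, 0}; // query consumed against nothing
        const char qc = query[i - 1];
        for (int j = 1; j <= n; ++j) {
            const char rc = ref[j - 1];
            const bool is_match = (qc == rc) && qc != 'N' && rc != 'N';
            GCell best = {prev[j - 1].e + (is_match ? 0 : 1), prev[j - 1].g,
                          prev[j - 1].m + (is_match ? 1 : 0)};
            GCell up = {prev[j].e + 1, prev[j].g + 1, prev[j].m};
            if (better(up, best)) best = up;
            GCell left = {cur[j - 1].e + 1, cur[j - 1].g + 1, cur[j - 1].m};
            if (better(left, best)) best = left;
            cur[j] = best;
        }
        std::swap(prev, cur);
    }
    GCell best = prev[0]; // free trailing ref
    for (int j = 1; j <= n; ++j) if (better(prev[j], best)) best = prev[j];
    return IntegerVector::create(best.e, best.m);
}

// Match count of the best glocal alignment of one query against each of
// several references.
// [[Rcpp::export(name = ".glocal_matches_cpp")]]
IntegerVector glocal_matches_cpp(std::string query, CharacterVector refs) {
    const int nr = refs.size();
    IntegerVector out(nr);
    for (int r = 0; r < nr; ++r) {
        IntegerVector em = glocal_align_cpp(query, as<std::string>(refs[r]));
        out[r] = em[1];
    }
    return out;
}

// Overlap-merge core. a = forward insert, b = reverse-complemented mate
// (already in forward orientation), qa/qb = Phred+33 quality strings.
// Offsets o >= 0 place b starting at position o of a; the offset maximizing
// (matches - mismatches) over the overlap is chosen among offsets with
// overlap >= min_overlap and overlap identity >= min_identity (ties: smallest
// offset). Disagreements resolve to the base with the higher Phred score;
// quality ties keep the base from a. Returns false when no admissible
// overlap exists.
static bool merge_one(const std::string &a, const std::string &qa,
                      const std::string &b, const std::string &qb,
                      int min_overlap, double min_identity, std::string &cons) {
    const int la = a.size(), lb = b.size();
    if ((int)qa.size() != la || (int)qb.size() != lb)
        stop("sequence/quality length mismatch");
    if (la < min_overlap || lb < min_overlap) return false;
    int best_o = -1, best_score = 0;
    for (int o = 0; o + min_overlap <= la; ++o) {
        const int ov = std::min(la - o, lb);
        if (ov < min_overlap) continue;
        int matches = 0;
        for (int k = 0; k < ov; ++k) if (a[o + k] == b[k]) ++matches;
        if ((double)matches / ov < min_identity) continue;
        const int score = 2 * matches - ov;
        if (best_o < 0 || score > best_score) { best_o = o; best_score = score; }
    }
    if (best_o < 0) return false;
    const int o = best_o;
    const int total = std::max(la, o + lb);
    cons.assign(total, 'N');
    for (int i = 0; i < o; ++i) cons[i] = a[i];
    const int ov = std::min(la - o, lb);
    for (int k = 0; k < ov; ++k) {
        if (a[o + k] == b[k]) cons[o + k] = a[o + k];
        else cons[o + k] = (qb[k] > qa[o + k]) ? b[k] : a[o + k];
    }
    if (o + lb > la) for (int k = ov; k < lb; ++k) cons[o + k] = b[k];
    else for (int i = o + lb; i < la; ++i) cons[i] = a[i];
    return true;
}

// [[Rcpp::export(name = ".merge_overlap_cpp")]]
CharacterVector merge_overlap_cpp(std::string a, std::string qa, std::string b,
                                  std::string qb, int min_overlap,
                                  double min_identity) {
    std::string cons;
    if (!merge_one(a, qa, b, qb, min_overlap, min_identity, cons))
        return CharacterVector::create(NA_STRING);
    return CharacterVector::create(cons);
}

// Vectorized wrapper used by the pipeline driver.
// [[Rcpp::export(name = ".merge_overlap_many_cpp")]]
CharacterVector merge_overlap_many_cpp(CharacterVector a, CharacterVector qa,
                                       CharacterVector b, CharacterVector qb,
                                       int min_overlap, double min_identity) {
    const int n = a.size();
    CharacterVector out(n);
    std::string cons;
    for (int i = 0; i < n; ++i) {
        if (merge_one(as<std::string>(a[i]), as<std::string>(qa[i]),
                      as<std::string>(b[i]), as<std::string>(qb[i]),
                      min_overlap, min_identity, cons))
            out[i] = cons;
        else
            out[i] = NA_STRING;
    }
    return out;
}
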