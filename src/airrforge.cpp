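#include <Rcpp.h>
#include <cctype>
using namespace Rcpp;

static inline char comp_base(char c) {
    switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a';
    default:  return 'N';
    }
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
    R_xlen_t n = seqs.size();
    CharacterVector out(n);
    for (R_xlen_t i = 0; i < n; ++i) {
        std::string s = as<std::string>(seqs[i]);
        std::string r(s.size(), 'N');
        for (size_t j = 0; j < s.size(); ++j)
            r[s.size() - 1 - j] = comp_base(s[j]);
        out[i] = r;
    }
    return out;
}

// Mean Phred score of each Phred+33 quality string.
// [[Rcpp::export]]
NumericVector cpp_mean_phred(CharacterVector quals) {
    R_xlen_t n = quals.size();
    NumericVector out(n);
    for (R_xlen_t i = 0; i < n; ++i) {
        std::string q = as<std::string>(quals[i]);
        if (q.empty()) { out[i] = NA_REAL; continue; }
        double s = 0;
        for (size_t j = 0; j < q.size(); ++j) {
            int ph = (int)q[j] - 33;
            if (ph < 0 || ph > 93) stop("malformed Phred+33 quality string");
            s += ph;
        }
        out[i] = s / q.size();
    }
    return out;
}

// Apply independent per-position substitution errors. rates[p] is the
// substitution probability at 0-based position p; substituted bases are drawn
// uniformly from the three alternatives. Uses the R RNG.
// [[Rcpp::export]]
CharacterVector cpp_apply_errors(CharacterVector seqs, NumericVector rates) {
    static const char BASES[4] = {'A', 'C', 'G', 'T'};
    R_xlen_t n = seqs.size();
    int maxp = rates.size();
    CharacterVector out(n);
    for (R_xlen_t i = 0; i < n; ++i) {
        std::string s = as<std::string>(seqs[i]);
        int L = (int)s.size();
        if (L > maxp) stop("rates vector shorter than sequence");
        for (int p = 0; p < L; ++p) {
            double r = rates[p];
            if (r > 0 && unif_rand() < r) {
                char cur = s[p];
                char sub;
                do {
                    sub = BASES[(int)(unif_rand() * 4) & 3];
                } while (sub == cur);
                s[p] = sub;
            }
        }
        out[i] = s;
    }
    return out;
}

static inline bool is_wild(char c, char w) { return c == w; }

// Length-normalized Hamming distance; wildcard (N for nucleotides, X for
// amino acids) matches anything.
// [[Rcpp::export]]
double cpp_norm_hamming(std::string a, std::string b, char wildcard = 'N') {
    if (a.size() != b.size() || a.empty())
        stop("sequences must have equal, positive length");
    int d = 0;
    for (size_t i = 0; i < a.size(); ++i) {
        if (is_wild(a[i], wildcard) || is_wild(b[i], wildcard)) continue;
        if (a[i] != b[i]) ++d;
    }
    return (double)d / a.size();
}

// [[Rcpp::export]]
NumericMatrix cpp_pairwise_norm_hamming(CharacterVector seqs, char wildcard = 'N') {
    int n = seqs.size();
    std::vector<std::string> s(n);
    for (int i = 0; i < n; ++i) s[i] = as<std::string>(seqs[i]);
    NumericMatrix m(n, n);
    for (int i = 0; i < n; ++i) {
        for (int j = i + 1; j < n; ++j) {
            double d = cpp_norm_hamming(s[i], s[j], wildcard);
            m(i, j) = d;
            m(j, i) = d;
        }
    }
    return m;
}

// [[Rcpp::export]]
bool cpp_wildcard_equal(std::string a, std::string b, char wildcard = 'N') {
    if (a.size() != b.size()) return false;
    for (size_t i = 0; i < a.size(); ++i) {
        if (is_wild(a[i], wildcard) || is_wild(b[i], wildcard)) continue;
        if (a[i] != b[i]) return false;
    }
    return true;
}

// For each query, 1-based index of the first ref equal under N-wildcard
// matching (0 if none). Refs are scanned in order.
// [[Rcpp::export]]
IntegerVector cpp_wildcard_match(CharacterVector queries, CharacterVector refs,
                                 char wildcard = 'N') {
    int nq = queries.size(), nr = refs.size();
    std::vector<std::string> r(nr);
    for (int j = 0; j < nr; ++j) r[j] = as<std::string>(refs[j]);
    IntegerVector out(nq);
    for (int i = 0; i < nq; ++i) {
        std::string q = as<std::string>(queries[i]);
        int hit = 0;
        for (int j = 0; j < nr; ++j) {
            if (q.size() == r[j].size() && cpp_wildcard_equal(q, r[j], wildcard)) {
                hit = j + 1;
                break;
            }
        }
        out[i] = hit;
    }
    return out;
}

// Column-wise consensus of equal-orientation reads. Members are truncated to
// the common minimum length. A column emits the modal base when its frequency
// (over group size) is >= min_freq, the mean column quality is >= min_qual and
// the mode is unique; otherwise N. Column quality is the rounded mean Phred.
// [[Rcpp::export]]
List cpp_consensus(CharacterVector seqs, CharacterVector quals,
                   double min_freq, double min_qual) {
    int n = seqs.size();
    if (n == 0) stop("empty group");
    if (quals.size() != n) stop("seqs and quals differ in length");
    std::vector<std::string> s(n), q(n);
    size_t L = std::string::npos;
    for (int i = 0; i < n; ++i) {
        s[i] = as<std::string>(seqs[i]);
        q[i] = as<std::string>(quals[i]);
        if (q[i].size() != s[i].size()) stop("sequence/quality length mismatch");
        L = std::min(L, s[i].size());
    }
    std::string cons(L, 'N'), cq(L, '#');
    for (size_t p = 0; p < L; ++p) {
        int cnt[5] = {0, 0, 0, 0, 0}; // A C G T other/N
        double qsum = 0;
        for (int i = 0; i < n; ++i) {
            switch (s[i][p]) {
            case 'A': ++cnt[0]; break; case 'C': ++cnt[1]; break;
            case 'G': ++cnt[2]; break; case 'T': ++cnt[3]; break;
            default: ++cnt[4];
            }
            qsum += (int)q[i][p] - 33;
        }
        double meanq = qsum / n;
        int best = 0, bestc = cnt[0];
        bool tie = false;
        for (int b = 1; b < 4; ++b) {
            if (cnt[b] > bestc) { best = b; bestc = cnt[b]; tie = false; }
            else if (cnt[b] == bestc) tie = true;
        }
        double freq = (double)bestc / n;
        int mq = (int)(meanq + 0.5);
        if (mq > 41) mq = 41;
        if (mq < 2) mq = 2;
        if (!tie && bestc > 0 && freq >= min_freq && meanq >= min_qual) {
            cons[p] = "ACGT"[best];
            cq[p] = (char)(mq + 33);
        }
    }
    return List::create(_["sequence"] = cons, _["quality"] = cq,
                        _["consensus_count"] = n);
}

// Merge a read pair by the best ungapped 3'-overlap. s2/q2 must already be
// reverse-complemented into the orientation of s1. Overlap o aligns the last
// o bases of s1 with the first o bases of s2; score = matches - mismatches
// (positions with N ignored). Candidate overlaps need mismatch fraction
// <= max_mm_frac over non-N positions. Disagreements resolve to the
// higher-quality base (N always loses); merged quality keeps the max.
// [[Rcpp::export]]
List cpp_merge_pair(std::string s1, std::string q1, std::string s2,
                    std::string q2, int min_overlap, double max_mm_frac) {
    int L1 = s1.size(), L2 = s2.size();
    int omax = std::min(L1, L2);
    int best_o = 0, best_score = -1, best_mm = 0;
    for (int o = min_overlap; o <= omax; ++o) {
        int match = 0, mm = 0, informative = 0;
        const char *a = s1.data() + (L1 - o);
        const char *b = s2.data();
        for (int i = 0; i < o; ++i) {
            char x = a[i], y = b[i];
            if (x == 'N' || y == 'N') continue;
            ++informative;
            if (x == y) ++match; else ++mm;
        }
        if (informative > 0 && (double)mm / informative > max_mm_frac) continue;
        int score = match - mm;
        if (score > best_score) { best_score = score; best_o = o; best_mm = mm; }
    }
    if (best_o == 0)
        return List::create(_["sequence"] = "", _["quality"] = "",
                            _["overlap"] = 0, _["mismatches"] = NA_INTEGER);
    int o = best_o;
    std::string mseq = s1.substr(0, L1 - o);
    std::string mqual = q1.substr(0, L1 - o);
    for (int i = 0; i < o; ++i) {
        char x = s1[L1 - o + i], y = s2[i];
        char qx = q1[L1 - o + i], qy = q2[i];
        char cb, cq;
        if (x == 'N' && y == 'N')      { cb = 'N'; cq = qx > qy ? qx : qy; }
        else if (x == 'N')             { cb = y; cq = qy; }
        else if (y == 'N')             { cb = x; cq = qx; }
        else if (x == y)               { cb = x; cq = qx > qy ? qx : qy; }
        else if (qy > qx)              { cb = y; cq = qy; }
        else                           { cb = x; cq = qx; }
        mseq += cb;
        mqual += cq;
    }
    mseq += s2.substr(o);
    mqual += q2.substr(o);
    return List::create(_["sequence"] = mseq, _["quality"] = mqual,
                        _["overlap"] = o, _["mismatches"] = best_mm);
}

// Best ungapped placement of a full reference segment against a query.
// Offsets d (0-based query position of reference position 0) are scanned in
// [dmin, dmax]; the overlapping region is clipped to the query. Score:
// match +1, mismatch -1, positions with N in either sequence 0. Ties keep the
// smallest offset. Returns c(score, offset, aligned_len, matches).
// [[Rcpp::export]]
IntegerVector cpp_best_placement(std::string query, std::string ref,
                                 int dmin, int dmax) {
    int LQ = query.size(), LR = ref.size();
    int best_score = INT_MIN, best_d = NA_INTEGER, best_len = 0, best_match = 0;
    for (int d = dmin; d <= dmax; ++d) {
        int from = std::max(0, -d);          // ref index where overlap starts
        int to = std::min(LR, LQ - d);       // ref index past overlap end
        if (to - from < 1) continue;
        int score = 0, match = 0;
        for (int i = from; i < to; ++i) {
            char r = ref[i], qc = query[d + i];
            if (r == 'N' || qc == 'N') continue;
            if (r == qc) { ++score; ++match; } else { --score; }
        }
        if (score > best_score) {
            best_score = score; best_d = d;
            best_len = to - from; best_match = match;
        }
    }
    if (best_d == NA_INTEGER)
        return IntegerVector::create(NA_INTEGER, NA_INTEGER, 0, 0);
    return IntegerVector::create(best_score, best_d, best_len, best_match);
}

// Maximum number of mismatches to an aligned germline within any sliding
// window of `window` positions (positions with N in either string skipped).
// [[Rcpp::export]]
int cpp_max_window_mismatch(std::string seq, std::string germ, int window) {
    int L = std::min(seq.size(), germ.size());
    if (L == 0) return 0;
    std::vector<int> mm(L, 0);
    for (int i = 0; i < L; ++i) {
        if (seq[i] == 'N' || germ[i] == 'N') continue;
        if (seq[i] != germ[i]) mm[i] = 1;
    }
    int cur = 0, best = 0;
    for (int i = 0; i < L; ++i) {
        cur += mm[i];
        if (i >= window) cur -= mm[i - window];
        if (cur > best) best = cur;
    }
    return best;
}

// Frame-0 translation via a codon table supplied from R (names = codons,
// values = single-letter amino acids). Codons not in the table (e.g. with N)
// translate to X; trailing bases short of a codon are ignored.
// [[Rcpp::export]]
CharacterVector cpp_translate(CharacterVector seqs, CharacterVector codons,
                              CharacterVector aas) {
    std::unordered_map<std::string, char> table;
    for (int i = 0; i < codons.size(); ++i) {
        table[as<std::string>(codons[i])] = as<std::string>(aas[i])[0];
    }
    R_xlen_t n = seqs.size();
    CharacterVector out(n);
    for (R_xlen_t i = 0; i < n; ++i) {
        std::string s = as<std::string>(seqs[i]);
        size_t nc = s.size() / 3;
        std::string aa(nc, 'X');
        for (size_t c = 0; c < nc; ++c) {
            auto it = table.find(s.substr(3 * c, 3));
            if (it != table.end()) aa[c] = it->second;
        }
        out[i] = aa;
    }
    return out;
}
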