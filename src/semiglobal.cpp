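#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Semi-global (free end-gap) alignment of a read against a reference:
// the read aligns globally, gaps at the reference ends are free, unit
// edit costs (match 0, mismatch/insertion/deletion 1). Suited to
// full-length amplicon reads whose target interval is a substring of the
// gene reference. Ties prefer diagonal, then vertical (read insertion),
// then horizontal (reference deletion); the alignment end ties toward the
// leftmost reference column.
//
// Returns per-column operation codes in 5'->3' order:
//   0 match, 1 mismatch, 2 insertion (read base absent from reference),
//   3 deletion (reference base absent from read).
// [[Rcpp::export]]
List semiglobal_align_cpp(std::string read, std::string ref) {
    const int m = read.size(), n = ref.size();
    if (m == 0) stop("empty read");
    if (n == 0) stop("empty reference");

    std::vector<int> prev(n + 1), cur(n + 1);
    // traceback: 1 diag, 2 vertical (up), 3 horizontal (left)
    std::vector<unsigned char> tb((size_t)(m + 1) * (n + 1), 0);

    for (int j = 0; j <= n; ++j) prev[j] = 0;  // free reference prefix
    const char *rf = ref.c_str();
    for (int i = 1; i <= m; ++i) {
        cur[0] = i;
        unsigned char *tbi = &tb[(size_t)i * (n + 1)];
        tbi[0] = 2;
        const char rc = read[i - 1];
        const int *pv = prev.data();
        int *cv = cur.data();
        int left = cur[0];
        for (int j = 1; j <= n; ++j) {
            int diag = pv[j - 1] + (rc != rf[j - 1]);
            int up = pv[j] + 1;
            ++left;
            int best = diag; unsigned char t = 1;
            if (up < best) { best = up; t = 2; }
            if (left < best) { best = left; t = 3; }
            cv[j] = best; tbi[j] = t;
            left = best;
        }
        std::swap(prev, cur);
    }

    int jend = 0, best = prev[0];
    for (int j = 1; j <= n; ++j)
        if (prev[j] < best) { best = prev[j]; jend = j; }

    std::vector<int> ops;
    ops.reserve(m + 16);
    int i = m, j = jend, nmatch = 0;
    while (i > 0) {
        unsigned char t = tb[(size_t)i * (n + 1) + j];
        if (t == 1) {
            if (read[i - 1] == ref[j - 1]) { ops.push_back(0); ++nmatch; }
            else ops.push_back(1);
            --i; --j;
        } else if (t == 2) {
            ops.push_back(2); --i;
        } else {
            ops.push_back(3); --j;
        }
    }
    std::reverse(ops.begin(), ops.end());

    return List::create(_["edit_distance"] = best,
                        _["rstart"] = j + 1,
                        _["rend"] = jend,
                        _["ops"] = IntegerVector(ops.begin(), ops.end()),
                        _["nmatch"] = nmatch);
}

// Add one alignment to a per-position, per-strand pileup count matrix
// (rows = reference positions, columns A,C,G,T,del on the forward strand
// then the same five on the reverse strand). The read must be given in
// reference orientation. Insertions are returned (not counted in the
// matrix) keyed to the reference position left of the insertion point;
// the caller aggregates them. `weight` supports collapsed duplicate
// reads.
// [[Rcpp::export]]
List pileup_add_cpp(IntegerMatrix counts, std::string read, int rstart,
                    IntegerVector ops, bool is_rev, int weight) {
    const int n = counts.nrow();
    const int off = is_rev ? 5 : 0;
    int i = 0;          // read index, 0-based
    int j = rstart - 1; // reference index, 0-based
    std::vector<int> ins_pos;
    std::vector<std::string> ins_seq;
    std::string pending;

    for (int k = 0; k < ops.size(); ++k) {
        int op = ops[k];
        if (op != 2 && !pending.empty()) {
            ins_pos.push_back(j);  // 1-based left flank == 0-based j
            ins_seq.push_back(pending);
            pending.clear();
        }
        if (op == 0 || op == 1) {
            if (j < 0 || j >= n) stop("alignment outside reference bounds");
            int col = -1;
            switch (read[i]) {
                case 'A': col = 0; break; case 'C': col = 1; break;
                case 'G': col = 2; break; case 'T': col = 3; break;
            }
            if (col >= 0) counts(j, col + off) += weight;
            ++i; ++j;
        } else if (op == 2) {
            pending.push_back(read[i]);
            ++i;
        } else {
            if (j < 0 || j >= n) stop("alignment outside reference bounds");
            counts(j, 4 + off) += weight;
            ++j;
        }
    }
    if (!pending.empty()) {
        ins_pos.push_back(j);
        ins_seq.push_back(pending);
    }
    return List::create(_["pos"] = IntegerVector(ins_pos.begin(),
                                                 ins_pos.end()),
                        _["seq"] = CharacterVector(ins_seq.begin(),
                                                   ins_seq.end()));
}
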