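#include <Rcpp.h>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// Site partitions as taxon bitsets.  For each pair of passing columns (i, j)
// the partition agreement pa(i,j) is the fraction of j's state sets whose
// restriction to i's scored taxa nests within some state set of i; empty
// restrictions are excluded from both numerator and denominator.  The rate
// of column i is the mean of pa(i,j) over all other passing columns with a
// defined agreement.

struct BitPart {
    std::vector<uint64_t> taxa;                    // scored taxa of the column
    std::vector< std::vector<uint64_t> > sets;     // one bitset per state
};

// partitions: list over passing columns; each element a list with
//   taxa: 0-based integer vector of scored taxa
//   sets: list of 0-based integer vectors, one per nucleotide state present
// [[Rcpp::export]]
NumericVector tiger_rates_cpp(List partitions, int n_taxa) {
    const int W = (n_taxa + 63) / 64;
    const int L = partitions.size();
    std::vector<BitPart> ps(L);
    for (int i = 0; i < L; ++i) {
        List p = partitions[i];
        IntegerVector taxa = p["taxa"];
        List sets = p["sets"];
        ps[i].taxa.assign(W, 0ULL);
        for (int k = 0; k < taxa.size(); ++k) {
            int t = taxa[k];
            ps[i].taxa[t >> 6] |= (1ULL << (t & 63));
        }
        ps[i].sets.resize(sets.size());
        for (int s = 0; s < sets.size(); ++s) {
            IntegerVector sv = sets[s];
            ps[i].sets[s].assign(W, 0ULL);
            for (int k = 0; k < sv.size(); ++k) {
                int t = sv[k];
                ps[i].sets[s][t >> 6] |= (1ULL << (t & 63));
            }
        }
    }

    NumericVector out(L);
    std::vector<uint64_t> restr(W);
    for (int i = 0; i < L; ++i) {
        if (i % 64 == 0) Rcpp::checkUserInterrupt();
        double acc = 0.0;
        long n_def = 0;
        for (int j = 0; j < L; ++j) {
            if (j == i) continue;
            int num = 0, den = 0;
            for (size_t a = 0; a < ps[j].sets.size(); ++a) {
                bool empty = true;
                for (int w = 0; w < W; ++w) {
                    restr[w] = ps[j].sets[a][w] & ps[i].taxa[w];
                    if (restr[w]) empty = false;
                }
                if (empty) continue;
                ++den;
                for (size_t s = 0; s < ps[i].sets.size(); ++s) {
                    bool subset = true;
                    for (int w = 0; w < W; ++w) {
                        if (restr[w] & ~ps[i].sets[s][w]) { subset = false; break; }
                    }
                    if (subset) { ++num; break; }
                }
            }
            if (den > 0) { acc += (double)num / den; ++n_def; }
        }
        out[i] = (n_def > 0) ? acc / n_def : NA_REAL;
    }
    return out;
}
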