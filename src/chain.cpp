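#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// Gap-limited longest co-linear chain (longest increasing subsequence by
// query position, strictly increasing reference minimizer index, base-gap
// capped on both reads). Processes many read pairs in one call: rows
// [groupOffset[g], groupOffset[g+1]) belong to pair g and must be sorted by
// refIndex then queryPos. For reverse-strand pairs query positions must
// decrease along the chain.
// [[Rcpp::export]]
List chain_matches_cpp(IntegerVector groupOffset,
                       IntegerVector refIndex,
                       IntegerVector refPos,
                       IntegerVector queryPos,
                       LogicalVector strandNeg,
                       int maxGap) {
    const int G = groupOffset.size() - 1;
    const int n = refIndex.size();
    LogicalVector keep(n, false);
    IntegerVector chainLen(G);
    std::vector<int> L, pred;
    for (int g = 0; g < G; ++g) {
        const int a = groupOffset[g], b = groupOffset[g + 1];
        const int m = b - a;
        const bool neg = strandNeg[g];
        L.assign(m, 1);
        pred.assign(m, -1);
        int bestEnd = 0, bestLen = 1;
        for (int i = 0; i < m; ++i) {
            const int ri = refIndex[a + i], rp = refPos[a + i], qi = queryPos[a + i];
            for (int j = i - 1; j >= 0; --j) {
                if (rp - refPos[a + j] > maxGap) break; // sorted by refPos
                if (refIndex[a + j] >= ri) continue;
                const int qj = queryPos[a + j];
                bool ok;
                if (!neg) ok = (qj < qi) && (qi - qj <= maxGap);
                else      ok = (qj > qi) && (qj - qi <= maxGap);
                if (ok && L[j] + 1 > L[i]) { L[i] = L[j] + 1; pred[i] = j; }
            }
            if (L[i] > bestLen) { bestLen = L[i]; bestEnd = i; }
        }
        if (m > 0) {
            chainLen[g] = bestLen;
            for (int i = bestEnd; i >= 0; i = pred[i]) {
                keep[a + i] = true;
                if (pred[i] < 0) break;
            }
        } else {
            chainLen[g] = 0;
        }
    }
    return List::create(_["keep"] = keep, _["chainLength"] = chainLen);
}
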