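#include <Rcpp.h>
#include <functional>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Route every training sample down one tree with its in-bag multiplicity,
// accumulating per-node covers. Split rule: left when x <= splitval.
// [[Rcpp::export]]
NumericVector cppNodeCovers(IntegerVector left, IntegerVector right,
                            IntegerVector splitvar, NumericVector splitval,
                            NumericMatrix X, NumericVector inbag) {
    int nnode = left.size();
    NumericVector cover(nnode);
    int n = X.nrow();
    for (int s = 0; s < n; ++s) {
        double w = inbag[s];
        if (w <= 0) continue;
        int node = 0;
        for (;;) {
            cover[node] += w;
            if (splitvar[node] < 0) break;
            node = (X(s, splitvar[node]) <= splitval[node]) ? left[node]
                                                            : right[node];
        }
    }
    return cover;
}

// Exact per-path Shapley values of one classification tree under the
// cover-conditioned expectation value function: for a coalition S the tree
// is traversed following the sample on features in S and split by in-bag
// cover fractions on features outside S. Per leaf, the traversal
// probability factorises over the distinct features D on its path as
// prod_j (a_j if j in S else b_j), with a_j the 0/1 consistency indicator
// and b_j the product of cover fractions of j's splits. The Shapley value
// of feature i is then, per leaf,
//   leafval * (a_i - b_i) * sum_k  k!(d-1-k)!/d!  * e_k,
// where e_k is the coefficient of z^k in prod_{j != i}(a_j z + b_j) --
// computed by building the full polynomial once and dividing out each
// factor (b_j > 0 always, covers of realised children are positive).
// Features never split on receive exactly zero.
//
// phi layout: [sample + nsamp * (feature + nfeat * class)]
// [[Rcpp::export]]
NumericVector cppTreeShap(IntegerVector left, IntegerVector right,
                          IntegerVector splitvar, NumericVector splitval,
                          IntegerVector leafclass, NumericVector cover,
                          NumericMatrix X, int nclass) {
    int nfeat = X.ncol(), nsamp = X.nrow();
    NumericVector phi((R_xlen_t)nsamp * nfeat * nclass);
    std::vector<int> pos(nfeat, -1);
    std::vector<int> pf;
    std::vector<double> pa, pb;
    int s = 0;

    std::function<void(int)> rec = [&](int node) {
        if (splitvar[node] < 0) {
            int d = (int)pf.size();
            if (d == 0) return;  // constant tree: nothing to attribute
            int cls = leafclass[node];
            std::vector<double> C(d + 1, 0.0);
            C[0] = 1.0;
            for (int j = 0; j < d; ++j) {
                for (int k = j + 1; k >= 1; --k)
                    C[k] = C[k] * pb[j] + C[k - 1] * pa[j];
                C[0] *= pb[j];
            }
            std::vector<double> w(d), q(d);
            for (int k = 0; k < d; ++k)
                w[k] = std::exp(std::lgamma(k + 1.0) +
                                std::lgamma((double)d - k) -
                                std::lgamma(d + 1.0));
            for (int i = 0; i < d; ++i) {
                double ai = pa[i], bi = pb[i];
                // divide C by (ai z + bi); ai is exactly 0 or 1, so use
                // whichever recurrence avoids dividing by the (possibly
                // tiny) cover fraction bi with cancellation
                if (ai == 0.0) {
                    for (int k = 0; k < d; ++k) q[k] = C[k] / bi;
                } else {
                    q[d - 1] = C[d] / ai;
                    for (int k = d - 1; k >= 1; --k)
                        q[k - 1] = (C[k] - bi * q[k]) / ai;
                }
                double acc = 0.0;
                for (int k = 0; k < d; ++k) acc += w[k] * q[k];
                phi[s + (R_xlen_t)nsamp * (pf[i] + (R_xlen_t)nfeat * cls)] +=
                    (ai - bi) * acc;
            }
            return;
        }
        int f = splitvar[node];
        bool goesLeft = X(s, f) <= splitval[node];
        double cl = cover[left[node]] / cover[node];
        double cr = cover[right[node]] / cover[node];
        int children[2] = {left[node], right[node]};
        double aF[2] = {goesLeft ? 1.0 : 0.0, goesLeft ? 0.0 : 1.0};
        double bF[2] = {cl, cr};
        for (int c = 0; c < 2; ++c) {
            if (bF[c] <= 0) continue;  // empty in-bag child: unreachable
            int p = pos[f];
            if (p < 0) {
                pos[f] = (int)pf.size();
                pf.push_back(f);
                pa.push_back(aF[c]);
                pb.push_back(bF[c]);
                rec(children[c]);
                pf.pop_back(); pa.pop_back(); pb.pop_back();
                pos[f] = -1;
            } else {
                double oa = pa[p], ob = pb[p];
                pa[p] = oa * aF[c];
                pb[p] = ob * bF[c];
                rec(children[c]);
                pa[p] = oa; pb[p] = ob;
            }
        }
    };

    for (s = 0; s < nsamp; ++s) rec(0);
    return phi;
}
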