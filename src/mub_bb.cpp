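#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Exact solver for the Minimum Uncovering Branching integer program.
//
// Vertices (distinct column supports) arrive in a topological order: every
// proper-inclusion arc (u, v) has u < v. Each vertex independently picks at
// most one out-arc (constraint set (1)); the objective counts, per vertex v,
// the rows of v not covered by the union of chosen in-neighbors (the y
// variables of constraint set (2), which are determined by the x variables at
// optimality). Supports are bitmasks (row count limited to 64).
//
// Depth-first search decides vertices 1..k in order. The admissible lower
// bound credits every undecided in-neighbor with full potential coverage:
//   LB(i) = sum_v [ |v| - | cover(v) | mask(v) & potRem(v, i) | ]
// where potRem(v, i) is the union of supports of in-neighbors of v with index
// >= i (precomputed suffix unions). Two passes: optimize, then enumerate all
// assignments attaining the optimum.

namespace {

struct MubProblem {
    int k;
    std::vector<uint64_t> mask;              // support bitmask per vertex
    std::vector<std::vector<int>> out;       // out-neighbors (0-based)
    std::vector<std::vector<uint64_t>> potRem; // [v][depth i], i in 0..k
    int totalOnes;
};

struct MubSearch {
    const MubProblem* P;
    std::vector<uint64_t> cover;   // covered rows per vertex
    std::vector<int> choice;       // -1 none, else 0-based target
    long long best;
    std::vector<std::vector<int>> solutions;
    long long maxSol;              // <0: unlimited
    bool truncated;
    long long nodes, nodeCap;
    bool aborted;

    int lowerBound(int depth) const {
        int lb = 0;
        for (int v = 0; v < P->k; ++v) {
            uint64_t reach = cover[v] | (P->mask[v] & P->potRem[v][depth]);
            lb += __builtin_popcountll(P->mask[v]) -
                  __builtin_popcountll(reach);
        }
        return lb;
    }

    // pass A: find the optimum
    void optimize(int depth) {
        if (aborted || ++nodes > nodeCap) { aborted = true; return; }
        long long lb = lowerBound(depth);
        if (lb >= best) return;
        if (depth == P->k) { best = lb; return; }
        // try covering arcs first (largest gain), 'no out-arc' last
        const std::vector<int>& tgts = P->out[depth];
        std::vector<int> order(tgts.size());
        for (size_t i = 0; i < tgts.size(); ++i) order[i] = (int)i;
        std::stable_sort(order.begin(), order.end(), [&](int a, int b) {
            uint64_t ga = P->mask[depth] & ~cover[tgts[a]];
            uint64_t gb = P->mask[depth] & ~cover[tgts[b]];
            return __builtin_popcountll(ga) > __builtin_popcountll(gb);
        });
        for (int oi : order) {
            int t = tgts[oi];
            uint64_t save = cover[t];
            cover[t] |= P->mask[depth];
            choice[depth] = t;
            optimize(depth + 1);
            cover[t] = save;
        }
        choice[depth] = -1;
        optimize(depth + 1);
    }

    // pass B: collect every assignment with cost == best
    bool enumerate(int depth) {
        if (aborted || ++nodes > nodeCap) { aborted = true; return false; }
        long long lb = lowerBound(depth);
        if (lb > best) return true;
        if (depth == P->k) {
            if (lb == best) {
                if (maxSol >= 0 && (long long)solutions.size() >= maxSol) {
                    truncated = true;
                    return false;
                }
                solutions.push_back(choice);
            }
            return true;
        }
        for (int t : P->out[depth]) {
            uint64_t save = cover[t];
            cover[t] |= P->mask[depth];
            choice[depth] = t;
            bool cont = enumerate(depth + 1);
            cover[t] = save;
            if (!cont) return false;
        }
        choice[depth] = -1;
        return enumerate(depth + 1);
    }
};

} // namespace

// [[Rcpp::export(name = ".mub_branch_and_bound")]]
List mub_branch_and_bound(NumericVector masks, List outArcs,
                          double maxSolutions, double nodeCap) {
    MubProblem P;
    P.k = masks.size();
    P.mask.resize(P.k);
    P.totalOnes = 0;
    for (int i = 0; i < P.k; ++i) {
        P.mask[i] = (uint64_t)masks[i];
        P.totalOnes += __builtin_popcountll(P.mask[i]);
    }
    P.out.assign(P.k, {});
    std::vector<std::vector<int>> in(P.k);
    for (int i = 0; i < P.k; ++i) {
        IntegerVector t = outArcs[i];
        for (int j = 0; j < t.size(); ++j) {
            int v = t[j] - 1;
            if (v <= i || v >= P.k)
                stop("arcs must respect the topological vertex order");
            P.out[i].push_back(v);
            in[v].push_back(i);
        }
    }
    // suffix unions of in-neighbor supports, potRem[v][i] over i = 0..k
    P.potRem.assign(P.k, std::vector<uint64_t>(P.k + 1, 0));
    for (int v = 0; v < P.k; ++v)
        for (int i = P.k - 1; i >= 0; --i) {
            uint64_t u = P.potRem[v][i + 1];
            for (int s : in[v]) if (s == i) u |= P.mask[s];
            P.potRem[v][i] = u;
        }

    MubSearch S;
    S.P = &P;
    S.cover.assign(P.k, 0);
    S.choice.assign(P.k, -1);
    S.best = (long long)P.totalOnes + 1;
    S.maxSol = maxSolutions < 0 ? -1 : (long long)maxSolutions;
    S.truncated = false;
    S.nodes = 0;
    S.nodeCap = (long long)nodeCap;
    S.aborted = false;
    S.optimize(0);
    if (S.aborted) stop("branch-and-bound node cap exceeded");
    long long beta = S.best;
    long long nodesA = S.nodes;

    S.nodes = 0;
    std::fill(S.cover.begin(), S.cover.end(), 0);
    std::fill(S.choice.begin(), S.choice.end(), -1);
    S.enumerate(0);
    if (S.aborted) stop("branch-and-bound node cap exceeded");

    IntegerMatrix sols((int)S.solutions.size(), P.k);
    for (size_t s = 0; s < S.solutions.size(); ++s)
        for (int v = 0; v < P.k; ++v)
            sols(s, v) = S.solutions[s][v] + 1; // 0 = no out-arc
    return List::create(
        _["beta"] = (int)beta,
        _["choices"] = sols,
        _["exhausted"] = !S.truncated,
        _["nodesOptimize"] = (double)nodesA,
        _["nodesEnumerate"] = (double)S.nodes);
}
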