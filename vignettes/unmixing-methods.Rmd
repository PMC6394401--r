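---
title: "Methods: minimum conflict-free row splits for tumor sample unmixing"
author: "phyloUnmix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: minimum conflict-free row splits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyloUnmix)
```

## Model and problem

Bulk tumor samples mix genetically distinct subclones. For SSNVs
$c_1,\dots,c_n$ observed in samples $r_1,\dots,r_m$, we threshold the VAF
matrix at $t$ (an entry is *present* when VAF $\ge t$; the boundary is
inclusive) to obtain a binary matrix $M$. Under the perfect phylogeny model
(mutations are inherited by all descendants and arise only once), the rows
of the unknown subclone matrix $M'$ must be conflict-free: no two columns
may exhibit the three-gamete pattern $(1,1),(1,0),(0,1)$ across three rows.
Each observed row is the bitwise OR of its sample's subclone rows, and
parsimony selects the split minimizing the total number of subclone rows,
$\gamma(M)$.

The search is performed on the containment digraph $D_M$ whose vertices are
the distinct column supports and whose arcs are **all** proper inclusions —
deliberately not the transitive reduction, because a branching (at most one
out-arc per vertex) may need a "skip" arc; removing transitive arcs can
change the optimum. The minimum number of branching-uncovered pairs
$\beta(M)$ equals $\gamma(M)$, and the B-split of an optimal branching is an
optimal conflict-free row split. The package tests this equivalence
end-to-end against two independent exhaustive oracles (all branchings; all
conflict-free row splits of tiny matrices).

## Exact solver

The integer program (binary $x_{u,v}$ per arc, $y_{r,v}$ per row-in-vertex
incidence, packing constraint per vertex, covering constraint per
incidence) is built explicitly — `mubModel()` exposes it and `writeModelLP()`
serializes it, and its dimensions are exactly $p=\ell+o$ and $q=k+o$. It is
solved by a branch-and-bound specialized to its structure: vertices are
processed in the deterministic topological order (by support size, then
lexicographic row indices), each choosing one out-arc or none; the
admissible bound credits every undecided in-neighbor with full potential
coverage via precomputed suffix unions of in-neighbor supports. Supports
are machine-word bitmasks, which caps the solver at 53 samples — far beyond
the intended use. After the optimum is proven, a second sweep enumerates
*every* optimal branching (optionally truncated by `maxSolutions`); each
returned branching's cost is recomputed combinatorially from the
uncovered-pair definition and checked against the optimum, so solver
bookkeeping can never silently corrupt a result. Objectives are integral
throughout; no floating-point tolerances are involved.

Branchings that induce identical split matrices (up to row order within a
sample) are collapsed before reporting, so multiplicities of equivalent
solutions cannot distort downstream averages. In practice each optimal
branching induces a distinct split, so this is a safeguard rather than a
common event.

## Tree construction and annotation

`buildPerfectPhylogeny()` uses the classical construction: distinct column
patterns (mutation groups) are sorted by decreasing support size with ties
broken by first column index (a stable, reproducible order), and each row's
group sequence is inserted into a trie. Identical rows form an equality
class attached to one node; a node whose incoming edge carries no group is
an internal point of the evolution rather than an observable subclone, and
is rendered accordingly in the DOT output. Edge labels are
`S|n|mean±std`: group name in tree pre-order, group size, and the mean and
*population* standard deviation (divide by the count, not count − 1) of the
group's VAFs across **all** samples, printed with two decimals. The
population form is pinned for reproducibility; with per-group counts this
small neither convention is statistically meaningful, but mixing them
silently would be worse.

## Threshold and filter parameters

* `t` (binarization threshold, fraction in (0, 1]): the only parameter a
  routine analysis must set. For the simulation benchmark the default is
  0.01: the read-count model produces zero variant reads for truly absent
  mutations, so any small positive threshold separates presence from
  absence, and 0.01 sits well below the smallest attainable true VAF
  (≈ 0.06 given the population bounds) while tolerating sampling noise.
* `k` (weak-SSNV filter, minClusterSize): drops columns whose
  presence/absence pattern occurs fewer than `k` times. The benchmark uses
  `k = 1` (no filtering) so every mutation stays in the evaluation
  denominator; real-data analyses may use `k = 2` to suppress
  pattern-singleton artifacts.
* `maxSolutions`: `"all"` by default; the enumeration is exhaustive and the
  flag exists for pathological inputs.

## Simulator

`randomCloneTree()` draws a uniformly random labeled tree on `c` clones by
decoding a uniform Prüfer sequence, roots it uniformly, assigns one forced
mutation per clone plus the remaining `n − c` uniformly, and draws integer
cell populations uniformly in [100, 200]. `drawSamples()` mixes a uniform
2–4 clone subset per sample (node count uniform on {2,3,4}, capped at `c`;
repeated subsets across samples are allowed — independent draws), with
usage fractions proportional to population sizes. True VAFs are
$F = \tfrac12 U B$ with $B$ the descendant-closure clonal matrix (diploid
heterozygous mutations, hence the factor ½ and $F \le \tfrac12$).
`simulateReads()` draws total reads Poisson(coverage) and variant reads
Binomial per cell; a zero-read cell's VAF is defined as 0, the conservative
absent call.

Loss-of-mutation events deliberately violate the infinite-sites assumption:
an event picks uniformly among eligible triples (clone $v$, child $u$,
mutation present at both) and removes the mutation from $u$'s entire
subtree; sampling is without replacement in the sense that eligibility is
recomputed after each cascade, and if fewer than `d` effective events
remain the achieved count is recorded. With losses, per-mutation presence
no longer factors through the clonal matrix, so the per-mutation VAF matrix
is computed directly from the post-loss presence profiles; for `d = 0` this
provably coincides with copying the originating clone's column of $F$.

What the generator does *not* emulate: sequencing error (absent mutations
never yield variant reads, so false positives cannot occur), copy-number
aberrations, and normal-cell contamination. Passing benchmarks therefore
demonstrates correct recovery under the mixture model's own assumptions,
not robustness to artifacts of real sequencing data.

## Evaluation metric and aggregation

An AD (ancestor–descendant) pair is an ordered mutation pair whose
locations are in strict ancestor relation; two mutations at the same node
or edge are not a pair. `adFraction()` reports the fraction of the truth
tree's AD pairs present in an output tree, over the full mutation universe:
mutations missing from the output (never sampled, or thresholded away)
count as unrecovered. Per scenario, `runBenchmark()` reports
Best = mean of per-instance best trees, Avg = mean of per-instance means
over all optimal trees, Std = standard deviation of the per-instance means
across instances. The per-instance-first convention was chosen so that
instances with many co-optimal trees do not dominate the scenario average.

Benchmark problem sizes are 100 instances per scenario at c = 10 clones and
n = 100 mutations — large enough that the scenario mean has a standard
error of roughly 0.01–0.015, small enough that the full grid runs in a few
minutes on one CPU.

## Known limitations

* **Co-optimal ambiguity.** The parsimony criterion is frequently
  degenerate: when a support has several incomparable supersets offering
  equal coverage, genuinely different optimal trees exist and the
  enumeration reports all of them. Their AD scores can differ substantially
  (spreads of 0.1–0.3 on some instances), so the Avg statistic is
  intrinsically sensitive to how completely co-optima are enumerated; tools
  that report only the solutions their solver happens to visit will show
  Avg close to Best, while this package's exhaustive enumeration yields a
  more conservative Avg.
* **Loss events.** The AD score after loss events depends strongly on
  *which* propagation event is suppressed (damage correlates with the size
  of the affected subtree and the prominence of the mutation); comparisons
  across implementations are only meaningful if the event-sampling scheme
  is fixed, which published descriptions rarely do.
* **Threshold bias.** With noisy VAFs near `t`, presence calls flip
  per-sample independently; very low thresholds are robust under this
  generator only because it has no false-positive mechanism.
* The solver is exponential in the worst case (the problem is NP-hard); the
  admissible bound keeps realistic instances (tens of distinct columns)
  in the millisecond range, and a node cap guards against adversarial
  inputs.
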