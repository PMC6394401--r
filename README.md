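# phyloUnmix

Tumor subclone deconvolution from multi-sample variant data via minimum
conflict-free row splits.

## The problem

Bulk sequencing samples of a tumor are mixtures of subclones. Given VAF
(variant allele frequency) tables for somatic single nucleotide variants
(SSNVs) across several samples, each sample's binary presence/absence row is
the bitwise OR of the unknown subclone rows. Under the infinite-sites
(perfect phylogeny) model the subclone rows must form a **conflict-free**
matrix: no two columns may show the three-gamete pattern (1,1), (1,0),
(0,1). `phyloUnmix` splits each sample row into a set of subclone rows so
that the resulting matrix is conflict-free and the **total number of
subclone rows is minimum** (the minimum conflict-free row split, with
optimum γ(M)), then reports the corresponding perfect phylogeny.

## The method

The optimization is carried out on the **containment digraph** D_M: vertices
are the distinct column supports supp(c) = {rows with a 1 in column c}, with
an arc (u, v) for every proper inclusion u ⊂ v. A **branching** B picks at
most one out-arc per vertex; a pair (r, v) with r ∈ v is *uncovered* when no
chosen in-neighbor of v contains r. The minimum number of uncovered pairs
β(M) over all branchings equals γ(M), and the *B-split* of an optimal
branching — one row per uncovered pair (r, v), with 1s exactly on the
columns whose supports are reachable from v along B — is an optimal
conflict-free row split.

The package formulates this as the integer program

    min  Σ_v Σ_{r∈v} y_{r,v}
    s.t. Σ_{(u,v)∈A} x_{u,v} ≤ 1                      for every vertex u
         y_{r,v} + Σ_{u∈N⁻(v): r∈u} x_{u,v} ≥ 1       for every r ∈ v
         x, y binary

(p = ℓ + o variables and q = k + o constraints, where k = distinct columns,
ℓ = comparable column pairs, o = ones in the column-deduplicated matrix) and
solves it exactly with a specialized branch-and-bound over branchings,
enumerating *all* optimal solutions. Each optimum is turned into a perfect
phylogeny whose edges carry mutation groups labeled `S|n|mean±std` (group
name, size, VAF mean ± population SD across all samples).

A simulator reproduces the standard benchmark design: uniform random clone
trees (Prüfer encoding), 2–4 clones mixed per sample, true VAFs F = ½·U·B
from usage and clonal matrices, Poisson(coverage) read depths with Binomial
variant reads, optional loss-of-mutation events, and the
ancestor–descendant (AD) pair recovery metric with Best/Avg/Std
aggregation.

## Worked example

`inst/extdata/example_vaf.tsv` holds VAFs for five SSNVs in four samples:

```r
library(phyloUnmix)
res <- runUnmix(system.file("extdata", "example_vaf.tsv", package = "phyloUnmix"),
                "demo_out", t = 0.1)
#> beta: 6  solutions: 2
```

Thresholding at t = 0.1 gives a binary matrix that is *not* conflict-free
(PIK3CA/CDKN2A vs KRAS cross in samples R3/R4), so γ(M) = 6 > 4 samples:
two samples must each be split into two subclones. The first optimal split
written to `demo_out/solution1_split.tsv`:

```
sample  TP53_R175H  PIK3CA_E545K  BRAF_V600E  CDKN2A_W110X  KRAS_G12D
R1_1    1           1             0           1             0
R2_1    1           0             1           0             0
R3_1    1           1             0           1             0
R3_2    1           0             0           0             1
R4_1    1           0             1           0             0
R4_2    1           0             0           0             1
```

R3 is a mixture of an (TP53, PIK3CA, CDKN2A) subclone — identical to R1 —
and a (TP53, KRAS) subclone; the OR of R3_1 and R3_2 reproduces R3's
original row. The phylogeny (`solution1_tree.nwk`, also written as DOT with
gray sample squares and an equality-class legend) places the truncal
TP53 group S1 on the root edge and three subclone branches below it:

```
((R1_1[&label=S2|2|0.14±0.16],R2_1[&label=S3|1|0.17±0.18],R3_2[&label=S4|1|0.10±0.10])n2[&label=S1|1|0.35±0.12])germline;
```

`solution1_groups.txt` maps the group names to SSNV identifiers
(`S2 = PIK3CA_E545K,CDKN2A_W110X`, ...). Because the data cannot decide
where the KRAS branch attaches, a second optimal solution is also written;
`manifest.json` records β = γ, the solution count and the ILP size.

The same pipeline is available from the shell:

```sh
Rscript inst/scripts/phylounmix.R run -i vaf.tsv -t 0.1 -o outdir
Rscript inst/scripts/phylounmix.R simulate --clones 10 --mutations 100 --samples 5 --coverage 100 --seed 1 -o simdir
Rscript inst/scripts/phylounmix.R benchmark --samples 10 --coverage 1000 --instances 100 --seed 1 -o benchdir
```

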