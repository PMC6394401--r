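test_that("the perfect phylogeny reproduces its matrix", {
    M <- fixtureNested()
    tree <- buildPerfectPhylogeny(M)
    # shared mutation c1 on one edge, private c2/c3 below it
    g1 <- which(vapply(treeGroups(tree), function(g) "c1" %in% g, NA))
    expect_length(treeGroups(tree)[[g1]], 1L)
    rebuilt <- rebuildMatrix(tree, rowOrder = rownames(binValues(M)),
                             colOrder = colnames(binValues(M)))
    expect_identical(binValues(rebuilt), binValues(M))

    ones <- BinaryMatrix(matrix(1L, 3, 1,
        dimnames = list(paste0("r", 1:3), "c1")))
    t1 <- buildPerfectPhylogeny(ones)
    expect_length(treeParents(t1), 2L)      # root plus one edge
    expect_length(nodeRows(t1)[[2L]], 3L)   # all rows in one class
})

test_that("the crossing fixture's split yields two branches with classes", {
    M <- fixtureCrossing()
    D <- containmentDigraph(M)
    rs <- bSplit(M, D, Branching(matrix(integer(), 0, 2), 2L))
    tree <- buildPerfectPhylogeny(splitMatrix(rs))
    expect_length(treeParents(tree), 3L)                 # root + 2 leaves
    expect_identical(unname(treeParents(tree)), c(0L, 1L, 1L))
    classes <- nodeRows(tree)[lengths(nodeRows(tree)) > 0]
    expect_identical(sort(lengths(classes)), c(2L, 2L))  # two equal pairs
})

test_that("conflicted input is rejected with a witness", {
    expect_error(buildPerfectPhylogeny(fixtureCrossing()),
                 "not conflict-free: columns \\(c[12], c[12]\\)")
})

test_that("rebuild is the identity on random conflict-free matrices", {
    set.seed(606)
    for (rep in 1:15) {
        M <- randomConflictFreeMatrix(sample(3:6, 1), sample(6:10, 1))
        tree <- buildPerfectPhylogeny(M)
        rebuilt <- rebuildMatrix(tree, rowOrder = rownames(binValues(M)),
                                 colOrder = colnames(binValues(M)))
        expect_identical(binValues(rebuilt), binValues(M))
        # each group labels exactly one edge and names are S1..Sg
        expect_setequal(treeGroupNames(tree),
                        paste0("S", seq_along(treeGroups(tree))))
    }
})

test_that("edge labels carry group size and VAF mean/population sd", {
    v <- VAFMatrix(matrix(c(0.5, 0.0), 2, 1,
                          dimnames = list(c("s1", "s2"), "mutA")))
    M <- binarize(v, 0.5)
    M <- dropEmpty(M, quiet = TRUE)
    tree <- labelEdges(buildPerfectPhylogeny(M), v)
    expect_identical(tree@groupLabel, "S1|1|0.25±0.25")

    # two mutations with constant VAF: zero spread
    v2 <- VAFMatrix(matrix(0.3, 2, 2,
                           dimnames = list(c("s1", "s2"), c("a", "b"))))
    t2 <- labelEdges(buildPerfectPhylogeny(binarize(v2, 0.1)), v2)
    expect_identical(t2@groupLabel, "S1|2|0.30±0.00")

    # population (not sample) standard deviation is pinned
    v3 <- VAFMatrix(matrix(c(0.2, 0.4), 2, 1,
                           dimnames = list(c("s1", "s2"), "a")))
    t3 <- labelEdges(buildPerfectPhylogeny(binarize(v3, 0.1)), v3)
    expect_identical(t3@groupLabel, "S1|1|0.30±0.10")

    vbad <- VAFMatrix(matrix(0.3, 2, 1,
                             dimnames = list(c("s1", "s2"), "other")))
    expect_error(labelEdges(buildPerfectPhylogeny(binarize(v2, 0.1)),
                            vbad), "absent")
})

test_that("tree exports produce DOT, Newick and group files", {
    M <- fixtureNested()
    D <- containmentDigraph(M)
    rs <- bSplit(M, D, solveMUB(D)@branchings[[1L]])
    tree <- buildPerfectPhylogeny(splitMatrix(rs))
    tree@sampleArrows <- splitPartition(rs)

    dot <- phyloDOT(tree)
    expect_match(dot, "shape=oval")
    expect_match(dot, "shape=box, style=filled")
    expect_match(dot, "germline")

    nwk <- phyloNewick(tree)
    expect_match(nwk, "^\\(.*\\)germline;$")
    expect_match(nwk, "\\[&label=S1\\]")

    gf <- tempfile()
    writeMutationGroups(tree, gf)
    lines <- readLines(gf)
    expect_identical(sub("\t.*", "", lines),
                     paste0("S", seq_along(lines)))

    phy <- asPhylo(tree)
    expect_s3_class(phy, "phylo")
    expect_identical(ape::Ntip(phy), 2L)
})
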