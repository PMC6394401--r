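# hand-built trees for metric tests
makeCloneTree <- function(parent, mutationsOf) {
    c0 <- length(parent)
    muts <- unlist(mutationsOf)
    presence <- matrix(FALSE, c0, length(muts),
                       dimnames = list(paste0("clone", seq_len(c0)), muts))
    desc <- phyloUnmix:::.descendantsOf(parent)
    origin <- rep(seq_len(c0), lengths(mutationsOf))
    for (j in seq_along(muts)) presence[desc[[origin[j]]], j] <- TRUE
    new("CloneTree", parent = as.integer(parent),
        root = which(parent == 0L), mutationsOf = mutationsOf,
        populations = rep(150L, c0), presence = presence,
        lossEvents = data.frame(clone = integer(), child = integer(),
                                mutation = character()))
}

# a chain/star output phylogeny: parent vector plus one mutation group per
# non-root node
makePhyloTree <- function(parent, groups) {
    n <- length(parent)
    new("PhyloTree", parent = as.integer(parent),
        edgeGroup = c(NA_integer_, seq_len(n - 1L)), groups = groups,
        groupName = paste0("S", seq_len(n - 1L)),
        groupLabel = character(0),
        nodeRows = c(list(character()),
                     lapply(seq_len(n - 1L), function(i) paste0("x", i))),
        sampleArrows = list())
}

test_that("AD pairs follow strict ancestry between mutation locations", {
    # two-clone path: one ordered pair
    path2 <- makeCloneTree(c(0L, 1L), list(c1 = "A", c2 = "B"))
    expect_identical(adPairs(path2),
                     cbind(ancestor = "A", descendant = "B"))
    # star: root mutations ancestral to every leaf mutation, leaves unrelated
    star <- makeCloneTree(c(0L, 1L, 1L, 1L),
                          list(c1 = "R", c2 = "L1", c3 = "L2", c4 = "L3"))
    ap <- adPairs(star)
    expect_identical(nrow(ap), 3L)
    expect_true(all(ap[, "ancestor"] == "R"))
    # two mutations in the same clone are not an AD pair
    same <- makeCloneTree(c(0L, 1L), list(c1 = c("A", "B"), c2 = "C"))
    ap2 <- adPairs(same)
    expect_false(any(ap2[, "ancestor"] == "A" & ap2[, "descendant"] == "B"))
    expect_identical(nrow(ap2), 2L)
})

test_that("adFraction counts recovered truth pairs", {
    truth <- makeCloneTree(c(0L, 1L, 2L),
                           list(c1 = "A", c2 = "B", c3 = "C"))
    # perfect output: chain in the true order
    good <- makePhyloTree(c(0L, 1L, 2L, 3L),
                          list("A", "B", "C"))
    expect_equal(adFraction(truth, good), 1.0)
    # swapped output recovers (A,B) and (A,C) but not (B,C)
    swapped <- makePhyloTree(c(0L, 1L, 2L, 3L),
                             list("A", "C", "B"))
    expect_equal(adFraction(truth, swapped), 2 / 3)
    # collapsing everything onto one edge recovers nothing
    flat <- makePhyloTree(c(0L, 1L), list(c("A", "B", "C")))
    expect_equal(adFraction(truth, flat), 0.0)
    # mutations absent from the output count as unrecovered
    partial <- makePhyloTree(c(0L, 1L, 2L), list("A", "B"))
    expect_equal(adFraction(truth, partial), 1 / 3)
    # a single-clone truth has no AD pairs to recover
    single <- makeCloneTree(0L, list(c1 = c("A", "B")))
    expect_error(adFraction(single, good), "no AD pairs")
})

test_that("phylogeny AD pairs respect edge placement", {
    tr <- makePhyloTree(c(0L, 1L, 2L), list(c("A", "B"), "C"))
    ap <- adPairs(tr)
    expect_setequal(paste(ap[, 1], ap[, 2]), c("A C", "B C"))
})

test_that("scoreMatrix ties the solver to the metric", {
    set.seed(71)
    ds <- simulateDataset(3, 6, 4, coverage = NA, d = 0)
    M <- dropEmpty(binarize(datasetVAF(ds, noisy = FALSE), 1e-9),
                   quiet = TRUE)
    sc <- scoreMatrix(M, truth = ds@tree)
    expect_true(all(sc$fractions >= 0 & sc$fractions <= 1))
    expect_identical(length(sc$trees), length(sc$splits))
    expect_gte(sc$beta, nrow(binValues(M)))
})

test_that("benchmark aggregation is reproducible and internally consistent", {
    r <- runBenchmark(c = 3, n = 6, m = 4, coverage = NA, d = 0,
                      nInstances = 3, seed = 5)
    expect_true(all(perInstanceMeans(r) >= 0 & perInstanceMeans(r) <= 1))
    expect_gte(benchBest(r), benchAvg(r))
    expect_gte(benchStd(r), 0)
    r2 <- runBenchmark(c = 3, n = 6, m = 4, coverage = NA, d = 0,
                       nInstances = 3, seed = 5)
    expect_identical(perInstanceMeans(r), perInstanceMeans(r2))
    # restricting the enumeration cannot improve the best tree
    rAll <- runBenchmark(c = 4, n = 8, m = 3, coverage = 100, d = 0,
                         nInstances = 3, seed = 6)
    rOne <- runBenchmark(c = 4, n = 8, m = 3, coverage = 100, d = 0,
                         nInstances = 3, seed = 6, maxSolutions = 1)
    expect_gte(benchBest(rAll), benchBest(rOne))
    # results table export
    path <- tempfile(fileext = ".tsv")
    writeBenchmarkTSV(list(r), path)
    df <- read.delim(path)
    expect_identical(nrow(df), 1L)
    expect_true(all(c("Best", "Avg", "Std") %in% names(df)))
})
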