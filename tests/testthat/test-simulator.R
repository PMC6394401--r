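test_that("clone trees satisfy their structural contract", {
    set.seed(1)
    tree <- randomCloneTree(10, 100, d = 0)
    expect_identical(sum(cloneParents(tree) == 0L), 1L)
    expect_identical(sum(lengths(cloneMutations(tree))), 100L)
    expect_true(all(lengths(cloneMutations(tree)) >= 1L))
    expect_true(all(clonePopulations(tree) >= 100L &
                    clonePopulations(tree) <= 200L))
    # two clones force the single-edge topology
    t2 <- randomCloneTree(2, 2)
    expect_identical(sort(c(t2@root, which(cloneParents(t2) != 0L))),
                     1:2)
    expect_error(randomCloneTree(10, 5), "n < c")
    expect_error(randomCloneTree(1, 5), "at least 2")
})

test_that("Prufer decoding yields uniform labeled trees", {
    set.seed(2)
    # c = 4: Cayley gives 4^2 = 16 labeled trees
    draws <- 8000L
    keys <- character(draws)
    for (i in seq_len(draws)) {
        pr <- sample.int(4L, 2L, replace = TRUE)
        e <- phyloUnmix:::.decodePrufer(pr, 4L)
        e <- t(apply(e, 1L, sort))
        keys[i] <- paste(e[order(e[, 1L], e[, 2L]), ], collapse = "-")
    }
    tab <- table(keys)
    expect_identical(length(tab), 16L)
    p <- stats::chisq.test(tab)$p.value
    expect_gt(p, 1e-4)
})

test_that("presence propagates to descendants and losses only remove", {
    set.seed(3)
    for (d in c(0L, 3L)) {
        tree <- randomCloneTree(8, 40, d = d)
        parent <- cloneParents(tree)
        desc <- phyloUnmix:::.descendantsOf(parent)
        origin <- phyloUnmix:::.mutationOrigin(tree)
        pres <- mutationPresence(tree)
        for (mut in colnames(pres)) {
            carriers <- which(pres[, mut])
            full <- desc[[origin[mut]]]
            # never present outside the originating subtree
            expect_true(all(carriers %in% full))
            # the originating clone keeps its mutation
            if (d == 0L) expect_setequal(carriers, full)
        }
        expect_identical(nrow(tree@lossEvents), d)
    }
})

test_that("usage, clonal and VAF matrices obey the mixture model", {
    set.seed(4)
    tree <- randomCloneTree(6, 20, d = 0)
    ds <- drawSamples(tree, 8)
    expect_equal(unname(rowSums(ds@U)), rep(1, 8))
    expect_true(all(lengths(ds@samples) >= 2L & lengths(ds@samples) <= 4L))
    expect_true(all(ds@F >= 0 & ds@F <= 0.5))
    # clonal matrix: (i, j) iff i descends from (or is) j
    desc <- phyloUnmix:::.descendantsOf(cloneParents(tree))
    for (j in seq_len(6)) {
        expect_setequal(which(ds@clonal[, j] == 1L), desc[[j]])
    }
    # with d = 0 the per-mutation column copies the clone column of F
    origin <- phyloUnmix:::.mutationOrigin(tree)
    for (mut in colnames(ds@Funpack))
        expect_equal(unname(ds@Funpack[, mut]),
                     unname(ds@F[, origin[mut]]))
    # equal populations give equal usage fractions
    tree@populations <- rep(150L, 6)
    ds2 <- drawSamples(tree, 1, seed = 9)
    sel <- ds2@samples[[1L]]
    expect_equal(unname(ds2@U[1L, sel]),
                 rep(1 / length(sel), length(sel)))
    # distinct clone profiles: d = 0 gives exactly c distinct columns
    expect_lte(length(unique(apply(ds@Funpack, 2, paste, collapse = ","))),
               6L)
})

test_that("read counts follow the Poisson/Binomial noise model", {
    set.seed(5)
    tree <- randomCloneTree(4, 50, d = 0)
    ds <- drawSamples(tree, 4)
    ds <- simulateReads(ds, 100)
    expect_true(all(ds@variantReads <= ds@reads))
    mY <- mean(ds@reads)
    se <- sqrt(100 / length(ds@reads))
    expect_lt(abs(mY - 100), 3 * se)
    # absent mutations never yield variant reads
    expect_true(all(ds@variantReads[ds@Funpack == 0] == 0L))
    expect_true(all(ds@noisyVAF[ds@Funpack == 0] == 0))
    # noisy VAF is unbiased at high coverage
    half <- which(abs(ds@Funpack - 0.5) < 1e-12)
    if (length(half) > 10) {
        ds2 <- simulateReads(ds, 1000)
        expect_lt(abs(mean(ds2@noisyVAF[half]) - 0.5),
                  3 * sqrt(0.25 / (1000 * length(half))))
    }
    expect_error(simulateReads(ds, 0), "coverage")
})

test_that("a fixed seed reproduces the dataset bit for bit", {
    d1 <- simulateDataset(5, 20, 4, coverage = 50, d = 1, seed = 77)
    d2 <- simulateDataset(5, 20, 4, coverage = 50, d = 1, seed = 77)
    expect_identical(d1@U, d2@U)
    expect_identical(d1@reads, d2@reads)
    expect_identical(d1@noisyVAF, d2@noisyVAF)
    expect_identical(d1@tree@lossEvents, d2@tree@lossEvents)
})

test_that("simulated VAF tables round-trip through the TSV dialect", {
    ds <- simulateDataset(4, 10, 3, coverage = 100, seed = 8)
    v <- datasetVAF(ds)
    path <- tempfile(fileext = ".tsv")
    writeVAFTable(v, path)
    back <- readVAFTable(path)
    expect_identical(rownames(vafValues(back)), rownames(vafValues(v)))
    expect_equal(vafValues(back), vafValues(v), tolerance = 1e-12)
    tf <- tempfile()
    writeTruth(ds, tf)
    lines <- readLines(tf)
    expect_identical(sum(grepl("^edge\t", lines)), 3L)
    expect_identical(sum(grepl("^sample\t", lines)), 3L)
})
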