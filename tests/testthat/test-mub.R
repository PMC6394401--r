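test_that("uncovered pairs follow the covering definition", {
    D <- containmentDigraph(fixtureNested())
    # vertices: {r1}, {r2}, {r1,r2}; both arcs point into the big vertex
    B <- Branching(rbind(c(1L, 3L), c(2L, 3L)), 3L)
    u <- uncoveredPairs(D, B)
    expect_identical(nrow(u), 2L)
    expect_setequal(paste(u$row, u$vertex), c("r1 1", "r2 2"))

    # the empty branching leaves every (row, vertex) incidence uncovered
    empty <- Branching(matrix(integer(), 0, 2), 3L)
    expect_identical(nrow(uncoveredPairs(D, empty)),
                     ilpSize(D)$o)

    D2 <- containmentDigraph(fixtureCrossing())
    expect_identical(nrow(uncoveredPairs(
        D2, Branching(matrix(integer(), 0, 2), 2L))), 4L)
})

test_that("branching contract violations are rejected", {
    D <- containmentDigraph(fixtureNested())
    expect_error(uncoveredPairs(D, Branching(rbind(c(2L, 1L)), 3L)),
                 "not present")
    # the class itself enforces out-degree <= 1
    expect_error(Branching(rbind(c(1L, 3L), c(1L, 2L)), 3L),
                 "one out-arc")
})

test_that("the exact solver matches hand-enumerated optima on fixtures", {
    DN <- containmentDigraph(fixtureNested())
    sN <- solveMUB(DN)
    expect_identical(betaValue(sN), 2L)
    expect_length(sN@branchings, 1L)
    expect_identical(nrow(branchingArcs(sN@branchings[[1L]])), 2L)

    DX <- containmentDigraph(fixtureCrossing())
    sX <- solveMUB(DX)
    expect_identical(betaValue(sX), 4L)
    expect_identical(nrow(branchingArcs(sX@branchings[[1L]])), 0L)

    DC <- containmentDigraph(fixtureChain())
    sC <- solveMUB(DC)
    expect_identical(betaValue(sC), 3L)
})

test_that("brute-force enumeration agrees and respects its cap", {
    DN <- containmentDigraph(fixtureNested())
    bf <- bruteForceMUB(DN)
    expect_identical(bf$beta, 2L)
    DC <- containmentDigraph(fixtureChain())
    expect_identical(bruteForceMUB(DC)$beta, 3L)
    # single-vertex digraph: the lone support stays uncovered
    D1 <- containmentDigraph(BinaryMatrix(
        matrix(1L, 1, 1, dimnames = list("r1", "c1"))))
    expect_identical(bruteForceMUB(D1)$beta, 1L)
    expect_error(bruteForceMUB(DN, cap = 1), "cap")
})

test_that("solver and brute force agree on random instances", {
    set.seed(101)
    for (rep in 1:60) {
        M <- randomBinaryMatrix(sample(2:5, 1), sample(2:6, 1))
        D <- containmentDigraph(M)
        s <- solveMUB(D)
        bf <- bruteForceMUB(D)
        expect_identical(betaValue(s), bf$beta)
        # enumeration soundness: identical sets of optimal branchings
        canon <- function(b) paste(sort(paste(branchingArcs(b)[, 1L],
                                              branchingArcs(b)[, 2L])),
                                   collapse = ";")
        expect_setequal(vapply(s@branchings, canon, ""),
                        vapply(bf$branchings, canon, ""))
        # lower bound: beta is at least the number of rows
        expect_gte(betaValue(s), nrow(binValues(M)))
    }
})

test_that("conflict-free matrices reach the row-count lower bound", {
    set.seed(202)
    for (rep in 1:15) {
        M <- randomConflictFreeMatrix(sample(3:6, 1), sample(6:9, 1))
        expect_true(isTRUE(isConflictFree(M)))
        expect_identical(betaValue(solveMUB(containmentDigraph(M))),
                         nrow(binValues(M)))
    }
})

test_that("maxSolutions truncates the enumeration", {
    # two incomparable parents over a common child: two optimal choices
    M <- BinaryMatrix(matrix(c(1, 1, 0,
                               1, 1, 1,
                               0, 1, 1), 3, 3, byrow = TRUE,
                             dimnames = list(paste0("r", 1:3),
                                             paste0("c", 1:3))))
    D <- containmentDigraph(M)
    all <- solveMUB(D, "all")
    one <- solveMUB(D, 1)
    expect_identical(betaValue(all), betaValue(one))
    expect_length(one@branchings, 1L)
    if (length(all@branchings) > 1L) expect_false(one@exhausted)
    expect_error(solveMUB(D, 0), "maxSolutions")
})

test_that("model sizes obey p = l + o and q = k + o", {
    sz <- ilpSize(containmentDigraph(fixtureNested()))
    expect_identical(sz[c("p", "q", "k", "ell", "o")],
                     list(p = 6L, q = 7L, k = 3L, ell = 2L, o = 4L))
    sz2 <- ilpSize(containmentDigraph(fixtureCrossing()))
    expect_identical(sz2[c("p", "q", "k", "ell", "o")],
                     list(p = 4L, q = 6L, k = 2L, ell = 0L, o = 4L))
    id2 <- BinaryMatrix(matrix(diag(2), 2, 2,
        dimnames = list(c("r1", "r2"), c("c1", "c2"))))
    sz3 <- ilpSize(containmentDigraph(id2))
    expect_identical(sz3$p, 2L)
    expect_identical(sz3$q, 4L)
})

test_that("the explicit model matches the size formulas exactly", {
    set.seed(303)
    for (rep in 1:20) {
        D <- containmentDigraph(randomBinaryMatrix(sample(2:5, 1),
                                                   sample(2:6, 1)))
        mod <- mubModel(D)
        sz <- ilpSize(D)
        expect_identical(length(mod$varNames), sz$p)
        expect_identical(length(mod$constraints), sz$q)
        expect_identical(sum(mod$objective == 0), sz$ell)
        expect_identical(sum(mod$objective == 1), sz$o)
    }
})

test_that("the model exports to LP format", {
    D <- containmentDigraph(fixtureNested())
    path <- tempfile(fileext = ".lp")
    writeModelLP(mubModel(D), path)
    txt <- readLines(path)
    expect_identical(txt[1L], "Minimize")
    expect_true(any(grepl("^Subject To$", txt)))
    expect_true(any(grepl("x_1_3", txt)))
})
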