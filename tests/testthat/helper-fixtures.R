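# small hand-checkable matrices used throughout the suite:
# fixtureNested: laminar supports, conflict-free, splits into itself
# fixtureCrossing: two overlapping incomparable columns, the classic
#   three-gamete conflict, minimum split doubles two rows
# fixtureChain: duplicate rows over a two-column chain

fixtureNested <- function() {
    BinaryMatrix(matrix(c(1, 1, 0,
                          1, 0, 1), 2, 3, byrow = TRUE,
                        dimnames = list(c("r1", "r2"),
                                        c("c1", "c2", "c3"))))
}

fixtureCrossing <- function() {
    BinaryMatrix(matrix(c(1, 1,
                          1, 0,
                          0, 1), 3, 2, byrow = TRUE,
                        dimnames = list(c("r1", "r2", "r3"),
                                        c("c1", "c2"))))
}

fixtureChain <- function() {
    BinaryMatrix(matrix(c(1, 1,
                          1, 1,
                          1, 0), 3, 2, byrow = TRUE,
                        dimnames = list(c("r1", "r2", "r3"),
                                        c("c1", "c2"))))
}

# random normalized binary matrix (no all-zero rows/columns)
randomBinaryMatrix <- function(m, n, p = 0.5) {
    repeat {
        mat <- matrix(rbinom(m * n, 1L, p), m, n,
                      dimnames = list(paste0("r", seq_len(m)),
                                      paste0("c", seq_len(n))))
        if (all(rowSums(mat) > 0L) && all(colSums(mat) > 0L))
            return(BinaryMatrix(mat))
    }
}

# uniform random branching of a digraph: each vertex picks one out-arc or
# none
randomBranching <- function(D) {
    arcs <- digraphArcs(D)
    k <- length(digraphVertices(D))
    chosen <- NULL
    for (u in seq_len(k)) {
        tgts <- arcs[arcs[, 1L] == u, 2L]
        pick <- sample(length(tgts) + 1L, 1L) - 1L
        if (pick > 0L) chosen <- rbind(chosen, c(u, tgts[pick]))
    }
    if (is.null(chosen)) chosen <- matrix(integer(), 0L, 2L)
    Branching(chosen, k)
}

# random conflict-free matrix: presence profiles of a random clone tree
randomConflictFreeMatrix <- function(c = 5L, n = 8L) {
    tree <- randomCloneTree(c, n, d = 0L)
    mat <- mutationPresence(tree) * 1L
    BinaryMatrix(mat)
}

writeVAFFixture <- function(lines, path = tempfile(fileext = ".tsv")) {
    writeLines(lines, path)
    path
}
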