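#' @include AllClasses.R phylogeny.R simulate.R
NULL

#' Benchmark aggregation result
#'
#' Ancestor-descendant (AD) pair recovery for one simulation scenario:
#' per-instance statistics over all optimal output trees, aggregated across
#' instances ("Best" = mean of per-instance best values, "Avg" = mean of
#' per-instance means, "Std" = standard deviation of per-instance means).
#'
#' @slot scenario named list (c, n, m, coverage, d, t, k).
#' @slot perInstanceBest numeric vector of per-instance best fractions.
#' @slot perInstanceMean numeric vector of per-instance mean fractions.
#' @slot best,avg,std the aggregated statistics.
#' @slot nTrees integer vector: optimal trees scored per instance.
#' @slot failed integer: instances excluded due to pipeline errors.
#'
#' @exportClass ADResult
setClass("ADResult",
    representation(scenario = "list", perInstanceBest = "numeric",
                   perInstanceMean = "numeric", best = "numeric",
                   avg = "numeric", std = "numeric", nTrees = "integer",
                   failed = "integer"))

setMethod("show", "ADResult", function(object) {
    s <- object@scenario
    cat(sprintf(
        "ADResult (c=%d, n=%d, m=%d, cov=%s, d=%d): Best=%.3f Avg=%.3f Std=%.2f over %d instances\n",
        s$c, s$n, s$m, format(s$coverage), s$d, object@best, object@avg,
        object@std, length(object@perInstanceMean)))
})

# strict ancestor matrix over clones: A[i, j] TRUE iff i is a strict
# ancestor of j
.strictAncestors <- function(parent) {
    c0 <- length(parent)
    A <- matrix(FALSE, c0, c0)
    for (j in seq_len(c0)) {
        w <- parent[j]
        while (w != 0L) {
            A[w, j] <- TRUE
            w <- parent[w]
        }
    }
    A
}

.unnameRows <- function(m) {
    rownames(m) <- NULL
    m
}

.mutationOrigin <- function(tree) {
    stats::setNames(rep(seq_along(tree@mutationsOf),
                        lengths(tree@mutationsOf)),
                    unlist(tree@mutationsOf))
}

# truth AD relation over all mutations, as a named logical matrix
.truthADMatrix <- function(tree) {
    origin <- .mutationOrigin(tree)
    muts <- colnames(tree@presence)
    A <- .strictAncestors(tree@parent)
    M <- A[origin[muts], origin[muts]]
    dimnames(M) <- list(muts, muts)
    M
}

# AD relation of an output phylogeny over the given mutation universe;
# mutations absent from the tree contribute no pairs
.outputADMatrix <- function(ptree, muts) {
    gOf <- stats::setNames(rep(seq_along(ptree@groups),
                               lengths(ptree@groups)),
                           unlist(ptree@groups))
    nodeOf <- match(seq_along(ptree@groups),
                    ptree@edgeGroup)          # node under each group's edge
    nodeAnc <- .strictAncestors(ptree@parent)
    gAnc <- nodeAnc[nodeOf, nodeOf, drop = FALSE]
    gi <- gOf[muts]
    M <- matrix(FALSE, length(muts), length(muts),
                dimnames = list(muts, muts))
    present <- !is.na(gi)
    if (any(present))
        M[present, present] <- gAnc[gi[present], gi[present]]
    M
}

#' Ancestor-descendant mutation pairs
#'
#' An AD pair is an ordered pair of mutations whose locations are in strict
#' ancestor-descendant relation; two mutations at the same node (or on the
#' same edge) are not an AD pair. For a \linkS4class{CloneTree} the location
#' is the originating clone; for a \linkS4class{PhyloTree} the edge carrying
#' the mutation's group.
#'
#' @param x a \linkS4class{CloneTree} or \linkS4class{PhyloTree}.
#' @return two-column character matrix (ancestor, descendant).
#' @export
setGeneric("adPairs", function(x) standardGeneric("adPairs"))

#' @rdname adPairs
#' @export
setMethod("adPairs", "CloneTree", function(x) {
    M <- .truthADMatrix(x)
    idx <- which(M, arr.ind = TRUE)
    .unnameRows(cbind(ancestor = rownames(M)[idx[, 1L]],
                      descendant = colnames(M)[idx[, 2L]]))
})

#' @rdname adPairs
#' @export
setMethod("adPairs", "PhyloTree", function(x) {
    muts <- unlist(x@groups, use.names = FALSE)
    M <- .outputADMatrix(x, muts)
    idx <- which(M, arr.ind = TRUE)
    .unnameRows(cbind(ancestor = rownames(M)[idx[, 1L]],
                      descendant = colnames(M)[idx[, 2L]]))
})

#' Fraction of true AD pairs preserved by an output tree
#'
#' Computes |AD(truth) intersected with AD(output)| / |AD(truth)|, over the
#' truth's mutation universe. Mutations missing from the output tree (e.g.
#' never sampled, or thresholded away) simply contribute no recovered pairs.
#'
#' @param truth a \linkS4class{CloneTree}.
#' @param output a \linkS4class{PhyloTree}.
#' @return fraction in \[0, 1\].
#' @export
adFraction <- function(truth, output) {
    tm <- .truthADMatrix(truth)
    total <- sum(tm)
    if (total == 0L)
        stop("the truth tree has no AD pairs; the fraction is undefined")
    om <- .outputADMatrix(output, rownames(tm))
    sum(tm & om) / total
}

# canonical key of a row split: per sample, the sorted set of split-row
# patterns (dedup of branchings yielding identical splits up to row order)
.splitKey <- function(rs) {
    m <- binValues(rs@matrix)
    pats <- apply(m, 1L, paste, collapse = "")
    paste(vapply(rs@partition, function(rows)
        paste(sort(pats[rows]), collapse = ";"), ""), collapse = "|")
}

#' Run the unmixing pipeline on one binary matrix and score its trees
#'
#' Solves the MUB problem, deduplicates optimal branchings that induce the
#' same row split, builds each perfect phylogeny and (optionally) scores it
#' against a truth clone tree.
#'
#' @param M a normalized \linkS4class{BinaryMatrix}.
#' @param truth optional \linkS4class{CloneTree} for scoring.
#' @param maxSolutions passed to \code{\link{solveMUB}}.
#' @return list with \code{beta}, \code{splits}, \code{trees} and, when a
#'   truth is given, \code{fractions}.
#' @export
scoreMatrix <- function(M, truth = NULL, maxSolutions = "all") {
    D <- containmentDigraph(M)
    sol <- solveMUB(D, maxSolutions)
    splits <- lapply(sol@branchings, function(b) bSplit(M, D, b))
    keys <- vapply(splits, .splitKey, "")
    splits <- splits[!duplicated(keys)]
    trees <- lapply(splits, function(s) buildPerfectPhylogeny(s@matrix))
    out <- list(beta = sol@beta, splits = splits, trees = trees,
                exhausted = sol@exhausted)
    if (!is.null(truth))
        out$fractions <- vapply(trees, adFraction, 0, truth = truth)
    out
}

#' Simulate and score one benchmark scenario
#'
#' For each instance: simulate a clonal tree and samples, draw Poisson /
#' Binomial read counts, binarize the noisy VAFs at threshold \code{t},
#' apply the weak-SSNV filter with multiplicity \code{k}, solve the MUB
#' problem enumerating optimal solutions, and score every optimal tree by
#' the fraction of true AD pairs it preserves. Aggregates Best (mean of
#' per-instance best), Avg (mean of per-instance means) and Std (standard
#' deviation of per-instance means across instances).
#'
#' @param c,n,m,coverage,d scenario parameters; \code{coverage = NA} runs
#'   the noiseless limit (true per-mutation VAFs).
#' @param nInstances number of simulated instances.
#' @param t binarization threshold.
#' @param k weak-SSNV filter multiplicity (1 disables filtering).
#' @param maxSolutions optimal-solution enumeration cap or \code{"all"}.
#' @param seed master seed; per-instance seeds are derived from it.
#' @return an \linkS4class{ADResult}.
#' @export
runBenchmark <- function(c = 10L, n = 100L, m = 5L, coverage = 100,
                         d = 0L, nInstances = 100L, t = 0.01, k = 1L,
                         maxSolutions = "all", seed = 1L) {
    set.seed(seed)
    seeds <- sample.int(.Machine$integer.max - 1L, nInstances)
    bests <- means <- numeric(0)
    nTrees <- integer(0)
    failed <- 0L
    for (i in seq_len(nInstances)) {
        res <- tryCatch({
            ds <- simulateDataset(c, n, m, coverage, d, seed = seeds[i])
            v <- datasetVAF(ds, noisy = !is.na(coverage))
            M <- binarize(v, t)
            M <- suppressWarnings(filterWeakSSNVs(M, k))
            M <- dropEmpty(M, quiet = TRUE)
            scoreMatrix(M, truth = ds@tree, maxSolutions = maxSolutions)
        }, error = function(e) e)
        if (inherits(res, "error")) {
            failed <- failed + 1L
            next
        }
        bests <- c(bests, max(res$fractions))
        means <- c(means, mean(res$fractions))
        nTrees <- c(nTrees, length(res$fractions))
    }
    if (failed > 0L)
        warning(failed, " instance(s) failed and were excluded")
    new("ADResult",
        scenario = list(c = c, n = n, m = m, coverage = coverage, d = d,
                        t = t, k = k),
        perInstanceBest = bests, perInstanceMean = means,
        best = mean(bests), avg = mean(means),
        std = stats::sd(means), nTrees = nTrees, failed = failed)
}

#' ADResult accessors
#'
#' @param x an \linkS4class{ADResult}.
#' @return numeric scalars / vectors.
#' @export
benchBest <- function(x) x@best

#' @rdname benchBest
#' @export
benchAvg <- function(x) x@avg

#' @rdname benchBest
#' @export
benchStd <- function(x) x@std

#' @rdname benchBest
#' @export
perInstanceMeans <- function(x) x@perInstanceMean

#' Write benchmark results as a TSV table
#'
#' One row per scenario with Best/Avg/Std columns, mirroring the layout of
#' published AD-pair benchmark tables.
#'
#' @param results list of \linkS4class{ADResult} objects.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeBenchmarkTSV <- function(results, path) {
    df <- do.call(rbind, lapply(results, function(r) {
        s <- r@scenario
        data.frame(d = s$d, c = s$c, n = s$n, m = s$m,
                   coverage = s$coverage, Best = round(r@best, 3),
                   Avg = round(r@avg, 3), Std = round(r@std, 2),
                   instances = length(r@perInstanceMean))
    }))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
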