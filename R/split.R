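#' @include AllClasses.R mub.R
NULL

#' Test a binary matrix for conflicts (three-gamete rule)
#'
#' Two columns are in conflict when three rows realize the patterns (1,1),
#' (1,0) and (0,1); a matrix admits a perfect phylogeny iff it is
#' conflict-free.
#'
#' @param M a \linkS4class{BinaryMatrix}.
#' @return TRUE, or FALSE with attribute \code{witness}: a list with the two
#'   column labels and three row labels realizing the forbidden pattern.
#' @export
isConflictFree <- function(M) {
    m <- binValues(M)
    n11 <- crossprod(m)                 # pairs of columns with a (1,1) row
    n10 <- crossprod(m, 1L - m)         # (1,0) rows for (col_i, col_j)
    conf <- n11 > 0 & n10 > 0 & t(n10) > 0
    diag(conf) <- FALSE
    if (!any(conf)) return(TRUE)
    ij <- which(conf, arr.ind = TRUE)[1L, ]
    i <- ij[[1L]]; j <- ij[[2L]]
    r11 <- which(m[, i] == 1L & m[, j] == 1L)[1L]
    r10 <- which(m[, i] == 1L & m[, j] == 0L)[1L]
    r01 <- which(m[, i] == 0L & m[, j] == 1L)[1L]
    out <- FALSE
    attr(out, "witness") <- list(
        columns = colnames(m)[c(i, j)],
        rows = rownames(m)[c(r11, r10, r01)])
    out
}

#' Split rows of a matrix according to a branching
#'
#' Builds the branching-induced row split: one split row per uncovered pair
#' (r, v), with a 1 in column j iff the support vertex of column j is
#' reachable from v along the branching (v itself included). The result is
#' conflict-free, has |U(B)| rows, and the bitwise OR of each sample's split
#' rows reproduces the sample's original row.
#'
#' @param M the normalized \linkS4class{BinaryMatrix}.
#' @param D its \linkS4class{ContainmentDigraph}.
#' @param B a \linkS4class{Branching} of \code{D} (not necessarily optimal).
#' @return a \linkS4class{RowSplit}.
#' @export
bSplit <- function(M, D, B) {
    .checkBranching(D, B)
    m <- binValues(M)
    k <- length(D@vertices)
    nxt <- integer(k)                    # out-arc chain of the branching
    if (nrow(B@arcs)) nxt[B@arcs[, 1L]] <- B@arcs[, 2L]
    reach <- matrix(FALSE, k, k)         # reach[v, ] = B+(v)
    for (v in seq_len(k)) {
        w <- v
        while (w != 0L && !reach[v, w]) {
            reach[v, w] <- TRUE
            w <- nxt[w]
        }
    }
    unc <- uncoveredPairs(D, B)
    colVert <- vertexOfColumn(D)[colnames(m)]
    split <- matrix(0L, nrow(unc), ncol(m),
                    dimnames = list(NULL, colnames(m)))
    for (i in seq_len(nrow(unc)))
        split[i, ] <- as.integer(reach[unc$vertex[i], colVert])
    ord <- order(match(unc$row, rownames(m)), unc$vertex)
    unc <- unc[ord, , drop = FALSE]
    split <- split[ord, , drop = FALSE]
    lab <- paste0(unc$row, "_", stats::ave(seq_len(nrow(unc)), unc$row,
                                           FUN = seq_along))
    rownames(split) <- lab
    partition <- split(lab, factor(unc$row, levels = rownames(m)))
    new("RowSplit", matrix = BinaryMatrix(split),
        partition = as.list(partition), gamma = nrow(split))
}

#' @describeIn gammaRows row count of a row split.
#' @export
setMethod("gammaRows", "RowSplit", function(x) x@gamma)

#' @rdname vafValues
#' @export
splitMatrix <- function(x) x@matrix

#' @rdname vafValues
#' @export
splitPartition <- function(x) x@partition

setMethod("show", "RowSplit", function(object) {
    cat("RowSplit:", object@gamma, "split rows over",
        length(object@partition), "samples\n")
})

#' Brute-force oracle for the minimum conflict-free row split
#'
#' Exhaustively searches conflict-free row splits by increasing total row
#' count: each sample row is replaced by a set of distinct nonzero subsets of
#' its 1-columns whose union recovers the row. Intended as an independent
#' oracle for the branching route on tiny instances.
#'
#' @param M a \linkS4class{BinaryMatrix}.
#' @param maxRows cap on the number of rows of \code{M}.
#' @param maxCols cap on the number of columns of \code{M}.
#' @return integer, the minimum number of rows of a conflict-free row split.
#' @export
bruteForceMinRowSplit <- function(M, maxRows = 3L, maxCols = 4L) {
    m <- binValues(M)
    if (nrow(m) > maxRows || ncol(m) > maxCols)
        stop(sprintf("instance is %dx%d, oracle capped at %dx%d",
                     nrow(m), ncol(m), maxRows, maxCols))
    nr <- nrow(m); nc <- ncol(m)
    suppList <- lapply(seq_len(nr), function(i) which(m[i, ] == 1L))
    if (any(lengths(suppList) == 0L)) stop("matrix must have no all-zero row")
    # distinct nonzero subsets of each row's support, as 0/1 vectors
    subsetsOf <- lapply(suppList, function(s) {
        subs <- list()
        for (sz in seq_along(s))
            subs <- c(subs, utils::combn(s, sz, simplify = FALSE))
        lapply(subs, function(ss) {
            v <- integer(nc); v[ss] <- 1L; v
        })
    })
    confFree <- function(rows) {
        mm <- do.call(rbind, rows)
        isConflictFree(BinaryMatrix(`dimnames<-`(mm,
            list(paste0("s", seq_len(nrow(mm))),
                 paste0("c", seq_len(nc))))))
    }
    # choose `cnt` distinct subsets for row i (indices into subsetsOf[[i]])
    # with union equal to the row's support
    rowChoices <- function(i, cnt) {
        subs <- subsetsOf[[i]]
        target <- m[i, ]
        out <- list()
        pick <- function(start, chosen, un) {
            if (length(chosen) == cnt) {
                if (all(un == target))
                    out[[length(out) + 1L]] <<- chosen
                return()
            }
            if (cnt - length(chosen) > length(subs) - start + 1L) return()
            for (s in start:length(subs)) {
                pick(s + 1L, c(chosen, s), pmax(un, subs[[s]]))
            }
        }
        if (cnt <= length(subs)) pick(1L, list(), integer(nc))
        out
    }
    upper <- sum(m)                     # the trivial one-row-per-one split
    for (gamma in nr:upper) {
        comps <- .compositions(gamma, nr)
        for (ci in seq_len(nrow(comps))) {
            cnt <- comps[ci, ]
            found <- FALSE
            assemble <- function(i, rows) {
                if (found) return()
                if (i > nr) {
                    found <<- TRUE
                    return()
                }
                for (ch in rowChoices(i, cnt[i])) {
                    cand <- c(rows, lapply(ch, function(s)
                        subsetsOf[[i]][[s]]))
                    # conflicts are monotone in the row set: prune early
                    if (isTRUE(confFree(cand))) assemble(i + 1L, cand)
                    if (found) return()
                }
            }
            assemble(1L, list())
            if (found) return(as.integer(gamma))
        }
    }
    as.integer(upper)
}

# compositions of n into k positive parts, one per row
.compositions <- function(n, k) {
    if (k == 1L) return(matrix(n, 1L, 1L))
    out <- NULL
    for (first in seq_len(n - k + 1L)) {
        rest <- .compositions(n - first, k - 1L)
        out <- rbind(out, cbind(first, rest))
    }
    unname(out)
}
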