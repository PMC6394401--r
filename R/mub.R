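#' @include AllClasses.R digraph.R
#' @useDynLib phyloUnmix, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Construct a Branching
#'
#' @param arcs two-column integer matrix of (from, to) vertex indices; may
#'   have zero rows (the empty branching).
#' @param nVertices number of vertices of the digraph the branching lives in.
#' @return a \linkS4class{Branching}.
#' @export
Branching <- function(arcs, nVertices) {
    arcs <- matrix(as.integer(arcs), ncol = 2L,
                   dimnames = list(NULL, c("from", "to")))
    new("Branching", arcs = arcs, nVertices = as.integer(nVertices))
}

#' @rdname digraphVertices
#' @param B a \linkS4class{Branching}.
#' @export
branchingArcs <- function(B) B@arcs

setMethod("show", "Branching", function(object) {
    cat("Branching with", nrow(object@arcs), "arcs over",
        object@nVertices, "vertices\n")
})

setMethod("show", "MUBSolution", function(object) {
    cat("MUBSolution: beta =", object@beta, "with",
        length(object@branchings), "optimal branching(s)",
        if (object@exhausted) "(exhaustive)\n" else "(truncated)\n")
})

#' @describeIn gammaRows optimum of a MUB solution.
#' @export
setMethod("betaValue", "MUBSolution", function(x) x@beta)

.checkBranching <- function(D, B) {
    a <- B@arcs
    if (nrow(a)) {
        dk <- paste(D@arcs[, 1L], D@arcs[, 2L])
        bk <- paste(a[, 1L], a[, 2L])
        if (!all(bk %in% dk))
            stop("branching contains arcs not present in the digraph")
        if (anyDuplicated(a[, 1L]))
            stop("branching violates the out-degree <= 1 constraint")
    }
    invisible(TRUE)
}

#' Uncovered pairs of a branching
#'
#' A pair (r, v) is uncovered when row r belongs to support v but to none of
#' the supports chosen as in-neighbors of v in the branching. The total count
#' over all vertices is the branching's cost; minimizing it over branchings
#' yields beta(M).
#'
#' @param D a \linkS4class{ContainmentDigraph}.
#' @param B a \linkS4class{Branching} of \code{D}.
#' @return data.frame with columns \code{row} (label) and \code{vertex}
#'   (index), one line per uncovered pair.
#' @export
uncoveredPairs <- function(D, B) {
    .checkBranching(D, B)
    rl <- D@rowLabels
    res <- lapply(seq_along(D@vertices), function(v) {
        sup <- D@vertices[[v]]
        src <- B@arcs[B@arcs[, 2L] == v, 1L]
        covered <- unique(unlist(D@vertices[src]))
        unc <- setdiff(sup, covered)
        if (length(unc))
            data.frame(row = rl[unc], vertex = v, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, res)
    if (is.null(out))
        out <- data.frame(row = character(), vertex = integer())
    out
}

#' The MUB integer program
#'
#' Builds the explicit integer linear program for the Minimum Uncovering
#' Branching problem: a binary variable x[u,v] per arc (x = 1 iff the arc is
#' in the branching), a binary variable y[r,v] per (row, vertex) incidence
#' (y = 1 iff r is uncovered in v), the objective min sum y, one packing
#' constraint per vertex (sum of outgoing x <= 1) and one covering constraint
#' per incidence (y[r,v] + sum of x[u,v] over in-neighbors u containing r
#' >= 1). The model has p = l + o variables and q = k + o constraints, where
#' k is the number of distinct columns, l the number of comparable column
#' pairs and o the number of ones in the column-deduplicated matrix.
#'
#' @param D a \linkS4class{ContainmentDigraph}.
#' @return list with \code{objective} (named 0/1 vector over variables),
#'   \code{constraints} (list of lists with \code{vars}, \code{coefs},
#'   \code{dir}, \code{rhs}) and \code{varNames}.
#' @export
mubModel <- function(D) {
    rl <- D@rowLabels
    xNames <- if (nrow(D@arcs))
        sprintf("x_%d_%d", D@arcs[, 1L], D@arcs[, 2L]) else character()
    yNames <- unlist(lapply(seq_along(D@vertices), function(v)
        sprintf("y_%s_%d", rl[D@vertices[[v]]], v)))
    varNames <- c(xNames, yNames)
    objective <- stats::setNames(rep(c(0, 1), c(length(xNames),
                                                length(yNames))), varNames)
    cons <- vector("list", 0L)
    for (u in seq_along(D@vertices)) {
        idx <- which(D@arcs[, 1L] == u)
        cons[[length(cons) + 1L]] <- list(
            vars = xNames[idx], coefs = rep(1, length(idx)),
            dir = "<=", rhs = 1, name = sprintf("outdeg_%d", u))
    }
    for (v in seq_along(D@vertices)) {
        inU <- D@arcs[D@arcs[, 2L] == v, 1L]
        for (r in D@vertices[[v]]) {
            hasR <- inU[vapply(inU, function(u) r %in% D@vertices[[u]],
                               NA)]
            xv <- sprintf("x_%d_%d", hasR, v)
            cons[[length(cons) + 1L]] <- list(
                vars = c(sprintf("y_%s_%d", rl[r], v), xv),
                coefs = rep(1, 1L + length(xv)),
                dir = ">=", rhs = 1,
                name = sprintf("cover_%s_%d", rl[r], v))
        }
    }
    list(objective = objective, constraints = cons, varNames = varNames)
}

#' Model size of the MUB integer program
#'
#' @param D a \linkS4class{ContainmentDigraph}.
#' @return list with \code{p} (variables), \code{q} (constraints), \code{k}
#'   (distinct columns), \code{ell} (comparable pairs) and \code{o} (ones in
#'   the deduplicated matrix); p = ell + o and q = k + o.
#' @export
ilpSize <- function(D) {
    k <- length(D@vertices)
    ell <- nrow(D@arcs)
    o <- sum(lengths(D@vertices))
    list(p = ell + o, q = k + o, k = k, ell = ell, o = o)
}

#' Write the MUB model in LP format
#'
#' @param model result of \code{\link{mubModel}}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeModelLP <- function(model, path) {
    obj <- names(model$objective)[model$objective != 0]
    lines <- c("Minimize", paste(" obj:", paste(obj, collapse = " + ")),
               "Subject To")
    for (cn in model$constraints) {
        if (!length(cn$vars)) next
        lines <- c(lines, sprintf(" %s: %s %s %g", cn$name,
                                  paste(cn$vars, collapse = " + "),
                                  ifelse(cn$dir == "<=", "<=", ">="),
                                  cn$rhs))
    }
    lines <- c(lines, "Binary", paste(" ", model$varNames), "End")
    writeLines(lines, path)
    invisible(path)
}

.digraphMasks <- function(D) {
    m <- length(D@rowLabels)
    if (m > 53L)
        stop("the exact solver supports at most 53 samples")
    vapply(D@vertices, function(v) sum(2^(v - 1)), 0)
}

.outArcList <- function(D) {
    k <- length(D@vertices)
    out <- rep(list(integer()), k)
    if (nrow(D@arcs))
        for (i in seq_len(nrow(D@arcs)))
            out[[D@arcs[i, 1L]]] <- c(out[[D@arcs[i, 1L]]], D@arcs[i, 2L])
    out
}

.choiceToBranching <- function(choice, k) {
    from <- which(choice > 0L)
    Branching(cbind(from, choice[from]), k)
}

#' Solve the Minimum Uncovering Branching problem exactly
#'
#' Solves the integer program of \code{\link{mubModel}} with a specialized
#' exact branch-and-bound over branchings (depth-first over the topologically
#' ordered vertices, pruning with an admissible coverage bound), then
#' enumerates optimal branchings up to \code{maxSolutions}. The cost of every
#' returned branching is recomputed combinatorially with
#' \code{\link{uncoveredPairs}} and checked against the optimum.
#'
#' @param D a \linkS4class{ContainmentDigraph}.
#' @param maxSolutions positive integer or \code{"all"}.
#' @param nodeCap search-node budget guarding against pathological instances.
#' @return a \linkS4class{MUBSolution}.
#' @export
solveMUB <- function(D, maxSolutions = "all", nodeCap = 5e7) {
    if (!length(D@vertices)) stop("digraph has no vertices")
    ms <- if (identical(maxSolutions, "all")) -1 else {
        if (!is.numeric(maxSolutions) || maxSolutions < 1)
            stop("maxSolutions must be a positive integer or \"all\"")
        as.double(maxSolutions)
    }
    res <- .mub_branch_and_bound(.digraphMasks(D), .outArcList(D),
                                 ms, nodeCap)
    k <- length(D@vertices)
    branchings <- lapply(seq_len(nrow(res$choices)), function(i)
        .choiceToBranching(res$choices[i, ], k))
    uncovered <- lapply(branchings, function(b) uncoveredPairs(D, b))
    costs <- vapply(uncovered, nrow, 1L)
    if (any(costs != res$beta))
        stop("internal error: enumerated branching cost differs from the ",
             "proven optimum")
    if (res$beta < length(D@rowLabels))
        stop("internal error: optimum below the row-count lower bound")
    new("MUBSolution", beta = as.integer(res$beta), branchings = branchings,
        uncovered = uncovered, solverStatus = "optimal",
        exhausted = isTRUE(res$exhausted))
}

#' Brute-force oracle for the MUB problem
#'
#' Exhaustively enumerates every branching (each vertex independently picks
#' one out-arc or none) and returns the exact minimum of |U(B)| together with
#' all attaining branchings. Intended as an independent test oracle for the
#' branch-and-bound solver; refuses instances whose branching count exceeds
#' \code{cap}.
#'
#' @param D a \linkS4class{ContainmentDigraph}.
#' @param cap maximum number of branchings to enumerate.
#' @return list with \code{beta} and \code{branchings}.
#' @export
bruteForceMUB <- function(D, cap = 1e6) {
    out <- .outArcList(D)
    k <- length(out)
    sizes <- lengths(out) + 1
    total <- prod(sizes)
    if (total > cap)
        stop(sprintf("instance has %g branchings, exceeding the cap of %g",
                     total, cap))
    verts <- D@vertices
    best <- Inf
    bestChoices <- list()
    counter <- rep(1L, k)
    repeat {
        cover <- rep(list(integer()), k)
        choice <- integer(k)
        for (u in seq_len(k)) {
            ci <- counter[u]
            if (ci > 1L) {
                v <- out[[u]][ci - 1L]
                choice[u] <- v
                cover[[v]] <- union(cover[[v]], verts[[u]])
            }
        }
        cost <- sum(vapply(seq_len(k), function(v)
            length(setdiff(verts[[v]], cover[[v]])), 1L))
        if (cost < best) {
            best <- cost
            bestChoices <- list(choice)
        } else if (cost == best) {
            bestChoices[[length(bestChoices) + 1L]] <- choice
        }
        pos <- 1L
        while (pos <= k) {
            counter[pos] <- counter[pos] + 1L
            if (counter[pos] <= sizes[pos]) break
            counter[pos] <- 1L
            pos <- pos + 1L
        }
        if (pos > k) break
    }
    list(beta = as.integer(best),
         branchings = lapply(bestChoices, .choiceToBranching, k = k))
}
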