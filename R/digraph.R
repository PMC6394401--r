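#' @include AllClasses.R
NULL

#' Column supports of a binary matrix
#'
#' The support of a column is the set of rows (samples) in which the SSNV is
#' present.
#'
#' @param M a \linkS4class{BinaryMatrix} (normalized: no all-zero columns).
#' @return named list of strictly increasing integer vectors, one per column.
#' @export
columnSupports <- function(M) {
    m <- binValues(M)
    res <- lapply(seq_len(ncol(m)), function(j)
        unname(which(m[, j] == 1L)))
    names(res) <- colnames(m)
    res
}

#' Build the containment digraph of a binary matrix
#'
#' Vertices are the distinct column supports; identical columns collapse into
#' one vertex whose \code{columnsOf} entry records all of them. The arc set
#' contains every proper inclusion between supports (including transitive
#' ones). Vertices are ordered by (size, lexicographic row indices), a
#' deterministic topological order used by all downstream iteration.
#'
#' @param M a normalized \linkS4class{BinaryMatrix}.
#' @return a \linkS4class{ContainmentDigraph}.
#' @export
containmentDigraph <- function(M) {
    m <- binValues(M)
    if (any(colSums(m) == 0L) || any(rowSums(m) == 0L))
        stop("matrix must be normalized (use dropEmpty) before building ",
             "the containment digraph")
    sup <- columnSupports(M)
    key <- vapply(sup, paste, "", collapse = ",")
    first <- !duplicated(key)
    verts <- unname(sup[first])
    ord <- order(lengths(verts),
                 vapply(verts, function(v) paste(sprintf("%06d", v),
                                                 collapse = ","), ""))
    verts <- verts[ord]
    vkey <- vapply(verts, paste, "", collapse = ",")
    colsOf <- lapply(vkey, function(kk) names(sup)[key == kk])
    k <- length(verts)
    arcs <- matrix(integer(), 0L, 2L)
    if (k > 1L) {
        from <- integer(); to <- integer()
        for (i in seq_len(k - 1L)) {
            vi <- verts[[i]]
            for (j in (i + 1L):k) {
                vj <- verts[[j]]
                if (length(vi) < length(vj) && all(vi %in% vj)) {
                    from <- c(from, i); to <- c(to, j)
                }
            }
        }
        arcs <- cbind(from, to)
    }
    new("ContainmentDigraph", vertices = verts,
        arcs = matrix(as.integer(arcs), ncol = 2L,
                      dimnames = list(NULL, c("from", "to"))),
        columnsOf = colsOf, rowLabels = rownames(m))
}

#' Digraph accessors
#'
#' @param D a \linkS4class{ContainmentDigraph}.
#' @return \code{digraphVertices}: list of integer supports;
#'   \code{digraphArcs}: two-column integer matrix; \code{columnsOf}: list of
#'   column-label vectors per vertex; \code{vertexOfColumn}: named integer
#'   vector mapping each column label to its vertex index.
#' @export
digraphVertices <- function(D) D@vertices

#' @rdname digraphVertices
#' @export
digraphArcs <- function(D) D@arcs

#' @rdname digraphVertices
#' @export
columnsOf <- function(D) D@columnsOf

#' @rdname digraphVertices
#' @export
vertexOfColumn <- function(D) {
    v <- rep(seq_along(D@columnsOf), lengths(D@columnsOf))
    names(v) <- unlist(D@columnsOf)
    v
}

setMethod("show", "ContainmentDigraph", function(object) {
    cat("ContainmentDigraph:", length(object@vertices), "vertices,",
        nrow(object@arcs), "arcs over", length(object@rowLabels), "rows\n")
})

#' Export a containment digraph in DOT format
#'
#' Vertices are labeled by their row sets and the columns mapping to them.
#'
#' @param D a \linkS4class{ContainmentDigraph}.
#' @param path output file; when NULL the DOT text is returned.
#' @return the DOT source, invisibly when written to a file.
#' @export
digraphDOT <- function(D, path = NULL) {
    rl <- D@rowLabels
    lab <- vapply(seq_along(D@vertices), function(i) {
        sprintf("{%s}\\n%s", paste(rl[D@vertices[[i]]], collapse = ","),
                paste(D@columnsOf[[i]], collapse = ","))
    }, "")
    lines <- c("digraph containment {",
               sprintf("  v%d [label=\"%s\"];", seq_along(lab), lab),
               if (nrow(D@arcs))
                   sprintf("  v%d -> v%d;", D@arcs[, 1L], D@arcs[, 2L]),
               "}")
    txt <- paste(lines, collapse = "\n")
    if (is.null(path)) return(txt)
    writeLines(txt, path)
    invisible(txt)
}
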