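#' @include AllClasses.R split.R
NULL

#' Build the perfect phylogeny of a conflict-free binary matrix
#'
#' Classical linear-time style construction: distinct column patterns
#' (mutation groups) are sorted by decreasing support size (ties broken by
#' first column index) and each row's sorted group sequence is inserted into
#' a trie rooted at the germline. Every group then labels exactly one edge,
#' and the groups on the root path of a row's node are exactly its
#' 1-columns. Identical rows form one equality class attached to a single
#' node. Group names "S1", "S2", ... are assigned in tree pre-order.
#'
#' @param M a conflict-free \linkS4class{BinaryMatrix} (e.g. the matrix of a
#'   \linkS4class{RowSplit}).
#' @return a \linkS4class{PhyloTree}.
#' @export
buildPerfectPhylogeny <- function(M) {
    cf <- isConflictFree(M)
    if (!isTRUE(cf)) {
        w <- attr(cf, "witness")
        stop(sprintf(paste0("matrix is not conflict-free: columns (%s, %s) ",
                            "conflict on rows (%s)"),
                     w$columns[1L], w$columns[2L],
                     paste(w$rows, collapse = ", ")))
    }
    m <- binValues(M)
    pat <- apply(m, 2L, paste, collapse = "")
    gid <- match(pat, unique(pat))
    nG <- max(gid)
    groups <- split(colnames(m), gid)[as.character(seq_len(nG))]
    gSize <- colSums(m)[match(seq_len(nG), gid)]
    gFirst <- match(seq_len(nG), gid)
    gOrder <- order(-gSize, gFirst)          # decreasing support, stable
    gRank <- match(seq_len(nG), gOrder)
    rep1 <- gFirst                            # representative column per group

    parent <- 0L
    edgeGroup <- NA_integer_
    children <- list(integer())               # per node: child node ids
    childGroup <- list(integer())             # group on the edge to each child
    rowNode <- integer(nrow(m))
    for (i in seq_len(nrow(m))) {
        gs <- unique(gid[m[i, ] == 1L])
        gs <- gs[order(gRank[gs])]
        node <- 1L
        for (g in gs) {
            hit <- children[[node]][childGroup[[node]] == g]
            if (length(hit)) {
                node <- hit
            } else {
                newNode <- length(parent) + 1L
                parent[newNode] <- node
                edgeGroup[newNode] <- g
                children[[newNode]] <- integer()
                childGroup[[newNode]] <- integer()
                children[[node]] <- c(children[[node]], newNode)
                childGroup[[node]] <- c(childGroup[[node]], g)
                node <- newNode
            }
        }
        rowNode[i] <- node
    }
    if (anyDuplicated(stats::na.omit(edgeGroup)))
        stop("internal error: a mutation group labels more than one edge")
    nodeRows <- lapply(seq_along(parent), function(v)
        rownames(m)[rowNode == v])
    # pre-order group naming
    groupName <- character(nG)
    counter <- 0L
    visit <- function(v) {
        g <- edgeGroup[v]
        if (!is.na(g)) {
            counter <<- counter + 1L
            groupName[g] <<- paste0("S", counter)
        }
        for (ch in children[[v]]) visit(ch)
    }
    visit(1L)
    new("PhyloTree", parent = parent, edgeGroup = edgeGroup,
        groups = groups, groupName = groupName,
        groupLabel = character(0), nodeRows = nodeRows,
        sampleArrows = list())
}

setMethod("show", "PhyloTree", function(object) {
    nn <- length(object@parent)
    cat("PhyloTree:", nn, "nodes,", length(object@groups),
        "mutation groups,", sum(lengths(object@groups)), "mutations\n")
})

#' PhyloTree accessors
#'
#' @param x a \linkS4class{PhyloTree}.
#' @return \code{treeGroups}: list of column labels per mutation group;
#'   \code{treeGroupNames}: the generated "S" names; \code{treeParents}:
#'   the parent vector; \code{nodeRows}: row equality classes per node.
#' @export
treeGroups <- function(x) x@groups

#' @rdname treeGroups
#' @export
treeGroupNames <- function(x) x@groupName

#' @rdname treeGroups
#' @export
treeParents <- function(x) x@parent

#' @rdname treeGroups
#' @export
nodeRows <- function(x) x@nodeRows

#' Reconstruct the matrix encoded by a perfect phylogeny
#'
#' Inverse of \code{\link{buildPerfectPhylogeny}}: for each row, the
#' 1-columns are the groups on the path from the root to the row's node.
#'
#' @param tree a \linkS4class{PhyloTree}.
#' @param rowOrder,colOrder optional label orders for the rebuilt matrix.
#' @return a \linkS4class{BinaryMatrix}.
#' @export
rebuildMatrix <- function(tree, rowOrder = NULL, colOrder = NULL) {
    cols <- unlist(tree@groups, use.names = FALSE)
    groupOfCol <- rep(seq_along(tree@groups), lengths(tree@groups))
    rows <- unlist(tree@nodeRows, use.names = FALSE)
    nodeOfRow <- rep(seq_along(tree@nodeRows), lengths(tree@nodeRows))
    m <- matrix(0L, length(rows), length(cols),
                dimnames = list(rows, cols))
    for (i in seq_along(rows)) {
        v <- nodeOfRow[i]
        gs <- integer()
        while (v != 1L) {
            gs <- c(gs, tree@edgeGroup[v])
            v <- tree@parent[v]
        }
        m[i, groupOfCol %in% gs] <- 1L
    }
    if (!is.null(rowOrder)) m <- m[rowOrder, , drop = FALSE]
    if (!is.null(colOrder)) m <- m[, colOrder, drop = FALSE]
    BinaryMatrix(m)
}

#' Annotate tree edges with VAF summary labels
#'
#' Renders each edge label as \code{S|n|mean±std} where S is the group
#' name, n the number of mutations in the group, and mean/std the mean and
#' population standard deviation of those mutations' VAF values across all
#' samples of \code{v}, both with two decimals.
#'
#' @param tree a \linkS4class{PhyloTree}.
#' @param v the \linkS4class{VAFMatrix} the matrix was derived from.
#' @return the tree with \code{groupLabel} filled in.
#' @export
labelEdges <- function(tree, v) {
    vals <- vafValues(v)
    labs <- vapply(seq_along(tree@groups), function(g) {
        muts <- tree@groups[[g]]
        if (!all(muts %in% colnames(vals)))
            stop("mutations absent from the VAF matrix: ",
                 paste(setdiff(muts, colnames(vals)), collapse = ", "))
        x <- as.vector(vals[, muts, drop = FALSE])
        mu <- mean(x)
        sdp <- sqrt(mean((x - mu)^2))     # population standard deviation
        sprintf("%s|%d|%.2f±%.2f", tree@groupName[g], length(muts),
                mu, sdp)
    }, "")
    tree@groupLabel <- labs
    tree
}

.nodeName <- function(tree, v) {
    rows <- tree@nodeRows[[v]]
    if (length(rows)) rows[1L] else sprintf("n%d", v)
}

#' Export a phylogeny (with its sample composition) in DOT format
#'
#' Mirrors the tool's tree drawings: oval nodes for split rows (one
#' representative per equality class), gray square nodes for the original
#' samples with arrows to their split rows, edge labels from
#' \code{\link{labelEdges}}, and a legend listing split-row equalities.
#'
#' @param tree a \linkS4class{PhyloTree}.
#' @param path output file; when NULL the DOT text is returned.
#' @return the DOT source, invisibly when written to a file.
#' @export
phyloDOT <- function(tree, path = NULL) {
    n <- length(tree@parent)
    lab <- vapply(seq_len(n), function(v) .nodeName(tree, v), "")
    lab[1L] <- "germline"
    nodeLines <- sprintf("  n%d [label=\"%s\", shape=oval];", seq_len(n), lab)
    edgeLines <- vapply(seq_len(n)[-1L], function(v) {
        g <- tree@edgeGroup[v]
        el <- if (length(tree@groupLabel)) tree@groupLabel[g]
              else tree@groupName[g]
        sprintf("  n%d -> n%d [label=\"%s\"];", tree@parent[v], v, el)
    }, "")
    sampleLines <- character()
    arrowLines <- character()
    if (length(tree@sampleArrows)) {
        reps <- stats::setNames(
            rep(vapply(seq_len(n), function(v) .nodeName(tree, v), ""),
                lengths(tree@nodeRows)),
            unlist(tree@nodeRows))
        nodeOf <- stats::setNames(
            rep(seq_len(n), lengths(tree@nodeRows)), unlist(tree@nodeRows))
        sampleLines <- sprintf(
            "  s_%s [label=\"%s\", shape=box, style=filled, fillcolor=gray];",
            names(tree@sampleArrows), names(tree@sampleArrows))
        arrowLines <- unlist(lapply(names(tree@sampleArrows), function(s)
            sprintf("  s_%s -> n%d [style=dashed];", s,
                    unique(nodeOf[tree@sampleArrows[[s]]]))))
    }
    legend <- character()
    eq <- tree@nodeRows[lengths(tree@nodeRows) > 1L]
    if (length(eq))
        legend <- sprintf(
            "  legend [shape=note, label=\"%s\"];",
            paste(vapply(eq, paste, "", collapse = " = "),
                  collapse = "\\n"))
    txt <- paste(c("digraph phylogeny {", nodeLines, edgeLines,
                   sampleLines, arrowLines, legend, "}"), collapse = "\n")
    if (is.null(path)) return(txt)
    writeLines(txt, path)
    invisible(txt)
}

#' Export a phylogeny as a Newick string
#'
#' Node names are the representative split rows; edge labels are carried in
#' Newick comments (\code{[&label=...]}) attached to each node.
#'
#' @param tree a \linkS4class{PhyloTree}.
#' @param path optional output file.
#' @return the Newick string, invisibly when written to a file.
#' @export
phyloNewick <- function(tree, path = NULL) {
    n <- length(tree@parent)
    children <- lapply(seq_len(n), function(v) which(tree@parent == v))
    rec <- function(v) {
        kids <- children[[v]]
        inner <- if (length(kids))
            paste0("(", paste(vapply(kids, rec, ""), collapse = ","), ")")
        else ""
        nm <- if (v == 1L) "germline" else .nodeName(tree, v)
        cm <- if (v == 1L) "" else {
            g <- tree@edgeGroup[v]
            el <- if (length(tree@groupLabel)) tree@groupLabel[g]
                  else tree@groupName[g]
            sprintf("[&label=%s]", el)
        }
        paste0(inner, nm, cm)
    }
    txt <- paste0(rec(1L), ";")
    if (is.null(path)) return(txt)
    writeLines(txt, path)
    invisible(txt)
}

#' Convert a PhyloTree to an ape phylo object
#'
#' Tips are the childless nodes; internal node labels carry the
#' representative split rows. Unit branch lengths.
#'
#' @param tree a \linkS4class{PhyloTree}.
#' @return an \code{ape} \code{phylo} object.
#' @export
asPhylo <- function(tree) {
    n <- length(tree@parent)
    isTip <- !(seq_len(n) %in% tree@parent)
    if (sum(isTip) < 2L || n < 3L) {
        # ape requires >= 2 tips; degenerate chains fall back to a cherry
        # with a placeholder zero-length tip
        stop("tree too small for phylo conversion; use phyloNewick()")
    }
    tipId <- integer(n); tipId[isTip] <- seq_len(sum(isTip))
    intId <- integer(n); intId[!isTip] <- sum(isTip) + seq_len(sum(!isTip))
    id <- ifelse(isTip, tipId, intId)
    edge <- cbind(id[tree@parent[-1L]], id[-1L])
    phy <- list(edge = edge,
                tip.label = vapply(which(isTip), function(v)
                    .nodeName(tree, v), ""),
                node.label = vapply(which(!isTip), function(v)
                    if (v == 1L) "germline" else .nodeName(tree, v), ""),
                Nnode = sum(!isTip),
                edge.length = rep(1, nrow(edge)))
    class(phy) <- "phylo"
    ape::reorder.phylo(phy)
}

#' Write the mutation-group membership file
#'
#' Maps each generated group name to the SSNV identifiers it contains, one
#' group per line.
#'
#' @param tree a \linkS4class{PhyloTree}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeMutationGroups <- function(tree, path) {
    ord <- order(as.integer(sub("^S", "", tree@groupName)))
    lines <- vapply(ord, function(g)
        paste0(tree@groupName[g], "\t",
               paste(tree@groups[[g]], collapse = ",")), "")
    writeLines(lines, path)
    invisible(path)
}
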