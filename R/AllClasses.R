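#' @import methods
NULL

#' VAF matrix of somatic variants across tumor samples
#'
#' Holds variant allele frequencies (VAFs) as fractions in \[0, 1\], with one
#' row per sequencing sample and one column per somatic single nucleotide
#' variant (SSNV). Column metadata (chromosome, position, description) is kept
#' alongside; the column names of \code{vaf} are the working SSNV identifiers.
#'
#' @slot vaf numeric matrix, samples x SSNVs, values in \[0, 1\], complete.
#' @slot mutationInfo data.frame with columns \code{chrom}, \code{pos},
#'   \code{description}, one row per SSNV, row names equal to
#'   \code{colnames(vaf)}.
#'
#' @exportClass VAFMatrix
setClass("VAFMatrix",
    representation(vaf = "matrix", mutationInfo = "data.frame"))

setValidity("VAFMatrix", function(object) {
    v <- object@vaf
    msg <- character()
    if (!is.numeric(v)) msg <- c(msg, "'vaf' must be numeric")
    if (anyNA(v)) msg <- c(msg, "'vaf' contains missing values")
    else if (length(v) && (min(v) < 0 || max(v) > 1))
        msg <- c(msg, "VAF values must lie in [0, 1]")
    if (is.null(rownames(v)) || anyDuplicated(rownames(v)))
        msg <- c(msg, "sample names must be present and distinct")
    if (is.null(colnames(v)) || anyDuplicated(colnames(v)))
        msg <- c(msg, "SSNV identifiers must be present and distinct")
    if (nrow(object@mutationInfo) != ncol(v))
        msg <- c(msg, "mutationInfo must have one row per SSNV")
    if (length(msg)) msg else TRUE
})

#' Binary presence/absence matrix
#'
#' A 0/1 matrix with samples as rows and SSNVs as columns, typically obtained
#' by thresholding a \linkS4class{VAFMatrix}. All-zero rows/columns are
#' permitted until \code{\link{dropEmpty}} is applied; downstream analysis
#' requires the normalized form.
#'
#' @slot mat integer matrix of 0s and 1s with distinct row and column names.
#'
#' @exportClass BinaryMatrix
setClass("BinaryMatrix", representation(mat = "matrix"))

setValidity("BinaryMatrix", function(object) {
    m <- object@mat
    msg <- character()
    if (!all(m %in% c(0L, 1L))) msg <- c(msg, "entries must be 0 or 1")
    if (nrow(m) && (is.null(rownames(m)) || anyDuplicated(rownames(m))))
        msg <- c(msg, "row labels must be present and distinct")
    if (ncol(m) && (is.null(colnames(m)) || anyDuplicated(colnames(m))))
        msg <- c(msg, "column labels must be present and distinct")
    if (length(msg)) msg else TRUE
})

#' Containment digraph over distinct column supports
#'
#' Vertices are the distinct column supports of a binary matrix (sets of row
#' indices); there is an arc (u, v) for every proper inclusion u < v. The full
#' proper-inclusion arc set is kept (not a transitive reduction): a branching
#' allows one out-arc per vertex, so dropping transitive arcs could change the
#' optimum. Vertices are ordered by (support size, lexicographic row indices),
#' which is a topological order.
#'
#' @slot vertices list of strictly increasing integer vectors (row indices).
#' @slot arcs two-column integer matrix of (from, to) vertex indices.
#' @slot columnsOf list, per vertex, of the column labels sharing that support.
#' @slot rowLabels character vector of the underlying matrix row labels.
#'
#' @exportClass ContainmentDigraph
setClass("ContainmentDigraph",
    representation(vertices = "list", arcs = "matrix",
                   columnsOf = "list", rowLabels = "character"))

setValidity("ContainmentDigraph", function(object) {
    msg <- character()
    k <- length(object@vertices)
    if (length(object@columnsOf) != k)
        msg <- c(msg, "columnsOf must map every vertex")
    if (ncol(object@arcs) != 2)
        msg <- c(msg, "arcs must have two columns")
    if (nrow(object@arcs)) {
        a <- object@arcs
        if (any(a < 1L) || any(a > k)) msg <- c(msg, "arc endpoints out of range")
        else {
            ok <- vapply(seq_len(nrow(a)), function(i) {
                u <- object@vertices[[a[i, 1L]]]
                v <- object@vertices[[a[i, 2L]]]
                length(u) < length(v) && all(u %in% v)
            }, logical(1))
            if (!all(ok)) msg <- c(msg, "every arc must be a proper inclusion")
        }
    }
    if (any(vapply(object@vertices, length, 1L) == 0L))
        msg <- c(msg, "vertex supports must be non-empty")
    if (length(msg)) msg else TRUE
})

#' Branching of a containment digraph
#'
#' A subset of the digraph's arcs in which every vertex has out-degree at most
#' one. The empty arc set is always a valid branching.
#'
#' @slot arcs two-column integer matrix of (from, to) vertex indices.
#' @slot nVertices integer, number of vertices of the digraph it belongs to.
#'
#' @exportClass Branching
setClass("Branching",
    representation(arcs = "matrix", nVertices = "integer"))

setValidity("Branching", function(object) {
    a <- object@arcs
    msg <- character()
    if (ncol(a) != 2) msg <- c(msg, "arcs must have two columns")
    else if (nrow(a) && anyDuplicated(a[, 1L]))
        msg <- c(msg, "a branching allows at most one out-arc per vertex")
    if (length(msg)) msg else TRUE
})

#' Solution of the Minimum Uncovering Branching problem
#'
#' @slot beta integer, the optimum |U(B)| over all branchings.
#' @slot branchings list of \linkS4class{Branching} objects attaining beta.
#' @slot uncovered list, per branching, of two-column matrices of
#'   (row label, vertex index) uncovered pairs.
#' @slot solverStatus character, e.g. "optimal".
#' @slot exhausted logical, TRUE if all optimal branchings were enumerated.
#'
#' @exportClass MUBSolution
setClass("MUBSolution",
    representation(beta = "integer", branchings = "list", uncovered = "list",
                   solverStatus = "character", exhausted = "logical"))

#' Conflict-free row split of a binary matrix
#'
#' @slot matrix the split \linkS4class{BinaryMatrix} (rows are subclones).
#' @slot partition named list mapping each original sample to the labels of
#'   its split rows; the bitwise OR of those rows equals the sample's row.
#' @slot gamma integer, total number of split rows.
#'
#' @exportClass RowSplit
setClass("RowSplit",
    representation(matrix = "BinaryMatrix", partition = "list",
                   gamma = "integer"))

#' Perfect phylogeny of a conflict-free binary matrix
#'
#' Rooted tree in which every distinct mutation group (set of identical
#' columns) labels exactly one edge, and each matrix row maps to the node
#' whose root path carries exactly its 1-columns. Identical rows form an
#' equality class represented by a single node.
#'
#' @slot parent integer vector over nodes; node 1 is the root with parent 0.
#' @slot edgeGroup integer vector: group id on the edge entering each node
#'   (NA for the root).
#' @slot groups list of character vectors: column labels per group id.
#' @slot groupName character vector of generated group names ("S1", ...).
#' @slot groupLabel character vector of rendered edge labels
#'   ("S|n|mean+-std"), empty until \code{\link{labelEdges}} is applied.
#' @slot nodeRows list, per node, of the row labels whose path ends there
#'   (an equality class; empty for unlabeled internal nodes).
#' @slot sampleArrows named list mapping samples to split-row labels (set by
#'   the pipeline when the matrix came from a row split).
#'
#' @exportClass PhyloTree
setClass("PhyloTree",
    representation(parent = "integer", edgeGroup = "integer",
                   groups = "list", groupName = "character",
                   groupLabel = "character", nodeRows = "list",
                   sampleArrows = "list"))

setValidity("PhyloTree", function(object) {
    p <- object@parent
    msg <- character()
    if (length(p) && p[1L] != 0L) msg <- c(msg, "node 1 must be the root")
    if (length(p) > 1 && any(p[-1L] >= seq_along(p)[-1L] | p[-1L] < 1L))
        msg <- c(msg, "parents must precede children")
    if (length(object@nodeRows) != length(p))
        msg <- c(msg, "nodeRows must have one entry per node")
    if (length(msg)) msg else TRUE
})

#' Simulated clonal tree
#'
#' A random rooted tree of tumor clones with mutation assignments, per-clone
#' cell population sizes, and optional loss-of-mutation events that suppress
#' the propagation of a mutation from a clone to one child's whole subtree
#' (violating the infinite-sites assumption).
#'
#' @slot parent integer vector over clones; the root has parent 0.
#' @slot root integer, the root clone index.
#' @slot mutationsOf list of character vectors: mutations originating in each
#'   clone (every clone gets at least one).
#' @slot populations integer vector of per-clone cell counts in \[100, 200\].
#' @slot presence logical matrix clones x mutations after loss events.
#' @slot lossEvents data.frame with columns \code{clone}, \code{child},
#'   \code{mutation}: the applied loss events.
#'
#' @exportClass CloneTree
setClass("CloneTree",
    representation(parent = "integer", root = "integer",
                   mutationsOf = "list", populations = "integer",
                   presence = "matrix", lossEvents = "data.frame"))

setValidity("CloneTree", function(object) {
    msg <- character()
    c0 <- length(object@parent)
    if (sum(object@parent == 0L) != 1L)
        msg <- c(msg, "exactly one root (parent 0) required")
    if (object@parent[object@root] != 0L)
        msg <- c(msg, "root slot must point at the parentless clone")
    if (any(vapply(object@mutationsOf, length, 1L) == 0L))
        msg <- c(msg, "every clone must originate at least one mutation")
    if (length(object@populations) != c0 ||
        any(object@populations < 100L) || any(object@populations > 200L))
        msg <- c(msg, "populations must be integers in [100, 200]")
    if (nrow(object@presence) != c0)
        msg <- c(msg, "presence must have one row per clone")
    if (length(msg)) msg else TRUE
})

#' Simulated multi-sample sequencing dataset
#'
#' @slot tree the underlying \linkS4class{CloneTree}.
#' @slot samples list of integer vectors: the clones mixed in each sample.
#' @slot U usage matrix (samples x clones), rows sum to 1 over the selected
#'   clones.
#' @slot clonal c x c 0/1 matrix: entry (i, j) is 1 iff clone i equals or
#'   descends from clone j.
#' @slot F true per-clone VAF matrix, F = U \%*\% clonal / 2.
#' @slot Funpack per-mutation true VAF matrix (samples x mutations).
#' @slot reads total read counts (Poisson), samples x mutations.
#' @slot variantReads variant-allele read counts (Binomial).
#' @slot noisyVAF variantReads / reads, with 0 where reads == 0.
#' @slot coverage numeric, the Poisson mean; NA before reads are simulated.
#'
#' @exportClass SimulatedDataset
setClass("SimulatedDataset",
    representation(tree = "CloneTree", samples = "list", U = "matrix",
                   clonal = "matrix", F = "matrix", Funpack = "matrix",
                   reads = "matrix", variantReads = "matrix",
                   noisyVAF = "matrix", coverage = "numeric"))

setValidity("SimulatedDataset", function(object) {
    msg <- character()
    if (nrow(object@U) != length(object@samples))
        msg <- c(msg, "U must have one row per sample")
    if (length(object@U) &&
        max(abs(rowSums(object@U) - 1)) > 1e-8)
        msg <- c(msg, "rows of U must sum to 1")
    if (length(object@F) && (min(object@F) < 0 || max(object@F) > 0.5 + 1e-12))
        msg <- c(msg, "true VAFs must lie in [0, 1/2]")
    if (length(object@reads) &&
        any(object@variantReads > object@reads))
        msg <- c(msg, "variant reads cannot exceed total reads")
    if (length(msg)) msg else TRUE
})
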