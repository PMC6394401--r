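#' @include evaluate.R
NULL

#' Run the full unmixing pipeline on a VAF table
#'
#' Reads the tab-separated VAF table, binarizes at threshold \code{t},
#' removes weak SSNVs (pattern multiplicity < \code{k}), normalizes, solves
#' the Minimum Uncovering Branching problem and writes, for every optimal
#' (deduplicated) solution: the split-matrix TSV, a DOT rendering of the
#' perfect phylogeny with sample composition arrows, a Newick string and the
#' mutation-group membership file. A JSON manifest records the parameters,
#' the optimum beta = gamma, the solution count and the model size.
#'
#' @param input path to the VAF TSV.
#' @param outdir output directory (created if needed).
#' @param t binarization threshold in (0, 1].
#' @param k weak-SSNV filter multiplicity (>= 1; 1 disables filtering).
#' @param maxSolutions positive integer or "all".
#' @param excludeColumns sample columns to drop (e.g. a matched normal).
#' @param seed optional seed recorded in the manifest (the pipeline itself
#'   is deterministic).
#' @return invisibly, a list with the solution objects and output paths.
#' @export
runUnmix <- function(input, outdir, t, k = 1L, maxSolutions = "all",
                     excludeColumns = character(), seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    v <- readVAFTable(input, excludeColumns)
    M <- binarize(v, t)
    M <- filterWeakSSNVs(M, k)
    M <- dropEmpty(M)
    D <- containmentDigraph(M)
    size <- ilpSize(D)
    res <- scoreMatrix(M, maxSolutions = maxSolutions)
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    paths <- vector("list", length(res$splits))
    for (i in seq_along(res$splits)) {
        rs <- res$splits[[i]]
        tree <- labelEdges(res$trees[[i]], v)
        tree@sampleArrows <- rs@partition
        base <- file.path(outdir, sprintf("solution%d", i))
        writeBinaryMatrix(rs@matrix, paste0(base, "_split.tsv"))
        phyloDOT(tree, paste0(base, "_tree.dot"))
        phyloNewick(tree, paste0(base, "_tree.nwk"))
        writeMutationGroups(tree, paste0(base, "_groups.txt"))
        paths[[i]] <- paste0(base, c("_split.tsv", "_tree.dot",
                                     "_tree.nwk", "_groups.txt"))
    }
    manifest <- list(
        input = input, threshold = t, minClusterSize = k,
        maxSolutions = if (identical(maxSolutions, "all")) "all"
                       else maxSolutions,
        excludeColumns = excludeColumns, seed = seed,
        samples = nrow(vafValues(v)), ssnvs = ncol(vafValues(v)),
        beta = res$beta, gamma = res$beta,
        nSolutions = length(res$splits),
        enumerationExhausted = res$exhausted,
        ilp = size, timestamp = format(Sys.time(), tz = "UTC"))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(list(vaf = v, matrix = M, digraph = D, result = res,
                   manifest = manifest, paths = paths))
}
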