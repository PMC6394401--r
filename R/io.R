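#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a VAFMatrix
#'
#' @param vaf numeric matrix, samples x SSNVs, values in \[0, 1\]; must carry
#'   row and column names.
#' @param mutationInfo optional data.frame (chrom, pos, description) with one
#'   row per SSNV; a placeholder is synthesized when omitted.
#' @return a \linkS4class{VAFMatrix}.
#' @export
VAFMatrix <- function(vaf, mutationInfo = NULL) {
    if (is.null(mutationInfo)) {
        mutationInfo <- data.frame(
            chrom = rep(".", ncol(vaf)), pos = seq_len(ncol(vaf)),
            description = colnames(vaf), row.names = colnames(vaf),
            stringsAsFactors = FALSE)
    }
    new("VAFMatrix", vaf = vaf, mutationInfo = mutationInfo)
}

#' Construct a BinaryMatrix
#'
#' @param mat 0/1 matrix with distinct row and column names (integer storage
#'   is enforced).
#' @return a \linkS4class{BinaryMatrix}.
#' @export
BinaryMatrix <- function(mat) {
    storage.mode(mat) <- "integer"
    new("BinaryMatrix", mat = mat)
}

#' Accessors for matrix containers
#'
#' \code{vafValues} and \code{binValues} return the underlying numeric and
#' integer matrices; \code{mutationInfo} the SSNV metadata.
#'
#' @param x a \linkS4class{VAFMatrix} or \linkS4class{BinaryMatrix}.
#' @return matrix or data.frame.
#' @export
vafValues <- function(x) x@vaf

#' @rdname vafValues
#' @export
binValues <- function(x) x@mat

#' @rdname vafValues
#' @export
mutationInfo <- function(x) x@mutationInfo

setMethod("show", "VAFMatrix", function(object) {
    cat("VAFMatrix:", nrow(object@vaf), "samples x", ncol(object@vaf),
        "SSNVs\n")
    cat("  samples:", paste(utils::head(rownames(object@vaf), 5),
        collapse = ", "),
        if (nrow(object@vaf) > 5) "...\n" else "\n")
})

setMethod("show", "BinaryMatrix", function(object) {
    cat("BinaryMatrix:", nrow(object@mat), "rows x", ncol(object@mat),
        "columns,", sum(object@mat), "ones\n")
})

#' Read a tab-separated multi-sample VAF table
#'
#' The expected dialect has a header line (optionally starting with '#')
#' naming three metadata columns (chromosome, position, description) followed
#' by one column per sample, and one data line per SSNV with a numeric VAF
#' fraction per sample. The returned matrix is transposed to samples x SSNVs.
#'
#' Duplicate SSNV identifiers are disambiguated with a numeric suffix;
#' duplicate sample names are an error. Values outside \[0, 1\] (e.g.
#' percentages) are rejected rather than rescaled.
#'
#' @param path path to the TSV file.
#' @param excludeColumns character vector of sample column names to drop
#'   (e.g. a matched normal sample).
#' @return a \linkS4class{VAFMatrix}.
#' @export
readVAFTable <- function(path, excludeColumns = character()) {
    if (!file.exists(path)) stop("input file not found: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) < 2L) stop("VAF table needs a header and data lines")
    header <- sub("^#", "", lines[[1L]])
    fields <- strsplit(header, "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 4L)
        stop("header must name 3 metadata columns plus at least one sample")
    sampleCols <- fields[-(1:3)]
    nf <- length(fields)
    body <- strsplit(lines[-1L], "\t", fixed = TRUE)
    bad <- which(lengths(body) != nf)
    if (length(bad))
        stop(sprintf("line %d has %d fields, expected %d",
                     bad[1L] + 1L, lengths(body)[bad[1L]], nf))
    meta <- do.call(rbind, lapply(body, function(f) f[1:3]))
    vals <- do.call(rbind, lapply(body, function(f)
        suppressWarnings(as.numeric(f[-(1:3)]))))
    if (anyNA(vals)) {
        idx <- which(is.na(vals), arr.ind = TRUE)[1L, ]
        stop(sprintf("non-numeric VAF at line %d, sample '%s'",
                     idx[1L] + 1L, sampleCols[idx[2L]]))
    }
    out <- which(vals < 0 | vals > 1, arr.ind = TRUE)
    if (nrow(out))
        stop(sprintf(
            "VAF %g at line %d, sample '%s' is outside [0, 1]; %s",
            vals[out[1L, , drop = FALSE]], out[1L, 1L] + 1L,
            sampleCols[out[1L, 2L]],
            "percent-scale tables must be converted to fractions"))
    ids <- ifelse(nzchar(meta[, 3L]) & meta[, 3L] != ".",
                  meta[, 3L], paste0(meta[, 1L], ":", meta[, 2L]))
    ids <- make.unique(ids, sep = "_")
    if (anyDuplicated(sampleCols))
        stop("duplicate sample names in header: ",
             paste(unique(sampleCols[duplicated(sampleCols)]), collapse = ", "))
    vaf <- t(vals)
    dimnames(vaf) <- list(sampleCols, ids)
    info <- data.frame(chrom = meta[, 1L], pos = meta[, 2L],
                       description = meta[, 3L], row.names = ids,
                       stringsAsFactors = FALSE)
    keep <- !(rownames(vaf) %in% excludeColumns)
    VAFMatrix(vaf[keep, , drop = FALSE], info)
}

#' @describeIn binarize entry (i, j) becomes 1 iff the VAF is >= \code{t}
#'   (the boundary is inclusive).
#' @export
setMethod("binarize", "VAFMatrix", function(x, t) {
    if (!is.numeric(t) || length(t) != 1L || t <= 0 || t > 1)
        stop("threshold t must be a single value in (0, 1]")
    BinaryMatrix((x@vaf >= t) * 1L)
})

#' Remove weak SSNVs
#'
#' Drops every column whose presence/absence pattern across samples occurs
#' strictly fewer than \code{k} times among all columns (the minClusterSize
#' heuristic); \code{k = 1} keeps everything.
#'
#' @param M a \linkS4class{BinaryMatrix}.
#' @param k positive integer minimum pattern multiplicity.
#' @return a \linkS4class{BinaryMatrix} with the surviving columns.
#' @export
filterWeakSSNVs <- function(M, k) {
    if (!is.numeric(k) || length(k) != 1L || k < 1 || k != floor(k))
        stop("k must be a positive integer")
    m <- binValues(M)
    pat <- apply(m, 2L, paste, collapse = "")
    keep <- table(pat)[pat] >= k
    if (!any(keep))
        warning("all SSNV columns removed by the weak-SSNV filter (k = ",
                k, ")")
    BinaryMatrix(m[, keep, drop = FALSE])
}

#' Drop all-zero rows and columns
#'
#' Normalizes a binary matrix by removing samples with no present SSNV and
#' SSNVs present in no sample, reporting each dropped label. Idempotent.
#'
#' @param M a \linkS4class{BinaryMatrix}.
#' @param quiet suppress the per-label messages.
#' @return the normalized \linkS4class{BinaryMatrix}.
#' @export
dropEmpty <- function(M, quiet = FALSE) {
    m <- binValues(M)
    rk <- rowSums(m) > 0L
    ck <- colSums(m) > 0L
    if (!quiet) {
        for (r in rownames(m)[!rk]) message("dropping all-zero row: ", r)
        for (c0 in colnames(m)[!ck]) message("dropping all-zero column: ", c0)
    }
    m <- m[rk, ck, drop = FALSE]
    if (nrow(m) == 0L || ncol(m) == 0L)
        stop("matrix is empty after removing all-zero rows/columns")
    BinaryMatrix(m)
}

#' Write a binary matrix as TSV
#'
#' Rows are samples, the header carries the SSNV identifiers, entries are
#' written as 0/1 characters.
#'
#' @param M a \linkS4class{BinaryMatrix}.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeBinaryMatrix <- function(M, path) {
    m <- binValues(M)
    df <- data.frame(sample = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
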