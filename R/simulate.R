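#' @include AllClasses.R io.R
NULL

# decode a Prufer sequence over labels 1..c into an undirected edge list
.decodePrufer <- function(pr, c) {
    if (c == 2L) return(matrix(c(1L, 2L), 1L, 2L))
    degree <- tabulate(pr, c) + 1L
    edges <- matrix(0L, c - 1L, 2L)
    for (i in seq_along(pr)) {
        leaf <- which(degree == 1L)[1L]
        edges[i, ] <- c(leaf, pr[i])
        degree[leaf] <- 0L
        degree[pr[i]] <- degree[pr[i]] - 1L
    }
    edges[c - 1L, ] <- which(degree >= 1L)
    edges
}

# parent vector (root has 0) from an undirected edge list and a root
.rootTree <- function(edges, root, c) {
    adj <- rep(list(integer()), c)
    for (i in seq_len(nrow(edges))) {
        a <- edges[i, 1L]; b <- edges[i, 2L]
        adj[[a]] <- c(adj[[a]], b)
        adj[[b]] <- c(adj[[b]], a)
    }
    parent <- rep(NA_integer_, c)
    parent[root] <- 0L
    queue <- root
    while (length(queue)) {
        v <- queue[1L]; queue <- queue[-1L]
        for (w in adj[[v]]) if (is.na(parent[w])) {
            parent[w] <- v
            queue <- c(queue, w)
        }
    }
    parent
}

.descendantsOf <- function(parent) {
    c0 <- length(parent)
    desc <- lapply(seq_len(c0), function(v) v)   # self included
    for (v in order(-.depths(parent)))           # deepest first
        if (parent[v] != 0L)
            desc[[parent[v]]] <- c(desc[[parent[v]]], desc[[v]])
    lapply(desc, sort)
}

.depths <- function(parent) {
    d <- integer(length(parent))
    for (v in seq_along(parent)) {
        w <- v
        while (parent[w] != 0L) {
            d[v] <- d[v] + 1L
            w <- parent[w]
        }
    }
    d
}

#' Simulate a random clonal tree
#'
#' Draws a uniformly random labeled tree on \code{c} clones (via a uniform
#' Prufer sequence), roots it at a uniformly chosen clone, assigns \code{n}
#' mutations (one forced per clone so every clone originates at least one,
#' the remaining n - c uniformly), draws per-clone cell populations uniformly
#' from 100..200, and applies \code{d} loss-of-mutation events. A loss event
#' picks, uniformly among eligible triples, a clone v, a child u and a
#' mutation currently present at both v and u, and removes the mutation from
#' u's whole subtree. If eligibility is exhausted before \code{d} events, the
#' achieved number is recorded in \code{lossEvents}.
#'
#' @param c number of clones (>= 2).
#' @param n number of mutations (>= c).
#' @param d number of loss events (0..9).
#' @param seed optional integer seed.
#' @return a \linkS4class{CloneTree}.
#' @export
randomCloneTree <- function(c, n, d = 0L, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    if (c < 2L) stop("need at least 2 clones")
    if (n < c) stop("n < c: cannot give each clone at least one mutation")
    if (d < 0L || d > 9L) stop("d must be between 0 and 9")
    pr <- if (c > 2L) sample.int(c, c - 2L, replace = TRUE) else integer()
    edges <- .decodePrufer(pr, c)
    root <- sample.int(c, 1L)
    parent <- .rootTree(edges, root, c)
    muts <- paste0("m", seq_len(n))
    assign <- integer(n)
    forced <- sample.int(n, c)
    assign[forced] <- seq_len(c)
    rest <- setdiff(seq_len(n), forced)
    assign[rest] <- sample.int(c, length(rest), replace = TRUE)
    mutationsOf <- split(muts, factor(assign, levels = seq_len(c)))
    names(mutationsOf) <- paste0("clone", seq_len(c))
    populations <- sample(100:200, c, replace = TRUE)
    desc <- .descendantsOf(parent)
    presence <- matrix(FALSE, c, n,
                       dimnames = list(paste0("clone", seq_len(c)), muts))
    for (v in seq_len(c))
        presence[desc[[v]], assign == v] <- TRUE
    loss <- data.frame(clone = integer(), child = integer(),
                       mutation = character(), stringsAsFactors = FALSE)
    if (d > 0L) {
        childrenOf <- lapply(seq_len(c), function(v) which(parent == v))
        for (ev in seq_len(d)) {
            elig <- do.call(rbind, lapply(seq_len(c), function(v) {
                kids <- childrenOf[[v]]
                if (!length(kids)) return(NULL)
                do.call(rbind, lapply(kids, function(u) {
                    mm <- which(presence[v, ] & presence[u, ])
                    if (length(mm)) cbind(v, u, mm) else NULL
                }))
            }))
            if (is.null(elig) || nrow(elig) == 0L) break
            pick <- elig[sample.int(nrow(elig), 1L), ]
            presence[desc[[pick[2L]]], pick[3L]] <- FALSE
            loss <- rbind(loss, data.frame(
                clone = pick[1L], child = pick[2L],
                mutation = muts[pick[3L]], stringsAsFactors = FALSE))
        }
    }
    new("CloneTree", parent = parent, root = root,
        mutationsOf = mutationsOf,
        populations = as.integer(populations), presence = presence,
        lossEvents = loss)
}

#' CloneTree accessors
#'
#' @param x a \linkS4class{CloneTree}.
#' @return \code{cloneParents}: parent vector; \code{cloneMutations}: list of
#'   originating mutations per clone; \code{clonePopulations}: cell counts;
#'   \code{mutationPresence}: clones x mutations logical matrix after losses.
#' @export
cloneParents <- function(x) x@parent

#' @rdname cloneParents
#' @export
cloneMutations <- function(x) x@mutationsOf

#' @rdname cloneParents
#' @export
clonePopulations <- function(x) x@populations

#' @rdname cloneParents
#' @export
mutationPresence <- function(x) x@presence

setMethod("show", "CloneTree", function(object) {
    cat("CloneTree:", length(object@parent), "clones,",
        ncol(object@presence), "mutations,",
        nrow(object@lossEvents), "loss event(s)\n")
})

#' Draw samples and build the usage/clonal/VAF matrices
#'
#' Each sample mixes a uniformly chosen set of 2-4 clones (capped at the
#' clone count) and includes all their cells and mutations. The usage matrix
#' U holds cell fractions (populations normalized within the sample), the
#' clonal matrix has a 1 at (i, j) iff clone i equals or descends from clone
#' j, and the true VAF matrix is F = U clonal / 2 (diploid heterozygous
#' variants). The per-mutation matrix Funpack is computed from the
#' post-loss presence profiles, which for d = 0 coincides with copying
#' column k of F for every mutation of clone k.
#'
#' @param tree a \linkS4class{CloneTree}.
#' @param m number of samples.
#' @param seed optional integer seed.
#' @return a \linkS4class{SimulatedDataset} without read counts.
#' @export
drawSamples <- function(tree, m, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    if (m < 1L) stop("need at least one sample")
    c0 <- length(tree@parent)
    desc <- .descendantsOf(tree@parent)
    clonal <- matrix(0L, c0, c0,
                     dimnames = list(rownames(tree@presence),
                                     rownames(tree@presence)))
    for (j in seq_len(c0)) clonal[desc[[j]], j] <- 1L
    samples <- vector("list", m)
    U <- matrix(0, m, c0,
                dimnames = list(paste0("r", seq_len(m)),
                                rownames(tree@presence)))
    for (i in seq_len(m)) {
        sz <- min(sample(2:4, 1L), c0)
        sel <- sort(sample.int(c0, sz))
        samples[[i]] <- sel
        U[i, sel] <- tree@populations[sel] / sum(tree@populations[sel])
    }
    Fmat <- U %*% clonal / 2
    Funpack <- (U %*% tree@presence) / 2
    dimnames(Funpack) <- list(rownames(U), colnames(tree@presence))
    new("SimulatedDataset", tree = tree, samples = samples, U = U,
        clonal = clonal, F = Fmat, Funpack = Funpack,
        reads = matrix(numeric(), 0L, 0L),
        variantReads = matrix(numeric(), 0L, 0L),
        noisyVAF = matrix(numeric(), 0L, 0L), coverage = NA_real_)
}

#' Simulate read counts over a dataset
#'
#' Total reads per (sample, mutation) cell are Poisson with mean
#' \code{coverage}; variant reads are Binomial with the cell's true VAF.
#' Noisy VAFs are variant/total with 0 substituted where the total is 0 (the
#' conservative absent call).
#'
#' @param ds a \linkS4class{SimulatedDataset}.
#' @param coverage Poisson mean read depth (> 0).
#' @param seed optional integer seed.
#' @return the dataset with \code{reads}, \code{variantReads} and
#'   \code{noisyVAF} filled in.
#' @export
simulateReads <- function(ds, coverage, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    if (coverage <= 0) stop("coverage must be positive")
    dm <- dim(ds@Funpack)
    y <- matrix(stats::rpois(prod(dm), coverage), dm[1L], dm[2L],
                dimnames = dimnames(ds@Funpack))
    x <- matrix(stats::rbinom(prod(dm), y, ds@Funpack), dm[1L], dm[2L],
                dimnames = dimnames(ds@Funpack))
    nv <- ifelse(y > 0, x / pmax(y, 1L), 0)
    ds@reads <- y
    ds@variantReads <- x
    ds@noisyVAF <- nv
    ds@coverage <- coverage
    ds
}

#' One-call dataset simulation
#'
#' Convenience wrapper: clone tree, samples and (optionally) read counts in
#' one deterministic stream.
#'
#' @param c,n,m,d scenario parameters (clones, mutations, samples, losses).
#' @param coverage Poisson read depth, or NA to skip read simulation (the
#'   noiseless limit: \code{noisyVAF} left empty, use \code{Funpack}).
#' @param seed optional integer seed for the whole stream.
#' @return a \linkS4class{SimulatedDataset}.
#' @export
simulateDataset <- function(c, n, m, coverage = NA, d = 0L, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    tree <- randomCloneTree(c, n, d)
    ds <- drawSamples(tree, m)
    if (!is.na(coverage)) ds <- simulateReads(ds, coverage)
    ds
}

setMethod("show", "SimulatedDataset", function(object) {
    cat("SimulatedDataset:", nrow(object@U), "samples,",
        ncol(object@U), "clones,", ncol(object@Funpack), "mutations,",
        if (is.na(object@coverage)) "no reads\n"
        else paste0("coverage ", object@coverage, "\n"))
})

#' Extract the (noisy) VAF matrix of a simulated dataset
#'
#' @param ds a \linkS4class{SimulatedDataset}.
#' @param noisy use the read-count derived VAFs (default) rather than the
#'   true per-mutation VAFs.
#' @return a \linkS4class{VAFMatrix}.
#' @export
datasetVAF <- function(ds, noisy = TRUE) {
    v <- if (noisy && length(ds@noisyVAF)) ds@noisyVAF else ds@Funpack
    muts <- colnames(v)
    VAFMatrix(v, data.frame(chrom = "chr1", pos = seq_along(muts),
                            description = muts, row.names = muts,
                            stringsAsFactors = FALSE))
}

#' Write a VAF matrix in the tool's input dialect
#'
#' One line per SSNV: chromosome, position, description, then one VAF column
#' per sample; tab-separated with a '#'-prefixed header.
#'
#' @param v a \linkS4class{VAFMatrix}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeVAFTable <- function(v, path) {
    vals <- vafValues(v)
    info <- mutationInfo(v)
    header <- paste(c("#chr", "position", "description", rownames(vals)),
                    collapse = "\t")
    body <- vapply(seq_len(ncol(vals)), function(j)
        paste(c(info$chrom[j], info$pos[j], info$description[j],
                format(vals[, j], trim = TRUE, scientific = FALSE,
                       digits = 15)),
              collapse = "\t"), "")
    writeLines(c(header, body), path)
    invisible(path)
}

#' Write the simulation ground truth as plain text
#'
#' Records the rooted tree edges, mutation assignment, populations, applied
#' loss events and sample compositions in a line-oriented format.
#'
#' @param ds a \linkS4class{SimulatedDataset}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeTruth <- function(ds, path) {
    tree <- ds@tree
    c0 <- length(tree@parent)
    lines <- c(
        sprintf("root\t%d", tree@root),
        sprintf("edge\t%d\t%d", tree@parent[tree@parent != 0L],
                which(tree@parent != 0L)),
        sprintf("mutations\t%d\t%s", seq_len(c0),
                vapply(tree@mutationsOf, paste, "", collapse = ",")),
        sprintf("population\t%d\t%d", seq_len(c0), tree@populations),
        if (nrow(tree@lossEvents))
            sprintf("loss\t%d\t%d\t%s", tree@lossEvents$clone,
                    tree@lossEvents$child, tree@lossEvents$mutation),
        sprintf("sample\t%s\t%s", rownames(ds@U),
                vapply(ds@samples, paste, "", collapse = ",")))
    writeLines(lines, path)
    invisible(path)
}
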