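#' @include AllClasses.R
NULL

#' Threshold a VAF matrix into presence/absence calls
#'
#' @param x a \linkS4class{VAFMatrix}.
#' @param t threshold in (0, 1]; an entry is called present when its VAF is
#'   greater than or equal to \code{t}.
#' @return a \linkS4class{BinaryMatrix}.
#' @export
setGeneric("binarize", function(x, t) standardGeneric("binarize"))

#' Number of split rows / optimum accessors
#'
#' \code{gammaRows} returns the row count of a \linkS4class{RowSplit};
#' \code{betaValue} the optimum of a \linkS4class{MUBSolution}.
#'
#' @param x object.
#' @return integer scalar.
#' @export
setGeneric("gammaRows", function(x) standardGeneric("gammaRows"))

#' @rdname gammaRows
#' @export
setGeneric("betaValue", function(x) standardGeneric("betaValue"))
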