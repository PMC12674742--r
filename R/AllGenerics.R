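#' Accessors for modrots result objects
#'
#' @param x a \code{\linkS4class{ModROTSResults}} (or, where noted, a
#'   \code{\linkS4class{VariancePrior}}).
#' @param ... additional arguments passed to methods.
#'
#' @return \code{deTable} returns the per-feature \code{DataFrame};
#'   \code{optAlpha} the optimized \eqn{(\alpha_1, \alpha_2)} pair;
#'   \code{optK} the optimized top-list size; \code{reproSurface} the
#'   \code{\linkS4class{ReproSurface}}; \code{variancePrior} the
#'   \code{\linkS4class{VariancePrior}}; \code{significantFeatures} the
#'   identifiers of features below the FDR cutoff; \code{priorDf} and
#'   \code{priorVar} the prior parameters.
#'
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("deTable", function(x, ...) standardGeneric("deTable"))

#' @rdname accessors
#' @export
setGeneric("optAlpha", function(x, ...) standardGeneric("optAlpha"))

#' @rdname accessors
#' @export
setGeneric("optK", function(x, ...) standardGeneric("optK"))

#' @rdname accessors
#' @export
setGeneric("reproSurface", function(x, ...) standardGeneric("reproSurface"))

#' @rdname accessors
#' @export
setGeneric("variancePrior", function(x, ...) standardGeneric("variancePrior"))

#' @rdname accessors
#' @param cutoff optional FDR cutoff overriding the one stored in the object.
#' @export
setGeneric("significantFeatures",
    function(x, cutoff = NULL, ...) standardGeneric("significantFeatures"))

#' @rdname accessors
#' @export
setGeneric("priorDf", function(x) standardGeneric("priorDf"))

#' @rdname accessors
#' @export
setGeneric("priorVar", function(x) standardGeneric("priorVar"))

#' Run the reproducibility-optimized moderated differential expression test
#'
#' @param x a features x samples numeric matrix of log2 intensities (with
#'   feature identifiers as rownames and sample identifiers as colnames), or a
#'   \code{SummarizedExperiment} whose first assay holds such a matrix.
#' @param ... arguments passed to methods; see
#'   \code{\link{modROTS,matrix-method}}.
#'
#' @export
setGeneric("modROTS", function(x, ...) standardGeneric("modROTS"))
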