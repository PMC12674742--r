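#' @rdname accessors
#' @export
setMethod("deTable", "ModROTSResults", function(x, ...) x@results)

#' @rdname accessors
#' @export
setMethod("optAlpha", "ModROTSResults",
    function(x, ...) c(alpha1 = x@alpha[1L], alpha2 = x@alpha[2L]))

#' @rdname accessors
#' @export
setMethod("optK", "ModROTSResults", function(x, ...) x@k)

#' @rdname accessors
#' @export
setMethod("reproSurface", "ModROTSResults", function(x, ...) x@surface)

#' @rdname accessors
#' @export
setMethod("variancePrior", "ModROTSResults", function(x, ...) x@prior)

#' @rdname accessors
#' @export
setMethod("significantFeatures", "ModROTSResults",
    function(x, cutoff = NULL, ...) {
        if (is.null(cutoff)) cutoff <- x@fdrCutoff
        x@results$feature_id[x@results$qvalue < cutoff]
    })

#' @rdname accessors
#' @export
setMethod("priorDf", "VariancePrior", function(x) x@priorDf)

#' @rdname accessors
#' @export
setMethod("priorVar", "VariancePrior", function(x) x@priorVar)

setMethod("show", "VariancePrior", function(object) {
    cat("VariancePrior: f0 =", format(object@priorDf),
        ", s0^2 =", format(object@priorVar), "\n")
})

setMethod("show", "ReproSurface", function(object) {
    cat("ReproSurface:", length(object@alpha1), "alpha pairs x",
        length(object@k), "top-list sizes\n")
    zf <- object@Z[is.finite(object@Z)]
    if (length(zf))
        cat("  Z range:", format(min(zf), digits = 4), "..",
            format(max(zf), digits = 4),
            sprintf(" (%d sentinel cells)\n", sum(!is.finite(object@Z))))
})

setMethod("show", "ModROTSResults", function(object) {
    cat("ModROTSResults with", nrow(object@results), "features\n")
    cat(sprintf("  optimized alpha = (%g, %g), k = %d, Z = %.3f\n",
        object@alpha[1L], object@alpha[2L], object@k, object@bestZ))
    cat(sprintf("  prior: f0 = %g, s0^2 = %g; u = %g, df = %g\n",
        object@prior@priorDf, object@prior@priorVar, object@u, object@df))
    cat(sprintf("  B = %d bootstrap pairs, P = %d permutations, seed = %d\n",
        object@B, object@P, object@seed))
    cat(sprintf("  %d features significant at adjusted p < %g\n",
        sum(object@results$significant), object@fdrCutoff))
})
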