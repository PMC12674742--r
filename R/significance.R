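#' Empirical p-values against a pooled permutation null
#'
#' Two-sided empirical p-values with the add-one (permutation-inclusive)
#' convention: \eqn{p_i = (1 + \#\{z : |z| \ge |d_i|\}) / (1 + N)}, where the
#' null pool collects the statistics of all features across all permuted
#' datasets. Guaranteed \eqn{p \in [1/(1+N), 1]}.
#'
#' @param observed numeric vector of observed statistics.
#' @param nullPool numeric vector of null statistics (pooled across features
#'   and permutations; non-empty).
#'
#' @return numeric vector of p-values, one per observed statistic.
#'
#' @export
empiricalPValues <- function(observed, nullPool) {
    if (length(nullPool) < 1L)
        .stopValidation("empty null pool")
    if (any(!is.finite(observed)) || any(!is.finite(nullPool)))
        .stopValidation("statistics must be finite")
    N <- length(nullPool)
    sorted <- sort(abs(nullPool))
    ## #{|z| >= |o|} = N - #{|z| < |o|}; left.open counts strict inequality
    below <- findInterval(abs(observed), sorted, left.open = TRUE)
    (1 + (N - below)) / (1 + N)
}

#' Adjust p-values for multiple testing
#'
#' Benjamini-Hochberg step-up by default (via \code{stats::p.adjust});
#' \code{method = "storey"} additionally scales by the null-proportion
#' estimate \eqn{\hat\pi_0 = \min(1, \mathrm{mean}(p > \lambda)/(1-\lambda))}
#' at \eqn{\lambda = 0.5} for a q-value-style estimator.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @param method \code{"BH"} (default) or \code{"storey"}.
#' @param lambda tuning parameter of the Storey null-proportion estimate.
#'
#' @return numeric vector of adjusted values, order-preserving in \code{p}.
#'
#' @export
adjustPValues <- function(p, method = c("BH", "storey"), lambda = 0.5) {
    method <- match.arg(method)
    if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
        .stopValidation("p-values must lie in (0, 1]")
    q <- stats::p.adjust(p, method = "BH")
    if (method == "storey") {
        pi0 <- min(1, mean(p > lambda) / (1 - lambda))
        q <- pmin(1, q * pi0)
    }
    q
}

## Align a metadata table to the expression columns by sample id (first
## metadata column or rownames), never by position.
.alignMetadata <- function(expr, metadata) {
    sids <- colnames(expr)
    if (is.null(sids))
        .stopValidation("expression matrix must have sample identifiers as colnames")
    ids <- NULL
    if (!is.null(rownames(metadata)) &&
        !identical(rownames(metadata), as.character(seq_len(nrow(metadata)))))
        ids <- rownames(metadata)
    if (is.null(ids) || !all(sids %in% ids)) {
        cand <- as.character(metadata[[1L]])
        if (all(sids %in% cand)) {
            ids <- cand
            metadata <- metadata[, -1L, drop = FALSE]
        }
    }
    if (is.null(ids))
        .stopValidation("metadata must carry sample ids (rownames or first column)")
    if (anyDuplicated(ids))
        .stopValidation("duplicated sample ids in metadata")
    unmatchedE <- setdiff(sids, ids)
    if (length(unmatchedE))
        .stopValidation("samples missing from metadata: %s",
            paste(unmatchedE, collapse = ", "))
    metadata <- metadata[match(sids, ids), , drop = FALSE]
    rownames(metadata) <- sids
    metadata
}

## Pooled null statistics at a fixed alpha: refit under each label
## permutation (covariates fixed), shrink with the global prior, collect d.
.permutationNullPool <- function(expr, design, prior, alpha, permPlan) {
    pool <- vector("list", permPlan$P)
    ctr <- design@contrast
    for (p in seq_len(permPlan$P)) {
        Xp <- .designMatrixWithCondition(design, permPlan$labels[[p]])
        st <- .lsStats(expr, Xp, ctr)
        sTilde <- sqrt(posteriorVariance(st$s2, st$df, prior))
        denom <- alpha[1L] + alpha[2L] * (st$u * sTilde)
        pool[[p]] <- st$betaHat / denom
    }
    unlist(pool, use.names = FALSE)
}

#' @describeIn modROTS on a features x samples log2 matrix plus a sample
#'   metadata table.
#'
#' @param metadata data.frame of sample metadata; rows are matched to the
#'   columns of \code{x} by sample id (rownames or first column), never by
#'   position.
#' @param condition name of the metadata column holding the tested condition.
#' @param covariates character vector of metadata columns to adjust for.
#' @param referenceLevel,contrastLevel condition levels defining the tested
#'   coefficient; see \code{\link{buildDesign}}.
#' @param B number of bootstrap pairs (default 1000).
#' @param P number of label permutations for the significance null
#'   (default \code{B}).
#' @param seed integer master seed; all resampling derives from it.
#' @param fdrCutoff adjusted-p cutoff used for the \code{significant} calls
#'   (default 0.05).
#' @param alphaGrid,kGrid lattice overrides; see \code{\link{defaultAlphaGrid}}
#'   and \code{\link{defaultKGrid}}.
#' @param verbose print progress messages.
#'
#' @return a \code{\linkS4class{ModROTSResults}}.
#'
#' @examples
#' sim <- simulateSpikeIn(nFeatures = 60, nPerGroup = c(4, 4),
#'                        deFraction = 0.1, seed = 7)
#' res <- modROTS(sim, condition = "condition", B = 5, P = 5, seed = 1)
#' head(deTable(res))
#'
#' @export
setMethod("modROTS", "matrix",
    function(x, metadata, condition, covariates = character(),
             referenceLevel = NULL, contrastLevel = NULL,
             B = 1000L, P = B, seed = 1L, fdrCutoff = 0.05,
             alphaGrid = NULL, kGrid = NULL, verbose = FALSE) {
    .validateExpression(x)
    if (!(fdrCutoff > 0 && fdrCutoff < 1))
        .stopConfig("fdrCutoff must lie in (0, 1)")
    metadata <- .alignMetadata(x, metadata)
    design <- buildDesign(metadata, condition, covariates,
        referenceLevel = referenceLevel, contrastLevel = contrastLevel)

    if (verbose) message("fitting feature-wise linear models")
    fit <- fitFeatureModels(x, design)
    prior <- estimatePrior(fit@s2, fit@df)
    if (verbose) message(sprintf("variance prior: f0 = %g, s0^2 = %g",
        prior@priorDf, prior@priorVar))

    if (is.null(alphaGrid)) alphaGrid <- defaultAlphaGrid()
    alphaGrid <- as.matrix(alphaGrid)
    if (is.null(kGrid)) kGrid <- defaultKGrid(nrow(x))

    bootPlan <- makeBootstrapPairs(design@condition, B,
        .deriveSeed(seed, 1L))
    nullPlan <- makeNullPairs(design@condition, B, .deriveSeed(seed, 2L))
    if (verbose) message(sprintf(
        "computing reproducibility surface (%d alpha pairs x %d k values, B = %d)",
        nrow(alphaGrid), length(kGrid), B))
    surface <- reproducibilitySurface(x, design, prior,
        alphaGrid = alphaGrid, kGrid = kGrid,
        bootPlan = bootPlan, nullPlan = nullPlan)
    opt <- optimizeSurface(surface)
    if (verbose) message(sprintf(
        "optimum: alpha = (%g, %g), k = %d, Z = %.3f",
        opt$alpha[1L], opt$alpha[2L], opt$k, opt$z))

    sTilde <- sqrt(posteriorVariance(fit@s2, fit@df, prior))
    stat <- moderatedStatistic(fit@betaHat, fit@u, sTilde,
        opt$alpha[1L], opt$alpha[2L])

    permPlan <- makePermutations(design@condition, P, .deriveSeed(seed, 3L))
    if (verbose) message(sprintf(
        "building pooled permutation null (%d permutations%s)",
        permPlan$P, if (permPlan$exhaustive) ", exhaustive" else ""))
    pool <- .permutationNullPool(x, design, prior, opt$alpha, permPlan)
    pvalue <- empiricalPValues(stat$d, pool)
    qvalue <- adjustPValues(pvalue, method = "BH")

    results <- DataFrame(
        feature_id = fit@featureIds,
        effect_log2fc = fit@betaHat,
        d_opt = stat$d,
        pvalue = pvalue,
        qvalue = qvalue,
        significant = qvalue < fdrCutoff
    )
    new("ModROTSResults", results = results,
        alpha = unname(opt$alpha), k = as.integer(opt$k), bestZ = opt$z,
        surface = surface, prior = prior, u = fit@u, df = fit@df,
        B = as.integer(B), P = as.integer(permPlan$P),
        seed = as.integer(seed), fdrCutoff = fdrCutoff)
})

#' @describeIn modROTS on a \code{SummarizedExperiment}; the first assay is
#'   the log2 matrix and \code{colData} supplies the metadata.
#' @export
setMethod("modROTS", "SummarizedExperiment",
    function(x, ...) {
    expr <- SummarizedExperiment::assay(x, 1L)
    md <- as.data.frame(SummarizedExperiment::colData(x))
    if (is.null(colnames(expr)))
        .stopValidation("SummarizedExperiment must have column names")
    modROTS(expr, metadata = md, ...)
})
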