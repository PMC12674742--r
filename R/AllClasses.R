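#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' Design specification for a tested contrast
#'
#' Holds the design matrix \eqn{X}, the contrast vector \eqn{c} selecting the
#' coefficient under test, the condition factor that defines the resampling
#' strata, and bookkeeping needed to rebuild the condition columns under label
#' permutations. Construct with \code{\link{buildDesign}}.
#'
#' @slot X numeric design matrix, samples x coefficients (intercept,
#'   treatment-coded condition columns, covariate columns).
#' @slot contrast numeric contrast vector of length \code{ncol(X)}.
#' @slot condition factor of length \code{nrow(X)}; the variable being tested.
#' @slot covariateNames character, names of adjustment covariates in the model.
#' @slot conditionColumns integer indices of the condition dummy columns in
#'   \code{X}, one per non-reference level (in level order).
#'
#' @exportClass DesignSpec
setClass("DesignSpec",
    representation(
        X = "matrix",
        contrast = "numeric",
        condition = "factor",
        covariateNames = "character",
        conditionColumns = "integer"
    )
)

setValidity("DesignSpec", function(object) {
    X <- object@X
    msg <- character()
    if (!is.numeric(X)) msg <- c(msg, "X must be numeric")
    if (length(object@contrast) != ncol(X))
        msg <- c(msg, "contrast length must equal ncol(X)")
    if (all(object@contrast == 0))
        msg <- c(msg, "contrast must not be the zero vector")
    if (length(object@condition) != nrow(X))
        msg <- c(msg, "condition length must equal nrow(X)")
    tab <- table(object@condition)
    if (any(tab < 2L))
        msg <- c(msg, sprintf("every condition level needs >= 2 samples (%s)",
            paste(names(tab)[tab < 2L], collapse = ", ")))
    r <- qr(X)$rank
    if (r < ncol(X)) msg <- c(msg, "design matrix is rank deficient")
    if (nrow(X) - r < 1L)
        msg <- c(msg, "no residual degrees of freedom (saturated design)")
    if (length(msg)) msg else TRUE
})

#' Per-feature linear-model summaries
#'
#' Output of \code{\link{fitFeatureModels}}: the contrast effect
#' \eqn{\hat\beta_i} (log2 fold change), observed residual variance
#' \eqn{s_i^2}, the shared residual degrees of freedom \eqn{f = n -
#' \mathrm{rank}(X)}, and the unscaled standard deviation
#' \eqn{u = \sqrt{c^T (X^T X)^{-1} c}} which depends on the design only.
#'
#' @slot betaHat numeric, contrast effect per feature (log2 fold change).
#' @slot s2 numeric, observed residual variance per feature.
#' @slot df numeric scalar, residual degrees of freedom.
#' @slot u numeric scalar, unscaled standard deviation of the contrast.
#' @slot featureIds character feature identifiers.
#'
#' @exportClass FeatureFit
setClass("FeatureFit",
    representation(
        betaHat = "numeric",
        s2 = "numeric",
        df = "numeric",
        u = "numeric",
        featureIds = "character"
    )
)

setValidity("FeatureFit", function(object) {
    msg <- character()
    G <- length(object@betaHat)
    if (length(object@s2) != G) msg <- c(msg, "s2 length mismatch")
    if (length(object@featureIds) != G) msg <- c(msg, "featureIds length mismatch")
    if (any(object@s2 < 0)) msg <- c(msg, "s2 must be nonnegative")
    if (length(object@df) != 1L || object@df < 1)
        msg <- c(msg, "df must be a scalar >= 1")
    if (length(object@u) != 1L || !(object@u > 0))
        msg <- c(msg, "u must be a positive scalar")
    if (length(msg)) msg else TRUE
})

#' Global variance prior
#'
#' The inverse-chi-square prior on residual variances, parameterized by prior
#' degrees of freedom \code{priorDf} (possibly \code{Inf}) and prior variance
#' \code{priorVar}, estimated from all features by
#' \code{\link{estimatePrior}}.
#'
#' @slot priorDf numeric scalar, prior degrees of freedom (> 0 or Inf; 0 is
#'   admitted as a boundary probe meaning "no shrinkage").
#' @slot priorVar numeric scalar, prior variance (> 0).
#'
#' @exportClass VariancePrior
setClass("VariancePrior",
    representation(priorDf = "numeric", priorVar = "numeric")
)

setValidity("VariancePrior", function(object) {
    msg <- character()
    if (length(object@priorDf) != 1L || is.na(object@priorDf) ||
        object@priorDf < 0)
        msg <- c(msg, "priorDf must be a nonnegative scalar (possibly Inf)")
    if (length(object@priorVar) != 1L || !is.finite(object@priorVar) ||
        object@priorVar <= 0)
        msg <- c(msg, "priorVar must be a positive finite scalar")
    if (length(msg)) msg else TRUE
})

#' Reproducibility surface over the (alpha, k) lattice
#'
#' For every scaling pair \eqn{(\alpha_1, \alpha_2)} (rows) and top-list size
#' \eqn{k} (columns): the mean bootstrap reproducibility \code{R}, the null
#' reproducibility \code{R0} from permuted-label data, the bootstrap standard
#' deviation \code{S}, and the standardized score \code{Z = (R - R0)/S}
#' (\code{-Inf} sentinel where \code{S == 0}).
#'
#' @slot alpha1,alpha2 numeric vectors defining the lattice rows.
#' @slot k integer vector of top-list sizes (strictly increasing).
#' @slot R,R0,S,Z numeric matrices, \code{length(alpha1)} x \code{length(k)}.
#'
#' @exportClass ReproSurface
setClass("ReproSurface",
    representation(
        alpha1 = "numeric", alpha2 = "numeric", k = "integer",
        R = "matrix", R0 = "matrix", S = "matrix", Z = "matrix"
    )
)

setValidity("ReproSurface", function(object) {
    msg <- character()
    nA <- length(object@alpha1)
    nK <- length(object@k)
    if (length(object@alpha2) != nA) msg <- c(msg, "alpha2 length mismatch")
    for (nm in c("R", "R0", "S", "Z")) {
        m <- slot(object, nm)
        if (!all(dim(m) == c(nA, nK)))
            msg <- c(msg, sprintf("%s must be %d x %d", nm, nA, nK))
    }
    if (nK && (is.unsorted(object@k, strictly = TRUE) || any(object@k < 1L)))
        msg <- c(msg, "k must be strictly increasing positive integers")
    if (any(object@R < 0 | object@R > 1)) msg <- c(msg, "R outside [0, 1]")
    if (any(object@R0 < 0 | object@R0 > 1)) msg <- c(msg, "R0 outside [0, 1]")
    if (any(object@S < 0)) msg <- c(msg, "S must be nonnegative")
    if (any(object@alpha1 < 0) || any(object@alpha2 < 0) ||
        any(object@alpha1 == 0 & object@alpha2 == 0))
        msg <- c(msg, "alpha pairs must be nonnegative and not both zero")
    if (length(msg)) msg else TRUE
})

#' Differential expression results
#'
#' Container returned by \code{\link{modROTS}}: the per-feature result table
#' plus the optimized scaling parameters, the reproducibility surface, the
#' variance prior and the run parameters. Use \code{\link{deTable}},
#' \code{\link{optAlpha}}, \code{\link{optK}}, \code{\link{reproSurface}},
#' \code{\link{variancePrior}} and \code{\link{significantFeatures}} to
#' access the pieces.
#'
#' @slot results a \code{DataFrame} with columns \code{feature_id},
#'   \code{effect_log2fc}, \code{d_opt}, \code{pvalue}, \code{qvalue},
#'   \code{significant}.
#' @slot alpha numeric length-2 vector, the optimized \eqn{(\alpha_1,\alpha_2)}.
#' @slot k integer scalar, the optimized top-list size.
#' @slot bestZ numeric scalar, the maximal standardized reproducibility.
#' @slot surface \code{\linkS4class{ReproSurface}}.
#' @slot prior \code{\linkS4class{VariancePrior}}.
#' @slot u numeric scalar, unscaled standard deviation of the tested contrast.
#' @slot df numeric scalar, residual degrees of freedom.
#' @slot B,P integer scalars, number of bootstrap pairs / permutations.
#' @slot seed integer scalar, master seed of the run.
#' @slot fdrCutoff numeric scalar, significance cutoff on the adjusted p-value.
#'
#' @exportClass ModROTSResults
setClass("ModROTSResults",
    representation(
        results = "DataFrame",
        alpha = "numeric",
        k = "integer",
        bestZ = "numeric",
        surface = "ReproSurface",
        prior = "VariancePrior",
        u = "numeric",
        df = "numeric",
        B = "integer",
        P = "integer",
        seed = "integer",
        fdrCutoff = "numeric"
    )
)

setValidity("ModROTSResults", function(object) {
    msg <- character()
    need <- c("feature_id", "effect_log2fc", "d_opt", "pvalue", "qvalue",
        "significant")
    if (!all(need %in% colnames(object@results)))
        msg <- c(msg, "results must contain the standard columns")
    if (length(object@alpha) != 2L) msg <- c(msg, "alpha must have length 2")
    if (length(msg)) msg else TRUE
})
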