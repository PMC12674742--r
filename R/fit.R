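## Feature-wise linear models. The hot loop fits all features against one
## design with a single QR decomposition (multi-response least squares).

## Core engine shared by the observed fit and every bootstrap/permutation
## refit. Y is features x samples, X is samples x coefficients, contrast a
## vector over the columns of X. Tolerates rank-deficient refit designs (a
## covariate level can vanish from a bootstrap resample): aliased columns are
## dropped, provided the contrast does not load on them.
.lsStats <- function(Y, X, contrast) {
    n <- ncol(Y)
    fit <- stats::lm.fit(X, t(Y))
    r <- fit$rank
    f <- n - r
    if (f < 1L)
        .stopValidation("saturated design: no residual degrees of freedom")
    piv <- fit$qr$pivot
    used <- piv[seq_len(r)]
    if (r < ncol(X)) {
        dropped <- piv[(r + 1L):ncol(X)]
        if (any(contrast[dropped] != 0))
            .stopValidation("contrast is not estimable: tested coefficient aliased")
    }
    coefs <- fit$coefficients            # p x G (or vector if G == 1)
    if (is.null(dim(coefs))) coefs <- matrix(coefs, ncol = 1L)
    coefs[is.na(coefs)] <- 0
    betaHat <- as.numeric(contrast %*% coefs)
    res <- fit$residuals
    if (is.null(dim(res))) res <- matrix(res, ncol = 1L)
    rss <- colSums(res^2)
    ## an exact fit leaves only rounding residue; count it as zero variance
    rss[rss <= 1e-12 * pmax(rowSums(Y^2), 1)] <- 0
    s2 <- rss / f
    ## u^2 = c' (X'X)^{-1} c via the R factor of the (pivoted) QR
    R <- qr.R(fit$qr)[seq_len(r), seq_len(r), drop = FALSE]
    z <- backsolve(R, contrast[used], transpose = TRUE)
    u <- sqrt(sum(z^2))
    if (!(u > 0))
        .stopValidation("unscaled standard deviation is zero: contrast lies outside the design")
    list(betaHat = unname(betaHat), s2 = unname(s2), df = as.numeric(f),
         u = u)
}

#' Fit feature-wise linear models
#'
#' Fits the same linear model to every feature by ordinary least squares
#' (one orthogonal decomposition of the design, reused across features) and
#' extracts the contrast effect \eqn{\hat\beta_i = c^T\hat\beta}, the observed
#' residual variance \eqn{s_i^2 = \mathrm{RSS}_i / f} with shared residual
#' degrees of freedom \eqn{f = n - \mathrm{rank}(X)}, and the unscaled
#' standard deviation \eqn{u = \sqrt{c^T (X^T X)^{-1} c}}, which depends only
#' on the design and contrast.
#'
#' @param expr numeric matrix of log2 intensities, features x samples,
#'   complete (no missing or non-finite values), with feature identifiers as
#'   rownames.
#' @param design a \code{\linkS4class{DesignSpec}} whose rows align with the
#'   columns of \code{expr}.
#'
#' @return a \code{\linkS4class{FeatureFit}}.
#'
#' @examples
#' md <- data.frame(group = rep(c("A", "B"), each = 3))
#' des <- buildDesign(md, "group")
#' y <- matrix(rnorm(60), 10, 6,
#'             dimnames = list(paste0("p", 1:10), paste0("s", 1:6)))
#' fit <- fitFeatureModels(y, des)
#'
#' @export
fitFeatureModels <- function(expr, design) {
    .validateExpression(expr)
    if (!is(design, "DesignSpec"))
        .stopConfig("design must be a DesignSpec")
    if (ncol(expr) != nrow(design@X))
        .stopValidation("expression has %d samples but design has %d rows",
            ncol(expr), nrow(design@X))
    st <- .lsStats(expr, design@X, design@contrast)
    new("FeatureFit", betaHat = st$betaHat, s2 = st$s2, df = st$df,
        u = st$u, featureIds = rownames(expr))
}
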