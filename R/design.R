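#' Build a design matrix and contrast from sample metadata
#'
#' Constructs the linear-model design for a tested condition with optional
#' adjustment covariates: an intercept, treatment-coded condition columns
#' (reference level dropped), treatment-coded categorical covariates and
#' mean-centered numeric covariates. The contrast selects a single condition
#' coefficient (by default, the second level versus the reference).
#'
#' @param metadata data.frame with one row per sample, in sample order.
#' @param condition name of the metadata column holding the tested condition
#'   (at least two levels, each with at least two samples).
#' @param covariates character vector of metadata column names to adjust for
#'   (categorical columns are treatment-coded; numeric columns are centered).
#' @param referenceLevel condition level to use as reference (default: first
#'   level of \code{factor(metadata[[condition]])}).
#' @param contrastLevel condition level whose coefficient (versus the
#'   reference) is tested (default: the first non-reference level).
#'
#' @return a \code{\linkS4class{DesignSpec}}.
#'
#' @examples
#' md <- data.frame(group = rep(c("A", "B"), each = 3),
#'                  batch = rep(c("b1", "b2"), 3))
#' buildDesign(md, "group", covariates = "batch")
#'
#' @export
buildDesign <- function(metadata, condition, covariates = character(),
                        referenceLevel = NULL, contrastLevel = NULL) {
    if (!is.data.frame(metadata))
        .stopConfig("metadata must be a data.frame")
    if (!condition %in% colnames(metadata))
        .stopConfig("condition column '%s' not found in metadata", condition)
    missing <- setdiff(covariates, colnames(metadata))
    if (length(missing))
        .stopConfig("covariate column(s) not found in metadata: %s",
            paste(missing, collapse = ", "))
    if (condition %in% covariates)
        .stopConfig("'%s' cannot be both the condition and a covariate",
            condition)

    cond <- factor(metadata[[condition]])
    if (nlevels(cond) < 2L)
        .stopValidation("condition '%s' must have at least 2 levels", condition)
    if (!is.null(referenceLevel)) {
        if (!referenceLevel %in% levels(cond))
            .stopConfig("reference level '%s' is not a level of '%s'",
                referenceLevel, condition)
        cond <- stats::relevel(cond, ref = referenceLevel)
    }
    tab <- table(cond)
    if (any(tab < 2L))
        .stopValidation("condition level(s) with fewer than 2 samples: %s",
            paste(names(tab)[tab < 2L], collapse = ", "))

    n <- nrow(metadata)
    lv <- levels(cond)
    X <- matrix(1, n, 1L, dimnames = list(rownames(metadata), "(Intercept)"))
    for (l in lv[-1L]) {
        X <- cbind(X, as.numeric(cond == l))
        colnames(X)[ncol(X)] <- paste0(condition, l)
    }
    conditionColumns <- seq.int(2L, length.out = length(lv) - 1L)

    for (cv in covariates) {
        v <- metadata[[cv]]
        if (is.numeric(v)) {
            X <- cbind(X, v - mean(v))
            colnames(X)[ncol(X)] <- cv
        } else {
            fv <- factor(v)
            if (nlevels(fv) < 2L)
                .stopValidation("covariate '%s' is constant", cv)
            for (l in levels(fv)[-1L]) {
                X <- cbind(X, as.numeric(fv == l))
                colnames(X)[ncol(X)] <- paste0(cv, l)
            }
        }
    }

    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
        aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
        .stopValidation("collinear design: column(s) %s are aliased",
            paste(aliased, collapse = ", "))
    }
    if (n - qrX$rank < 1L)
        .stopValidation("saturated design: no residual degrees of freedom")

    if (is.null(contrastLevel)) contrastLevel <- lv[2L]
    if (!contrastLevel %in% lv[-1L])
        .stopConfig("contrast level '%s' must be a non-reference level of '%s'",
            contrastLevel, condition)
    contrast <- numeric(ncol(X))
    contrast[conditionColumns[match(contrastLevel, lv[-1L])]] <- 1

    new("DesignSpec", X = X, contrast = contrast, condition = cond,
        covariateNames = as.character(covariates),
        conditionColumns = as.integer(conditionColumns))
}

## Rebuild the design matrix with a different condition labelling (same level
## set, same treatment coding), leaving covariate columns untouched. Used for
## label permutations, where covariates stay fixed to their samples.
.designMatrixWithCondition <- function(design, newCondition) {
    X <- design@X
    lv <- levels(design@condition)
    newCondition <- factor(as.character(newCondition), levels = lv)
    stopifnot(!anyNA(newCondition), length(newCondition) == nrow(X))
    for (j in seq_along(design@conditionColumns))
        X[, design@conditionColumns[j]] <- as.numeric(newCondition == lv[j + 1L])
    X
}
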