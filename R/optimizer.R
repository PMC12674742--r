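## Reproducibility optimization: overlap of top-k lists across bootstrap
## pairs, standardized against permuted-data overlap, maximized over the
## (alpha, k) lattice.

#' Top-k overlap between two rankings
#'
#' Fraction of features ranked in the top \code{k} by both rankings:
#' \eqn{\#\{i : r_1(i) \le k \wedge r_2(i) \le k\} / k}.
#'
#' @param rank1,rank2 integer rank vectors, each a permutation of
#'   \code{1..G} (rank 1 = strongest feature).
#' @param k top-list size(s), each in \code{1..G}; may be a vector.
#'
#' @return numeric vector of overlaps in \code{[0, 1]}, one per \code{k}.
#'
#' @examples
#' overlapAtK(1:10, 10:1, k = 3)  # disjoint top-3 lists: 0
#'
#' @export
overlapAtK <- function(rank1, rank2, k) {
    G <- length(rank1)
    if (length(rank2) != G)
        .stopValidation("rank vectors must have equal length")
    if (any(sort(rank1) != seq_len(G)) || any(sort(rank2) != seq_len(G)))
        .stopValidation("rank vectors must be permutations of 1..G")
    if (any(k < 1L) || any(k > G))
        .stopValidation("k out of range 1..%d", G)
    .overlapCurve(rank1, rank2, G)[k] / k
}

## #{i : rank1_i <= k & rank2_i <= k} for every k = 1..G in O(G):
## a feature enters both top lists at k = max(rank1_i, rank2_i).
.overlapCurve <- function(rank1, rank2, G) {
    cumsum(tabulate(pmax(rank1, rank2), nbins = G))
}

#' Default alpha lattice
#'
#' The established grid of the reproducibility-optimization family:
#' \code{(a, 1)} for \code{a} in \code{0, 0.01, ..., 0.20} (step 0.01),
#' \code{0.22, ..., 1.00} (step 0.02), \code{1.2, ..., 5.0} (step 0.2),
#' plus the pair \code{(1, 0)}, which makes the pure log2-fold-change
#' statistic a candidate.
#'
#' @return a two-column numeric matrix with columns \code{alpha1},
#'   \code{alpha2}.
#' @export
defaultAlphaGrid <- function() {
    a1 <- round(c(seq(0, 0.20, by = 0.01), seq(0.22, 1.00, by = 0.02),
        seq(1.2, 5.0, by = 0.2)), 10)
    grid <- cbind(alpha1 = c(a1, 1), alpha2 = c(rep(1, length(a1)), 0))
    grid
}

#' Default top-list size grid
#'
#' About 40 approximately log-spaced integers from
#' \code{max(5, ceiling(0.005 G))} to \code{floor(G/4)}, deduplicated.
#' \code{k = G} is always excluded (overlap there is identically 1 and the
#' standardized score degenerates to 0/0).
#'
#' @param G number of features.
#' @param size target number of grid points.
#' @return an increasing integer vector of top-list sizes.
#' @export
defaultKGrid <- function(G, size = 40L) {
    hi <- floor(G / 4)
    if (hi < 1L) .stopValidation("too few features (G = %d) for a k grid", G)
    lo <- max(5L, ceiling(0.005 * G))
    if (lo > hi) lo <- hi
    k <- unique(as.integer(round(exp(seq(log(lo), log(hi),
        length.out = size)))))
    k[k >= 1L & k < G]
}

## Rank matrix (G x nAlpha) for one (resampled) dataset: refit the linear
## model on the drawn columns, shrink with the GLOBAL prior, rank |d| for
## every alpha pair.
.datasetRanks <- function(expr, X, idx, contrast, prior, alpha1, alpha2) {
    st <- .lsStats(expr[, idx, drop = FALSE], X[idx, , drop = FALSE], contrast)
    sTilde <- sqrt(posteriorVariance(st$s2, st$df, prior))
    us <- st$u * sTilde
    G <- length(st$betaHat)
    ranks <- matrix(0L, G, length(alpha1))
    for (a in seq_along(alpha1)) {
        denom <- alpha1[a] + alpha2[a] * us
        if (any(denom <= 0))
            .stopDegenerate("zero denominator at alpha pair (%g, %g)",
                alpha1[a], alpha2[a])
        ranks[, a] <- .absRanks(st$betaHat / denom)
    }
    ranks
}

## Overlap matrix (nAlpha x nK) for one pair of rank matrices.
.pairOverlaps <- function(r1, r2, k) {
    G <- nrow(r1)
    out <- matrix(0, ncol(r1), length(k))
    for (a in seq_len(ncol(r1)))
        out[a, ] <- .overlapCurve(r1[, a], r2[, a], G)[k] / k
    out
}

#' Reproducibility surface over the (alpha, k) lattice
#'
#' For every bootstrap pair the feature-wise model is refitted on each
#' resampled dataset, variances are shrunk with the globally estimated prior,
#' the moderated statistic and its ranking are computed for every alpha pair,
#' and the top-k overlap is evaluated at every k. \code{R} is the mean overlap
#' over pairs, \code{S} its standard deviation over pairs
#' (denominator \code{B - 1}), \code{R0} the mean overlap over the
#' permuted-label pairs, and \code{Z = (R - R0) / S}, with cells where
#' \code{S == 0} set to the \code{-Inf} sentinel (ineligible: zero bootstrap
#' spread makes reproducibility uninformative there).
#'
#' @param expr complete log2 expression matrix, features x samples.
#' @param design a \code{\linkS4class{DesignSpec}}.
#' @param prior a \code{\linkS4class{VariancePrior}} estimated once from the
#'   observed data and reused for every refit.
#' @param alphaGrid two-column matrix of \code{(alpha1, alpha2)} pairs
#'   (default \code{\link{defaultAlphaGrid}}).
#' @param kGrid increasing integer vector of top-list sizes (default
#'   \code{\link{defaultKGrid}}).
#' @param bootPlan a \code{"BootstrapPlan"} from
#'   \code{\link{makeBootstrapPairs}}.
#' @param nullPlan a \code{"NullPlan"} from \code{\link{makeNullPairs}} with
#'   the same number of pairs.
#' @param keepOverlaps keep the per-pair overlap matrices in the
#'   \code{"overlaps"} attribute (used by consistency checks).
#'
#' @return a \code{\linkS4class{ReproSurface}}.
#'
#' @export
reproducibilitySurface <- function(expr, design, prior,
                                   alphaGrid = defaultAlphaGrid(),
                                   kGrid = defaultKGrid(nrow(expr)),
                                   bootPlan, nullPlan,
                                   keepOverlaps = FALSE) {
    .validateExpression(expr)
    alphaGrid <- as.matrix(alphaGrid)
    if (ncol(alphaGrid) != 2L || nrow(alphaGrid) < 1L)
        .stopConfig("alphaGrid must be a two-column matrix of (alpha1, alpha2) pairs")
    G <- nrow(expr)
    kGrid <- as.integer(kGrid)
    if (any(kGrid < 1L) || any(kGrid > G) || is.unsorted(kGrid, strictly = TRUE))
        .stopValidation("kGrid must be strictly increasing integers in 1..G")
    if (!inherits(bootPlan, "BootstrapPlan") || !inherits(nullPlan, "NullPlan"))
        .stopConfig("bootPlan/nullPlan must come from makeBootstrapPairs/makeNullPairs")
    if (bootPlan$B != nullPlan$B)
        .stopConfig("bootstrap and null plans must have the same number of pairs")

    a1 <- alphaGrid[, 1L]
    a2 <- alphaGrid[, 2L]
    nA <- length(a1)
    nK <- length(kGrid)
    B <- bootPlan$B
    X <- design@X
    ctr <- design@contrast

    obs <- matrix(0, nA * nK, B)
    for (b in seq_len(B)) {
        pr <- bootPlan$pairs[[b]]
        r1 <- .datasetRanks(expr, X, pr$d1, ctr, prior, a1, a2)
        r2 <- .datasetRanks(expr, X, pr$d2, ctr, prior, a1, a2)
        obs[, b] <- .pairOverlaps(r1, r2, kGrid)
    }
    nul <- matrix(0, nA * nK, B)
    for (b in seq_len(B)) {
        pr <- nullPlan$pairs[[b]]
        Xp <- .designMatrixWithCondition(design, pr$labels)
        r1 <- .datasetRanks(expr, Xp, pr$d1, ctr, prior, a1, a2)
        r2 <- .datasetRanks(expr, Xp, pr$d2, ctr, prior, a1, a2)
        nul[, b] <- .pairOverlaps(r1, r2, kGrid)
    }

    R <- rowMeans(obs)
    S <- sqrt(rowSums((obs - R)^2) / (B - 1))
    R0 <- rowMeans(nul)
    Z <- ifelse(S > 0, (R - R0) / S, -Inf)

    surf <- new("ReproSurface", alpha1 = a1, alpha2 = a2, k = kGrid,
        R = matrix(R, nA, nK), R0 = matrix(R0, nA, nK),
        S = matrix(S, nA, nK), Z = matrix(Z, nA, nK))
    if (keepOverlaps)
        attr(surf, "overlaps") <- list(observed = obs, null = nul)
    surf
}

#' Maximize the standardized reproducibility over the lattice
#'
#' Returns the \code{(alpha, k)} cell attaining the maximal finite \code{Z}.
#' Ties are broken by smaller \code{alpha1}, then larger \code{k}, then
#' earlier alpha-pair order; \code{-Inf} sentinel cells never win.
#'
#' @param surface a \code{\linkS4class{ReproSurface}}.
#'
#' @return a list with \code{alpha} (length-2 numeric), \code{k}, \code{z},
#'   and the lattice indices \code{row}, \code{col}.
#'
#' @export
optimizeSurface <- function(surface) {
    if (!is(surface, "ReproSurface"))
        .stopConfig("surface must be a ReproSurface")
    Z <- surface@Z
    ok <- is.finite(Z)
    if (!any(ok))
        .stopOptim(paste0("all lattice cells are ineligible (zero bootstrap ",
            "spread everywhere); %d alpha pairs x %d k values examined"),
            length(surface@alpha1), length(surface@k))
    zmax <- max(Z[ok])
    hits <- which(Z == zmax & ok, arr.ind = TRUE)
    o <- order(surface@alpha1[hits[, 1L]], -surface@k[hits[, 2L]],
        hits[, 1L])
    i <- hits[o[1L], 1L]
    j <- hits[o[1L], 2L]
    list(alpha = c(alpha1 = surface@alpha1[i], alpha2 = surface@alpha2[i]),
        k = surface@k[j], z = zmax, row = unname(i), col = unname(j))
}
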