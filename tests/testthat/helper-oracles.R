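## Independent reference implementations used as oracles. Deliberately naive:
## explicit per-feature normal equations, explicit dataset materialization,
## explicit sorting and set intersection, double loops. They share no code
## path with the package internals.

## Per-feature OLS via the normal equations.
oracleLsFit <- function(Y, X, contrast) {
    XtXinv <- solve(t(X) %*% X)
    H <- XtXinv %*% t(X)
    G <- nrow(Y)
    beta <- numeric(G)
    s2 <- numeric(G)
    f <- nrow(X) - ncol(X)
    for (i in seq_len(G)) {
        b <- H %*% Y[i, ]
        r <- Y[i, ] - X %*% b
        beta[i] <- sum(contrast * b)
        s2[i] <- sum(r^2) / f
    }
    u <- sqrt(drop(t(contrast) %*% XtXinv %*% contrast))
    list(beta = beta, s2 = s2, f = f, u = u)
}

## Eq.4 shrinkage applied verbatim.
oracleShrink <- function(s2, f, f0, s0sq) {
    if (is.infinite(f0)) rep(s0sq, length(s2))
    else (f0 * s0sq + f * s2) / (f0 + f)
}

## Ranks of |d|, ties by ascending index; an independent route (rank() with
## ties.method = "first" on the negated magnitudes).
oracleAbsRank <- function(d) rank(-abs(d), ties.method = "first")

## Explicit top-k set intersection.
oracleOverlap <- function(rank1, rank2, k) {
    length(intersect(which(rank1 <= k), which(rank2 <= k))) / k
}

## Fully naive reproducibility surface: materialize every resampled dataset,
## refit by normal equations, shrink with the supplied global prior, sort,
## intersect.
oracleSurface <- function(expr, design, prior, alphaGrid, kGrid,
                          bootPlan, nullPlan) {
    X <- design@X
    ctr <- design@contrast
    f0 <- priorDf(prior)
    s0 <- priorVar(prior)
    nA <- nrow(alphaGrid)
    nK <- length(kGrid)
    B <- bootPlan$B

    rankMat <- function(Y, Xd) {
        fit <- oracleLsFit(Y, Xd, ctr)
        st <- sqrt(oracleShrink(fit$s2, fit$f, f0, s0))
        out <- matrix(0L, nrow(Y), nA)
        for (a in seq_len(nA)) {
            d <- fit$beta / (alphaGrid[a, 1] + alphaGrid[a, 2] * fit$u * st)
            out[, a] <- oracleAbsRank(d)
        }
        out
    }
    pairOv <- function(r1, r2) {
        o <- matrix(0, nA, nK)
        for (a in seq_len(nA))
            for (j in seq_len(nK))
                o[a, j] <- oracleOverlap(r1[, a], r2[, a], kGrid[j])
        o
    }

    obs <- array(0, c(nA, nK, B))
    for (b in seq_len(B)) {
        pr <- bootPlan$pairs[[b]]
        obs[, , b] <- pairOv(rankMat(expr[, pr$d1], X[pr$d1, , drop = FALSE]),
                             rankMat(expr[, pr$d2], X[pr$d2, , drop = FALSE]))
    }
    nul <- array(0, c(nA, nK, B))
    for (b in seq_len(B)) {
        pr <- nullPlan$pairs[[b]]
        Xp <- modrots:::.designMatrixWithCondition(design, pr$labels)
        nul[, , b] <- pairOv(rankMat(expr[, pr$d1], Xp[pr$d1, , drop = FALSE]),
                             rankMat(expr[, pr$d2], Xp[pr$d2, , drop = FALSE]))
    }
    R <- apply(obs, c(1, 2), mean)
    S <- matrix(0, nA, nK)
    for (a in seq_len(nA))
        for (j in seq_len(nK))
            S[a, j] <- sqrt(sum((obs[a, j, ] - R[a, j])^2) / (B - 1))
    R0 <- apply(nul, c(1, 2), mean)
    Z <- ifelse(S > 0, (R - R0) / S, -Inf)
    list(R = R, R0 = R0, S = S, Z = Z)
}

## Brute-force empirical p-values: explicit double loop.
oracleEmpiricalP <- function(observed, nullPool) {
    N <- length(nullPool)
    vapply(observed, function(o)
        (1 + sum(abs(nullPool) >= abs(o))) / (1 + N), 0)
}

## Textbook BH step-up by sorting.
oracleBH <- function(p) {
    n <- length(p)
    o <- order(p)
    q <- p[o] * n / seq_len(n)
    q <- rev(cummin(rev(q)))
    out <- numeric(n)
    out[o] <- pmin(q, 1)
    out
}

## ROC points by exhaustive threshold enumeration (called = score >= t).
oracleRoc <- function(scores, truth) {
    th <- sort(unique(scores), decreasing = TRUE)
    fpr <- numeric(length(th))
    tpr <- numeric(length(th))
    for (i in seq_along(th)) {
        called <- scores >= th[i]
        tpr[i] <- sum(called & truth) / sum(truth)
        fpr[i] <- sum(called & !truth) / sum(!truth)
    }
    list(fpr = c(0, fpr), tpr = c(0, tpr))
}

## Trapezoidal partial area under the exhaustive-threshold ROC.
oraclePauc <- function(scores, truth, fprMax, normalize = TRUE) {
    roc <- oracleRoc(scores, truth)
    x <- roc$fpr
    y <- roc$tpr
    area <- 0
    for (i in seq_len(length(x) - 1)) {
        if (x[i] >= fprMax) break
        x1 <- x[i + 1]; y1 <- y[i + 1]
        if (x1 > fprMax) {
            y1 <- y[i] + (y1 - y[i]) * (fprMax - x[i]) / (x1 - x[i])
            x1 <- fprMax
        }
        area <- area + (x1 - x[i]) * (y[i] + y1) / 2
    }
    if (normalize) area / fprMax else area
}

## Rank-sum (Mann-Whitney) AUC with average ranks for ties.
oracleRankSumAuc <- function(scores, truth) {
    nP <- sum(truth)
    nN <- sum(!truth)
    (sum(rank(scores)[truth]) - nP * (nP + 1) / 2) / (nP * nN)
}

## Precision/recall at every distinct threshold by explicit counting.
oraclePrPoints <- function(scores, truth) {
    th <- sort(unique(scores), decreasing = TRUE)
    rec <- numeric(length(th))
    prec <- numeric(length(th))
    for (i in seq_along(th)) {
        called <- scores >= th[i]
        rec[i] <- sum(called & truth) / sum(truth)
        prec[i] <- sum(called & truth) / sum(called)
    }
    data.frame(threshold = th, recall = rec, precision = prec)
}
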