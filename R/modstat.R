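## The moderated ranking statistic and its two-sided ranking.

## Rank features by decreasing |d|, ties broken by ascending feature index
## (stable, deterministic). Returns the rank vector: rank 1 = largest |d|.
.absRanks <- function(d) {
    ord <- order(-abs(d), seq_along(d))
    r <- integer(length(d))
    r[ord] <- seq_along(d)
    r
}

#' Moderated ranking statistic
#'
#' Computes \deqn{d_i = \frac{\hat\beta_i}{\alpha_1 + \alpha_2 (u \tilde
#' s_i)}} for scaling parameters \eqn{(\alpha_1, \alpha_2)}, together with the
#' two-sided ranking of features by decreasing \eqn{|d_i|} (ties broken by
#' ascending feature index). With \eqn{(\alpha_1, \alpha_2) = (0, 1)} this is
#' the empirical-Bayes moderated t-statistic; with \eqn{(1, 0)} it is the raw
#' log2 fold change.
#'
#' @param betaHat numeric vector of contrast effects (log2 fold changes).
#' @param u scalar unscaled standard deviation of the contrast.
#' @param sTilde numeric vector of posterior residual standard deviations.
#' @param alpha1,alpha2 nonnegative scaling parameters, not both zero.
#'
#' @return a list with components \code{d} (signed statistic) and
#'   \code{absRank} (integer ranks; 1 = largest magnitude).
#'
#' @examples
#' moderatedStatistic(c(2, -3, 1), 1, c(1, 1, 1), alpha1 = 1, alpha2 = 1)
#'
#' @export
moderatedStatistic <- function(betaHat, u, sTilde, alpha1, alpha2) {
    if (alpha1 < 0 || alpha2 < 0 || (alpha1 == 0 && alpha2 == 0))
        .stopDegenerate("alpha pair (%g, %g) invalid: must be nonnegative, not both zero",
            alpha1, alpha2)
    if (length(sTilde) != length(betaHat))
        .stopValidation("betaHat and sTilde must have the same length")
    if (any(!is.finite(betaHat)) || any(!is.finite(sTilde)) || !is.finite(u))
        .stopValidation("inputs to the moderated statistic must be finite")
    denom <- alpha1 + alpha2 * (u * sTilde)
    if (any(denom <= 0))
        .stopDegenerate("zero denominator in moderated statistic for alpha pair (%g, %g)",
            alpha1, alpha2)
    d <- betaHat / denom
    list(d = d, absRank = .absRanks(d))
}
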