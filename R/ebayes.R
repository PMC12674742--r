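## Empirical Bayes variance shrinkage: a scaled F-distribution is fitted to
## the observed residual variances by moment matching on the log scale, giving
## a global prior (f0, s0^2); posterior variances are the df-weighted average
## of prior and observed variance.

## Invert the trigamma function: solve trigamma(x) = y for x > 0 by Newton
## iteration with the asymptotic initializer x0 = 0.5 + 1/y.
.trigammaInverse <- function(y, tol = 1e-8, maxit = 50L) {
    if (!is.finite(y) || y <= 0)
        .stopValidation("trigamma inverse needs a positive finite target")
    x <- 0.5 + 1 / y
    for (i in seq_len(maxit)) {
        tri <- trigamma(x)
        ## Newton step on 1/trigamma (convex in x), as is standard for this
        ## inversion: delta = tri*(1 - tri/y) / psigamma'(x)
        delta <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
        x <- x + delta
        if (x <= 0) x <- .Machine$double.eps
        if (abs(delta) < tol) break
    }
    x
}

#' Estimate the global variance prior
#'
#' Fits a scaled F-distribution to the observed residual variances by moment
#' matching on the log scale. With \eqn{e_g = \log s_g^2 - \psi(f/2) +
#' \log(f/2)}, the prior degrees of freedom \eqn{f_0} solve
#' \eqn{\psi'(f_0/2) = \mathrm{var}(e) - \psi'(f/2)} (trigamma inversion) and
#' the prior variance is \eqn{s_0^2 = \exp\{\mathrm{mean}(e) + \psi(f_0/2) -
#' \log(f_0/2)\}}. When \eqn{\mathrm{var}(e) \le \psi'(f/2)} the spread of the
#' variances is no larger than sampling noise alone explains, and
#' \eqn{f_0 = \infty} with \eqn{s_0^2 = \exp\{\mathrm{mean}(e)\}}.
#'
#' Zero variances are excluded from the moment estimation (they carry no
#' information about the variance distribution on the log scale) but are still
#' shrunk downstream. Estimates of \eqn{f_0} above 1e7 are reported as
#' \code{Inf}.
#'
#' @param s2 numeric vector of observed residual variances (finite,
#'   nonnegative; at least 10 must be positive).
#' @param df residual degrees of freedom (scalar, >= 1).
#'
#' @return a \code{\linkS4class{VariancePrior}}.
#'
#' @seealso \code{\link{posteriorVariance}}
#' @export
estimatePrior <- function(s2, df) {
    if (any(!is.finite(s2)) || any(s2 < 0))
        .stopValidation("variances must be finite and nonnegative")
    if (length(df) != 1L || !is.finite(df) || df < 1)
        .stopValidation("df must be a finite scalar >= 1")
    pos <- s2 > 0
    if (sum(pos) < 10L)
        .stopValidation("need at least 10 positive variances to estimate the prior (got %d)",
            sum(pos))
    e <- log(s2[pos]) - digamma(df / 2) + log(df / 2)
    eMean <- mean(e)
    eVar <- stats::var(e)
    target <- eVar - trigamma(df / 2)
    if (!is.finite(target) || target <= .Machine$double.eps) {
        f0 <- Inf
        s0sq <- exp(eMean)
    } else {
        x <- .trigammaInverse(target)
        f0 <- 2 * x
        if (f0 > 1e7) {
            f0 <- Inf
            s0sq <- exp(eMean)
        } else {
            s0sq <- exp(eMean + digamma(x) - log(x))
        }
    }
    new("VariancePrior", priorDf = f0, priorVar = s0sq)
}

#' Posterior (shrunken) residual variances
#'
#' The empirical Bayes posterior residual variance
#' \deqn{\tilde s_i^2 = \frac{f_0 s_0^2 + f s_i^2}{f_0 + f},}
#' a convex combination of the observed variance and the global prior; with
#' \eqn{f_0 = \infty} every \eqn{\tilde s_i^2 = s_0^2}, and with
#' \eqn{f_0 = 0} (boundary probe) \eqn{\tilde s_i^2 = s_i^2}. Features with
#' \eqn{s_i^2 = 0} receive \eqn{f_0 s_0^2 / (f_0 + f)}: the formula itself
#' regularizes, no extra floor is applied.
#'
#' @param s2 numeric vector of observed residual variances (>= 0).
#' @param df residual degrees of freedom (scalar).
#' @param prior a \code{\linkS4class{VariancePrior}}.
#'
#' @return numeric vector of posterior variances \eqn{\tilde s_i^2}.
#'
#' @export
posteriorVariance <- function(s2, df, prior) {
    if (!is(prior, "VariancePrior"))
        .stopConfig("prior must be a VariancePrior")
    if (any(!is.finite(s2)) || any(s2 < 0))
        .stopValidation("variances must be finite and nonnegative")
    f0 <- prior@priorDf
    s0sq <- prior@priorVar
    if (is.infinite(f0)) return(rep(s0sq, length(s2)))
    (f0 * s0sq + df * s2) / (f0 + df)
}
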