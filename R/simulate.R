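## Spike-in style synthetic data with known ground truth: Gaussian noise on
## the log2 scale with inverse-chi-square per-feature variances (the model the
## empirical Bayes machinery assumes), known shifted features between
## conditions, and optional batch-effect injection.

#' Batch-effect specification
#'
#' Describes a technical batch structure and an injected artificial signal: a
#' uniform log2 shift applied to a random subset of (by default non-DE)
#' features in the samples of one batch only. The defaults mirror the two
#' canonical injection schemes: a random shift between 5 and 20 log2 units
#' (set \code{shiftRange = c(10, 10)} for the fixed-shift variant).
#'
#' @param nShifted number of features receiving the shift.
#' @param shiftRange length-2 numeric, uniform range of the log2 shift (use a
#'   degenerate range for a fixed shift).
#' @param targetBatch label of the batch whose samples are shifted (default:
#'   the first batch).
#' @param labels optional explicit per-sample batch labels; if \code{NULL},
#'   samples are assigned to two batches crossed with the condition at an
#'   unbalanced (roughly 2:1) ratio, the confounded layout that makes
#'   omitting the batch covariate harmful.
#' @param fromNonDE draw the shifted features from the non-differential pool
#'   (default TRUE).
#'
#' @return a list of class \code{"BatchSpec"}.
#'
#' @export
batchSpec <- function(nShifted = 50L, shiftRange = c(5, 20),
                      targetBatch = NULL, labels = NULL, fromNonDE = TRUE) {
    if (nShifted < 1L) .stopValidation("nShifted must be positive")
    if (length(shiftRange) != 2L || any(shiftRange < 0) ||
        shiftRange[2L] < shiftRange[1L])
        .stopValidation("shiftRange must be nondecreasing and nonnegative")
    structure(list(nShifted = as.integer(nShifted),
        shiftRange = as.numeric(shiftRange), targetBatch = targetBatch,
        labels = labels, fromNonDE = isTRUE(fromNonDE)), class = "BatchSpec")
}

## Unbalanced two-batch labels crossed with condition: within each condition
## level, about 2/3 of samples go to one batch -- alternating which batch gets
## the majority so batch and condition are confounded but not aliased.
.defaultBatchLabels <- function(condition) {
    condition <- as.factor(condition)
    out <- character(length(condition))
    for (j in seq_along(levels(condition))) {
        members <- which(condition == levels(condition)[j])
        nMaj <- ceiling(2 * length(members) / 3)
        maj <- if (j %% 2L == 1L) "batch1" else "batch2"
        minb <- if (j %% 2L == 1L) "batch2" else "batch1"
        out[members] <- c(rep(maj, nMaj),
            rep(minb, length(members) - nMaj))
    }
    out
}

#' Inject an artificial batch shift
#'
#' Adds a uniform log2 shift to a random subset of features, in the samples of
#' one batch only; deterministic given the seed. The returned log permits
#' exact removal of the injected signal.
#'
#' @param expr features x samples log2 matrix.
#' @param batchLabels per-sample batch labels covering all samples.
#' @param targetBatch label of the batch to shift.
#' @param nShifted number of features to shift.
#' @param shiftRange length-2 uniform range of the shift.
#' @param pool optional integer/character vector restricting which features
#'   may be shifted (e.g. the non-DE features).
#' @param seed integer seed.
#'
#' @return list with \code{expr} (modified matrix) and \code{log} (data.frame
#'   \code{feature_id}, \code{shift}).
#'
#' @export
injectBatchEffect <- function(expr, batchLabels, targetBatch, nShifted,
                              shiftRange, pool = NULL, seed = 1L) {
    if (length(batchLabels) != ncol(expr))
        .stopValidation("batch labels must cover all samples")
    if (!targetBatch %in% batchLabels)
        .stopValidation("target batch '%s' not present", targetBatch)
    G <- nrow(expr)
    if (is.null(pool)) pool <- seq_len(G)
    if (is.character(pool)) pool <- match(pool, rownames(expr))
    if (nShifted > length(pool))
        .stopValidation("cannot shift %d features: pool has only %d",
            nShifted, length(pool))
    drawn <- .withSeed(.deriveSeed(seed, 77L), {
        feats <- pool[sample.int(length(pool), nShifted)]
        shifts <- stats::runif(nShifted, shiftRange[1L], shiftRange[2L])
        list(feats = feats, shifts = shifts)
    })
    cols <- which(batchLabels == targetBatch)
    expr[drawn$feats, cols] <- expr[drawn$feats, cols] + drawn$shifts
    list(expr = expr,
         log = data.frame(feature_id = rownames(expr)[drawn$feats],
             shift = drawn$shifts))
}

#' Simulate a spike-in style dataset with known ground truth
#'
#' Background features are a per-feature baseline (log-uniform over
#' \code{baselineRange}, cosmetic) plus Gaussian noise whose per-feature
#' variance is drawn from a scaled inverse-chi-square prior with parameters
#' \code{(priorDf, priorVar)} — the model assumed by the empirical Bayes
#' shrinkage, so prior-recovery checks are meaningful. Truly differential
#' features are additionally shifted by \code{effectLog2} (random sign) in
#' every non-reference condition. An optional \code{\link{batchSpec}} injects
#' a technical batch signal into (by default) non-differential features.
#'
#' Defaults encode the reference benchmark conditions used throughout the
#' package: 1000 features, two groups of 5, 10\% differential at an effect of
#' 4 prior standard deviations (\code{4 * sqrt(0.25) = 2} log2 units), noise
#' prior \code{f0 = 4}, \code{s0^2 = 0.25}.
#'
#' @param nFeatures number of features G.
#' @param nPerGroup integer vector of per-condition sample sizes; names give
#'   the condition labels (default \code{c(A = 5, B = 5)}).
#' @param deFraction fraction of truly differential features in (0, 1).
#' @param effectLog2 true log2 effect: a scalar, or a length-2 range from
#'   which magnitudes are drawn uniformly. Default 2 (4 prior sd).
#' @param priorDf,priorVar parameters of the variance prior generating the
#'   per-feature noise variances (\code{priorDf = Inf} gives constant
#'   variance \code{priorVar}).
#' @param baselineRange log2 range of baseline abundances (cosmetic).
#' @param batch \code{NULL} or a \code{\link{batchSpec}}.
#' @param seed integer seed; every artifact is deterministic given the seed.
#'
#' @return a \code{SummarizedExperiment}: assay \code{"log2intensity"},
#'   \code{rowData} columns \code{is_de}, \code{true_effect},
#'   \code{batch_shift}; \code{colData} columns \code{condition} and (if a
#'   batch spec was given) \code{batch}.
#'
#' @examples
#' sim <- simulateSpikeIn(nFeatures = 200, seed = 1)
#' table(SummarizedExperiment::rowData(sim)$is_de)
#'
#' @export
simulateSpikeIn <- function(nFeatures = 1000L, nPerGroup = c(A = 5L, B = 5L),
                            deFraction = 0.1, effectLog2 = 2,
                            priorDf = 4, priorVar = 0.25,
                            baselineRange = c(15, 30), batch = NULL,
                            seed = 1L) {
    G <- as.integer(nFeatures)
    if (G < 2L) .stopValidation("need at least 2 features")
    if (any(nPerGroup < 2L) || length(nPerGroup) < 2L)
        .stopValidation("need >= 2 conditions with >= 2 samples each")
    if (!(deFraction > 0 && deFraction < 1))
        .stopValidation("deFraction must lie in (0, 1)")
    nDE <- round(deFraction * G)
    if (nDE < 1L) .stopValidation("deFraction * G must be at least 1")
    if (!is.null(batch) && !inherits(batch, "BatchSpec"))
        .stopConfig("batch must come from batchSpec()")

    condLabels <- names(nPerGroup)
    if (is.null(condLabels))
        condLabels <- LETTERS[seq_along(nPerGroup)]
    condition <- factor(rep(condLabels, times = nPerGroup),
        levels = condLabels)
    n <- length(condition)

    sim <- .withSeed(.deriveSeed(seed, 11L), {
        baseline <- stats::runif(G, baselineRange[1L], baselineRange[2L])
        sd2 <- if (is.infinite(priorDf)) rep(priorVar, G)
            else priorVar * priorDf / stats::rchisq(G, df = priorDf)
        deIdx <- sample.int(G, nDE)
        mag <- if (length(effectLog2) == 2L)
            stats::runif(nDE, effectLog2[1L], effectLog2[2L])
            else rep(effectLog2, nDE)
        sgn <- sample(c(-1, 1), nDE, replace = TRUE)
        eff <- numeric(G)
        eff[deIdx] <- mag * sgn
        noise <- matrix(stats::rnorm(G * n, sd = rep(sqrt(sd2), n)), G, n)
        list(baseline = baseline, eff = eff, deIdx = deIdx, noise = noise)
    })

    shiftMat <- outer(sim$eff, as.numeric(condition != condLabels[1L]))
    expr <- sim$baseline + shiftMat + sim$noise
    rownames(expr) <- sprintf("feature%05d", seq_len(G))
    colnames(expr) <- sprintf("sample%03d", seq_len(n))

    cd <- data.frame(condition = condition, row.names = colnames(expr))
    batchShift <- numeric(G)
    if (!is.null(batch)) {
        labels <- batch$labels
        if (is.null(labels)) labels <- .defaultBatchLabels(condition)
        if (length(labels) != n)
            .stopValidation("batch labels must cover all samples")
        target <- batch$targetBatch
        if (is.null(target)) target <- sort(unique(labels))[1L]
        pool <- if (batch$fromNonDE) setdiff(seq_len(G), sim$deIdx)
            else seq_len(G)
        inj <- injectBatchEffect(expr, labels, target, batch$nShifted,
            batch$shiftRange, pool = pool, seed = .deriveSeed(seed, 13L))
        expr <- inj$expr
        batchShift[match(inj$log$feature_id, rownames(expr))] <- inj$log$shift
        cd$batch <- factor(labels)
    }

    isDE <- logical(G)
    isDE[sim$deIdx] <- TRUE
    SummarizedExperiment::SummarizedExperiment(
        assays = list(log2intensity = expr),
        rowData = S4Vectors::DataFrame(is_de = isDE,
            true_effect = sim$eff, batch_shift = batchShift),
        colData = S4Vectors::DataFrame(cd)
    )
}
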