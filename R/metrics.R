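## Benchmarking metrics for spike-in style evaluations: confusion-matrix
## summaries, partial AUC at a low false-positive-rate bound, and
## precision-recall curves.

#' Confusion counts
#'
#' @param truth logical vector, TRUE = truly differential.
#' @param called logical vector, TRUE = called significant.
#' @return named integer vector with elements \code{TP}, \code{FP}, \code{TN},
#'   \code{FN}.
#' @export
confusionCounts <- function(truth, called) {
    if (length(truth) != length(called))
        .stopValidation("truth and called must have equal length")
    truth <- as.logical(truth)
    called <- as.logical(called)
    if (anyNA(truth) || anyNA(called))
        .stopValidation("truth/called must not contain NA")
    c(TP = sum(truth & called), FP = sum(!truth & called),
      TN = sum(!truth & !called), FN = sum(truth & !called))
}

#' Normalized Matthews correlation coefficient
#'
#' \eqn{\mathrm{nMCC} = (\mathrm{MCC} + 1)/2} with
#' \eqn{\mathrm{MCC} = (TP \cdot TN - FP \cdot FN) / \sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}};
#' when any factor under the root is zero, MCC is defined as 0 (nMCC = 0.5).
#'
#' @param counts named vector from \code{\link{confusionCounts}}.
#' @return nMCC in [0, 1].
#' @export
nMCC <- function(counts) {
    tp <- as.numeric(counts[["TP"]]); fp <- as.numeric(counts[["FP"]])
    tn <- as.numeric(counts[["TN"]]); fn <- as.numeric(counts[["FN"]])
    denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
    mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / sqrt(denom)
    (mcc + 1) / 2
}

#' F1 score, G-mean and balanced accuracy
#'
#' \eqn{F_1 = 2TP / (2TP + FP + FN)};
#' \eqn{\mathrm{G} = \sqrt{\mathrm{sens} \times \mathrm{spec}}};
#' balanced accuracy \eqn{= (\mathrm{sens} + \mathrm{spec})/2}.
#' Sensitivity/specificity terms with zero denominators are taken as 0. The
#' empty case \code{TP = FP = FN = 0} (no positives in truth, none called)
#' gives \eqn{F_1 = 1}.
#'
#' @param counts named vector from \code{\link{confusionCounts}}.
#' @return named numeric vector \code{f1}, \code{gmean},
#'   \code{balanced_accuracy}.
#' @export
f1GmeanBalacc <- function(counts) {
    tp <- as.numeric(counts[["TP"]]); fp <- as.numeric(counts[["FP"]])
    tn <- as.numeric(counts[["TN"]]); fn <- as.numeric(counts[["FN"]])
    f1 <- if (tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn)
    sens <- if (tp + fn == 0) 0 else tp / (tp + fn)
    spec <- if (tn + fp == 0) 0 else tn / (tn + fp)
    c(f1 = f1, gmean = sqrt(sens * spec),
      balanced_accuracy = (sens + spec) / 2)
}

## ROC curve points over distinct score thresholds (descending), with tied
## scores collapsed into one step so ties are interpolated trapezoidally.
## Returns FPR/TPR including the (0, 0) origin.
.rocPoints <- function(scores, truth) {
    truth <- as.logical(truth)
    nPos <- sum(truth)
    nNeg <- sum(!truth)
    if (nPos == 0L || nNeg == 0L)
        .stopValidation("both classes must be present")
    ord <- order(scores, decreasing = TRUE)
    s <- scores[ord]
    t <- truth[ord]
    last <- cumsum(rle(s)$lengths)      # block ends of tied scores
    cumTP <- cumsum(t)[last]
    cumFP <- cumsum(!t)[last]
    list(fpr = c(0, cumFP / nNeg), tpr = c(0, cumTP / nPos))
}

#' Partial area under the ROC curve
#'
#' Trapezoidal area under the ROC curve over \eqn{\mathrm{FPR} \in [0,
#' \mathrm{fprMax}]}, with tied scores interpolated linearly across their
#' block. By default the area is normalized by \code{fprMax} so the value lies
#' in [0, 1] (0.5 = chance); set \code{normalize = FALSE} for the raw area.
#'
#' @param scores numeric vector, larger = more confidently positive.
#' @param truth logical vector of true labels (both classes present).
#' @param fprMax false-positive-rate bound in (0, 1]; with \code{fprMax = 1}
#'   the (normalized) value equals the full AUC.
#' @param normalize divide by \code{fprMax} (default TRUE).
#'
#' @return partial AUC.
#'
#' @export
pAUC <- function(scores, truth, fprMax = 0.05, normalize = TRUE) {
    if (!(fprMax > 0 && fprMax <= 1))
        .stopValidation("fprMax must lie in (0, 1]")
    if (length(scores) != length(truth))
        .stopValidation("scores and truth must have equal length")
    roc <- .rocPoints(scores, truth)
    fpr <- roc$fpr
    tpr <- roc$tpr
    area <- 0
    for (i in seq_len(length(fpr) - 1L)) {
        x0 <- fpr[i]; x1 <- fpr[i + 1L]
        y0 <- tpr[i]; y1 <- tpr[i + 1L]
        if (x0 >= fprMax) break
        if (x1 > fprMax) {                # clip the segment at the bound
            y1 <- if (x1 > x0)
                y0 + (y1 - y0) * (fprMax - x0) / (x1 - x0) else y1
            x1 <- fprMax
        }
        area <- area + (x1 - x0) * (y0 + y1) / 2
    }
    if (normalize) area / fprMax else area
}

#' Precision-recall curve and its area
#'
#' Precision and recall over all distinct score thresholds (descending), with
#' the area computed by trapezoidal interpolation over the monotone recall
#' grid. A point at recall 0 with the precision of the first threshold block
#' anchors the curve.
#'
#' @inheritParams pAUC
#'
#' @return a list with \code{curve} (data.frame: \code{threshold},
#'   \code{recall}, \code{precision}) and \code{auc}.
#'
#' @export
prCurve <- function(scores, truth) {
    truth <- as.logical(truth)
    nPos <- sum(truth)
    if (nPos == 0L || nPos == length(truth))
        .stopValidation("both classes must be present")
    ord <- order(scores, decreasing = TRUE)
    s <- scores[ord]
    t <- truth[ord]
    last <- cumsum(rle(s)$lengths)
    cumTP <- cumsum(t)[last]
    cumFP <- cumsum(!t)[last]
    recall <- cumTP / nPos
    precision <- cumTP / (cumTP + cumFP)
    curve <- data.frame(threshold = s[last], recall = recall,
        precision = precision)
    r <- c(0, recall)
    p <- c(precision[1L], precision)
    auc <- sum(diff(r) * (p[-1L] + p[-length(p)]) / 2)
    list(curve = curve, auc = auc)
}

#' Evaluate differential expression calls against known truth
#'
#' Computes the full benchmarking metric set for one result table: confusion
#' metrics (nMCC, F1, G-mean, balanced accuracy) from the significance calls,
#' and score-based metrics (partial AUC at \code{fprMax}, PR AUC) from the
#' score \eqn{-\log_{10} p} with \eqn{|\mathrm{effect}|} as tie-breaker.
#'
#' @param results a \code{\linkS4class{ModROTSResults}} or a data.frame with
#'   columns \code{feature_id}, \code{pvalue}, \code{qvalue} (or
#'   \code{significant}) and \code{effect_log2fc}.
#' @param truth logical vector named by feature id, or a data.frame with
#'   columns \code{feature_id} and \code{is_de}.
#' @param fdrCutoff cutoff on the adjusted p-value defining the calls
#'   (default 0.05).
#' @param fprMax false-positive-rate bound of the partial AUC (default 0.05).
#'
#' @return named numeric vector: \code{nmcc}, \code{f1}, \code{gmean},
#'   \code{balanced_accuracy}, \code{pauc}, \code{pr_auc}.
#'
#' @export
evaluateCalls <- function(results, truth, fdrCutoff = 0.05, fprMax = 0.05) {
    if (is(results, "ModROTSResults")) results <- as.data.frame(deTable(results))
    if (is.data.frame(truth)) {
        if (!all(c("feature_id", "is_de") %in% colnames(truth)))
            .stopConfig("truth table needs columns feature_id and is_de")
        tr <- truth$is_de[match(results$feature_id, truth$feature_id)]
    } else {
        tr <- truth[results$feature_id]
    }
    if (anyNA(tr))
        .stopValidation("truth is missing for some features")
    tr <- as.logical(tr)
    called <- if ("qvalue" %in% colnames(results))
        results$qvalue < fdrCutoff else as.logical(results$significant)
    cc <- confusionCounts(tr, called)
    fgb <- f1GmeanBalacc(cc)
    score <- -log10(results$pvalue) +
        1e-9 * rank(abs(results$effect_log2fc), ties.method = "average") /
            length(tr)
    c(nmcc = nMCC(cc), fgb,
      pauc = pAUC(score, tr, fprMax = fprMax),
      pr_auc = prCurve(score, tr)$auc)
}
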