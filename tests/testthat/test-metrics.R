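test_that("confusion counts match an explicit tabulation", {
    tr <- modrots:::.withSeed(1, runif(1000) < 0.3)
    cl <- modrots:::.withSeed(2, runif(1000) < 0.4)
    cc <- confusionCounts(tr, cl)
    ## explicit loop oracle
    tp <- fp <- tn <- fn <- 0L
    for (i in seq_along(tr)) {
        if (tr[i] && cl[i]) tp <- tp + 1L
        else if (!tr[i] && cl[i]) fp <- fp + 1L
        else if (!tr[i] && !cl[i]) tn <- tn + 1L
        else fn <- fn + 1L
    }
    expect_identical(cc, c(TP = tp, FP = fp, TN = tn, FN = fn))
    expect_identical(confusionCounts(tr, tr)[["FP"]], 0L)
    expect_identical(confusionCounts(tr, tr)[["FN"]], 0L)
    all1 <- confusionCounts(rep(FALSE, 5), rep(TRUE, 5))
    expect_identical(unname(all1[c("TP", "TN")]), c(0L, 0L))
    expect_error(confusionCounts(c(TRUE, FALSE), TRUE),
        class = "modrotsValidationError")
})

test_that("nMCC follows the printed formula with its zero convention", {
    expect_equal(nMCC(c(TP = 10, FP = 0, TN = 20, FN = 0)), 1.0)
    expect_equal(nMCC(c(TP = 25, FP = 25, TN = 25, FN = 25)), 0.5)
    ## zero factor under the root: MCC defined as 0
    expect_equal(nMCC(c(TP = 0, FP = 0, TN = 50, FN = 10)), 0.5)
    cc <- c(TP = 80, FP = 10, TN = 90, FN = 20)
    mcc <- (80 * 90 - 10 * 20) / sqrt((80 + 10) * (80 + 20) * (90 + 10) * (90 + 20))
    expect_equal(nMCC(cc), (mcc + 1) / 2, tolerance = 1e-12)
    ## symmetry under simultaneous TP<->TN, FP<->FN swap
    expect_equal(nMCC(c(TP = 7, FP = 3, TN = 11, FN = 5)),
                 nMCC(c(TP = 11, FP = 5, TN = 7, FN = 3)))
})

test_that("F1, G-mean and balanced accuracy match direct evaluation", {
    perfect <- f1GmeanBalacc(c(TP = 10, FP = 0, TN = 10, FN = 0))
    expect_equal(unname(perfect), c(1, 1, 1))
    zeroSens <- f1GmeanBalacc(c(TP = 0, FP = 2, TN = 8, FN = 5))
    expect_equal(zeroSens[["f1"]], 0)
    expect_equal(zeroSens[["gmean"]], 0)
    ## empty case: no positives in truth and none called
    expect_equal(f1GmeanBalacc(c(TP = 0, FP = 0, TN = 9, FN = 0))[["f1"]], 1)
    ## random tables against independent precision/recall arithmetic
    tabs <- modrots:::.withSeed(3, matrix(sample(0:30, 400, TRUE), ncol = 4))
    for (r in seq_len(nrow(tabs))) {
        cc <- c(TP = tabs[r, 1], FP = tabs[r, 2], TN = tabs[r, 3],
            FN = tabs[r, 4])
        got <- f1GmeanBalacc(cc)
        tp <- cc[["TP"]]; fp <- cc[["FP"]]; tn <- cc[["TN"]]; fn <- cc[["FN"]]
        prec <- if (tp + fp > 0) tp / (tp + fp) else NA
        rec <- if (tp + fn > 0) tp / (tp + fn) else NA
        f1ref <- if (tp + fp + fn == 0) 1
            else if (is.na(prec) || is.na(rec) || prec + rec == 0) 0
            else 2 * prec * rec / (prec + rec)
        sens <- if (tp + fn > 0) tp / (tp + fn) else 0
        spec <- if (tn + fp > 0) tn / (tn + fp) else 0
        expect_equal(got[["f1"]], f1ref, tolerance = 1e-12)
        expect_equal(got[["gmean"]], sqrt(sens * spec), tolerance = 1e-12)
        expect_equal(got[["balanced_accuracy"]], (sens + spec) / 2,
            tolerance = 1e-12)
    }
})

test_that("partial AUC matches the exhaustive-threshold oracle", {
    dat <- modrots:::.withSeed(4, {
        truth <- rep(c(TRUE, FALSE), each = 100)
        scores <- c(rnorm(100, 1.2), rnorm(100, 0))
        list(truth = truth, scores = scores)
    })
    for (fm in c(0.05, 0.2, 0.5, 1)) {
        expect_equal(pAUC(dat$scores, dat$truth, fprMax = fm),
            oraclePauc(dat$scores, dat$truth, fm), tolerance = 1e-9)
    }
    ## perfect separation
    expect_equal(pAUC(c(5, 4, 3, 2, 1), c(TRUE, TRUE, FALSE, FALSE, FALSE),
        fprMax = 0.05), 1.0)
    ## degenerate: all scores tied -> chance diagonal
    expect_equal(pAUC(rep(1, 10), rep(c(TRUE, FALSE), 5), fprMax = 1), 0.5)
    ## tied blocks interpolated trapezoidally
    scoresTied <- modrots:::.withSeed(5, sample(round(rnorm(60), 1)))
    truthTied <- modrots:::.withSeed(6, runif(60) < 0.5)
    expect_equal(pAUC(scoresTied, truthTied, fprMax = 0.3),
        oraclePauc(scoresTied, truthTied, 0.3), tolerance = 1e-9)
    expect_error(pAUC(1:5, rep(TRUE, 5), 0.05),
        class = "modrotsValidationError")
})

test_that("pAUC at fprMax = 1 equals the rank-sum AUC", {
    dat <- modrots:::.withSeed(7, {
        truth <- runif(200) < 0.4
        scores <- rnorm(200) + truth      # with ties impossible
        list(truth = truth, scores = scores)
    })
    expect_equal(pAUC(dat$scores, dat$truth, fprMax = 1),
        oracleRankSumAuc(dat$scores, dat$truth), tolerance = 1e-9)
    ## and with heavy ties (average-rank convention = trapezoid over blocks)
    sc <- modrots:::.withSeed(8, sample(1:5, 100, TRUE))
    tr <- modrots:::.withSeed(9, runif(100) < 0.5)
    expect_equal(pAUC(sc, tr, fprMax = 1), oracleRankSumAuc(sc, tr),
        tolerance = 1e-9)
})

test_that("precision-recall curve matches explicit threshold counting", {
    dat <- modrots:::.withSeed(10, {
        truth <- runif(80) < 0.35
        scores <- rnorm(80) + 1.5 * truth
        list(truth = truth, scores = scores)
    })
    pr <- prCurve(dat$scores, dat$truth)
    ref <- oraclePrPoints(dat$scores, dat$truth)
    expect_equal(pr$curve$recall, ref$recall, tolerance = 1e-12)
    expect_equal(pr$curve$precision, ref$precision, tolerance = 1e-12)
    ## perfect separation
    expect_equal(prCurve(c(4, 3, 2, 1), c(TRUE, TRUE, FALSE, FALSE))$auc, 1.0)
    ## permutation invariance of all metrics
    prm <- modrots:::.withSeed(11, sample.int(80))
    expect_equal(prCurve(dat$scores[prm], dat$truth[prm])$auc, pr$auc)
    expect_equal(pAUC(dat$scores[prm], dat$truth[prm], 0.1),
        pAUC(dat$scores, dat$truth, 0.1))
    expect_error(prCurve(1:4, rep(FALSE, 4)), class = "modrotsValidationError")
})

test_that("evaluateCalls assembles the full metric set", {
    res <- data.frame(feature_id = sprintf("f%02d", 1:40),
        pvalue = c(seq(0.001, 0.01, length.out = 10), runif(30, 0.2, 1)),
        effect_log2fc = rnorm(40))
    res$qvalue <- adjustPValues(res$pvalue)
    truth <- data.frame(feature_id = res$feature_id,
        is_de = c(rep(TRUE, 10), rep(FALSE, 30)))
    m <- evaluateCalls(res, truth)
    expect_named(m, c("nmcc", "f1", "gmean", "balanced_accuracy", "pauc",
        "pr_auc"))
    expect_true(all(m >= 0 & m <= 1))
    expect_gt(m[["f1"]], 0.9)
})
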