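test_that("empirical p-values follow the add-one convention", {
    nullPool <- modrots:::.withSeed(3, rnorm(999))
    big <- max(abs(nullPool)) + 1
    expect_equal(empiricalPValues(big, nullPool), 1 / 1000)
    expect_equal(empiricalPValues(0, nullPool), 1)
    obs <- modrots:::.withSeed(4, rnorm(50))
    expect_equal(empiricalPValues(obs, nullPool),
        oracleEmpiricalP(obs, nullPool))
    ## ties between observed and null statistics count as at-least-as-extreme
    expect_equal(empiricalPValues(nullPool[1], nullPool),
        oracleEmpiricalP(nullPool[1], nullPool))
    expect_error(empiricalPValues(1, numeric(0)),
        class = "modrotsValidationError")
})

test_that("BH adjustment matches the textbook step-up", {
    expect_equal(adjustPValues(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
    expect_equal(adjustPValues(rep(1, 5)), rep(1, 5))
    p <- modrots:::.withSeed(5, runif(200))
    expect_equal(adjustPValues(p), oracleBH(p))
    ## order preservation
    expect_true(all(diff(adjustPValues(p)[order(p)]) >= 0))
    q <- adjustPValues(p, method = "storey")
    expect_true(all(q <= adjustPValues(p) + 1e-12))
})

test_that("a constant matrix fails cleanly in variance estimation", {
    y <- matrix(5, 20, 6, dimnames = list(sprintf("f%02d", 1:20),
        sprintf("s%02d", 1:6)))
    md <- twoGroupMeta(c(3, 3), sampleIds = colnames(y))
    expect_error(
        modROTS(y, metadata = md, condition = "group", B = 4, P = 4, seed = 1),
        class = "modrotsValidationError")
})

test_that("a global intercept shift leaves p-values unchanged", {
    sim <- simulateSpikeIn(nFeatures = 80, nPerGroup = c(4, 4), seed = 12)
    y <- SummarizedExperiment::assay(sim)
    md <- as.data.frame(SummarizedExperiment::colData(sim))
    r1 <- modROTS(y, metadata = md, condition = "condition", B = 15, P = 15,
        seed = 5)
    r2 <- modROTS(y + 7, metadata = md, condition = "condition", B = 15,
        P = 15, seed = 5)
    ## the statistic is algebraically invariant; p-values can move by at most
    ## one null-pool count where an observed |d| ties a null |d| exactly and
    ## rounding breaks the tie differently
    N <- nrow(y) * 15
    expect_lt(max(abs(deTable(r1)$pvalue - deTable(r2)$pvalue)), 2 / (1 + N))
    expect_equal(deTable(r1)$effect_log2fc, deTable(r2)$effect_log2fc,
        tolerance = 1e-10)
})

test_that("with alpha fixed at (0,1) the p-value order is the moderated-t order", {
    sim <- simulateSpikeIn(nFeatures = 150, nPerGroup = c(4, 4), seed = 31)
    res <- modROTS(sim, condition = "condition", B = 10, P = 20, seed = 2,
        alphaGrid = matrix(c(0, 1), 1))
    tab <- deTable(res)
    expect_equal(unname(optAlpha(res)), c(0, 1))
    ## p must be non-increasing in |d| = |moderated t|
    expect_true(all(diff(tab$pvalue[order(-abs(tab$d_opt))]) >= 0))
})

test_that("null data yield near-uniform p-values and few discoveries", {
    sim <- simulateSpikeIn(nFeatures = 300, nPerGroup = c(5, 5),
        effectLog2 = 0, seed = 77)
    res <- modROTS(sim, condition = "condition", B = 60, P = 60, seed = 9)
    tab <- deTable(res)
    ks <- suppressWarnings(ks.test(tab$pvalue, "punif"))
    expect_lt(unname(ks$statistic), 0.1)
    expect_lte(sum(tab$qvalue < 0.05), 3)
})

test_that("runs are deterministic given the seed", {
    sim <- simulateSpikeIn(nFeatures = 60, nPerGroup = c(4, 4), seed = 2)
    r1 <- modROTS(sim, condition = "condition", B = 8, P = 8, seed = 3)
    r2 <- modROTS(sim, condition = "condition", B = 8, P = 8, seed = 3)
    expect_identical(as.data.frame(deTable(r1)), as.data.frame(deTable(r2)))
    expect_identical(optAlpha(r1), optAlpha(r2))
})

test_that("metadata is aligned by sample id, never by position", {
    sim <- simulateSpikeIn(nFeatures = 60, nPerGroup = c(4, 4), seed = 6)
    y <- SummarizedExperiment::assay(sim)
    md <- as.data.frame(SummarizedExperiment::colData(sim))
    shuffled <- md[rev(seq_len(nrow(md))), , drop = FALSE]
    r1 <- modROTS(y, metadata = md, condition = "condition", B = 6, P = 6,
        seed = 4)
    r2 <- modROTS(y, metadata = shuffled, condition = "condition", B = 6,
        P = 6, seed = 4)
    expect_identical(as.data.frame(deTable(r1)), as.data.frame(deTable(r2)))
    rownames(shuffled)[1] <- "not_a_sample"
    err <- tryCatch(modROTS(y, metadata = shuffled, condition = "condition",
        B = 6, P = 6, seed = 4), error = identity)
    expect_s3_class(err, "modrotsValidationError")
    expect_match(conditionMessage(err), "sample")
})
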