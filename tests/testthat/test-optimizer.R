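test_that("overlap at k obeys the set-intersection definition", {
    expect_equal(overlapAtK(1:10, 1:10, 4), 1.0)
    expect_equal(overlapAtK(1:10, 10:1, 3), 0.0)
    expect_equal(overlapAtK(1:10, 10:1, 10), 1.0)  # k = G: everything overlaps
    r <- modrots:::.withSeed(1, list(a = randomRanks(50), b = randomRanks(50)))
    expect_equal(overlapAtK(r$a, r$b, c(1, 5, 10, 25)),
        vapply(c(1, 5, 10, 25), function(k) oracleOverlap(r$a, r$b, k), 0))
    expect_error(overlapAtK(1:10, 1:10, 11), class = "modrotsValidationError")
})

test_that("the default lattice has the documented shape", {
    ag <- defaultAlphaGrid()
    expect_identical(ncol(ag), 2L)
    expect_true(any(ag[, 1] == 1 & ag[, 2] == 0))   # pure fold change member
    expect_true(any(ag[, 1] == 0 & ag[, 2] == 1))   # pure moderated t member
    expect_identical(nrow(ag), 82L)
    k <- defaultKGrid(1000)
    expect_true(all(diff(k) > 0))
    expect_identical(min(k), 5L)
    expect_identical(max(k), 250L)
    expect_true(all(k < 1000L))
})

test_that("surface matches streaming/naive recomputation from stored overlaps", {
    y <- makeMatrix(20, c(3, 3), nDE = 4, seed = 21)
    des <- buildDesign(twoGroupMeta(c(3, 3)), "group")
    prior <- fixedPrior(4, 0.25)
    boot <- makeBootstrapPairs(des@condition, 5, 31)
    nul <- makeNullPairs(des@condition, 5, 32)
    ag <- rbind(c(0, 1), c(0.5, 1), c(1, 0))
    kg <- c(2L, 4L, 8L)
    surf <- reproducibilitySurface(y, des, prior, ag, kg, boot, nul,
        keepOverlaps = TRUE)
    ov <- attr(surf, "overlaps")$observed
    Rn <- matrix(rowMeans(ov), 3, 3)
    expect_equal(surf@R, Rn, tolerance = 1e-12)
    Sn <- matrix(apply(ov, 1, function(x) sqrt(sum((x - mean(x))^2) / 4)),
        3, 3)
    expect_equal(surf@S, Sn, tolerance = 1e-12)
})

test_that("degenerate zero-spread cells get the -Inf sentinel", {
    y <- makeMatrix(20, c(3, 3), seed = 2)
    des <- buildDesign(twoGroupMeta(c(3, 3)), "group")
    prior <- fixedPrior(4, 0.25)
    boot <- makeBootstrapPairs(des@condition, 2, 3)
    ## force both pairs identical: zero bootstrap spread at every cell
    boot$pairs[[2]] <- boot$pairs[[1]]
    nul <- makeNullPairs(des@condition, 2, 4)
    surf <- reproducibilitySurface(y, des, prior, rbind(c(0.5, 1)), c(2L, 5L),
        boot, nul)
    expect_true(all(surf@S == 0))
    expect_true(all(surf@Z == -Inf))
    expect_true(validObject(surf))
    expect_error(optimizeSurface(surf), class = "modrotsOptimError")
})

test_that("a single dominant feature drives overlap at k = 1", {
    ## one feature shifted far above heteroscedastic noise: it tops both
    ## bootstrap rankings of nearly every pair, while under label permutation
    ## its inflated refit variance keeps the null overlap near baseline
    sim <- simulateSpikeIn(nFeatures = 100, nPerGroup = c(4, 4),
        deFraction = 0.01, effectLog2 = 6, seed = 9)
    y <- SummarizedExperiment::assay(sim)
    des <- buildDesign(as.data.frame(SummarizedExperiment::colData(sim)),
        "condition")
    fit <- fitFeatureModels(y, des)
    prior <- estimatePrior(fit@s2, fit@df)
    boot <- makeBootstrapPairs(des@condition, 20, 109)
    nul <- makeNullPairs(des@condition, 20, 209)
    surf <- reproducibilitySurface(y, des, prior, rbind(c(0.1, 1)), 1L,
        boot, nul)
    expect_gte(surf@R[1, 1], 0.95)
    expect_lte(surf@R0[1, 1], 0.4)
})

test_that("pure noise yields a lower maximal Z than strong signal", {
    des <- buildDesign(twoGroupMeta(c(4, 4)), "group")
    run <- function(y) {
        fit <- fitFeatureModels(y, des)
        prior <- estimatePrior(fit@s2, fit@df)
        boot <- makeBootstrapPairs(des@condition, 30, 71)
        nul <- makeNullPairs(des@condition, 30, 72)
        surf <- reproducibilitySurface(y, des, prior,
            rbind(c(0, 1), c(0.5, 1), c(2, 1)), c(5L, 10L, 20L), boot, nul)
        max(surf@Z[is.finite(surf@Z)])
    }
    zNoise <- run(makeMatrix(100, c(4, 4), nDE = 0, seed = 61))
    zSignal <- run(makeMatrix(100, c(4, 4), nDE = 20, effect = 3, sd = 0.5,
        seed = 61))
    expect_lt(zNoise, zSignal)
})

test_that("optimization breaks ties by smaller alpha1 then larger k", {
    mk <- function(Z) new("ReproSurface",
        alpha1 = c(0.2, 0.1), alpha2 = c(1, 1), k = c(3L, 7L),
        R = matrix(0.5, 2, 2), R0 = matrix(0.1, 2, 2),
        S = matrix(0.1, 2, 2), Z = Z)
    ## tie across alpha rows: smaller alpha1 (row 2) wins
    opt <- optimizeSurface(mk(matrix(c(4, 4, 1, 1), 2, 2)))
    expect_equal(unname(opt$alpha[1]), 0.1)
    ## tie across k within one row: larger k wins
    opt2 <- optimizeSurface(mk(matrix(c(4, 1, 4, 1), 2, 2)))
    expect_identical(opt2$k, 7L)
})

test_that("optimal k tracks the true number of changed features", {
    hits <- 0L
    for (s in 1:3) {
        sim <- simulateSpikeIn(nFeatures = 300, deFraction = 0.1,
            effectLog2 = 2, seed = s)
        res <- modROTS(sim, condition = "condition", B = 60, P = 10,
            seed = 100 + s)
        if (optK(res) >= 15L && optK(res) <= 60L) hits <- hits + 1L
    }
    ## true DE count is 30; within a factor of two in most runs
    expect_gte(hits, 2L)
})
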