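## Small fixture builders shared across test files.

## Plain two-group expression matrix with optional spiked features.
makeMatrix <- function(G, nPerGroup = c(3, 3), nDE = 0, effect = 2,
                       sd = 0.5, seed = 1) {
    withr_seed <- function(code) modrots:::.withSeed(seed, code)
    n <- sum(nPerGroup)
    withr_seed({
        m <- matrix(rnorm(G * n, mean = 20, sd = sd), G, n)
        if (nDE > 0) {
            grpB <- seq.int(nPerGroup[1] + 1, n)
            m[seq_len(nDE), grpB] <- m[seq_len(nDE), grpB] + effect
        }
        dimnames(m) <- list(sprintf("f%04d", seq_len(G)),
                            sprintf("s%02d", seq_len(n)))
        m
    })
}

twoGroupMeta <- function(nPerGroup = c(3, 3), sampleIds = NULL) {
    md <- data.frame(group = rep(c("A", "B"), times = nPerGroup))
    if (!is.null(sampleIds)) rownames(md) <- sampleIds
    md
}

## A valid VariancePrior without running the estimator.
fixedPrior <- function(f0 = 4, s0sq = 0.25) {
    new("VariancePrior", priorDf = f0, priorVar = s0sq)
}

## Random rank permutation.
randomRanks <- function(G) sample.int(G, G)
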