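## Resampling plans: paired stratified bootstraps for the reproducibility
## estimate, label permutations for the nulls. Plans are pure functions of
## (inputs, seed); every pair draws from its own derived RNG stream so results
## do not depend on evaluation order.

.checkCondition <- function(condition) {
    condition <- as.factor(condition)
    tab <- table(condition)
    if (any(tab < 2L))
        .stopValidation("condition level(s) with a single sample: %s (bootstrap variance undefined)",
            paste(names(tab)[tab < 2L], collapse = ", "))
    condition
}

## One stratified-with-replacement draw of sample indices: stratum sizes
## preserved exactly, indices drawn within each condition level.
.stratifiedDraw <- function(condition) {
    idx <- integer(length(condition))
    pos <- 1L
    for (lev in levels(condition)) {
        members <- which(condition == lev)
        take <- members[sample.int(length(members), length(members),
            replace = TRUE)]
        idx[seq.int(pos, length.out = length(members))] <- take
        pos <- pos + length(members)
    }
    idx
}

#' Paired stratified bootstrap plan
#'
#' Draws \code{B} independent pairs of bootstrap datasets: each member of a
#' pair resamples sample indices with replacement within the condition strata,
#' preserving every stratum's size exactly. Covariates travel with their
#' sample (whole rows are resampled).
#'
#' @param condition factor (or coercible) of condition labels, one per sample;
#'   every level needs at least 2 samples.
#' @param B number of bootstrap pairs (>= 2; the method default is 1000).
#' @param seed integer seed; the plan is a pure function of
#'   \code{(condition, B, seed)} and each pair uses its own derived stream.
#'
#' @return an object of class \code{"BootstrapPlan"}: a list with elements
#'   \code{B}, \code{seed}, \code{condition} and \code{pairs}, where
#'   \code{pairs[[b]]} holds integer index vectors \code{d1} and \code{d2}.
#'
#' @export
makeBootstrapPairs <- function(condition, B, seed) {
    if (B < 2L) .stopValidation("B must be at least 2")
    condition <- .checkCondition(condition)
    pairs <- vector("list", B)
    for (b in seq_len(B)) {
        pairs[[b]] <- .withSeed(.deriveSeed(seed, b), list(
            d1 = .stratifiedDraw(condition),
            d2 = .stratifiedDraw(condition)
        ))
    }
    structure(list(B = as.integer(B), seed = as.integer(seed),
        condition = condition, pairs = pairs), class = "BootstrapPlan")
}

## Enumerate all distinct arrangements of a multiset of labels (used when the
## number of distinct label assignments is small enough to be exhaustive).
.multisetPermutations <- function(labels) {
    lv <- unique(labels)
    counts <- as.integer(table(factor(labels, levels = lv)))
    n <- length(labels)
    out <- list()
    rec <- function(prefix, counts) {
        if (length(prefix) == n) {
            out[[length(out) + 1L]] <<- prefix
            return(invisible())
        }
        for (j in seq_along(lv)) {
            if (counts[j] > 0L) {
                counts[j] <- counts[j] - 1L
                rec(c(prefix, lv[j]), counts)
                counts[j] <- counts[j] + 1L
            }
        }
    }
    rec(character(0), counts)
    out
}

#' Label permutation plan
#'
#' Generates \code{P} permutations of the condition labels over samples.
#' Covariates are never permuted: a permutation replaces the condition column
#' only, and design matrices are rebuilt with the permuted condition but the
#' original covariates. When the number of distinct label assignments is at
#' most \code{P}, all of them are enumerated exactly once (exhaustive mode);
#' otherwise \code{P} uniformly random permutations are drawn (duplicates
#' possible).
#'
#' @param condition factor (or coercible) of condition labels.
#' @param P number of permutations requested (>= 2).
#' @param seed integer seed (ignored in exhaustive mode, which is
#'   deterministic by construction).
#'
#' @return an object of class \code{"PermutationPlan"}: a list with elements
#'   \code{P} (the number of permutations actually produced),
#'   \code{exhaustive} (logical), \code{seed} and \code{labels} (a list of
#'   permuted label factors, levels identical to the input).
#'
#' @export
makePermutations <- function(condition, P, seed) {
    if (P < 2L) .stopValidation("P must be at least 2")
    condition <- as.factor(condition)
    n <- length(condition)
    counts <- as.integer(table(condition))
    nDistinct <- round(exp(lfactorial(n) - sum(lfactorial(counts))))
    if (is.finite(nDistinct) && nDistinct <= P) {
        perms <- .multisetPermutations(as.character(condition))
        labels <- lapply(perms, factor, levels = levels(condition))
        return(structure(list(P = length(labels), exhaustive = TRUE,
            seed = as.integer(seed), labels = labels),
            class = "PermutationPlan"))
    }
    labels <- vector("list", P)
    for (p in seq_len(P)) {
        labels[[p]] <- .withSeed(.deriveSeed(seed, 500000L + p),
            condition[sample.int(n, n)])
    }
    structure(list(P = as.integer(P), exhaustive = FALSE,
        seed = as.integer(seed), labels = labels), class = "PermutationPlan")
}

#' Null resampling plan for the reproducibility baseline
#'
#' Builds the permuted-data ensemble against which bootstrap reproducibility
#' is standardized: \code{B} pairs, where each pair draws one fresh uniform
#' permutation of the condition labels (shared by both members, covariates
#' fixed to their samples) and then two independent stratified bootstraps
#' under the permuted labels — i.e. permuted datasets bootstrapped exactly
#' like the observed data.
#'
#' @inheritParams makeBootstrapPairs
#'
#' @return an object of class \code{"NullPlan"}: a list with \code{B},
#'   \code{seed} and \code{pairs}, where \code{pairs[[b]]} holds the permuted
#'   label factor \code{labels} and index vectors \code{d1}, \code{d2}.
#'
#' @export
makeNullPairs <- function(condition, B, seed) {
    if (B < 2L) .stopValidation("B must be at least 2")
    condition <- .checkCondition(condition)
    n <- length(condition)
    pairs <- vector("list", B)
    for (b in seq_len(B)) {
        pairs[[b]] <- .withSeed(.deriveSeed(seed, 1000000L + b), {
            labels <- condition[sample.int(n, n)]
            list(labels = labels,
                 d1 = .stratifiedDraw(labels),
                 d2 = .stratifiedDraw(labels))
        })
    }
    structure(list(B = as.integer(B), seed = as.integer(seed),
        condition = condition, pairs = pairs), class = "NullPlan")
}
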