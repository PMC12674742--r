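## Internal helpers: classed error conditions, seed management, input checks.

.stopValidation <- function(fmt, ...) {
    stop(errorCondition(sprintf(fmt, ...),
        class = c("modrotsValidationError", "modrotsError")))
}

.stopConfig <- function(fmt, ...) {
    stop(errorCondition(sprintf(fmt, ...),
        class = c("modrotsConfigError", "modrotsError")))
}

.stopDegenerate <- function(fmt, ...) {
    stop(errorCondition(sprintf(fmt, ...),
        class = c("modrotsDegenerateError", "modrotsError")))
}

.stopOptim <- function(fmt, ...) {
    stop(errorCondition(sprintf(fmt, ...),
        class = c("modrotsOptimError", "modrotsError")))
}

.stopParse <- function(fmt, ...) {
    stop(errorCondition(sprintf(fmt, ...),
        class = c("modrotsParseError", "modrotsError")))
}

## Evaluate `expr` under a fixed RNG state without disturbing the caller's
## .Random.seed.
.withSeed <- function(seed, expr) {
    env <- globalenv()
    had <- exists(".Random.seed", envir = env, inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = env) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, envir = env)
        else if (exists(".Random.seed", envir = env, inherits = FALSE))
            rm(".Random.seed", envir = env)
    })
    set.seed(seed)
    expr
}

## Deterministic sub-stream seeds, kept inside 32-bit integer range.
## 48271 is the MINSTD multiplier; products stay below 2^53 in double
## arithmetic so the modular reduction is exact.
.deriveSeed <- function(seed, tag) {
    as.integer((abs(as.double(seed)) * 48271 + abs(as.double(tag))) %%
        2147483647) + 1L
}

## Validate a features x samples log2 expression matrix.
.validateExpression <- function(x) {
    if (!is.matrix(x) || !is.numeric(x))
        .stopValidation("expression data must be a numeric matrix (features x samples)")
    if (any(!is.finite(x))) {
        bad <- which(!is.finite(x), arr.ind = TRUE)[1L, ]
        .stopValidation(paste0(
            "expression matrix must be complete: non-finite value at ",
            "feature %s, sample %s (missing values must be handled upstream)"),
            bad[1L], bad[2L])
    }
    if (nrow(x) < 2L)
        .stopValidation("need at least 2 features, got %d", nrow(x))
    if (ncol(x) < 4L)
        .stopValidation("need at least 4 samples, got %d", ncol(x))
    ids <- rownames(x)
    if (is.null(ids))
        .stopValidation("expression matrix must have feature identifiers as rownames")
    if (anyDuplicated(ids))
        .stopValidation("duplicated feature identifiers: %s",
            paste(unique(ids[duplicated(ids)])[seq_len(min(5L, sum(duplicated(ids))))],
                collapse = ", "))
    if (!is.null(colnames(x)) && anyDuplicated(colnames(x)))
        .stopValidation("duplicated sample identifiers")
    invisible(TRUE)
}

.packageVersionString <- function() {
    as.character(utils::packageVersion("modrots"))
}
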