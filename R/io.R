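## TSV/CSV readers and writers. Canonical dialect: tab-separated, UTF-8,
## '#'-prefixed comment header lines; CSV accepted on input (by extension).
## Samples are always aligned by id, never by column position.

.readDelim <- function(path) {
    if (!file.exists(path)) .stopConfig("file not found: %s", path)
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    data.table::fread(path, sep = sep, header = TRUE, data.table = FALSE,
        check.names = FALSE, na.strings = c("NA", "NaN", ""))
}

#' Read a log2 expression matrix
#'
#' First column = feature identifier, remaining columns = samples, values =
#' log2 intensities. The matrix must be complete: any missing or non-numeric
#' cell is an error naming its coordinates.
#'
#' @param path TSV or CSV file (delimiter inferred from the extension).
#' @return numeric matrix, features x samples, with identifiers as dimnames.
#' @export
readExpressionMatrix <- function(path) {
    df <- .readDelim(path)
    if (ncol(df) < 2L) .stopParse("expression file needs id + sample columns")
    ids <- as.character(df[[1L]])
    if (anyDuplicated(ids))
        .stopValidation("duplicate feature ids in %s: %s", path,
            paste(unique(ids[duplicated(ids)])[1:min(3, sum(duplicated(ids)))],
                collapse = ", "))
    m <- as.matrix(df[, -1L, drop = FALSE])
    if (is.character(m)) {
        num <- suppressWarnings(matrix(as.numeric(m), nrow(m), ncol(m)))
        bad <- which(is.na(num) & !is.na(m), arr.ind = TRUE)
        if (nrow(bad))
            .stopParse("non-numeric cell at feature '%s', sample '%s' in %s",
                ids[bad[1L, 1L]], colnames(df)[-1L][bad[1L, 2L]], path)
        m <- num
    }
    storage.mode(m) <- "double"
    if (anyNA(m)) {
        bad <- which(is.na(m), arr.ind = TRUE)
        .stopValidation(paste0("missing value at feature '%s', sample '%s' in ",
            "%s: the expression matrix must be complete (impute upstream)"),
            ids[bad[1L, 1L]], colnames(df)[-1L][bad[1L, 2L]], path)
    }
    dimnames(m) <- list(ids, colnames(df)[-1L])
    m
}

#' Read a sample metadata table
#'
#' First column = sample identifier (matched against the expression header by
#' id, not position), one column per variable.
#'
#' @param path TSV or CSV file.
#' @return data.frame with sample ids as rownames.
#' @export
readSampleMetadata <- function(path) {
    df <- .readDelim(path)
    if (ncol(df) < 2L) .stopParse("metadata needs id + variable columns")
    ids <- as.character(df[[1L]])
    if (anyDuplicated(ids)) .stopValidation("duplicate sample ids in %s", path)
    out <- df[, -1L, drop = FALSE]
    rownames(out) <- ids
    out
}

#' Write (and read back) a differential expression result table
#'
#' The TSV carries '#'-prefixed header lines recording the estimated prior,
#' the optimized parameters, the run configuration and the package version,
#' followed by the per-feature columns \code{feature_id},
#' \code{effect_log2fc}, \code{d_opt}, \code{alpha1}, \code{alpha2},
#' \code{k_opt}, \code{pvalue}, \code{qvalue}, \code{significant}.
#'
#' @param res a \code{\linkS4class{ModROTSResults}}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeResults <- function(res, path) {
    if (!is(res, "ModROTSResults"))
        .stopConfig("res must be a ModROTSResults")
    hdr <- c(
        sprintf("# modrots version=%s", .packageVersionString()),
        sprintf("# prior_df=%.17g prior_var=%.17g", res@prior@priorDf,
            res@prior@priorVar),
        sprintf("# alpha1=%.17g alpha2=%.17g k=%d bestZ=%.17g",
            res@alpha[1L], res@alpha[2L], res@k, res@bestZ),
        sprintf("# B=%d P=%d seed=%d fdr_cutoff=%g u=%.17g df=%g",
            res@B, res@P, res@seed, res@fdrCutoff, res@u, res@df)
    )
    tab <- as.data.frame(res@results)
    tab$alpha1 <- res@alpha[1L]
    tab$alpha2 <- res@alpha[2L]
    tab$k_opt <- res@k
    tab <- tab[, c("feature_id", "effect_log2fc", "d_opt", "alpha1",
        "alpha2", "k_opt", "pvalue", "qvalue", "significant")]
    for (col in c("effect_log2fc", "d_opt", "pvalue", "qvalue"))
        tab[[col]] <- sprintf("%.15g", tab[[col]])
    con <- file(path, open = "wt")
    on.exit(close(con))
    writeLines(hdr, con)
    utils::write.table(tab, con, sep = "\t", quote = FALSE,
        row.names = FALSE)
    invisible(path)
}

#' @rdname writeResults
#' @param path TSV written by \code{writeResults}.
#' @return \code{readResults} returns a list with \code{header} (named
#'   character vector of the recorded run parameters) and \code{table}
#'   (data.frame of the per-feature columns).
#' @export
readResults <- function(path) {
    if (!file.exists(path)) .stopConfig("file not found: %s", path)
    lines <- readLines(path)
    hdrLines <- lines[startsWith(lines, "#")]
    kv <- unlist(regmatches(hdrLines,
        gregexpr("[A-Za-z_0-9]+=[^ ]+", hdrLines)))
    header <- vapply(strsplit(kv, "=", fixed = TRUE), `[`, "", 2L)
    names(header) <- vapply(strsplit(kv, "=", fixed = TRUE), `[`, "", 1L)
    tab <- utils::read.delim(text = lines[!startsWith(lines, "#")],
        stringsAsFactors = FALSE)
    tab$significant <- as.logical(tab$significant)
    list(header = header, table = tab)
}

#' Write a simulated dataset to plain-text files
#'
#' Emits \code{<prefix>_expression.tsv}, \code{<prefix>_metadata.tsv} and
#' \code{<prefix>_truth.tsv} (columns \code{feature_id}, \code{is_de},
#' \code{true_effect}, \code{batch_shift}).
#'
#' @param sim a \code{SummarizedExperiment} from \code{\link{simulateSpikeIn}}.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return named character vector of the three paths, invisibly.
#' @export
writeSimulation <- function(sim, dir, prefix = "sim") {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    expr <- SummarizedExperiment::assay(sim, 1L)
    rd <- as.data.frame(SummarizedExperiment::rowData(sim))
    cd <- as.data.frame(SummarizedExperiment::colData(sim))
    paths <- c(
        expression = file.path(dir, paste0(prefix, "_expression.tsv")),
        metadata = file.path(dir, paste0(prefix, "_metadata.tsv")),
        truth = file.path(dir, paste0(prefix, "_truth.tsv"))
    )
    utils::write.table(data.frame(feature_id = rownames(expr), expr,
        check.names = FALSE), paths["expression"], sep = "\t", quote = FALSE,
        row.names = FALSE)
    utils::write.table(data.frame(sample_id = rownames(cd), cd,
        check.names = FALSE), paths["metadata"], sep = "\t", quote = FALSE,
        row.names = FALSE)
    utils::write.table(data.frame(feature_id = rownames(expr),
        is_de = rd$is_de, true_effect = rd$true_effect,
        batch_shift = rd$batch_shift), paths["truth"], sep = "\t",
        quote = FALSE, row.names = FALSE)
    invisible(paths)
}
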