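#' Read a gene x sample expression matrix (cBioPortal z-score dialect)
#'
#' Tab-separated, header row of sample IDs, first column gene symbols.  In
#' the cBioPortal dialect an optional second `Entrez_Gene_Id` column is
#' skipped.  Missing cells become `NA` (never silent zeros).
#'
#' @param path file path.
#' @param dialect `"cbioportal"` (default) or `"plain"` (no Entrez column
#'   special-casing).
#' @param duplicates policy for duplicated gene symbols: `"error"` (default)
#'   or `"mean"` (collapse by row mean, NA-aware).
#' @return numeric matrix with gene rownames and sample colnames.
#' @export
readExpression <- function(path, dialect = c("cbioportal", "plain"),
    duplicates = c("error", "mean")) {
    dialect <- match.arg(dialect)
    duplicates <- match.arg(duplicates)
    df <- utils::read.delim(path, check.names = FALSE,
        stringsAsFactors = FALSE, na.strings = c("NA", ""))
    if (ncol(df) < 2L)
        stopf("malformed expression header in '%s': need >= 2 columns",
            path)
    genes <- as.character(df[[1L]])
    df <- df[, -1L, drop = FALSE]
    if (dialect == "cbioportal" &&
        tolower(colnames(df)[1L]) %in% c("entrez_gene_id", "entrez"))
        df <- df[, -1L, drop = FALSE]
    if (ncol(df) < 1L || anyDuplicated(colnames(df)) ||
        any(!nzchar(colnames(df))))
        stopf("malformed expression header in '%s'", path)
    mat <- as.matrix(df)
    if (!is.numeric(mat)) storage.mode(mat) <- "double"
    rownames(mat) <- genes

    allMissing <- rowSums(!is.na(mat)) == 0L
    if (any(allMissing)) {
        warnf("dropping %d all-missing gene row(s): %s", sum(allMissing),
            paste(utils::head(genes[allMissing], 5L), collapse = ", "))
        mat <- mat[!allMissing, , drop = FALSE]
    }
    dup <- unique(rownames(mat)[duplicated(rownames(mat))])
    if (length(dup)) {
        if (duplicates == "error")
            stopf("duplicated gene symbol(s): %s",
                paste(dup, collapse = ", "))
        mat <- do.call(rbind, lapply(split.data.frame(mat, rownames(mat)),
            function(m) colMeans(m, na.rm = TRUE)))
        mat <- mat[unique(genes[genes %in% rownames(mat)]), , drop = FALSE]
        mat[is.nan(mat)] <- NA_real_
    }
    mat
}

.fmt <- function(x) ifelse(is.na(x), "NA", formatC(signif(x, 6),
    format = "g", digits = 6))

#' Write an expression matrix as tab-separated z-scores
#' @param mat numeric matrix, gene rownames, sample colnames.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeExpression <- function(mat, path) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(paste(c("Hugo_Symbol", colnames(mat)), collapse = "\t"),
        con, sep = "\n")
    body <- apply(mat, 1L, function(z) paste(.fmt(z), collapse = "\t"))
    writeLines(paste(rownames(mat), body, sep = "\t"), con, sep = "\n")
    invisible(path)
}

#' Read a clinical table
#'
#' Tab-separated with columns `sample`, `subtype`, `age`, `os_months`,
#' `os_status`.  Status accepts `0`/`1` and the cBioPortal strings
#' `0:LIVING` / `1:DECEASED`.
#'
#' @param path file path.
#' @return data.frame, one row per sample.
#' @export
readClinical <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE,
        stringsAsFactors = FALSE, na.strings = c("NA", ""))
    need <- c("sample", "subtype", "age", "os_months", "os_status")
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        stopf("clinical table lacks column(s): %s",
            paste(miss, collapse = ", "))
    if (anyDuplicated(df$sample))
        stopf("duplicated sample ID(s) in clinical table")
    st <- as.character(df$os_status)
    st <- sub("^([01]):(LIVING|DECEASED)$", "\\1", st)
    bad <- !is.na(st) & !st %in% c("0", "1")
    if (any(bad)) stopf("unparseable os_status value(s): %s",
        paste(unique(st[bad]), collapse = ", "))
    df$os_status <- as.integer(st)
    df$os_months <- as.numeric(df$os_months)
    if (any(df$os_months < 0, na.rm = TRUE))
        stopf("negative os_months")
    df[need]
}

#' Write a clinical table
#' @param clin data.frame with sample, subtype, age, os_months, os_status.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeClinical <- function(clin, path) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(paste(colnames(clin), collapse = "\t"), con, sep = "\n")
    rows <- apply(clin, 1L, function(z) paste(trimws(z), collapse = "\t"))
    writeLines(rows, con, sep = "\n")
    invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Each line: name TAB description TAB member gene symbols.  Duplicate
#' members within a set are collapsed with a warning; empty sets are errors.
#'
#' @param path file path.
#' @return named list of character vectors; descriptions kept in
#'   `attr(, "description")`.
#' @export
readGMT <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    if (!length(lines)) stopf("empty GMT file '%s'", path)
    sets <- list(); desc <- character()
    for (ln in lines) {
        parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
        if (length(parts) < 3L)
            stopf("GMT line with no members: '%s'",
                substr(ln, 1, 40))
        members <- parts[-(1:2)]
        members <- members[nzchar(members)]
        if (!length(members)) stopf("empty gene set '%s'", parts[1L])
        if (anyDuplicated(members)) {
            warnf("duplicate members in set '%s' collapsed", parts[1L])
            members <- unique(members)
        }
        sets[[parts[1L]]] <- members
        desc[parts[1L]] <- parts[2L]
    }
    attr(sets, "description") <- desc
    sets
}

#' Write gene sets to a GMT file
#' @param sets named list of character vectors; optional
#'   `attr(sets, "description")`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeGMT <- function(sets, path) {
    desc <- attr(sets, "description")
    if (is.null(desc)) desc <- setNames(rep("na", length(sets)),
        names(sets))
    con <- file(path, open = "wb")
    on.exit(close(con))
    for (nm in names(sets))
        writeLines(paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t"),
            con, sep = "\n")
    invisible(path)
}

#' Read an interaction edge list
#'
#' Tab-separated `node TAB node TAB confidence`; confidence must lie in
#' `[0, 1]`; self-loops and duplicate (unordered) edges are errors.
#'
#' @param path file path.
#' @return an undirected igraph with a `confidence` edge attribute.
#' @export
readEdges <- function(path) {
    df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
        stringsAsFactors = FALSE)
    if (ncol(df) < 3L) stopf("edge list needs 3 columns (node, node, score)")
    colnames(df)[1:3] <- c("from", "to", "confidence")
    df$confidence <- as.numeric(df$confidence)
    if (any(is.na(df$confidence) | df$confidence < 0 | df$confidence > 1))
        stopf("edge confidence outside [0, 1]")
    if (any(df$from == df$to))
        stopf("self-loop edge(s): %s",
            paste(unique(df$from[df$from == df$to]), collapse = ", "))
    key <- apply(df[, 1:2], 1L, function(z) paste(sort(z), collapse = "|"))
    if (anyDuplicated(key)) stopf("duplicate edge(s) in '%s'", path)
    igraph::graph_from_data_frame(df, directed = FALSE)
}

#' Write an interaction graph as an edge list
#' @param graph an igraph with a `confidence` edge attribute.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeEdges <- function(graph, path) {
    el <- igraph::as_edgelist(graph)
    conf <- igraph::edge_attr(graph, "confidence")
    if (is.null(conf)) conf <- rep(1, nrow(el))
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines("from\tto\tconfidence", con, sep = "\n")
    writeLines(paste(el[, 1L], el[, 2L], .fmt(conf), sep = "\t"), con,
        sep = "\n")
    invisible(path)
}

#' Over/under/neutral expression-status call from a z-score
#'
#' Over iff z > hi, under iff z < lo, else neutral; both inequalities are
#' strict, so z exactly at a threshold is neutral.
#'
#' @param z numeric vector of z-scores (finite).
#' @param hi upper threshold (default +1).
#' @param lo lower threshold (default -1).
#' @return character vector over \{"over", "under", "neutral"\}.
#' @export
callExpressionStatus <- function(z, hi = 1, lo = -1) {
    if (hi <= lo) stopf("hi must exceed lo")
    if (any(!is.finite(z)))
        stopf("non-finite z-score(s) passed to callExpressionStatus")
    ifelse(z > hi, "over", ifelse(z < lo, "under", "neutral"))
}

#' Drop samples lacking expression, subtype or survival data
#'
#' Retains samples present in both the expression matrix and clinical table
#' with a non-missing subtype, survival time and event status; every drop is
#' itemized with its (first applicable) reason.
#'
#' @param expr gene x sample matrix.
#' @param clin clinical data.frame (as from [readClinical()]).
#' @return list with `expr`, `clin`, and `drops` (data.frame sample,
#'   reason).
#' @export
filterCompleteCases <- function(expr, clin) {
    universe <- union(colnames(expr), clin$sample)
    reason <- setNames(rep(NA_character_, length(universe)), universe)
    inExpr <- universe %in% colnames(expr)
    inClin <- universe %in% clin$sample
    reason[!inExpr] <- "expression"
    reason[inExpr & !inClin] <- "clinical"
    idx <- match(universe, clin$sample)
    noSub <- inClin & (is.na(clin$subtype[idx]) |
        !nzchar(as.character(clin$subtype[idx])))
    noSurv <- inClin & (is.na(clin$os_months[idx]) |
        is.na(clin$os_status[idx]))
    reason[is.na(reason) & noSub] <- "subtype"
    reason[is.na(reason) & noSurv] <- "survival"
    keep <- universe[is.na(reason)]
    if (!length(keep)) stopf("no samples survive complete-case filtering")
    drops <- data.frame(sample = universe[!is.na(reason)],
        reason = unname(reason[!is.na(reason)]),
        stringsAsFactors = FALSE)
    keepExpr <- colnames(expr)[colnames(expr) %in% keep]
    list(expr = expr[, keepExpr, drop = FALSE],
        clin = clin[clin$sample %in% keep, , drop = FALSE],
        drops = drops[order(drops$sample), , drop = FALSE])
}

#' Per-sample flag: any listed cytokine overexpressed?
#'
#' TRUE iff at least one of the listed genes has status "over"
#' (z > `hi`) in the sample.
#'
#' @param expr gene x sample matrix of z-scores.
#' @param cytokines gene symbols to test (all must be present).
#' @param hi overexpression threshold (default +1, strict).
#' @return named logical vector over samples.
#' @export
anyCytokinePositive <- function(expr, cytokines = cytokinePanel(),
    hi = 1) {
    miss <- setdiff(cytokines, rownames(expr))
    if (length(miss))
        stopf("cytokine(s) absent from matrix: %s",
            paste(miss, collapse = ", "))
    sub <- expr[cytokines, , drop = FALSE]
    apply(sub, 2L, function(z) any(z > hi, na.rm = TRUE))
}
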