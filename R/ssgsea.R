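#' Per-sample rank transform of an expression matrix
#'
#' Within each sample, genes are ranked ascending in expression (1 = lowest,
#' N = highest) with average ranks for ties.  Missing values rank below all
#' observed values, with a deterministic tie-break by gene symbol
#' (lexicographically earlier symbols receive the lower ranks), so that each
#' column still sums to N(N+1)/2.
#'
#' @param expr gene x sample matrix.
#' @return rank matrix of the same shape.
#' @export
rankTransform <- function(expr) {
    if (nrow(expr) < 2L) stopf("rank transform needs >= 2 genes")
    genes <- rownames(expr)
    out <- apply(expr, 2L, function(x) {
        r <- numeric(length(x))
        obs <- !is.na(x)
        m <- sum(!obs)
        if (m) {
            missOrd <- order(genes[!obs])
            r[!obs][missOrd] <- seq_len(m)
        }
        r[obs] <- m + rank(x[obs], ties.method = "average")
        r
    })
    dimnames(out) <- dimnames(expr)
    out
}

# Walk positions (1 = highest rank) and their "remaining steps" weight
# v_g = N - pos_g + 1; ties in rank are broken by gene symbol so the walk
# order is deterministic.
.walkWeights <- function(ranks, genes) {
    N <- length(ranks)
    ord <- order(-ranks, genes)
    v <- numeric(N)
    v[ord] <- N:1
    v
}

#' Single-sample enrichment score for one gene set
#'
#' The ssGSEA statistic: genes are walked in decreasing rank order while two
#' cumulative distributions are maintained — the in-set ECDF weighted by
#' rank^tau and the unweighted out-of-set ECDF — and the ES is the sum of
#' their running difference over all N positions.  Computed here via the
#' algebraically identical closed form
#' `ES = sum_{g in S} w_g v_g / sum_{g in S} w_g - sum_{g notin S} v_g / (N - |S|)`
#' with `w_g = rank_g^tau` and `v_g = N - pos_g + 1`, which is O(N) and
#' vectorizes over many gene sets.
#'
#' @param ranks named per-gene rank vector for one sample (as one column of
#'   [rankTransform()]).
#' @param gene_set character vector of member gene symbols.
#' @param tau rank-weighting exponent (default 0.25).
#' @return the raw ES (unitless scalar).
#' @export
esSample <- function(ranks, gene_set, tau = 0.25) {
    genes <- names(ranks)
    if (is.null(genes)) stopf("ranks must be named by gene symbol")
    inSet <- genes %in% gene_set
    N <- length(ranks)
    nIn <- sum(inSet)
    if (nIn == 0L) stopf("gene set does not intersect the matrix genes")
    if (nIn == N) stopf("gene set covers all genes; out-of-set ECDF undefined")
    v <- .walkWeights(ranks, genes)
    w <- ranks^tau
    sum(w[inSet] * v[inSet]) / sum(w[inSet]) -
        sum(v[!inSet]) / (N - nIn)
}

#' Score gene sets over all samples (ssGSEA)
#'
#' Computes the raw ES for every (gene set, sample) pair and normalizes to
#' NES.  With `normalize = "global-range"` (the default, matching the
#' convention behind the package's NES), NES = ES / (max ES - min ES) over
#' the entire result, so all scores share one scale; when the result is a
#' single value (or all values coincide) the range degenerates and |ES| is
#' used, giving NES in \{-1, 0, +1\}.  Gene-set members absent from the
#' matrix are dropped (their count is recorded); an intersection below
#' `min_overlap_frac` of the set triggers a warning, an empty intersection
#' is an error.
#'
#' @param expr gene x sample z-score matrix.
#' @param sets named list of gene-symbol vectors.
#' @param tau rank-weighting exponent (default 0.25).
#' @param normalize `"global-range"` or `"none"`.
#' @param min_overlap_frac warn when a set's measured fraction falls below
#'   this floor (default 0.5).
#' @return an [EnrichmentResult-class].
#' @export
ssgseaScore <- function(expr, sets, tau = 0.25,
    normalize = c("global-range", "none"), min_overlap_frac = 0.5) {
    normalize <- match.arg(normalize)
    if (!length(sets)) stopf("empty gene-set collection")
    if (is.null(names(sets)) || any(!nzchar(names(sets))))
        stopf("gene sets must be named")
    genes <- rownames(expr)
    N <- length(genes)
    M <- vapply(sets, function(s) genes %in% s, logical(N))
    overlap <- colSums(M)
    if (any(overlap == 0L))
        stopf("gene set(s) with empty intersection: %s",
            paste(names(sets)[overlap == 0L], collapse = ", "))
    if (any(overlap == N))
        stopf("gene set(s) covering every gene: %s",
            paste(names(sets)[overlap == N], collapse = ", "))
    frac <- overlap / lengths(sets)
    if (any(frac < min_overlap_frac))
        warnf("low measured fraction for set(s): %s",
            paste(sprintf("%s (%.0f%%)", names(sets)[frac < min_overlap_frac],
                100 * frac[frac < min_overlap_frac]), collapse = ", "))

    R <- rankTransform(expr)
    storage.mode(M) <- "double"
    es <- matrix(NA_real_, nrow = length(sets), ncol = ncol(expr),
        dimnames = list(names(sets), colnames(expr)))
    for (j in seq_len(ncol(R))) {
        v <- .walkWeights(R[, j], genes)
        w <- R[, j]^tau
        agg <- crossprod(M, cbind(w * v, w, v))   # K x 3
        es[, j] <- agg[, 1L] / agg[, 2L] -
            (sum(v) - agg[, 3L]) / (N - overlap)
    }
    nesMat <- .normalizeES(es, normalize)
    new("EnrichmentResult", es = es, nes = nesMat, tau = tau,
        normalization = normalize, overlap = as.integer(overlap))
}

.normalizeES <- function(es, normalize) {
    if (normalize == "none") return(es)
    rng <- max(es) - min(es)
    if (rng == 0) rng <- abs(max(es))
    if (rng == 0) return(es * 0)
    es / rng
}
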