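#' Pearson correlation matrix with t-distribution p-values
#'
#' Pairwise-complete Pearson correlations among the requested genes across
#' samples, with two-sided p-values from `t = r * sqrt(n - 2) / sqrt(1 - r^2)`
#' against the t distribution on n - 2 degrees of freedom, where n is the
#' pairwise-complete sample count (recorded per pair).
#'
#' @param expr gene x sample z-score matrix.
#' @param genes gene symbols to correlate (all must be present).
#' @return a [CorrelationMatrix-class].
#' @export
pearsonMatrix <- function(expr, genes = rownames(expr)) {
    miss <- setdiff(genes, rownames(expr))
    if (length(miss))
        stopf("gene(s) absent from matrix: %s", paste(miss, collapse = ", "))
    X <- t(expr[genes, , drop = FALSE])    # samples x genes
    obs <- !is.na(X)
    nUsed <- crossprod(obs)
    if (any(nUsed[upper.tri(nUsed)] < 3L))
        stopf("fewer than 3 pairwise-complete samples for some gene pair")
    sds <- apply(X, 2L, stats::sd, na.rm = TRUE)
    if (any(sds == 0 | is.na(sds)))
        stopf("constant gene(s), correlation undefined: %s",
            paste(genes[sds == 0 | is.na(sds)], collapse = ", "))
    r <- stats::cor(X, use = "pairwise.complete.obs")
    r <- pmin(pmax(r, -1), 1)
    tt <- r * sqrt(pmax(nUsed - 2L, 0)) / sqrt(pmax(1 - r^2, 0))
    p <- 2 * stats::pt(abs(tt), df = pmax(nUsed - 2L, 1L),
        lower.tail = FALSE)
    p[abs(r) >= 1] <- 0
    diag(p) <- 0
    storage.mode(nUsed) <- "integer"
    new("CorrelationMatrix", r = r, p = p, nUsed = nUsed)
}

#' Derive the extended signature from seed genes
#'
#' A candidate enters the positive set iff (i) its mean correlation against
#' the seed genes is positive, (ii) its correlation with at least one seed
#' (or every seed, with `require = "all"`) is significantly positive at
#' `p < p_threshold`, and (iii) it has no significantly negative seed
#' correlation.  A candidate enters the negative set iff it has at least one
#' significantly negative seed correlation.  Everything else is
#' unclassified.  Seeds always belong to the positive set.
#'
#' @param corr a [CorrelationMatrix-class] covering seeds and candidates.
#' @param seeds seed gene symbols.
#' @param p_threshold significance threshold (default 0.01).
#' @param require `"any"` (default): one significant seed suffices;
#'   `"all"`: every seed correlation must be significantly positive.
#' @return a [SignatureDerivation-class].
#' @export
deriveExtendedSignature <- function(corr, seeds, p_threshold = 0.01,
    require = c("any", "all")) {
    require <- match.arg(require)
    genes <- rownames(corr@r)
    miss <- setdiff(seeds, genes)
    if (length(miss))
        stopf("seed(s) absent from correlation matrix: %s",
            paste(miss, collapse = ", "))
    candidates <- setdiff(genes, seeds)
    if (!length(candidates)) stopf("no candidate genes beyond the seeds")

    R <- corr@r[candidates, seeds, drop = FALSE]
    P <- corr@p[candidates, seeds, drop = FALSE]
    sigPos <- P < p_threshold & R > 0
    sigNeg <- P < p_threshold & R < 0
    meanR <- rowMeans(R)
    posRule <- if (require == "any") rowSums(sigPos) > 0 else
        rowSums(sigPos) == length(seeds)
    isNeg <- rowSums(sigNeg) > 0
    isPos <- meanR > 0 & posRule & !isNeg

    summary <- data.frame(gene = c(seeds, candidates),
        mean_r = c(rep(1, length(seeds)), unname(meanR)),
        min_p = c(rep(0, length(seeds)),
            unname(apply(P, 1L, min))),
        class = c(rep("seed", length(seeds)),
            ifelse(isNeg, "negative",
                ifelse(isPos, "positive", "unclassified"))),
        stringsAsFactors = FALSE, row.names = NULL)

    new("SignatureDerivation", seeds = seeds, candidates = candidates,
        positiveSet = c(seeds, candidates[isPos]),
        negativeSet = candidates[isNeg],
        pThreshold = p_threshold, summary = summary, corr = corr)
}

#' Closeness and betweenness centrality of an interaction graph
#'
#' Edges below the confidence threshold are dropped first (STRING-style
#' "highest confidence" filtering, default 0.900).  Betweenness is the
#' shortest-path pair-counting statistic normalized by (n-1)(n-2)/2;
#' closeness uses the reachable-component convention
#' `((k-1)/sum d) * ((k-1)/(n-1))` with k the component size, so it is
#' defined (and in [0, 1]) on disconnected graphs.  Ties in the ranking are
#' broken lexicographically by gene symbol.
#'
#' @param graph an undirected igraph with a `confidence` edge attribute.
#' @param min_score minimum edge confidence retained (default 0.900).
#' @return data.frame (node, closeness, betweenness), ordered by decreasing
#'   closeness then symbol.
#' @export
nodeCentrality <- function(graph, min_score = 0.900) {
    conf <- igraph::edge_attr(graph, "confidence")
    if (!is.null(conf))
        graph <- igraph::delete_edges(graph, which(conf < min_score))
    if (igraph::ecount(graph) == 0L)
        stopf("empty graph after confidence thresholding")
    n <- igraph::vcount(graph)
    nodes <- igraph::V(graph)$name

    btw <- igraph::betweenness(graph, directed = FALSE, weights = NA,
        normalized = n > 2L)
    d <- igraph::distances(graph, weights = NA)
    clo <- vapply(seq_len(n), function(i) {
        di <- d[i, -i]
        reach <- di[is.finite(di)]
        k1 <- length(reach)                 # component size minus one
        if (k1 == 0L) return(0)
        (k1 / sum(reach)) * (k1 / (n - 1L))
    }, numeric(1))

    out <- data.frame(node = nodes, closeness = clo,
        betweenness = unname(btw), stringsAsFactors = FALSE)
    out[order(-out$closeness, out$node), , drop = FALSE]
}
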