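#' Subtype composition by stratum
#'
#' Counts and within-stratum fractions of each subtype per stratum (e.g.
#' cytokine-positive vs -negative, or age group).
#'
#' @param clin clinical data.frame with `sample` and `subtype`.
#' @param strata named (by sample) or positional per-sample stratum labels.
#' @return data.frame: stratum, subtype, n, fraction (fractions sum to 1
#'   within each stratum).
#' @export
compositionTable <- function(clin, strata) {
    if (!is.null(names(strata))) strata <- strata[clin$sample]
    if (length(strata) != nrow(clin))
        stopf("strata must cover every sample")
    if (any(is.na(strata)) || any(is.na(clin$subtype)))
        stopf("missing stratum or subtype label")
    tab <- table(stratum = strata, subtype = clin$subtype)
    if (any(rowSums(tab) == 0L))
        stopf("empty stratum: %s",
            paste(rownames(tab)[rowSums(tab) == 0L], collapse = ", "))
    df <- as.data.frame(tab, stringsAsFactors = FALSE)
    colnames(df) <- c("stratum", "subtype", "n")
    tot <- tapply(df$n, df$stratum, sum)
    df$fraction <- df$n / as.numeric(tot[df$stratum])
    df[order(df$stratum, df$subtype), , drop = FALSE]
}

#' Principal component analysis of a sample x variable matrix
#'
#' Column-centered SVD; explained-variance fractions are the normalized
#' squared singular values; each component's sign is fixed so its
#' largest-magnitude loading is positive.
#'
#' @param values numeric sample x variable matrix (e.g. the four cytokine
#'   z-scores).
#' @return list: `scores` (sample x PC), `loadings` (variable x PC),
#'   `explained` (fractions summing to 1).
#' @export
cytokinePCA <- function(values) {
    values <- as.matrix(values)
    if (ncol(values) < 2L || nrow(values) < 3L)
        stopf("need >= 2 variables and >= 3 samples")
    sds <- apply(values, 2L, stats::sd)
    if (any(sds == 0))
        stopf("constant variable(s): %s",
            paste(colnames(values)[sds == 0], collapse = ", "))
    pc <- stats::prcomp(values, center = TRUE, scale. = FALSE)
    flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
        l <- pc$rotation[, j]
        sign(l[which.max(abs(l))])
    }, numeric(1))
    scores <- sweep(pc$x, 2L, flip, `*`)
    loadings <- sweep(pc$rotation, 2L, flip, `*`)
    list(scores = scores, loadings = loadings,
        explained = pc$sdev^2 / sum(pc$sdev^2))
}

#' Two-cluster Lloyd K-means with seeded restarts
#'
#' k is fixed at 2 (the aggressive / non-aggressive reading of the
#' cytokine clusters).  Each restart initializes the two centroids at
#' distinct sampled points and iterates Lloyd updates, asserting that the
#' within-cluster sum of squares never increases; the best restart by WSS
#' wins.  Label 1 is assigned to the cluster with the higher mean first
#' coordinate, so labels are deterministic.
#'
#' @param scores numeric sample x dimension matrix.
#' @param seed integer seed.
#' @param restarts number of seeded restarts (default 10).
#' @return list: `labels` (1/2 per sample), `centers`, `wss`.
#' @export
kmeans2 <- function(scores, seed = 1L, restarts = 10L) {
    scores <- as.matrix(scores)
    n <- nrow(scores)
    if (n < 2L) stopf("need >= 2 samples")
    if (nrow(unique(scores)) < 2L)
        stopf("all points identical; clustering degenerate")
    best <- NULL
    for (r in seq_len(restarts)) {
        set.seed(deriveSeed(seed, r))
        repeat {
            ctr <- scores[sample(n, 2L), , drop = FALSE]
            if (any(ctr[1L, ] != ctr[2L, ])) break
        }
        lab <- NULL
        wssPrev <- Inf
        for (iter in seq_len(100L)) {
            d1 <- rowSums(sweep(scores, 2L, ctr[1L, ])^2)
            d2 <- rowSums(sweep(scores, 2L, ctr[2L, ])^2)
            lab <- ifelse(d1 <= d2, 1L, 2L)
            if (length(unique(lab)) < 2L) break
            ctr <- rbind(colMeans(scores[lab == 1L, , drop = FALSE]),
                colMeans(scores[lab == 2L, , drop = FALSE]))
            wss <- sum(pmin(rowSums(sweep(scores, 2L, ctr[1L, ])^2),
                rowSums(sweep(scores, 2L, ctr[2L, ])^2)))
            if (wss > wssPrev + 1e-8)
                stopf("Lloyd objective increased; numerical fault")
            if (wssPrev - wss < 1e-12) { wssPrev <- wss; break }
            wssPrev <- wss
        }
        if (length(unique(lab)) < 2L) next
        if (is.null(best) || wssPrev < best$wss)
            best <- list(labels = lab, centers = ctr, wss = wssPrev)
    }
    if (is.null(best)) stopf("clustering degenerate")
    # deterministic orientation: cluster 1 has the higher mean first coord
    m1 <- mean(scores[best$labels == 1L, 1L])
    m2 <- mean(scores[best$labels == 2L, 1L])
    if (m2 > m1) {
        best$labels <- 3L - best$labels
        best$centers <- best$centers[2:1, , drop = FALSE]
    }
    names(best$labels) <- rownames(scores)
    best
}

#' Map subtypes to aggressive / non-aggressive disease
#'
#' basal, claudin-low and Her2-enriched count as aggressive; luminal A/B
#' and normal-like as non-aggressive.
#'
#' @param subtype character vector of subtype labels.
#' @param aggressive labels counted as aggressive.
#' @return character vector over \{"aggressive", "non-aggressive"\}.
#' @export
aggressiveGroup <- function(subtype,
    aggressive = c("basal", "claudin-low", "Her2")) {
    ifelse(subtype %in% aggressive, "aggressive", "non-aggressive")
}

#' Sample and gene orderings for a signature co-occurrence heatmap
#'
#' Each sample's score is its mean Pearson correlation to all other samples
#' over the union of the signature genes; samples are ordered by that mean
#' (descending, ties by sample ID).  Genes are grouped by signature
#' membership in the input order (a gene appearing in several signatures is
#' kept with the first).
#'
#' @param expr gene x sample z-score matrix.
#' @param sigs named list of signature gene sets.
#' @return list: `samples` (ordered IDs), `genes` (ordered symbols),
#'   `gene_block` (signature name per ordered gene), `mean_cor` (named,
#'   per sample).
#' @export
heatmapOrder <- function(expr, sigs) {
    if (ncol(expr) < 3L) stopf("need >= 3 samples to order")
    genes <- unique(unlist(sigs))
    genes <- genes[genes %in% rownames(expr)]
    if (!length(genes)) stopf("no signature gene present in the matrix")
    C <- stats::cor(expr[genes, , drop = FALSE],
        use = "pairwise.complete.obs")
    meanCor <- (rowSums(C, na.rm = TRUE) - 1) / (ncol(C) - 1)
    ord <- order(-meanCor, colnames(expr))
    block <- character(); geneOrd <- character()
    for (nm in names(sigs)) {
        g <- sigs[[nm]][sigs[[nm]] %in% rownames(expr)]
        g <- setdiff(g, geneOrd)
        geneOrd <- c(geneOrd, g)
        block <- c(block, rep(nm, length(g)))
    }
    list(samples = colnames(expr)[ord], genes = geneOrd,
        gene_block = setNames(block, geneOrd),
        mean_cor = setNames(meanCor, colnames(expr)))
}
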