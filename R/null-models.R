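#' Sample size-matched null gene sets from a universe
#'
#' Each permutation draws `size` genes without replacement from the
#' universe (all array genes, or an immune-restricted list); sets may repeat
#' across permutations.  Each permutation uses its own seed derived from the
#' master seed by a counter, so increasing `n_perm` never reshuffles
#' earlier sets.
#'
#' @param universe character vector of gene symbols.
#' @param size genes per set (must not exceed the universe).
#' @param n_perm number of sets (default 1000).
#' @param seed master integer seed.
#' @return named list (`perm_0001`, ...) of gene-symbol vectors.
#' @export
sampleNullSets <- function(universe, size, n_perm = 1000L, seed = 1L) {
    universe <- unique(universe)
    if (size > length(universe))
        stopf("set size (%d) exceeds universe (%d)", size,
            length(universe))
    out <- vector("list", n_perm)
    for (i in seq_len(n_perm)) {
        set.seed(deriveSeed(seed, i))
        out[[i]] <- sample(universe, size)
    }
    names(out) <- sprintf("perm_%04d", seq_len(n_perm))
    out
}

#' Permutation null distribution of NES, jointly normalized
#'
#' Scores the observed signature together with `n_perm` size-matched random
#' sets in one ssGSEA run, so observed and null ES share a single
#' global-range NES scale and remain directly comparable.
#'
#' @param expr gene x sample z-score matrix.
#' @param signature the observed gene set (character vector); the null sets
#'   are size-matched to its measured intersection.
#' @param universe gene universe to sample from (default: all matrix
#'   genes); pass an immune-related list for the restricted null.
#' @param n_perm permutations (default 1000).
#' @param seed master integer seed.
#' @param tau ssGSEA weighting exponent.
#' @param universe_name tag stored on the result (`"all-genes"`,
#'   `"immune-related"`, ...).
#' @return a [NullDistribution-class].
#' @export
nullNES <- function(expr, signature, universe = rownames(expr),
    n_perm = 1000L, seed = 1L, tau = 0.25,
    universe_name = "all-genes") {
    size <- sum(rownames(expr) %in% signature)
    if (size == 0L) stopf("signature does not intersect the matrix genes")
    nulls <- sampleNullSets(intersect(universe, rownames(expr)), size,
        n_perm, seed)
    res <- ssgseaScore(expr, c(list(observed = signature), nulls),
        tau = tau, normalize = "global-range", min_overlap_frac = 0)
    nesAll <- nes(res)
    new("NullDistribution", universeName = universe_name,
        setSize = as.integer(size), nPerm = as.integer(n_perm),
        nesValues = nesAll[-1L, , drop = FALSE],
        observedNES = nesAll[1L, ], seed = as.integer(seed))
}

#' Mann-Whitney-Wilcoxon rank-sum test
#'
#' U with average ranks; two-sided p by the normal approximation with tie
#' correction and continuity correction, or exactly (via the null Wilcoxon
#' distribution) when the data are tie-free and n1*n2 <= 400.
#'
#' @param x,y numeric samples.
#' @param exact force (`TRUE`) or forbid (`FALSE`) the exact p-value;
#'   `NULL` (default) auto-selects as above.
#' @return list: `U`, `z`, `p`, `n1`, `n2`, `tie_corrected`, `exact`,
#'   `direction` (`"enriched"` when median(x) > median(y), else
#'   `"excluded"`, `"none"` on equality).
#' @export
mannWhitney <- function(x, y, exact = NULL) {
    n1 <- length(x); n2 <- length(y)
    if (!n1 || !n2) stopf("both groups must be non-empty")
    r <- rank(c(x, y))
    U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    n <- n1 + n2
    ties <- table(r)
    hasTies <- any(ties > 1L)
    if (is.null(exact)) exact <- !hasTies && n1 * n2 <= 400
    if (exact && hasTies)
        stopf("exact p-value unavailable with ties")
    mu <- n1 * n2 / 2
    if (exact) {
        # two-sided: double the smaller tail of the exact U distribution
        lo <- stats::pwilcox(min(U, n1 * n2 - U), n1, n2)
        p <- min(1, 2 * lo)
        z <- stats::qnorm(p / 2) * sign(mu - U)
    } else {
        tieTerm <- sum(ties^3 - ties) / (n * (n - 1))
        sigma <- sqrt(n1 * n2 / 12 * ((n + 1) - tieTerm))
        if (sigma == 0) return(list(U = U, z = 0, p = 1, n1 = n1, n2 = n2,
            tie_corrected = hasTies, exact = FALSE, direction = "none"))
        cc <- sign(U - mu) * 0.5
        z <- (U - mu - cc) / sigma
        p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    md <- stats::median(x) - stats::median(y)
    list(U = U, z = z, p = max(p, .Machine$double.xmin), n1 = n1, n2 = n2,
        tie_corrected = hasTies, exact = exact,
        direction = if (md > 0) "enriched" else if (md < 0) "excluded"
            else "none")
}

#' Compare a subtype's observed NES with its permutation null
#'
#' Group x is the observed per-sample NES over the subtype's samples; group
#' y is, by default, the pooled null NES of the same samples across all
#' permutations (`pooling = "pooled"`), or the per-permutation mean over
#' those samples (`pooling = "perm-mean"`).  Two-sided Mann-Whitney p with
#' tie and continuity corrections; the direction (enriched / excluded) is
#' the sign of the median difference.
#'
#' @param obs_nes named per-sample observed NES (defaults to the null
#'   object's jointly normalized observed NES).
#' @param null a [NullDistribution-class].
#' @param subtype_mask logical vector over samples (or sample names).
#' @param pooling `"pooled"` (default) or `"perm-mean"`.
#' @param exact passed to [mannWhitney()].
#' @return the [mannWhitney()] list.
#' @export
compareSubtypeToNull <- function(obs_nes = NULL, null, subtype_mask,
    pooling = c("pooled", "perm-mean"), exact = NULL) {
    pooling <- match.arg(pooling)
    if (is.null(obs_nes)) obs_nes <- null@observedNES
    if (is.character(subtype_mask))
        subtype_mask <- names(obs_nes) %in% subtype_mask
    if (!any(subtype_mask)) stopf("empty subtype")
    x <- obs_nes[subtype_mask]
    y <- if (pooling == "pooled")
        as.vector(null@nesValues[, subtype_mask, drop = FALSE])
    else rowMeans(null@nesValues[, subtype_mask, drop = FALSE])
    mannWhitney(x, y, exact = exact)
}
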