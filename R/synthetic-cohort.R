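#' Configuration for a synthetic breast-cancer-like cohort
#'
#' Bundles and validates every knob of the synthetic-cohort generator.  The
#' defaults describe the study conditions the package's analyses assume: a
#' claudin-low minority of 11%, a planted signature program of 24 genes whose
#' pairwise correlation is driven by a one-factor model (r = lambda^2), one
#' anti-correlated STAT3 analogue calibrated to r ~ -0.38 against the
#' program, and exponential survival with hazard ratio 1.8 for
#' signature-positive disease, administratively censored at 120 months.
#'
#' @param n_samples number of samples.
#' @param subtype_proportions named fractions summing to 1; names are the
#'   subtype vocabulary.
#' @param n_genes total genes (signature + STAT3 analogue + background).
#' @param signature_size planted program size, seeds included.
#' @param effect_shift z-units added to signature genes in the target
#'   subtype (delta).
#' @param factor_loading loading lambda in `[0, 1)` of signature genes on the
#'   per-sample latent factor; pairwise signature correlation is lambda^2.
#' @param negative_loading loading in `(-1, 0]` of the STAT3 analogue on the
#'   same factor.
#' @param target_subtype label whose samples carry the program.
#' @param hazard_ratio_positive hazard ratio (> 0) of signature-positive vs
#'   negative samples.
#' @param baseline_hazard events per month for signature-negative samples.
#' @param censor_horizon administrative censoring time in months.
#' @param age_range length-2 numeric, uniform age range in years.
#' @param seed integer master seed.
#' @return a validated list of class `CohortConfig`.
#' @export
cohortConfig <- function(n_samples = 500L,
    subtype_proportions = c(lumA = 0.30, lumB = 0.22, Her2 = 0.12,
        basal = 0.18, `claudin-low` = 0.11, normal = 0.07),
    n_genes = 2000L, signature_size = 24L,
    effect_shift = 1, factor_loading = sqrt(0.5),
    negative_loading = -0.563, target_subtype = "claudin-low",
    hazard_ratio_positive = 1.8, baseline_hazard = log(2) / 100,
    censor_horizon = 120, age_range = c(25, 85), seed = 1L) {

    cfg <- list(n_samples = as.integer(n_samples),
        subtype_proportions = subtype_proportions,
        n_genes = as.integer(n_genes),
        signature_size = as.integer(signature_size),
        effect_shift = effect_shift, factor_loading = factor_loading,
        negative_loading = negative_loading,
        target_subtype = target_subtype,
        hazard_ratio_positive = hazard_ratio_positive,
        baseline_hazard = baseline_hazard,
        censor_horizon = censor_horizon, age_range = age_range,
        seed = as.integer(seed))

    p <- cfg$subtype_proportions
    if (is.null(names(p)) || any(!nzchar(names(p))))
        stopf("subtype_proportions must be a named vector")
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
        stopf("subtype proportions must be >= 0 and sum to 1 (got %.12f)",
            sum(p))
    if (!cfg$target_subtype %in% names(p))
        stopf("target_subtype '%s' not among the subtype labels",
            cfg$target_subtype)
    if (cfg$signature_size >= cfg$n_genes)
        stopf("signature_size (%d) must be < n_genes (%d)",
            cfg$signature_size, cfg$n_genes)
    if (cfg$signature_size < 4L)
        stopf("signature_size must be >= 4 (three seeds plus one)")
    if (cfg$censor_horizon <= 0) stopf("censor_horizon must be > 0")
    if (cfg$baseline_hazard <= 0) stopf("baseline_hazard must be > 0")
    if (cfg$hazard_ratio_positive <= 0)
        stopf("hazard_ratio_positive must be > 0")
    if (cfg$factor_loading < 0 || cfg$factor_loading >= 1)
        stopf("factor_loading must lie in [0, 1)")
    if (cfg$negative_loading > 0 || cfg$negative_loading <= -1)
        stopf("negative_loading must lie in (-1, 0]")
    if (length(cfg$age_range) != 2L || diff(cfg$age_range) <= 0)
        stopf("age_range must be an increasing length-2 vector")
    class(cfg) <- "CohortConfig"
    cfg
}

#' The three seed cytokines anchoring the extended signature
#'
#' GM-CSF (CSF2), MCP-1 (CCL2) and RANTES (CCL5): the cytokines the extended
#' M1-like signature is derived from.  G-CSF (CSF3) completes the
#' four-cytokine panel but does not seed the signature.
#'
#' @return character vector of the three seed gene symbols.
#' @export
seedCytokines <- function() c("CSF2", "CCL2", "CCL5")

#' The four-cytokine panel (seeds plus G-CSF)
#' @return character vector of four gene symbols.
#' @export
cytokinePanel <- function() c("CSF2", "CSF3", "CCL2", "CCL5")

.signatureGeneNames <- function(size) {
    c(seedCytokines(), sprintf("M1X%02d", seq_len(size - 3L) + 3L))
}

#' Generate a synthetic cohort with a planted signature program
#'
#' Expression is a gene x sample z-score matrix.  Background genes are
#' i.i.d. standard normal.  Each signature gene i in sample j is
#' `sqrt(1 - lambda^2) * eps_ij + lambda * F_j + delta * [subtype_j == target]`
#' where `F_j` is a per-sample latent factor, so signature genes are
#' equicorrelated with pairwise r = lambda^2 and shifted by delta z-units in
#' the target subtype.  A designated STAT3 analogue loads negatively on the
#' same factor.  The clinical table carries subtype, age (uniform), and
#' exponential survival whose hazard depends on target-subtype membership
#' (the ground-truth signature positivity); censoring is administrative at
#' the configured horizon.  Attached metadata provide the planted signature,
#' three size-matched decoy sets, an immune-analogue gene universe, and a
#' seed-anchored interaction graph with decoy nodes and edges.
#'
#' @param config a [cohortConfig()] object.
#' @return a [SignatureCohort-class].
#' @export
generateCohort <- function(config = cohortConfig()) {
    if (!inherits(config, "CohortConfig"))
        config <- do.call(cohortConfig, config)
    set.seed(deriveSeed(config$seed, 0L))

    n <- config$n_samples
    G <- config$n_genes
    k <- config$signature_size
    lam <- config$factor_loading
    lneg <- config$negative_loading
    delta <- config$effect_shift

    sampleIDs <- sprintf("S%04d", seq_len(n))
    sigGenes <- .signatureGeneNames(k)
    nBack <- G - k - 1L
    backGenes <- sprintf("G%05d", seq_len(nBack))
    # G-CSF analogue is an ordinary background gene under another name
    if (nBack >= 1L) backGenes[1L] <- "CSF3"
    genes <- c(sigGenes, "STAT3", backGenes)

    subtype <- sample(names(config$subtype_proportions), n, replace = TRUE,
        prob = config$subtype_proportions)
    inTarget <- as.numeric(subtype == config$target_subtype)
    Fj <- stats::rnorm(n)

    X <- matrix(stats::rnorm(G * n), nrow = G, ncol = n,
        dimnames = list(genes, sampleIDs))
    X[sigGenes, ] <- sqrt(1 - lam^2) * X[sigGenes, ] +
        rep(lam * Fj + delta * inTarget, each = k)
    X["STAT3", ] <- sqrt(1 - lneg^2) * X["STAT3", ] + lneg * rep(Fj, 1)

    age <- round(stats::runif(n, config$age_range[1], config$age_range[2]),
        1)
    surv <- generateSurvival(subtype, inTarget == 1, config)

    clinical <- S4Vectors::DataFrame(subtype = subtype, age = age,
        os_months = surv$months, os_status = surv$status,
        row.names = sampleIDs)

    geneSets <- list(M1_extended_planted = sigGenes)
    for (d in 1:3) {
        set.seed(deriveSeed(config$seed, d))
        geneSets[[sprintf("decoy_%d", d)]] <-
            sort(sample(backGenes, min(k, nBack)))
    }

    set.seed(deriveSeed(config$seed, 4L))
    nImmune <- min(nBack, max(100L, as.integer(0.1 * G)))
    immuneUniverse <- sort(unique(c(sigGenes, "STAT3",
        sample(backGenes, nImmune))))

    set.seed(deriveSeed(config$seed, 5L))
    graph <- .plantedGraph(sigGenes, backGenes)

    new("SignatureCohort", SummarizedExperiment::SummarizedExperiment(
        assays = list(zscore = X), colData = clinical,
        metadata = list(geneSets = geneSets, graph = graph,
            immuneUniverse = immuneUniverse, config = config)))
}

# Seed-anchored interaction graph: every signature gene and the STAT3
# analogue touch a seed at high confidence; decoy nodes and edges carry the
# usual mid-range STRING-like scores.
.plantedGraph <- function(sigGenes, backGenes, nDecoyNodes = 17L) {
    seeds <- sigGenes[1:3]
    others <- setdiff(sigGenes, seeds)
    decoys <- backGenes[seq_len(min(nDecoyNodes, length(backGenes)))]
    from <- character(); to <- character(); conf <- numeric()
    add <- function(a, b, s) {
        from <<- c(from, a); to <<- c(to, b); conf <<- c(conf, s)
    }
    for (g in c(others, "STAT3"))
        add(sample(seeds, 1L), g, round(stats::runif(1, 0.90, 0.999), 3))
    add(seeds[1], seeds[2], 0.95); add(seeds[2], seeds[3], 0.95)
    for (g in decoys) {
        tgt <- sample(c(others, decoys[decoys != g]), 1L)
        add(g, tgt, round(stats::runif(1, 0.40, 0.95), 3))
    }
    df <- data.frame(from = from, to = to, confidence = conf)
    key <- apply(df[, 1:2], 1L, function(z) paste(sort(z), collapse = "|"))
    df <- df[!duplicated(key) & df$from != df$to, ]
    igraph::graph_from_data_frame(df, directed = FALSE)
}

#' Draw exponential survival with a positivity-dependent hazard
#'
#' Survival time is exponential with rate
#' `baseline_hazard * HR^[positive]`, administratively censored at the
#' configured horizon (status 0 when censored, 1 otherwise).  Months are
#' reported to 2 decimals.
#'
#' @param subtype_labels character vector of subtype labels (length defines
#'   the cohort).
#' @param positivity logical vector, ground-truth signature positivity.
#' @param config a [cohortConfig()]; uses `baseline_hazard`,
#'   `hazard_ratio_positive`, `censor_horizon`.
#' @return list with numeric `months` and integer `status`.
#' @export
generateSurvival <- function(subtype_labels, positivity, config) {
    if (length(subtype_labels) != length(positivity))
        stopf("subtype labels and positivity flags differ in length")
    if (config$hazard_ratio_positive <= 0)
        stopf("hazard_ratio_positive must be > 0")
    rate <- config$baseline_hazard *
        config$hazard_ratio_positive^as.numeric(positivity)
    draw <- stats::rexp(length(rate), rate = rate)
    status <- as.integer(draw <= config$censor_horizon)
    months <- round(pmin(draw, config$censor_horizon), 2)
    list(months = months, status = status)
}

#' Write the standard fixture set for a cohort
#'
#' Emits the expression TSV (cBioPortal z-score dialect), clinical TSV, a
#' GMT of the attached gene sets, the interaction edge list, and the
#' immune-analogue universe (one symbol per line).
#'
#' @param cohort a [SignatureCohort-class].
#' @param dir output directory (created if absent).
#' @return invisibly, the named vector of file paths written.
#' @export
writeCohortFixtures <- function(cohort, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(expression = file.path(dir, "expression.tsv"),
        clinical = file.path(dir, "clinical.tsv"),
        gmt = file.path(dir, "signatures.gmt"),
        edges = file.path(dir, "edges.tsv"),
        immune = file.path(dir, "immune_universe.txt"))
    writeExpression(zscores(cohort), paths["expression"])
    writeClinical(clinicalTable(cohort), paths["clinical"])
    writeGMT(cohortGeneSets(cohort), paths["gmt"])
    writeEdges(interactionGraph(cohort), paths["edges"])
    writeLines(metadata(cohort)$immuneUniverse, paths["immune"])
    invisible(paths)
}
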