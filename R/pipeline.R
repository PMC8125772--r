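.defaultThresholds <- function() list(
    z_hi = 1, z_lo = -1, p_threshold = 0.01, tau = 0.25, k_sd = 1,
    n_perm = 1000L, age_split = 55, horizon = 120, min_confidence = 0.900,
    min_overlap_frac = 0.5)

#' Build and validate a pipeline run configuration
#'
#' Either a `simulate` block (arguments to [cohortConfig()]) or an `inputs`
#' block (paths: `expression`, `clinical`, `gmt`, `edges`, optional
#' `immune_universe`) must be supplied.  Unknown keys anywhere are errors,
#' not warnings.
#'
#' @param simulate named list of [cohortConfig()] overrides, or `NULL`.
#' @param inputs named list of input file paths, or `NULL`.
#' @param stages stages to run, in dependency order.
#' @param thresholds named overrides of the analysis thresholds (z hi/lo,
#'   `p_threshold`, `tau`, `k_sd`, `n_perm`, `age_split`, `horizon`,
#'   `min_confidence`, `min_overlap_frac`).
#' @param seed master integer seed.
#' @param outdir output directory for artifacts (`NULL` = keep in memory).
#' @return validated list of class `RunConfig`.
#' @export
runConfig <- function(simulate = list(), inputs = NULL,
    stages = c("simulate", "filter", "derive", "score", "nulltest",
        "survive", "structure"),
    thresholds = list(), seed = 1L, outdir = NULL) {
    known <- c("simulate", "filter", "derive", "score", "nulltest",
        "survive", "structure")
    bad <- setdiff(stages, known)
    if (length(bad)) stopf("unknown stage(s): %s", paste(bad, collapse = ", "))
    thr <- .defaultThresholds()
    extra <- setdiff(names(thresholds), names(thr))
    if (length(extra))
        stopf("unknown threshold key(s): %s", paste(extra, collapse = ", "))
    thr[names(thresholds)] <- thresholds
    if (is.null(simulate) && is.null(inputs))
        stopf("either a simulate block or an inputs block is required")
    if (!is.null(inputs)) {
        need <- c("expression", "clinical", "gmt", "edges")
        miss <- setdiff(need, names(inputs))
        if (length(miss))
            stopf("inputs block lacks: %s", paste(miss, collapse = ", "))
        gone <- unlist(inputs)[!file.exists(unlist(inputs))]
        if (length(gone))
            stopf("missing input file(s): %s", paste(gone, collapse = ", "))
    }
    if (!is.null(simulate)) {
        extra <- setdiff(names(simulate), names(formals(cohortConfig)))
        if (length(extra))
            stopf("unknown simulate key(s): %s",
                paste(extra, collapse = ", "))
    }
    structure(list(simulate = simulate, inputs = inputs,
        stages = stages, thresholds = thr, seed = as.integer(seed),
        outdir = outdir), class = "RunConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys: `version`, `simulate`, `inputs`, `stages`,
#' `thresholds`, `seed`, `outdir`.  Unknown keys are errors.
#'
#' @param path YAML file.
#' @return a validated `RunConfig`.
#' @export
readRunConfig <- function(path) {
    y <- yaml::read_yaml(path)
    known <- c("version", "simulate", "inputs", "stages", "thresholds",
        "seed", "outdir")
    bad <- setdiff(names(y), known)
    if (length(bad))
        stopf("unknown configuration key(s): %s", paste(bad, collapse = ", "))
    args <- y[setdiff(names(y), "version")]
    defaults <- formals(runConfig)
    if (is.null(args$stages)) args$stages <- eval(defaults$stages)
    if (is.null(args$simulate) && !is.null(args$inputs))
        args["simulate"] <- list(NULL)
    do.call(runConfig, args)
}

.writeArtifact <- function(outdir, stage, name, writer) {
    if (is.null(outdir)) return(NULL)
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    path <- file.path(outdir, name)
    writer(path)
    data.frame(file = name, stage = stage,
        checksum = unname(tools::md5sum(path)), stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order — simulate (or load),
#' complete-case filter, signature derivation (+ centrality), ssGSEA
#' scoring, permutation null testing, NES classification + survival, and
#' subtype structure (composition, PCA, K-means, heatmap ordering) — and
#' returns a machine-readable report with one block per stage.  When
#' `outdir` is set, every intermediate artifact is written there along with
#' a `manifest.json` (file, stage, checksum); identical configuration and
#' seed reproduce identical checksums.
#'
#' @param config a `RunConfig` from [runConfig()] or [readRunConfig()].
#' @return list of class `RunReport`.
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "RunConfig"))
    thr <- config$thresholds
    outdir <- config$outdir
    report <- list()
    manifest <- list()
    add <- function(mf) if (!is.null(mf)) manifest[[length(manifest) + 1L]] <<- mf
    stageOn <- function(s) s %in% config$stages

    ## -- simulate / load -------------------------------------------------
    if (!is.null(config$simulate)) {
        simArgs <- config$simulate
        if (is.null(simArgs$seed)) simArgs$seed <- deriveSeed(config$seed, 11L)
        cc <- do.call(cohortConfig, simArgs)
        cohort <- generateCohort(cc)
        expr <- zscores(cohort)
        clin <- clinicalTable(cohort)
        sets <- cohortGeneSets(cohort)
        graph <- interactionGraph(cohort)
        immune <- metadata(cohort)$immuneUniverse
        if (stageOn("simulate")) {
            report$simulate <- list(n_samples = ncol(expr),
                n_genes = nrow(expr),
                subtype_counts = as.list(table(clin$subtype)))
            add(.writeArtifact(outdir, "simulate", "expression.tsv",
                function(p) writeExpression(expr, p)))
            add(.writeArtifact(outdir, "simulate", "clinical.tsv",
                function(p) writeClinical(clin, p)))
            add(.writeArtifact(outdir, "simulate", "signatures.gmt",
                function(p) writeGMT(sets, p)))
            add(.writeArtifact(outdir, "simulate", "edges.tsv",
                function(p) writeEdges(graph, p)))
        }
    } else {
        expr <- readExpression(config$inputs$expression)
        clin <- readClinical(config$inputs$clinical)
        sets <- readGMT(config$inputs$gmt)
        graph <- readEdges(config$inputs$edges)
        immune <- if (!is.null(config$inputs$immune_universe))
            readLines(config$inputs$immune_universe) else NULL
        report$simulate <- list(n_samples = ncol(expr),
            n_genes = nrow(expr), loaded = TRUE)
    }

    ## -- filter ----------------------------------------------------------
    if (stageOn("filter")) {
        fc <- filterCompleteCases(expr, clin)
        expr <- fc$expr; clin <- fc$clin
        report$filter <- list(n_retained = ncol(expr),
            n_dropped = nrow(fc$drops),
            reasons = as.list(table(fc$drops$reason)))
    }

    ## -- derive ----------------------------------------------------------
    seeds <- intersect(seedCytokines(), rownames(expr))
    extSig <- NULL
    if (stageOn("derive")) {
        if (length(seeds) < 1L)
            stopf("derive: no seed cytokine present in the matrix")
        nodes <- igraph::V(graph)$name
        candGenes <- union(seeds, intersect(nodes, rownames(expr)))
        corr <- pearsonMatrix(expr, candGenes)
        deriv <- deriveExtendedSignature(corr, seeds,
            p_threshold = thr$p_threshold)
        cent <- nodeCentrality(graph, min_score = thr$min_confidence)
        extSig <- positiveSet(deriv)
        report$derive <- list(
            n_candidates = length(deriv@candidates),
            positive_set_size = length(extSig),
            negative_set = negativeSet(deriv),
            top_closeness = cent$node[1L])
        add(.writeArtifact(outdir, "derive", "derivation.json",
            function(p) jsonlite::write_json(list(
                seeds = seeds, positive_set = extSig,
                negative_set = negativeSet(deriv),
                summary = deriv@summary), p, auto_unbox = TRUE,
                digits = NA)))
        add(.writeArtifact(outdir, "derive", "extended_signature.gmt",
            function(p) writeGMT(list(M1_extended_derived = extSig), p)))
    }

    ## -- score -----------------------------------------------------------
    enr <- NULL
    if (stageOn("score")) {
        scoreSets <- sets
        if (!is.null(extSig)) scoreSets <-
            c(list(M1_extended_derived = extSig), sets)
        enr <- ssgseaScore(expr, scoreSets, tau = thr$tau,
            min_overlap_frac = thr$min_overlap_frac)
        report$score <- list(n_sets = nrow(nes(enr)),
            mean_nes = as.list(rowMeans(nes(enr))))
        add(.writeArtifact(outdir, "score", "nes.tsv", function(p) {
            con <- file(p, "wb"); on.exit(close(con))
            writeLines(paste(c("set", colnames(nes(enr))),
                collapse = "\t"), con, sep = "\n")
            writeLines(paste(rownames(nes(enr)),
                apply(nes(enr), 1L, function(z)
                    paste(.fmt(z), collapse = "\t")), sep = "\t"),
                con, sep = "\n")
        }))
    }

    ## -- nulltest --------------------------------------------------------
    if (stageOn("nulltest")) {
        sig <- if (!is.null(extSig)) extSig else sets[[1L]]
        null <- nullNES(expr, sig, n_perm = thr$n_perm,
            seed = deriveSeed(config$seed, 21L), tau = thr$tau)
        cmp <- lapply(sort(unique(clin$subtype)), function(st) {
            mask <- clin$subtype[match(colnames(expr), clin$sample)] == st
            mw <- compareSubtypeToNull(null = null, subtype_mask = mask)
            list(subtype = st, U = mw$U, p = mw$p,
                direction = mw$direction)
        })
        names(cmp) <- vapply(cmp, `[[`, character(1), "subtype")
        report$nulltest <- list(n_perm = thr$n_perm,
            comparisons = cmp)
        if (!is.null(immune)) {
            nullI <- nullNES(expr, sig, universe = immune,
                n_perm = thr$n_perm,
                seed = deriveSeed(config$seed, 22L), tau = thr$tau,
                universe_name = "immune-related")
            cmpI <- lapply(sort(unique(clin$subtype)), function(st) {
                mask <- clin$subtype[match(colnames(expr),
                    clin$sample)] == st
                mw <- compareSubtypeToNull(null = nullI,
                    subtype_mask = mask)
                list(subtype = st, U = mw$U, p = mw$p,
                    direction = mw$direction)
            })
            names(cmpI) <- vapply(cmpI, `[[`, character(1), "subtype")
            report$nulltest$immune_comparisons <- cmpI
        }
        add(.writeArtifact(outdir, "nulltest", "null_comparison.json",
            function(p) jsonlite::write_json(report$nulltest, p,
                auto_unbox = TRUE, digits = NA)))
    }

    ## -- survive ---------------------------------------------------------
    if (stageOn("survive")) {
        if (is.null(enr)) stopf("survive stage needs the score stage")
        sigName <- rownames(nes(enr))[1L]
        call1 <- classifyByNES(nes(enr)[sigName, ], k = thr$k_sd)
        labs <- positivityLabels(call1)
        keep <- labs != "intermediate"
        idx <- match(names(labs), clin$sample)
        cs <- applyHorizon(clin$os_months[idx], clin$os_status[idx],
            thr$horizon)
        cmp <- compareSurvival(cs$months[keep], cs$status[keep],
            (labs == "positive")[keep], horizon = thr$horizon)
        calls <- lapply(rownames(nes(enr)), function(s)
            classifyByNES(nes(enr)[s, ], k = thr$k_sd))
        names(calls) <- rownames(nes(enr))
        cogroups <- copositivityGroups(calls)
        report$survive <- list(signature = sigName,
            n_positive = sum(labs == "positive"),
            n_negative = sum(labs == "negative"),
            n_intermediate = sum(labs == "intermediate"),
            hr = cmp$cox$hr, hr_ci = cmp$cox$ci, hr_p = cmp$cox$p,
            logrank_chisq = cmp$logrank$chisq,
            logrank_p = cmp$logrank$p,
            median_positive = cmp$km$index$median,
            median_negative = cmp$km$reference$median,
            copositivity = as.list(table(cogroups)))
        add(.writeArtifact(outdir, "survive", "calls.tsv", function(p) {
            con <- file(p, "wb"); on.exit(close(con))
            writeLines("sample\tlabel\tnes", con, sep = "\n")
            writeLines(paste(names(labs), labs,
                .fmt(nes(enr)[sigName, ]), sep = "\t"), con, sep = "\n")
        }))
        add(.writeArtifact(outdir, "survive", "survival_comparison.json",
            function(p) jsonlite::write_json(report$survive, p,
                auto_unbox = TRUE, digits = NA)))
    }

    ## -- structure -------------------------------------------------------
    if (stageOn("structure")) {
        panel <- intersect(cytokinePanel(), rownames(expr))
        if (length(panel) >= 2L) {
            pos <- anyCytokinePositive(expr, panel, hi = thr$z_hi)
            comp <- compositionTable(clin,
                setNames(ifelse(pos, "cytokine-positive",
                    "cytokine-negative"), names(pos)))
            pc <- cytokinePCA(t(expr[panel, , drop = FALSE]))
            km <- kmeans2(pc$scores[, 1:2, drop = FALSE],
                seed = deriveSeed(config$seed, 31L))
            ord <- heatmapOrder(expr,
                if (!is.null(extSig))
                    c(list(M1_extended_derived = extSig), sets)
                else sets)
            report$structure <- list(
                pc1_explained = pc$explained[1L],
                cytokine_positive_fraction = mean(pos),
                cluster_sizes = as.list(table(km$labels)),
                top_sample = ord$samples[1L])
            add(.writeArtifact(outdir, "structure", "composition.tsv",
                function(p) {
                    con <- file(p, "wb"); on.exit(close(con))
                    writeLines(paste(colnames(comp), collapse = "\t"),
                        con, sep = "\n")
                    writeLines(apply(comp, 1L, function(z)
                        paste(trimws(z), collapse = "\t")), con,
                        sep = "\n")
                }))
        } else {
            report$structure <- list(skipped = "cytokine panel absent")
        }
    }

    if (!is.null(outdir) && length(manifest)) {
        mf <- do.call(rbind, manifest)
        jsonlite::write_json(mf, file.path(outdir, "manifest.json"),
            auto_unbox = TRUE, digits = NA)
        report$manifest <- mf
    }
    class(report) <- "RunReport"
    report
}

#' @export
print.RunReport <- function(x, ...) {
    cat("sigclaud run report —", length(setdiff(names(x), "manifest")),
        "stage blocks\n")
    for (nm in setdiff(names(x), "manifest"))
        cat(sprintf("  %-10s %s\n", nm,
            paste(names(x[[nm]])[1:min(3, length(x[[nm]]))],
                collapse = ", ")))
    invisible(x)
}
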