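#' @include AllClasses.R
NULL

#' Extract the z-score assay of a cohort
#' @param x a [SignatureCohort-class].
#' @return numeric gene x sample matrix.
#' @export
setGeneric("zscores", function(x) standardGeneric("zscores"))

#' @rdname zscores
#' @export
setMethod("zscores", "SignatureCohort", function(x)
    SummarizedExperiment::assay(x, "zscore"))

#' Extract the clinical table of a cohort
#' @param x a [SignatureCohort-class].
#' @return data.frame with sample, subtype, age, os_months, os_status.
#' @export
setGeneric("clinicalTable", function(x) standardGeneric("clinicalTable"))

#' @rdname clinicalTable
#' @export
setMethod("clinicalTable", "SignatureCohort", function(x) {
    cd <- as.data.frame(colData(x))
    data.frame(sample = colnames(x), cd, row.names = NULL,
        check.names = FALSE)
})

#' Gene sets attached to a cohort
#' @param x a [SignatureCohort-class].
#' @return named list of gene-symbol character vectors.
#' @export
setGeneric("cohortGeneSets", function(x) standardGeneric("cohortGeneSets"))

#' @rdname cohortGeneSets
#' @export
setMethod("cohortGeneSets", "SignatureCohort", function(x)
    metadata(x)$geneSets)

#' Interaction graph attached to a cohort
#' @param x a [SignatureCohort-class].
#' @return an igraph object with a `confidence` edge attribute.
#' @export
setGeneric("interactionGraph", function(x)
    standardGeneric("interactionGraph"))

#' @rdname interactionGraph
#' @export
setMethod("interactionGraph", "SignatureCohort", function(x)
    metadata(x)$graph)

#' Raw enrichment scores
#' @param x an [EnrichmentResult-class].
#' @return gene-set x sample matrix.
#' @export
setGeneric("enrichmentScores", function(x)
    standardGeneric("enrichmentScores"))

#' @rdname enrichmentScores
#' @export
setMethod("enrichmentScores", "EnrichmentResult", function(x) x@es)

#' Normalized enrichment scores
#' @param x an [EnrichmentResult-class] or [NullDistribution-class].
#' @return for an enrichment result, the gene-set x sample NES matrix; for a
#'   null distribution, the permutation x sample NES matrix.
#' @export
setGeneric("nes", function(x) standardGeneric("nes"))

#' @rdname nes
#' @export
setMethod("nes", "EnrichmentResult", function(x) x@nes)

#' @rdname nes
#' @export
setMethod("nes", "NullDistribution", function(x) x@nesValues)

#' Positive (extended-signature) gene set of a derivation
#' @param x a [SignatureDerivation-class].
#' @return character vector of gene symbols (seeds included).
#' @export
setGeneric("positiveSet", function(x) standardGeneric("positiveSet"))

#' @rdname positiveSet
#' @export
setMethod("positiveSet", "SignatureDerivation", function(x) x@positiveSet)

#' Significant negative correlates of a derivation
#' @param x a [SignatureDerivation-class].
#' @return character vector of gene symbols.
#' @export
setGeneric("negativeSet", function(x) standardGeneric("negativeSet"))

#' @rdname negativeSet
#' @export
setMethod("negativeSet", "SignatureDerivation", function(x) x@negativeSet)

#' Per-sample positivity labels
#' @param x a [PositivityCall-class].
#' @return named character vector over \{positive, intermediate, negative\}.
#' @export
setGeneric("positivityLabels", function(x)
    standardGeneric("positivityLabels"))

#' @rdname positivityLabels
#' @export
setMethod("positivityLabels", "PositivityCall", function(x) x@labels)

setMethod("show", "SignatureCohort", function(object) {
    cat("SignatureCohort:", nrow(object), "genes x", ncol(object),
        "samples\n")
    tab <- table(colData(object)$subtype)
    cat("subtypes:",
        paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
    cat("gene sets:", length(metadata(object)$geneSets), "\n")
})

setMethod("show", "CorrelationMatrix", function(object) {
    cat("CorrelationMatrix over", nrow(object@r), "genes\n")
})

setMethod("show", "SignatureDerivation", function(object) {
    cat("SignatureDerivation\n")
    cat("  seeds:      ", paste(object@seeds, collapse = ", "), "\n")
    cat("  positive set:", length(object@positiveSet), "genes (",
        length(setdiff(object@positiveSet, object@seeds)),
        "beyond the seeds )\n")
    cat("  negative set:", length(object@negativeSet), "genes:",
        paste(object@negativeSet, collapse = ", "), "\n")
    cat("  p threshold: ", object@pThreshold, "\n")
})

setMethod("show", "EnrichmentResult", function(object) {
    cat("EnrichmentResult:", nrow(object@es), "gene sets x",
        ncol(object@es), "samples (tau =", object@tau,
        ", normalization =", object@normalization, ")\n")
})

setMethod("show", "NullDistribution", function(object) {
    cat("NullDistribution (", object@universeName, "):", object@nPerm,
        "permutations of size", object@setSize, "over",
        ncol(object@nesValues), "samples\n")
})

setMethod("show", "PositivityCall", function(object) {
    tab <- table(factor(object@labels,
        levels = c("positive", "intermediate", "negative")))
    cat("PositivityCall: median =", signif(object@median, 4), ", SD =",
        signif(object@sd, 4), ", k =", object@k, "\n")
    cat("  ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
})
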