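#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame metadata
NULL

#' SignatureCohort: expression z-scores plus clinical annotation
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding a
#' gene x sample matrix of cohort-normalized z-scores in the `"zscore"` assay
#' and the per-sample clinical table (`subtype`, `age`, `os_months`,
#' `os_status`) as `colData`.  Gene sets, the protein-interaction graph and
#' the generating configuration (for synthetic cohorts) live in `metadata()`.
#'
#' @slot ... inherited from `SummarizedExperiment`.
#' @export
setClass("SignatureCohort", contains = "SummarizedExperiment")

setValidity("SignatureCohort", function(object) {
    msg <- character()
    if (!"zscore" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'zscore' is required")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "duplicate gene symbols")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "duplicate sample IDs")
    cd <- colData(object)
    need <- c("subtype", "age", "os_months", "os_status")
    miss <- setdiff(need, colnames(cd))
    if (length(miss))
        msg <- c(msg, paste0("colData lacks: ", paste(miss, collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' Pairwise Pearson correlation matrix with significance
#'
#' Symmetric gene x gene Pearson coefficients with two-sided p-values from
#' the t distribution on n - 2 degrees of freedom and the pairwise-complete
#' sample count actually used for each pair.
#'
#' @slot r symmetric correlation matrix, unit diagonal.
#' @slot p symmetric two-sided p-value matrix, zero diagonal.
#' @slot nUsed integer matrix of pairwise-complete sample counts.
#' @export
setClass("CorrelationMatrix",
    representation(r = "matrix", p = "matrix", nUsed = "matrix"))

setValidity("CorrelationMatrix", function(object) {
    msg <- character()
    if (!isTRUE(all.equal(object@r, t(object@r), tolerance = 1e-10)))
        msg <- c(msg, "r must be symmetric")
    if (any(abs(object@r) > 1 + 1e-12, na.rm = TRUE))
        msg <- c(msg, "|r| must be <= 1")
    if (length(msg)) msg else TRUE
})

#' Extended-signature derivation result
#'
#' Records the seed genes, the candidate (network) genes, the positively
#' co-expressed genes retained in the extended signature, the genes flagged
#' as significant negative correlates, and a per-gene summary (mean r
#' against the seeds, minimum seed p-value, class).
#'
#' @slot seeds seed gene symbols (always members of the positive set).
#' @slot candidates candidate gene symbols evaluated.
#' @slot positiveSet genes retained in the extended signature.
#' @slot negativeSet genes with a significant negative seed correlation.
#' @slot pThreshold significance threshold applied (default 0.01).
#' @slot summary data.frame: gene, mean_r, min_p, class.
#' @slot corr the [CorrelationMatrix-class] the derivation was read from.
#' @export
setClass("SignatureDerivation",
    representation(seeds = "character", candidates = "character",
        positiveSet = "character", negativeSet = "character",
        pThreshold = "numeric", summary = "data.frame",
        corr = "CorrelationMatrix"))

setValidity("SignatureDerivation", function(object) {
    msg <- character()
    if (length(intersect(object@positiveSet, object@negativeSet)))
        msg <- c(msg, "positive and negative sets must be disjoint")
    if (!all(object@negativeSet %in% object@candidates))
        msg <- c(msg, "negative set must be drawn from the candidates")
    if (!all(object@seeds %in% object@positiveSet))
        msg <- c(msg, "seeds must belong to the positive set")
    if (length(msg)) msg else TRUE
})

#' Single-sample enrichment result
#'
#' Raw enrichment scores (ES) and normalized enrichment scores (NES) for
#' every (gene set, sample) pair.  With `normalization = "global-range"`,
#' NES = ES / (max ES - min ES) over the whole result, so the NES span a
#' shared range of exactly 1 (and lie in [-1, 1] whenever the raw scores
#' straddle zero).
#'
#' @slot es gene-set x sample matrix of raw ES.
#' @slot nes gene-set x sample matrix of NES.
#' @slot tau rank-weighting exponent used (default 0.25).
#' @slot normalization `"global-range"` or `"none"`.
#' @slot overlap integer vector: per-set size of the intersection with the
#'   expression matrix genes.
#' @export
setClass("EnrichmentResult",
    representation(es = "matrix", nes = "matrix", tau = "numeric",
        normalization = "character", overlap = "integer"))

setValidity("EnrichmentResult", function(object) {
    msg <- character()
    if (!identical(dim(object@es), dim(object@nes)))
        msg <- c(msg, "es and nes must have identical dimensions")
    if (object@normalization == "global-range" && length(object@nes) &&
        (max(object@nes) - min(object@nes)) > 1 + 1e-9)
        msg <- c(msg, "global-range NES must span a range of at most 1")
    if (length(msg)) msg else TRUE
})

#' Permutation null distribution of NES
#'
#' NES for `nPerm` size-matched gene sets sampled from a gene universe
#' (all genes, or an immune-restricted list), normalized jointly with the
#' observed signature on a single shared global range so observed and null
#' scores are directly comparable.
#'
#' @slot universeName `"all-genes"` or `"immune-related"` (or a custom tag).
#' @slot setSize size of the sampled sets (matches the observed signature).
#' @slot nPerm number of permutation sets.
#' @slot nesValues permutation x sample NES matrix.
#' @slot observedNES per-sample NES of the observed signature on the shared
#'   scale.
#' @slot seed master seed the permutation streams were derived from.
#' @export
setClass("NullDistribution",
    representation(universeName = "character", setSize = "integer",
        nPerm = "integer", nesValues = "matrix", observedNES = "numeric",
        seed = "integer"))

setValidity("NullDistribution", function(object) {
    msg <- character()
    if (nrow(object@nesValues) != object@nPerm)
        msg <- c(msg, "nesValues must have exactly nPerm rows")
    if (ncol(object@nesValues) != length(object@observedNES))
        msg <- c(msg, "observedNES length must match nesValues columns")
    if (length(msg)) msg else TRUE
})

#' NES-threshold positivity call
#'
#' Per-sample label in \{positive, intermediate, negative\} from the rule:
#' positive iff NES >= median + k * SD, negative iff NES <= median - k * SD
#' (sample median, n - 1 SD, k defaults to 1).
#'
#' @slot labels named character vector of per-sample labels.
#' @slot nes the NES values classified.
#' @slot median sample median of NES.
#' @slot sd sample standard deviation of NES (n - 1 denominator).
#' @slot k threshold multiplier.
#' @export
setClass("PositivityCall",
    representation(labels = "character", nes = "numeric", median = "numeric",
        sd = "numeric", k = "numeric"))

setValidity("PositivityCall", function(object) {
    ok <- all(object@labels %in% c("positive", "intermediate", "negative"))
    hi <- object@median + object@k * object@sd
    lo <- object@median - object@k * object@sd
    want <- ifelse(object@nes >= hi, "positive",
        ifelse(object@nes <= lo, "negative", "intermediate"))
    if (!ok) return("labels must be positive/intermediate/negative")
    if (!identical(unname(want), unname(object@labels)))
        return("labels inconsistent with the median +/- k*SD rule")
    TRUE
})
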