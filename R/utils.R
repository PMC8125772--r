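#' Derive a reproducible sub-seed from a master seed
#'
#' One master seed fans out into independent per-stage / per-permutation
#' streams via a fixed affine step modulo 2^31 - 1, so changing the number
#' of permutations never reshuffles earlier ones.
#'
#' @param seed master integer seed.
#' @param offset non-negative integer stream index.
#' @return an integer seed.
#' @export
deriveSeed <- function(seed, offset) {
    stopifnot(is.numeric(seed), length(seed) == 1L,
        is.numeric(offset), length(offset) == 1L, offset >= 0)
    m <- 2147483647               # 2^31 - 1, keeps set.seed() in range
    as.integer((as.numeric(seed) %% m + 104729 * (offset + 1)) %% m)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
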