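test_that("null sets are size-matched, seeded, and counter-stable", {
    u <- sprintf("g%03d", 1:200)
    s1 <- sampleNullSets(u, 10L, 50L, seed = 99L)
    s2 <- sampleNullSets(u, 10L, 50L, seed = 99L)
    expect_identical(s1, s2)
    expect_true(all(lengths(s1) == 10L))
    expect_true(all(unlist(s1) %in% u))
    # growing n_perm never reshuffles earlier permutations
    s3 <- sampleNullSets(u, 10L, 80L, seed = 99L)
    expect_identical(s3[1:50], s1)
    expect_error(sampleNullSets(u[1:5], 10L, 5L), "exceeds")
    # universe of size == set size: every permutation is the universe
    s4 <- sampleNullSets(u[1:10], 10L, 5L)
    expect_true(all(vapply(s4, setequal, logical(1), u[1:10])))
})

test_that("inclusion frequency matches the hypergeometric expectation", {
    u <- sprintf("g%05d", 1:2000)
    sets <- sampleNullSets(u, 24L, 1000L, seed = 5L)
    freq <- mean(vapply(sets, function(s) "g00042" %in% s, logical(1)))
    p <- 24 / 2000
    expect_lt(abs(freq - p), 4 * sqrt(p * (1 - p) / 1000))
})

test_that("null NES shares one scale with the observed signature", {
    co <- generateCohort(cohortConfig(n_samples = 60L, n_genes = 300L,
        effect_shift = 0, factor_loading = 0, negative_loading = 0,
        seed = 71L))
    X <- zscores(co)
    sig <- cohortGeneSets(co)$M1_extended_planted
    nd <- nullNES(X, sig, n_perm = 50L, seed = 8L)
    expect_s4_class(nd, "NullDistribution")
    expect_equal(dim(nes(nd)), c(50L, 60L))
    expect_equal(nd@setSize, 24L)
    allv <- c(nes(nd), nd@observedNES)
    expect_true(all(abs(allv) <= 1))
    # null cohort: observed set is exchangeable with the null sets
    expect_lt(abs(mean(nd@observedNES) - mean(nes(nd))),
        4 * sd(nes(nd)) / sqrt(50))
})

test_that("restricted universes are honoured", {
    co <- generateCohort(cohortConfig(n_samples = 40L, n_genes = 200L,
        seed = 72L))
    X <- zscores(co)
    sig <- cohortGeneSets(co)$M1_extended_planted
    immune <- S4Vectors::metadata(co)$immuneUniverse
    nd <- nullNES(X, sig, universe = immune, n_perm = 20L, seed = 9L,
        universe_name = "immune-related")
    expect_identical(nd@universeName, "immune-related")
    sets <- sampleNullSets(intersect(immune, rownames(X)), 24L, 20L,
        seed = 9L)
    expect_true(all(unlist(sets) %in% immune))
})

test_that("Mann-Whitney handles separation and exchangeability poles", {
    mw <- mannWhitney(c(1, 2), c(3, 4), exact = FALSE)
    expect_equal(mw$U, 0)
    expect_identical(mw$direction, "excluded")
    x <- c(5, 7, 9)
    mw2 <- mannWhitney(x, x, exact = FALSE)
    expect_equal(mw2$U, length(x)^2 / 2)
    expect_gt(mw2$p, 0.9)
    expect_true(mw2$tie_corrected)
})

test_that("Mann-Whitney agrees with wilcox.test on both paths", {
    set.seed(15)
    x <- rnorm(12); y <- rnorm(15, 0.5)
    mw <- mannWhitney(x, y, exact = FALSE)
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
        correct = TRUE))
    expect_equal(mw$U, unname(wt$statistic))
    expect_equal(mw$p, wt$p.value, tolerance = 1e-10)
    mwE <- mannWhitney(x, y, exact = TRUE)
    wtE <- stats::wilcox.test(x, y, exact = TRUE)
    expect_equal(mwE$p, wtE$p.value, tolerance = 1e-10)
})

test_that("small-n p matches exact enumeration over all assignments", {
    set.seed(19)
    x <- rnorm(8); y <- rnorm(10)
    # n1*n2 = 80 <= 400 and tie-free: the default path is exact and must
    # agree with an independently coded enumeration of all C(18,8) label
    # assignments
    auto <- mannWhitney(x, y)
    expect_true(auto$exact)
    expect_equal(auto$p, mwEnumOracle(x, y), tolerance = 1e-12)
    # the normal approximation is within its documented accuracy here
    mw <- mannWhitney(x, y, exact = FALSE)
    expect_lt(abs(mw$p - mwEnumOracle(x, y)), 0.01)
})

test_that("subtype comparison pools null NES across permutations", {
    co <- generateCohort(cohortConfig(n_samples = 100L, n_genes = 400L,
        effect_shift = 1, seed = 73L))
    X <- zscores(co)
    clin <- clinicalTable(co)
    sig <- cohortGeneSets(co)$M1_extended_planted
    nd <- nullNES(X, sig, n_perm = 100L, seed = 10L)
    tgt <- clin$subtype == "claudin-low"
    mw <- compareSubtypeToNull(null = nd, subtype_mask = tgt)
    expect_identical(mw$direction, "enriched")
    expect_lt(mw$p, 0.01)
    expect_equal(mw$n2, 100L * sum(tgt))
    mwM <- compareSubtypeToNull(null = nd, subtype_mask = tgt,
        pooling = "perm-mean")
    expect_equal(mwM$n2, 100L)
    expect_error(compareSubtypeToNull(null = nd,
        subtype_mask = rep(FALSE, 100)), "empty subtype")
})

test_that("planted signal exceeds the null 97.5th percentile", {
    co <- generateCohort(cohortConfig(n_samples = 150L, n_genes = 400L,
        effect_shift = 1, factor_loading = 0, seed = 74L))
    X <- zscores(co)
    clin <- clinicalTable(co)
    sig <- cohortGeneSets(co)$M1_extended_planted
    nd <- nullNES(X, sig, n_perm = 100L, seed = 11L)
    tgt <- which(clin$subtype == "claudin-low")
    exceed <- vapply(tgt, function(j)
        nd@observedNES[j] > quantile(nes(nd)[, j], 0.975),
        logical(1))
    expect_gt(mean(exceed), 0.5)
})

test_that("rejection frequency grows with the planted effect", {
    pForDelta <- function(delta, seeds) {
        vapply(seeds, function(s) {
            co <- generateCohort(cohortConfig(n_samples = 100L,
                n_genes = 300L, effect_shift = delta,
                factor_loading = 0, negative_loading = 0,
                seed = s))
            nd <- nullNES(zscores(co),
                cohortGeneSets(co)$M1_extended_planted,
                n_perm = 100L, seed = s + 1L)
            compareSubtypeToNull(null = nd,
                subtype_mask =
                    clinicalTable(co)$subtype == "claudin-low")$p
        }, numeric(1))
    }
    seeds <- 600:614
    rej <- vapply(c(0, 0.5, 1), function(d)
        mean(pForDelta(d, seeds) < 0.05), numeric(1))
    expect_true(rej[3] >= rej[1])
    expect_gt(rej[3], 0.8)
    expect_lt(rej[1], 0.4)
})
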