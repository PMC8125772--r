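test_that("pearsonMatrix matches the two-pass covariance oracle", {
    set.seed(8)
    X <- matrix(rnorm(250), 5, 50,
        dimnames = list(paste0("G", 1:5), paste0("S", 1:50)))
    cm <- pearsonMatrix(X)
    for (i in 1:4) for (j in (i + 1):5)
        expect_equal(cm@r[i, j], pearsonOracle(X[i, ], X[j, ]),
            tolerance = 1e-12)
    # p-values against cor.test
    ct <- cor.test(X[1, ], X[2, ])
    expect_equal(cm@p[1, 2], ct$p.value, tolerance = 1e-10)
    expect_equal(unname(diag(cm@r)), rep(1, 5))
    expect_equal(unname(diag(cm@p)), rep(0, 5))
})

test_that("perfect anticorrelation and degenerate inputs behave", {
    X <- rbind(x = c(1, 2, 3), y = c(3, 2, 1), z = c(0.5, 9, 2))
    colnames(X) <- paste0("S", 1:3)
    cm <- pearsonMatrix(X)
    expect_equal(cm@r["x", "y"], -1)
    expect_equal(cm@p["x", "y"], 0)
    Xc <- rbind(X, w = c(5, 5, 5))
    expect_error(pearsonMatrix(Xc), "constant")
    expect_error(pearsonMatrix(X, c("x", "nope")), "absent")
})

test_that("pairwise-complete counts are recorded for missing data", {
    set.seed(3)
    X <- matrix(rnorm(200), 4, 50,
        dimnames = list(paste0("G", 1:4), paste0("S", 1:50)))
    X[1, 1:10] <- NA
    cm <- pearsonMatrix(X)
    expect_equal(cm@nUsed[1, 2], 40L)
    expect_equal(cm@nUsed[3, 4], 50L)
    expect_equal(cm@r[1, 2],
        pearsonOracle(X[1, 11:50], X[2, 11:50]), tolerance = 1e-12)
})

test_that("signature derivation recovers the planted program", {
    co <- generateCohort(cohortConfig(n_samples = 500L, n_genes = 800L,
        factor_loading = sqrt(0.5), effect_shift = 1, seed = 31L))
    X <- zscores(co)
    planted <- cohortGeneSets(co)$M1_extended_planted
    nodes <- igraph::V(interactionGraph(co))$name
    corr <- pearsonMatrix(X, union(seedCytokines(), nodes))
    d <- deriveExtendedSignature(corr, seedCytokines())
    expect_gte(mean(planted %in% positiveSet(d)), 0.95)
    expect_true("STAT3" %in% negativeSet(d))
    r_stat3 <- d@summary$mean_r[d@summary$gene == "STAT3"]
    expect_lt(abs(r_stat3 - (-0.38)), 0.1)
})

test_that("uncorrelated candidates stay unclassified", {
    set.seed(9)
    X <- matrix(rnorm(5 * 200), 5, 200,
        dimnames = list(c("CSF2", "CCL2", "CCL5", "lone", "other"),
            paste0("S", 1:200)))
    cm <- pearsonMatrix(X)
    d <- deriveExtendedSignature(cm, seedCytokines())
    expect_false("lone" %in% positiveSet(d))
    expect_false("lone" %in% negativeSet(d))
    expect_identical(d@summary$class[d@summary$gene == "lone"],
        "unclassified")
    expect_true(all(seedCytokines() %in% positiveSet(d)))
})

test_that("selection is monotone in the p threshold", {
    co <- generateCohort(cohortConfig(n_samples = 120L, n_genes = 300L,
        factor_loading = 0.4, seed = 17L))
    nodes <- igraph::V(interactionGraph(co))$name
    corr <- pearsonMatrix(zscores(co), union(seedCytokines(), nodes))
    thresholds <- c(0.05, 0.01, 0.001)
    sets <- lapply(thresholds, function(th)
        positiveSet(deriveExtendedSignature(corr, seedCytokines(),
            p_threshold = th)))
    expect_true(all(sets[[2]] %in% sets[[1]]))
    expect_true(all(sets[[3]] %in% sets[[2]]))
})

test_that("derivation is invariant to sample order", {
    co <- generateCohort(cohortConfig(n_samples = 100L, n_genes = 200L,
        seed = 23L))
    X <- zscores(co)
    nodes <- igraph::V(interactionGraph(co))$name
    genes <- union(seedCytokines(), intersect(nodes, rownames(X)))
    set.seed(1)
    perm <- sample(ncol(X))
    d1 <- deriveExtendedSignature(pearsonMatrix(X, genes),
        seedCytokines())
    d2 <- deriveExtendedSignature(pearsonMatrix(X[, perm], genes),
        seedCytokines())
    expect_identical(positiveSet(d1), positiveSet(d2))
    expect_identical(negativeSet(d1), negativeSet(d2))
    expect_equal(d1@summary$mean_r, d2@summary$mean_r, tolerance = 1e-12)
})

test_that("false-positive rate on null cohorts tracks the p threshold", {
    hits <- vapply(1:30, function(i) {
        co <- generateCohort(cohortConfig(n_samples = 150L,
            n_genes = 200L, effect_shift = 0, factor_loading = 0,
            negative_loading = 0, seed = 400L + i))
        nodes <- igraph::V(interactionGraph(co))$name
        corr <- pearsonMatrix(zscores(co),
            union(seedCytokines(), nodes))
        d <- deriveExtendedSignature(corr, seedCytokines())
        length(setdiff(positiveSet(d), seedCytokines()))
    }, numeric(1))
    nCand <- 39   # 42-node graph minus the three seeds
    # each candidate needs >=1 of 3 seed tests at p<.01 (and mean r > 0):
    # per-candidate false-positive rate is bounded by ~3 * 0.01 / 2
    expect_lt(mean(hits) / nCand, 0.03)
    expect_gt(mean(hits) / nCand, 0)
})

test_that("centrality matches definitions on path and star graphs", {
    path <- igraph::graph_from_literal(A - B - C)
    ct <- nodeCentrality(path)
    expect_equal(ct$betweenness[ct$node == "B"], 1)
    expect_equal(ct$betweenness[ct$node == "A"], 0)
    star <- igraph::make_star(5, mode = "undirected", center = 1)
    igraph::V(star)$name <- c("c", "l1", "l2", "l3", "l4")
    cs <- nodeCentrality(star)
    expect_equal(cs$closeness[cs$node == "c"], 1)
    expect_identical(cs$node[1], "c")
})

test_that("confidence thresholding drops weak edges before scoring", {
    df <- data.frame(from = c("A", "B", "C"), to = c("B", "C", "D"),
        confidence = c(0.95, 0.91, 0.2))
    g <- igraph::graph_from_data_frame(df, directed = FALSE)
    ct <- nodeCentrality(g, min_score = 0.9)
    expect_equal(ct$betweenness[ct$node == "C"], 0)  # C-D edge dropped
    expect_error(nodeCentrality(g, min_score = 0.99), "empty graph")
})

test_that("centrality equals the brute-force all-pairs oracle", {
    set.seed(55)
    for (rep in 1:12) {
        n <- 20L
        adj <- matrix(0L, n, n)
        m <- sample(20:40, 1)
        idx <- cbind(sample(n, m, TRUE), sample(n, m, TRUE))
        idx <- idx[idx[, 1] != idx[, 2], , drop = FALSE]
        adj[idx] <- 1L
        adj <- pmax(adj, t(adj))
        if (sum(adj) == 0) next
        nm <- sprintf("N%02d", 1:n)
        dimnames(adj) <- list(nm, nm)
        g <- igraph::graph_from_adjacency_matrix(adj,
            mode = "undirected")
        igraph::E(g)$confidence <- 1
        ct <- nodeCentrality(g, min_score = 0)
        ord <- match(ct$node, nm)
        expect_equal(ct$betweenness, betweennessOracle(adj)[ord],
            tolerance = 1e-9)
        expect_equal(ct$closeness, closenessOracle(adj)[ord],
            tolerance = 1e-9)
    }
})
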