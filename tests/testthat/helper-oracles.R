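# Independent oracles, each coded from the literal definition of the
# statistic it checks, never via the package's own code path.

# ssGSEA ES by the literal cumulative walk: order genes by decreasing rank,
# maintain the rank^tau-weighted in-set ECDF and the unweighted out-of-set
# ECDF, and sum their running difference over all positions.
esWalkOracle <- function(ranks, gene_set, tau = 0.25) {
    genes <- names(ranks)
    ord <- order(-ranks, genes)
    inSet <- genes[ord] %in% gene_set
    w <- ranks[ord]^tau
    N <- length(ranks)
    Wtot <- sum(w[inSet])
    pin <- 0; pout <- 0; es <- 0
    nOut <- N - sum(inSet)
    for (i in seq_len(N)) {
        if (inSet[i]) pin <- pin + w[i] / Wtot
        else pout <- pout + 1 / nOut
        es <- es + (pin - pout)
    }
    unname(es)
}

# Pearson r by the two-pass covariance formula.
pearsonOracle <- function(x, y) {
    mx <- mean(x); my <- mean(y)
    sum((x - mx) * (y - my)) /
        sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# All-pairs shortest-path distances and path counts by per-source BFS
# (unweighted graphs); the basis of the brute-force centrality oracles.
pathCountOracle <- function(adj) {
    n <- nrow(adj)
    d <- matrix(Inf, n, n)
    sigma <- matrix(0, n, n)
    for (s in seq_len(n)) {
        dist <- rep(Inf, n); dist[s] <- 0
        cnt <- rep(0, n); cnt[s] <- 1
        frontier <- s
        while (length(frontier)) {
            nxt <- integer()
            for (u in frontier) for (v in which(adj[u, ] > 0)) {
                if (is.infinite(dist[v])) {
                    dist[v] <- dist[u] + 1
                    nxt <- c(nxt, v)
                }
                if (dist[v] == dist[u] + 1)
                    cnt[v] <- cnt[v] + cnt[u]
            }
            frontier <- unique(nxt)
        }
        d[s, ] <- dist; sigma[s, ] <- cnt
    }
    list(d = d, sigma = sigma)
}

betweennessOracle <- function(adj) {
    pc <- pathCountOracle(adj)
    d <- pc$d; sigma <- pc$sigma
    n <- nrow(adj)
    btw <- numeric(n)
    for (v in seq_len(n)) for (s in seq_len(n - 1)) for (t in (s + 1):n) {
        if (s == v || t == v || !is.finite(d[s, t])) next
        if (d[s, v] + d[v, t] == d[s, t])
            btw[v] <- btw[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
    }
    if (n > 2) btw / ((n - 1) * (n - 2) / 2) else btw
}

closenessOracle <- function(adj) {
    d <- pathCountOracle(adj)$d
    n <- nrow(adj)
    vapply(seq_len(n), function(i) {
        di <- d[i, -i]
        reach <- di[is.finite(di)]
        if (!length(reach)) return(0)
        (length(reach) / sum(reach)) * (length(reach) / (n - 1))
    }, numeric(1))
}

# Exact two-sided Mann-Whitney p by enumerating every assignment of group
# labels to the pooled sample (tie-free data).
mwEnumOracle <- function(x, y) {
    n1 <- length(x)
    pooled <- c(x, y)
    r <- rank(pooled)
    Uobs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    combos <- utils::combn(length(pooled), n1)
    U <- apply(combos, 2L, function(idx)
        sum(r[idx]) - n1 * (n1 + 1) / 2)
    mu <- n1 * length(y) / 2
    mean(abs(U - mu) >= abs(Uobs - mu))
}

# Log-rank chi-square by literal 2x2 tabulation at every event time.
logrank2Oracle <- function(m1, s1, m2, s2) {
    months <- c(m1, m2); status <- c(s1, s2)
    grp <- rep(1:2, c(length(m1), length(m2)))
    evt <- sort(unique(months[status == 1]))
    O <- 0; E <- 0; V <- 0
    for (t in evt) {
        n <- sum(months >= t)
        n1 <- sum(months >= t & grp == 1)
        dTot <- sum(months == t & status == 1)
        d1 <- sum(months == t & status == 1 & grp == 1)
        O <- O + d1
        E <- E + dTot * n1 / n
        if (n > 1)
            V <- V + dTot * (n1 / n) * (1 - n1 / n) * (n - dTot) / (n - 1)
    }
    (O - E)^2 / V
}

# Breslow partial log-likelihood for a binary covariate, maximized by grid
# search.
coxGridOracle <- function(months, status, x, grid = seq(-4, 4, 1e-4)) {
    evt <- which(status == 1)
    ll <- vapply(grid, function(b) {
        s <- 0
        for (i in evt) {
            risk <- months >= months[i]
            s <- s + b * x[i] - log(sum(exp(b * x[risk])))
        }
        s
    }, numeric(1))
    grid[which.max(ll)]
}

# Hand product-limit estimator.
kmOracle <- function(months, status) {
    evt <- sort(unique(months[status == 1]))
    s <- 1; out <- numeric(0)
    for (t in evt) {
        n <- sum(months >= t)
        dd <- sum(months == t & status == 1)
        s <- s * (1 - dd / n)
        out <- c(out, s)
    }
    list(time = evt, surv = out)
}

# Small fixture: a cohort with every gap type for complete-case filtering.
toyClinical <- function() {
    data.frame(
        sample = sprintf("S%02d", 1:10),
        subtype = c("lumA", "basal", NA, "lumB", "Her2", "claudin-low",
            "normal", "basal", "lumA", "lumB"),
        age = c(45, 61, 53, 70, 38, 55, 49, 66, 51, 59),
        os_months = c(100, 55, 80, NA, 120, 30, 88, 61, 45, 99),
        os_status = c(0, 1, 0, 1, 0, 1, 0, 1, 1, 0),
        stringsAsFactors = FALSE)
}
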