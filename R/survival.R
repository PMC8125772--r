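#' Classify samples by the median +/- k*SD rule on NES
#'
#' Positive iff NES >= median + k*SD, negative iff NES <= median - k*SD,
#' intermediate otherwise (sample median; SD with the n - 1 denominator;
#' k defaults to 1).
#'
#' @param nes named numeric vector of per-sample NES.
#' @param k threshold multiplier (default 1).
#' @return a [PositivityCall-class].
#' @export
classifyByNES <- function(nes, k = 1) {
    if (length(nes) < 2L) stopf("need >= 2 samples to classify")
    s <- stats::sd(nes)
    if (!is.finite(s) || s == 0)
        stopf("degenerate NES distribution (SD = 0)")
    m <- stats::median(nes)
    lab <- ifelse(nes >= m + k * s, "positive",
        ifelse(nes <= m - k * s, "negative", "intermediate"))
    names(lab) <- names(nes)
    new("PositivityCall", labels = lab, nes = nes, median = m, sd = s,
        k = k)
}

#' Co-positivity grouping across several signatures
#'
#' `all-positive` iff the sample is positive for every signature,
#' `all-negative` iff negative for every signature, `other` otherwise.
#'
#' @param calls named list of [PositivityCall-class] objects over the same
#'   samples.
#' @return named character vector of per-sample groups.
#' @export
copositivityGroups <- function(calls) {
    if (length(calls) < 2L) stopf("need >= 2 signatures")
    samples <- names(positivityLabels(calls[[1L]]))
    for (cl in calls)
        if (!setequal(names(positivityLabels(cl)), samples))
            stopf("mismatched sample sets across signatures")
    lab <- vapply(calls, function(cl) positivityLabels(cl)[samples],
        character(length(samples)))
    out <- ifelse(rowSums(lab == "positive") == ncol(lab), "all-positive",
        ifelse(rowSums(lab == "negative") == ncol(lab), "all-negative",
            "other"))
    setNames(out, samples)
}

#' Apply an administrative censoring horizon
#' @param months,status follow-up times and event indicators.
#' @param horizon months; events beyond it become censored at the horizon.
#' @return list with censored `months` and `status`.
#' @export
applyHorizon <- function(months, status, horizon = 120) {
    status <- ifelse(months > horizon, 0L, as.integer(status))
    list(months = pmin(months, horizon), status = status)
}

#' Kaplan-Meier product-limit estimate
#'
#' Observations beyond the follow-up horizon are administratively censored
#' at the horizon first.  The median is the smallest event time t with
#' S(t) <= 0.5, or `NA` ("not reached") when S never drops that far.
#'
#' @param months follow-up in months (>= 0).
#' @param status 1 = event, 0 = censored.
#' @param horizon follow-up window in months (default 120); `Inf` disables.
#' @return list: `time`, `surv`, `n_risk`, `n_event`, `n_censor` (at each
#'   distinct event time), and `median`.
#' @export
kmEstimate <- function(months, status, horizon = 120) {
    if (!length(months)) stopf("empty group")
    if (any(months < 0)) stopf("negative follow-up time")
    if (!all(status %in% c(0, 1))) stopf("status must be 0/1")
    cs <- applyHorizon(months, status, horizon)
    months <- cs$months; status <- cs$status
    evt <- sort(unique(months[status == 1]))
    nRisk <- vapply(evt, function(t) sum(months >= t), numeric(1))
    nEvent <- vapply(evt, function(t) sum(months == t & status == 1),
        numeric(1))
    nCens <- vapply(evt, function(t) sum(months == t & status == 0),
        numeric(1))
    surv <- cumprod(1 - nEvent / nRisk)
    med <- if (length(evt) && any(surv <= 0.5)) evt[which(surv <= 0.5)[1L]]
        else NA_real_
    list(time = evt, surv = surv, n_risk = nRisk, n_event = nEvent,
        n_censor = nCens, median = med)
}

#' Log-rank test across groups
#'
#' Standard observed-minus-expected statistic over the pooled distinct
#' event times with the hypergeometric variance/covariance; chi-square with
#' (number of groups - 1) degrees of freedom.
#'
#' @param groups list of `list(months=, status=)` per group.
#' @return list: `chisq`, `df`, `p`, `observed`, `expected` (per group).
#' @export
logrankTest <- function(groups) {
    if (length(groups) < 2L) stopf("need >= 2 groups")
    if (any(!vapply(groups, function(g) length(g$months) > 0, logical(1))))
        stopf("empty group")
    G <- length(groups)
    months <- unlist(lapply(groups, `[[`, "months"))
    status <- unlist(lapply(groups, `[[`, "status"))
    grp <- rep(seq_len(G), vapply(groups, function(g) length(g$months),
        integer(1)))
    if (!any(status == 1)) stopf("no events in any group")

    evt <- sort(unique(months[status == 1]))
    OmE <- numeric(G)
    V <- matrix(0, G, G)
    for (t in evt) {
        atRisk <- months >= t
        nT <- sum(atRisk)
        dT <- sum(months == t & status == 1)
        nG <- vapply(seq_len(G), function(g) sum(atRisk & grp == g),
            numeric(1))
        dG <- vapply(seq_len(G), function(g)
            sum(months == t & status == 1 & grp == g), numeric(1))
        e <- dT * nG / nT
        OmE <- OmE + (dG - e)
        if (nT > 1) {
            c0 <- dT * (nT - dT) / (nT - 1)
            V <- V + c0 * (diag(nG * nT, G, G) - outer(nG, nG)) / nT^2
        }
    }
    idx <- seq_len(G - 1L)
    Vi <- V[idx, idx, drop = FALSE]
    chisq <- tryCatch(
        drop(t(OmE[idx]) %*% solve(Vi, OmE[idx])),
        error = function(e) 0)
    expected <- vapply(seq_len(G), function(g)
        sum(status[grp == g] == 1), numeric(1)) - OmE
    list(chisq = chisq, df = G - 1L,
        p = stats::pchisq(chisq, df = G - 1L, lower.tail = FALSE),
        observed = expected + OmE, expected = expected)
}

#' Univariate Cox proportional-hazards fit for a binary group flag
#'
#' Partial likelihood with Breslow tie handling, maximized by Newton
#' iteration to gradient below 1e-8; HR = exp(beta) with the Wald 95% CI
#' `exp(beta +/- 1.96 se)` and two-sided Wald p.
#'
#' @param months follow-up times.
#' @param status 1 = event, 0 = censored.
#' @param group_flag logical (or 0/1): membership in the index group.
#' @return list: `hr`, `ci` (length 2), `p`, `beta`, `se`, `iterations`.
#' @export
coxHR <- function(months, status, group_flag) {
    x <- as.numeric(group_flag)
    if (!all(x %in% c(0, 1))) stopf("group_flag must be binary")
    if (!any(x == 1) || !any(x == 0)) stopf("both groups must be non-empty")
    if (!any(status == 1)) stopf("no events")

    ord <- order(months)
    tm <- months[ord]; st <- status[ord]; xx <- x[ord]
    evtIdx <- which(st == 1)
    # risk-set composition at each event time, via reverse cumulative sums
    n1Tail <- rev(cumsum(rev(xx)))       # index-group subjects with tm >= tm[i]
    nTail <- length(tm) - seq_along(tm) + 1
    # subjects tied at the same time all belong to the risk set; with tm
    # sorted, the risk set at an event starts at the first tied index
    jv <- match(tm[evtIdx], tm)
    n1 <- n1Tail[jv]; n0 <- nTail[jv] - n1
    xEvt <- xx[evtIdx]

    beta <- 0
    for (it in seq_len(100L)) {
        eb <- exp(beta)
        denom <- n0 + n1 * eb
        mu <- n1 * eb / denom
        grad <- sum(xEvt) - sum(mu)
        info <- sum(mu * (1 - mu))
        if (info <= 0)
            stopf("monotone partial likelihood (complete separation)")
        if (abs(grad) < 1e-8) break
        beta <- beta + grad / info
        if (abs(beta) > 15)
            stopf("monotone partial likelihood (complete separation)")
        if (it == 100L) stopf("Cox Newton iteration failed to converge")
    }
    se <- 1 / sqrt(info)
    z <- beta / se
    list(hr = exp(beta), ci = exp(beta + c(-1.96, 1.96) * se),
        p = 2 * stats::pnorm(-abs(z)), beta = beta, se = se,
        iterations = it)
}

#' Two-group survival comparison (KM + log-rank + Cox HR)
#'
#' Convenience wrapper producing the full comparison the survival figures
#' rest on: per-group product-limit curves and median survival, the
#' log-rank test, and the Cox hazard ratio of the index group with its
#' Wald 95% CI.
#'
#' @param months,status follow-up and event indicators.
#' @param group_flag logical: index-group membership.
#' @param horizon follow-up window in months (default 120).
#' @return list: `km` (named list of two [kmEstimate()] results),
#'   `logrank`, `cox`.
#' @export
compareSurvival <- function(months, status, group_flag, horizon = 120) {
    cs <- applyHorizon(months, status, horizon)
    g1 <- group_flag
    km <- list(
        index = kmEstimate(cs$months[g1], cs$status[g1], horizon),
        reference = kmEstimate(cs$months[!g1], cs$status[!g1], horizon))
    lr <- logrankTest(list(
        list(months = cs$months[g1], status = cs$status[g1]),
        list(months = cs$months[!g1], status = cs$status[!g1])))
    cx <- coxHR(cs$months, cs$status, g1)
    list(km = km, logrank = lr, cox = cx)
}
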