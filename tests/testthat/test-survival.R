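test_that("NES classification applies the median +/- k*SD rule", {
    nes <- c(a = 0, b = 0, c = 0, d = 10)
    cl <- classifyByNES(nes)
    # median 0, SD 5: only d crosses median + SD; none fall below -5
    expect_identical(unname(positivityLabels(cl)),
        c("intermediate", "intermediate", "intermediate", "positive"))
    expect_equal(cl@median, 0)
    expect_equal(cl@sd, 5)
    expect_error(classifyByNES(c(a = 1, b = 1)), "degenerate")
})

test_that("normal NES yields ~16% tails under the 1-SD rule", {
    set.seed(30)
    nes <- rnorm(20000)
    cl <- classifyByNES(nes)
    tab <- table(positivityLabels(cl)) / length(nes)
    expect_equal(unname(tab["positive"]), pnorm(-1), tolerance = 0.15)
    expect_equal(unname(tab["negative"]), pnorm(-1), tolerance = 0.15)
})

test_that("classification is invariant to positive affine transforms", {
    set.seed(31)
    nes <- setNames(rnorm(50), paste0("S", 1:50))
    l1 <- positivityLabels(classifyByNES(nes))
    l2 <- positivityLabels(classifyByNES(3.7 * nes + 2))
    expect_identical(l1, l2)
})

test_that("co-positivity grouping needs unanimity", {
    s <- paste0("S", 1:4)
    craft <- function(pattern) {
        # hand-built call: median 0, SD 1, so +/-2 are decisive
        v <- setNames(c(positive = 2, intermediate = 0,
            negative = -2)[pattern], s)
        new("PositivityCall", labels = setNames(pattern, s), nes = v,
            median = 0, sd = 1, k = 1)
    }
    calls <- list(
        a = craft(c("positive", "positive", "negative", "intermediate")),
        b = craft(c("positive", "positive", "negative", "intermediate")))
    g <- copositivityGroups(calls)
    expect_identical(unname(g[1]), "all-positive")
    expect_identical(unname(g[3]), "all-negative")
    expect_identical(unname(g[4]), "other")
    # positive in 3 of 4 signatures -> other
    calls4 <- c(calls, list(
        c = calls$a,
        d = craft(c("intermediate", "positive", "negative",
            "negative"))))
    g4 <- copositivityGroups(calls4)
    expect_identical(unname(g4[1]), "other")
    expect_identical(unname(g4[2]), "all-positive")
    bad <- calls
    names(bad$b@labels)[1] <- "SX"
    expect_error(copositivityGroups(bad), "mismatched")
})

test_that("product-limit estimate matches hand computation", {
    km <- kmEstimate(c(1, 2, 3, 4), c(1, 1, 1, 1))
    expect_equal(km$surv, c(0.75, 0.50, 0.25, 0))
    expect_equal(km$median, 2)
    # all censored: S stays 1, median not reached
    km2 <- kmEstimate(c(5, 10, 15), c(0, 0, 0))
    expect_length(km2$time, 0)
    expect_true(is.na(km2$median))
    # single subject, single event
    km3 <- kmEstimate(5, 1)
    expect_equal(km3$surv, 0)
    expect_equal(km3$median, 5)
    expect_error(kmEstimate(numeric(0), integer(0)), "empty")
})

test_that("product-limit matches the oracle and survival::survfit", {
    set.seed(40)
    months <- round(rexp(60, 1 / 40), 2)
    status <- rbinom(60, 1, 0.7)
    km <- kmEstimate(months, status, horizon = Inf)
    orc <- kmOracle(months, status)
    expect_equal(km$time, orc$time)
    expect_equal(km$surv, orc$surv, tolerance = 1e-12)
    sf <- survival::survfit(survival::Surv(months, status) ~ 1)
    idx <- match(km$time, sf$time)
    expect_equal(km$surv, sf$surv[idx], tolerance = 1e-12)
})

test_that("the horizon administratively censors inside kmEstimate", {
    km <- kmEstimate(c(50, 130, 140), c(1, 1, 1), horizon = 120)
    expect_equal(km$time, 50)             # later events censored at 120
    expect_equal(km$surv, 2 / 3)
})

test_that("log-rank is null on identical groups and label-symmetric", {
    g <- list(months = c(3, 6, 9, 12), status = c(1, 0, 1, 1))
    lr <- logrankTest(list(g, g))
    expect_equal(lr$chisq, 0)
    expect_equal(lr$p, 1)
    set.seed(41)
    g1 <- list(months = rexp(30, 1 / 30), status = rbinom(30, 1, 0.8))
    g2 <- list(months = rexp(30, 1 / 10), status = rbinom(30, 1, 0.8))
    expect_equal(logrankTest(list(g1, g2))$chisq,
        logrankTest(list(g2, g1))$chisq, tolerance = 1e-12)
    expect_error(logrankTest(list(g1)), ">= 2 groups")
    expect_error(logrankTest(list(
        list(months = 1, status = 0), list(months = 2, status = 0))),
        "no events")
})

test_that("log-rank matches the per-event-time tabulation oracle", {
    set.seed(42)
    m1 <- rexp(30, 1 / 20); s1 <- rbinom(30, 1, 0.85)
    m2 <- rexp(30, 3 / 20); s2 <- rbinom(30, 1, 0.85)
    lr <- logrankTest(list(list(months = m1, status = s1),
        list(months = m2, status = s2)))
    expect_equal(lr$chisq, logrank2Oracle(m1, s1, m2, s2),
        tolerance = 1e-9)
    sd <- survival::survdiff(
        survival::Surv(c(m1, m2), c(s1, s2)) ~ rep(1:2, each = 30))
    expect_equal(lr$chisq, sd$chisq, tolerance = 1e-8)
})

test_that("log-rank is invariant to monotone time transforms", {
    set.seed(43)
    m1 <- rexp(25, 1 / 20); s1 <- rbinom(25, 1, 0.9)
    m2 <- rexp(25, 1 / 10); s2 <- rbinom(25, 1, 0.9)
    lr1 <- logrankTest(list(list(months = m1, status = s1),
        list(months = m2, status = s2)))
    lr2 <- logrankTest(list(list(months = sqrt(m1), status = s1),
        list(months = sqrt(m2), status = s2)))
    expect_equal(lr1$chisq, lr2$chisq, tolerance = 1e-12)
})

test_that("Cox fit is null for an independent flag", {
    set.seed(44)
    months <- rexp(400, 1 / 50)
    status <- rbinom(400, 1, 0.8)
    flag <- rep(c(TRUE, FALSE), 200)
    cx <- coxHR(months, status, flag)
    expect_equal(cx$hr, 1, tolerance = 0.35)
    expect_true(cx$ci[1] < 1 && cx$ci[2] > 1)
})

test_that("Cox matches the grid-search oracle on a tie-free toy", {
    months <- c(2, 5, 7, 11, 13, 17)
    status <- c(1, 1, 1, 1, 1, 1)
    flag <- c(1, 0, 1, 0, 1, 0)
    cx <- coxHR(months, status, flag)
    bGrid <- coxGridOracle(months, status, flag)
    expect_equal(cx$beta, bGrid, tolerance = 1e-3)
    fit <- survival::coxph(survival::Surv(months, status) ~ flag,
        ties = "breslow")
    expect_equal(cx$beta, unname(coef(fit)), tolerance = 1e-6)
    expect_equal(cx$se, sqrt(unname(vcov(fit)[1, 1])), tolerance = 1e-6)
})

test_that("Cox handles Breslow ties like survival::coxph", {
    set.seed(45)
    months <- sample(1:12, 80, replace = TRUE)   # heavy month-level ties
    status <- rbinom(80, 1, 0.7)
    flag <- rbinom(80, 1, 0.5)
    cx <- coxHR(months, status, flag)
    fit <- survival::coxph(survival::Surv(months, status) ~ flag,
        ties = "breslow")
    expect_equal(cx$beta, unname(coef(fit)), tolerance = 1e-6)
    expect_equal(cx$p, summary(fit)$coefficients[1, "Pr(>|z|)"],
        tolerance = 1e-5)
})

test_that("Cox detects monotone likelihood under separation", {
    months <- c(1, 2, 3, 50, 60, 70)
    status <- c(1, 1, 1, 0, 0, 0)
    flag <- c(1, 1, 1, 0, 0, 0)
    expect_error(coxHR(months, status, flag), "separation|monotone")
    expect_error(coxHR(c(1, 2), c(1, 1), c(1, 1)), "non-empty")
})

test_that("Cox estimate is consistent as n grows", {
    bias <- vapply(c(100L, 1000L), function(n) {
        set.seed(46)
        cc <- cohortConfig(hazard_ratio_positive = 2)
        hrs <- replicate(20, {
            flag <- rep(c(TRUE, FALSE), each = n / 2)
            s <- generateSurvival(rep("x", n), flag, cc)
            coxHR(s$months, s$status, flag)$hr
        })
        abs(mean(hrs) - 2)
    }, numeric(1))
    expect_lt(bias[2], bias[1] + 0.05)
    expect_lt(bias[2], 0.15)
})

test_that("compareSurvival assembles KM, log-rank and HR coherently", {
    set.seed(47)
    cc <- cohortConfig(hazard_ratio_positive = 3,
        baseline_hazard = log(2) / 80)
    flag <- rep(c(TRUE, FALSE), each = 100)
    s <- generateSurvival(rep("x", 200), flag, cc)
    cmp <- compareSurvival(s$months, s$status, flag)
    expect_gt(cmp$cox$hr, 1)
    expect_lt(cmp$logrank$p, 0.01)
    expect_true(cmp$km$index$median <= cmp$km$reference$median ||
        is.na(cmp$km$reference$median))
    expect_true(cmp$cox$ci[1] < cmp$cox$hr && cmp$cox$hr < cmp$cox$ci[2])
})
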