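test_that("Mann-Whitney exact enumeration matches hand-counted separation", {
    d <- data.frame(v = c(1, 2, 3, 10, 11, 12),
                    group = rep(c("PD", "HC"), each = 3))
    g <- groupCompare(d, "v")
    expect_equal(g$U, 0)
    expect_equal(g$p, 0.1)  # 2 / choose(6, 3)
    expect_match(g$method, "exact")
    # identical groups: every assignment gives the same U, p = 1
    d2 <- data.frame(v = rep(5, 8), group = rep(c("PD", "HC"), each = 4))
    expect_equal(groupCompare(d2, "v")$p, 1)
    expect_error(groupCompare(data.frame(v = 1, group = "PD"), "v"), "empty")
})

test_that("exact and approximate branches agree with the standard test", {
    set.seed(14)
    for (i in 1:20) {
        x <- rnorm(sample(4:8, 1)); y <- rnorm(sample(4:8, 1), 0.5)
        d <- data.frame(v = c(x, y),
                        group = rep(c("PD", "HC"), c(length(x), length(y))))
        ref <- wilcox.test(x, y, exact = TRUE)
        expect_equal(groupCompare(d, "v")$p, ref$p.value, tolerance = 1e-12)
    }
    for (i in 1:10) {
        x <- round(rnorm(15), 1); y <- round(rnorm(20, 0.4), 1)  # ties likely
        d <- data.frame(v = c(x, y),
                        group = rep(c("PD", "HC"), c(15, 20)))
        ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE,
                                            correct = FALSE))
        expect_equal(groupCompare(d, "v")$p, ref$p.value, tolerance = 1e-10)
    }
})

test_that("group separation at the study's SN-volume distributions is detected", {
    hits <- 0L
    for (s in 1:500) {
        set.seed(s)
        d <- data.frame(v = c(rnorm(18, 236, 50), rnorm(18, 344, 51)),
                        group = rep(c("PD", "HC"), each = 18))
        if (groupCompare(d, "v")$p < 0.001) hits <- hits + 1L
    }
    expect_gte(hits / 500, 0.95)
})

test_that("Spearman battery handles ranks, ties, monotone transforms and constants", {
    d <- data.frame(x = 1:5, y = c(2, 1, 4, 3, 5))
    b <- spearmanBattery(d, list(c("x", "y")))
    expect_equal(b$rho, 0.8)  # sum d^2 = 4 -> 1 - 24/120
    expect_equal(b$rho, unname(cor(d$x, d$y, method = "spearman")))
    # monotone transform has rho 1
    d2 <- data.frame(x = 1:8, y = exp(1:8))
    expect_equal(spearmanBattery(d2, list(c("x", "y")))$rho, 1)
    # constant variable is reported missing, not an error
    d3 <- data.frame(x = 1:6, y = rep(2, 6))
    b3 <- spearmanBattery(d3, list(c("x", "y")))
    expect_true(is.na(b3$rho))
    expect_error(spearmanBattery(data.frame(x = 1:3, y = 1:3),
                                 list(c("x", "y"))), "4 complete")
    # p-value matches the t approximation of the standard test
    set.seed(2)
    d4 <- data.frame(x = rnorm(30), y = rnorm(30))
    b4 <- spearmanBattery(d4, list(c("x", "y")))
    ref <- cor.test(d4$x, d4$y, method = "spearman", exact = FALSE)
    expect_equal(b4$rho, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(b4$p, ref$p.value, tolerance = 1e-10)
})

test_that("Benjamini-Hochberg adjustment is monotone and fixes equal p-values", {
    d <- data.frame(a = rnorm(20), b = rnorm(20), c = rnorm(20))
    set.seed(3)
    b <- spearmanBattery(d, list(c("a", "b"), c("a", "c"), c("b", "c")))
    expect_true(all(b$p_adj >= b$p - 1e-15))
    o <- order(b$p)
    expect_true(all(diff(b$p_adj[o]) >= -1e-15))
    # m tests sharing one raw p keep it after adjustment
    expect_equal(p.adjust(rep(0.01, 7), "BH"), rep(0.01, 7))
})

test_that("Clopper-Pearson equals exact binomial tail inversion everywhere", {
    for (n in 1:30) for (k in 0:n) {
        ref <- binom.test(k, n)$conf.int
        got <- clopperPearson(k, n)
        expect_equal(unname(got[1, ]), as.numeric(ref), tolerance = 1e-12)
    }
    expect_equal(as.numeric(round(100 * clopperPearson(16, 18), 2)),
                 c(65.29, 98.62))
})

test_that("ROC on separated groups puts all named cut-offs between the groups", {
    d <- data.frame(v = c(1:5, 11:15), group = rep(c("PD", "HC"), each = 5))
    r <- rocAnalysis(d, "v", direction = "lower")
    expect_equal(auc(r), 1)
    for (w in c("sens100", "spec100", "best")) {
        cc <- rocNamedCutoff(r, w)$cutoff
        expect_gt(cc, 5); expect_lt(cc, 11)
    }
    expect_equal(rocNamedCutoff(r, "best")$accuracy, 1)
})

test_that("trapezoid AUC equals the rank statistic U/(n1 n2) on random tables", {
    set.seed(4)
    for (i in 1:200) {
        n1 <- sample(5:25, 1); n2 <- sample(5:25, 1)
        x <- round(rnorm(n1, 0, 2), sample(0:1, 1))  # ties exercised
        y <- round(rnorm(n2, 1, 2), 1)
        d <- data.frame(v = c(x, y), group = rep(c("PD", "HC"), c(n1, n2)))
        r <- rocAnalysis(d, "v", direction = "lower")
        rk <- rank(c(y, x))  # U counting pairs with HC above PD
        U <- sum(rk[seq_len(n2)]) - n2 * (n2 + 1) / 2
        expect_equal(auc(r), U / (n1 * n2), tolerance = 1e-12)
    }
})

test_that("AUC agrees with an independent ROC implementation", {
    set.seed(19)
    d <- data.frame(v = c(rnorm(18, 236, 50), rnorm(18, 344, 51)),
                    group = rep(c("PD", "HC"), each = 18))
    r <- rocAnalysis(d, "v", direction = "lower")
    ref <- pROC::auc(pROC::roc(d$group, d$v, levels = c("PD", "HC"),
                               direction = "<", quiet = TRUE))
    expect_equal(auc(r), as.numeric(ref), tolerance = 1e-12)
})

test_that("ROC cut-off table and degenerate input behave as declared", {
    d <- data.frame(v = c(4, 4, 4, 4), group = c("PD", "PD", "HC", "HC"))
    r <- rocAnalysis(d, "v")
    expect_true(r@degenerate)
    expect_equal(auc(r), 0.5)
    # orientation declared, not inferred: higher direction mirrors lower
    d2 <- data.frame(v = c(10, 9, 1, 2), group = c("PD", "PD", "HC", "HC"))
    r2 <- rocAnalysis(d2, "v", direction = "higher")
    expect_equal(auc(r2), 1)
    cls <- classifyAtCutoff(d2, "v", 5, direction = "higher")
    expect_equal(cls$sensitivity, 100)
    expect_equal(cls$specificity, 100)
})

test_that("ICC(2,1) matches the ANOVA mean-squares oracle", {
    set.seed(5)
    m <- matrix(rnorm(12, rep(c(2, 5, 9), 4)), nrow = 3)
    got <- iccReliability(m)
    # brute-force oracle: two-way ANOVA mean squares via aov
    df <- data.frame(y = as.vector(m),
                     subj = factor(rep(1:3, 4)),
                     rater = factor(rep(1:4, each = 3)))
    ms <- summary(aov(y ~ subj + rater, df))[[1]]$`Mean Sq`
    msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
    ref <- (msr - mse) / (msr + 3 * mse + 4 * (msc - mse) / 3)
    expect_equal(got$icc, ref, tolerance = 1e-12)
})

test_that("ICC reaches 1 for perfect agreement and 0.5 at equal variance components", {
    m <- matrix(rep(c(1, 5, 9, 13), 3), nrow = 4)
    expect_equal(iccReliability(m)$icc, 1)
    flat <- matrix(rep(c(3, 3, 3), each = 4), nrow = 4)
    z <- iccReliability(flat)
    expect_equal(z$icc, 0)
    expect_true(z$flagged)
    set.seed(6)
    subj <- rnorm(200, 0, 1)
    m2 <- sapply(1:4, function(j) subj + rnorm(200, 0, 1))
    expect_lt(abs(iccReliability(m2)$icc - 0.5), 0.05)
})

test_that("DAT prediction reports OLS fit quality with a leave-one-out PRESS", {
    set.seed(7)
    n <- 18
    d <- data.frame(sn_volume_contra = rnorm(n, 236, 50),
                    cnr_sn_contra = rnorm(n, 4.3, 0.4),
                    cnr_lc_contra = rnorm(n, 3.5, 0.9))
    d$putamen_contra <- 0.01 * d$sn_volume_contra + rnorm(n, 0, 0.01)
    fit <- predictDAT(d, "putamen_contra")
    expect_gt(fit$r2, 0.99)
    expect_equal(fit$best_predictor, "sn_volume_contra")
    expect_gte(fit$press, sum(residuals(fit$fit)^2))  # LOO inequality
    # PRESS equals the brute-force refit-n-times value
    d6 <- d[1:6, ]
    f6 <- predictDAT(d6, "putamen_contra")
    loo <- sum(sapply(1:6, function(i) {
        f <- lm(putamen_contra ~ sn_volume_contra + cnr_sn_contra +
                    cnr_lc_contra, d6[-i, ])
        (d6$putamen_contra[i] - predict(f, d6[i, ]))^2
    }))
    expect_equal(f6$press, loo, tolerance = 1e-9)
    # collinearity is flagged
    d$dup <- d$sn_volume_contra
    expect_warning(fc <- predictDAT(d, "putamen_contra",
                                    c("sn_volume_contra", "dup")),
                   "collinear")
    expect_true(fc$rank_deficient)
})
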