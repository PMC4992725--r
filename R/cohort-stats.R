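#' Mann-Whitney group comparison
#'
#' Two-sided Mann-Whitney U test of one measure between two groups.  When
#' both groups have at most `exactMax` observations the two-sided p-value is
#' computed by exact enumeration of every group assignment of the observed
#' (possibly tied) values; otherwise the tie-corrected normal approximation
#' (no continuity correction) is used.
#'
#' @param data data.frame of subject records.
#' @param measure column name of the measure.
#' @param group column holding the group labels (default `"group"`).
#' @param levels the two group labels; the U statistic is reported for the
#'   first.
#' @param exactMax enumeration threshold per group (default 8).
#' @return List: `U`, `p`, `method`, `n` (per-group sizes).
#' @examples
#' d <- data.frame(v = c(1, 2, 3, 10, 11, 12),
#'                 group = rep(c("PD", "HC"), each = 3))
#' groupCompare(d, "v")
#' @export
groupCompare <- function(data, measure, group = "group",
                         levels = c("PD", "HC"), exactMax = 8) {
    x <- data[[measure]][data[[group]] == levels[1]]
    y <- data[[measure]][data[[group]] == levels[2]]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    stopIfNot(length(x) > 0 && length(y) > 0,
              "group '%s' is empty for measure '%s'",
              levels[if (length(x)) 2 else 1], measure)
    n1 <- length(x); n2 <- length(y); N <- n1 + n2
    rk <- rank(c(x, y))
    U <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    if (n1 <= exactMax && n2 <= exactMax) {
        combos <- utils::combn(N, n1)
        Us <- colSums(matrix(rk[combos], nrow = n1)) - n1 * (n1 + 1) / 2
        p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-9)
        method <- "exact enumeration"
    } else {
        ties <- table(rk)
        tieAdj <- sum(ties^3 - ties) / (N * (N - 1))
        sdU <- sqrt(n1 * n2 / 12 * ((N + 1) - tieAdj))
        stopIfNot(sdU > 0, "all values tied; test degenerate")
        p <- 2 * stats::pnorm(-abs(U - mu) / sdU)
        method <- "tie-corrected normal approximation"
    }
    list(U = U, p = min(p, 1), method = method, n = c(n1, n2))
}

#' Battery of Spearman correlations with FDR correction
#'
#' Spearman's rho (mid-rank ties) for each declared variable pair, p-values
#' from the t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2
#' degrees of freedom, and Benjamini-Hochberg adjustment across the battery
#' with significance flagged at adjusted p < 0.05.  Pairs with a constant
#' variable have undefined rho and are reported as missing (and excluded from
#' the adjustment family).
#'
#' @param data data.frame of subject records.
#' @param pairs list of character(2) vectors naming the variable pairs.
#' @param alpha significance level on the adjusted p (default 0.05).
#' @return data.frame: `x`, `y`, `n`, `rho`, `p`, `p_adj`, `significant`.
#' @export
spearmanBattery <- function(data, pairs, alpha = 0.05) {
    rows <- lapply(pairs, function(pr) {
        cc <- stats::complete.cases(data[[pr[1]]], data[[pr[2]]])
        x <- data[[pr[1]]][cc]; y <- data[[pr[2]]][cc]
        n <- length(x)
        stopIfNot(n >= 4, "fewer than 4 complete pairs for (%s, %s)",
                  pr[1], pr[2])
        if (stats::sd(x) == 0 || stats::sd(y) == 0)
            return(data.frame(x = pr[1], y = pr[2], n = n, rho = NA_real_,
                              p = NA_real_))
        rho <- stats::cor(rank(x), rank(y))
        p <- if (abs(rho) >= 1) 0 else {
            tt <- rho * sqrt((n - 2) / (1 - rho^2))
            2 * stats::pt(-abs(tt), n - 2)
        }
        data.frame(x = pr[1], y = pr[2], n = n, rho = rho, p = p)
    })
    out <- do.call(rbind, rows)
    out$p_adj <- NA_real_
    ok <- !is.na(out$p)
    out$p_adj[ok] <- stats::p.adjust(out$p[ok], method = "BH")
    out$significant <- !is.na(out$p_adj) & out$p_adj < alpha
    out
}

#' Exact Clopper-Pearson binomial confidence interval
#'
#' The exact interval for a binomial proportion by beta-quantile tail
#' inversion: lower bound `qbeta(alpha/2, k, n - k + 1)` (0 when k = 0),
#' upper bound `qbeta(1 - alpha/2, k + 1, n - k)` (1 when k = n).
#'
#' @param k number of successes (vectorised).
#' @param n number of trials.
#' @param conf confidence level (default 0.95).
#' @return Matrix with columns `lower`, `upper` on the proportion scale.
#' @examples
#' round(100 * clopperPearson(16, 18), 2)
#' @export
clopperPearson <- function(k, n, conf = 0.95) {
    stopIfNot(all(k >= 0 & k <= n), "k must be in [0, n]")
    a <- (1 - conf) / 2
    lower <- ifelse(k == 0, 0, stats::qbeta(a, k, n - k + 1))
    upper <- ifelse(k == n, 1, stats::qbeta(1 - a, k + 1, n - k))
    cbind(lower = lower, upper = upper)
}

#' ROC analysis with named cut-offs and exact intervals
#'
#' Empirical ROC of one measure for discriminating the positive group
#' (default PD) from the rest.  The measure's orientation is declared, not
#' inferred: with `direction = "lower"` a subject tests positive when the
#' value falls strictly below the cut-off.  Candidate cut-offs are the
#' midpoints between adjacent sorted distinct values plus one candidate
#' beyond each extreme; the AUC is the trapezoid area under the operating
#' points (which equals the Mann-Whitney `U / (n1 * n2)`).  Three operating
#' points are named: `sens100` (retaining 100% sensitivity with the best
#' specificity), `spec100` (100% specificity with the best sensitivity), and
#' `best` (maximal accuracy `(TP + TN) / N`, ties broken by Youden's J and
#' then the smaller cut-off).  Sensitivity and specificity at every candidate
#' carry exact Clopper-Pearson 95% intervals.
#'
#' @param data data.frame of subject records.
#' @param measure column name of the measure.
#' @param group grouping column (default `"group"`).
#' @param positive label of the positive class (default `"PD"`).
#' @param direction `"lower"` (smaller values indicate the positive class)
#'   or `"higher"`.
#' @param conf confidence level for the intervals.
#' @return A [RocResult-class].
#' @examples
#' coh <- simulateCohort(seed = 3)
#' rocAnalysis(coh, "sn_volume_contra")
#' @export
rocAnalysis <- function(data, measure, group = "group", positive = "PD",
                        direction = c("lower", "higher"), conf = 0.95) {
    direction <- match.arg(direction)
    pos <- data[[measure]][data[[group]] == positive]
    neg <- data[[measure]][data[[group]] != positive]
    pos <- pos[!is.na(pos)]; neg <- neg[!is.na(neg)]
    stopIfNot(length(pos) > 0 && length(neg) > 0,
              "both groups must be present for '%s'", measure)
    flip <- direction == "higher"
    if (flip) { pos <- -pos; neg <- -neg }
    n1 <- length(pos); n2 <- length(neg)
    v <- sort(unique(c(pos, neg)))
    degenerate <- length(v) == 1L
    gap <- if (degenerate) 1 else min(diff(v)) / 2
    cand <- c(v[1] - gap, if (!degenerate) (v[-length(v)] + v[-1]) / 2,
              v[length(v)] + gap)
    sens <- vapply(cand, function(cc) mean(pos < cc), numeric(1))
    spec <- vapply(cand, function(cc) mean(neg >= cc), numeric(1))
    accuracy <- (sens * n1 + spec * n2) / (n1 + n2)
    aucVal <- if (degenerate) 0.5 else {
        fpr <- 1 - spec
        o <- order(fpr, sens)
        sum(diff(fpr[o]) * (sens[o][-1] + sens[o][-length(o)]) / 2)
    }
    ci_s <- clopperPearson(round(sens * n1), n1, conf)
    ci_p <- clopperPearson(round(spec * n2), n2, conf)
    cutoffs <- data.frame(cutoff = if (flip) -cand else cand,
                          sensitivity = sens, specificity = spec,
                          accuracy = accuracy, youden = sens + spec - 1,
                          sens_lo = ci_s[, 1], sens_hi = ci_s[, 2],
                          spec_lo = ci_p[, 1], spec_hi = ci_p[, 2])
    pick <- function(i) cutoffs[i, , drop = FALSE]
    iS <- which(sens == 1)
    sens100 <- if (length(iS)) pick(iS[which.max(spec[iS])]) else NULL
    iP <- which(spec == 1)
    spec100 <- if (length(iP)) pick(iP[which.max(sens[iP])]) else NULL
    ordBest <- order(-accuracy, -(sens + spec - 1), cutoffs$cutoff)
    best <- pick(ordBest[1])
    named <- list(sens100 = sens100, spec100 = spec100, best = best)
    new("RocResult", auc = aucVal, cutoffs = cutoffs, named = named,
        nPositive = as.integer(n1), nNegative = as.integer(n2),
        direction = direction, degenerate = degenerate)
}

#' Classify at a fixed cut-off
#'
#' Sensitivity, specificity and accuracy (percent) of one measure at a given
#' cut-off under the declared orientation (positive when strictly below the
#' cut-off for `direction = "lower"`).
#'
#' @inheritParams rocAnalysis
#' @param cutoff the decision threshold (original measure scale).
#' @return List: `sensitivity`, `specificity`, `accuracy` (percent), `n`.
#' @export
classifyAtCutoff <- function(data, measure, cutoff, group = "group",
                             positive = "PD",
                             direction = c("lower", "higher")) {
    direction <- match.arg(direction)
    pos <- data[[measure]][data[[group]] == positive]
    neg <- data[[measure]][data[[group]] != positive]
    pos <- pos[!is.na(pos)]; neg <- neg[!is.na(neg)]
    testPos <- function(x) if (direction == "lower") x < cutoff else x > cutoff
    tp <- sum(testPos(pos)); tn <- sum(!testPos(neg))
    list(sensitivity = 100 * tp / length(pos),
         specificity = 100 * tn / length(neg),
         accuracy = 100 * (tp + tn) / (length(pos) + length(neg)),
         n = c(length(pos), length(neg)))
}

#' Intraclass correlation coefficient ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measurement intraclass
#' correlation from the standard mean-squares decomposition of a subjects x
#' repeats matrix:
#' `ICC = (MSR - MSE) / (MSR + (k - 1) MSE + k (MSC - MSE) / n)`.
#' A matrix with zero between-subject variance returns ICC 0 with a flag.
#'
#' @param mat numeric matrix, rows = subjects (>= 3), columns = repeated
#'   measurements (>= 2).
#' @return List: `icc`, `msr`, `msc`, `mse`, `n`, `k`, `flagged`.
#' @examples
#' m <- cbind(c(1, 5, 9), c(1.1, 5.2, 8.9), c(0.9, 4.9, 9.2))
#' iccReliability(m)$icc
#' @export
iccReliability <- function(mat) {
    mat <- as.matrix(mat)
    n <- nrow(mat); k <- ncol(mat)
    stopIfNot(n >= 3 && k >= 2, "need >= 3 subjects and >= 2 repeats")
    grand <- mean(mat)
    rm_ <- rowMeans(mat); cm_ <- colMeans(mat)
    msr <- k * sum((rm_ - grand)^2) / (n - 1)
    msc <- n * sum((cm_ - grand)^2) / (k - 1)
    sse <- sum((mat - outer(rm_, rep(1, k)) -
                outer(rep(1, n), cm_) + grand)^2)
    mse <- sse / ((n - 1) * (k - 1))
    if (stats::var(rm_) == 0)
        return(list(icc = 0, msr = msr, msc = msc, mse = mse, n = n, k = k,
                    flagged = TRUE))
    icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
    list(icc = icc, msr = msr, msc = msc, mse = mse, n = n, k = k,
         flagged = FALSE)
}

#' Least-squares prediction of DAT binding
#'
#' Ordinary least squares of a striatal DAT binding response on the NM-MRI
#' measures, reporting the fit quality used to compare predictors: R^2, RMSE
#' (`sqrt(SSE / df_residual)`), PRESS (leave-one-out predicted residual sum
#' of squares, computed from the hat matrix), the overall F-test p-value and
#' per-predictor (leverage) p-values; the best predictor is the one with the
#' smallest per-predictor p.  Collinear predictors are flagged as rank
#' deficient.
#'
#' @param data data.frame of subject records (typically the PD rows).
#' @param response response column (e.g. `"putamen_contra"`).
#' @param predictors predictor columns (default the three contralateral
#'   NM measures).
#' @return List: `fit` (the `lm`), `r2`, `rmse`, `press`, `f_p`,
#'   `predictor_p` (named), `best_predictor`, `rank_deficient`, `n`.
#' @export
predictDAT <- function(data, response,
                       predictors = c("sn_volume_contra", "cnr_sn_contra",
                                      "cnr_lc_contra")) {
    cols <- c(response, predictors)
    d <- data[stats::complete.cases(data[, cols]), cols]
    stopIfNot(nrow(d) >= length(predictors) + 2,
              "need at least %d complete cases", length(predictors) + 2)
    fml <- stats::as.formula(paste(response, "~",
                                   paste(predictors, collapse = " + ")))
    fit <- stats::lm(fml, data = d)
    rankDef <- any(is.na(stats::coef(fit)))
    if (rankDef) warning("collinear predictors: model is rank deficient")
    sm <- summary(fit)
    h <- stats::lm.influence(fit, do.coef = FALSE)$hat
    press <- sum((stats::residuals(fit) / (1 - h))^2)
    fstat <- sm$fstatistic
    fp <- stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
    cf <- sm$coefficients
    predP <- cf[setdiff(rownames(cf), "(Intercept)"), "Pr(>|t|)"]
    names(predP) <- setdiff(rownames(cf), "(Intercept)")
    list(fit = fit, r2 = sm$r.squared, rmse = sm$sigma, press = press,
         f_p = unname(fp), predictor_p = predP,
         best_predictor = names(predP)[which.min(predP)],
         rank_deficient = rankDef, n = nrow(d))
}
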