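## Repeated 10-fold cross-validated weighted genetic risk scores with
## control-quartile odds ratios and AUC.

#' Weighted genetic risk score for dosage vectors
#'
#' Score = sum over variants of weight x risk-allele count, where the risk
#' allele count equals the dosage when the minor allele is the risk allele
#' and 2 - dosage otherwise. Missing dosages are replaced by the model's
#' per-variant mean dosage.
#'
#' @param dosages variants x samples dosage matrix (rows named by variant
#'   id), or a single named per-variant vector for one sample.
#' @param model data.frame with columns \code{id}, \code{riskIsMinor}
#'   (logical orientation), \code{weight} and \code{meanDosage}.
#' @return Numeric score per sample.
#' @export
computeScore <- function(dosages, model) {
    if (is.null(dim(dosages)))
        dosages <- matrix(dosages, ncol = 1,
                          dimnames = list(names(dosages), NULL))
    if (!all(model$id %in% rownames(dosages)))
        stop("variant absent from dosage matrix: ",
             paste(setdiff(model$id, rownames(dosages)), collapse = ", "))
    d <- dosages[model$id, , drop = FALSE]
    for (j in seq_len(nrow(d))) {
        miss <- is.na(d[j, ])
        if (any(miss)) d[j, miss] <- model$meanDosage[j]
    }
    counts <- ifelse(model$riskIsMinor, 1, -1) * d +
        ifelse(model$riskIsMinor, 0, 2)
    colSums(counts * model$weight)
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: U statistic over case-control score pairs
#' divided by the number of pairs, ties counted one half.
#' @param scores numeric risk scores.
#' @param labels binary outcome (1 = case).
#' @return AUC in [0, 1]; NA (with a warning) if one class is absent.
#' @export
rocAUC <- function(scores, labels) {
    n1 <- sum(labels == 1); n0 <- sum(labels == 0)
    if (n1 == 0 || n0 == 0) {
        warning("AUC undefined: one class absent")
        return(NA_real_)
    }
    r <- rank(scores)
    (sum(r[labels == 1]) - as.numeric(n1) * (n1 + 1) / 2) /
        (as.numeric(n1) * n0)
}

## quartile assignment: controls split into 4 near-equal rank groups; break
## values (midpoints between adjacent group boundary scores) classify cases
assignQuartiles <- function(scores, isControl) {
    cs <- scores[isControl]
    ord <- order(cs)
    nC <- length(cs)
    grp <- integer(nC)
    grp[ord] <- ceiling(4 * seq_len(nC) / nC)
    breaks <- vapply(1:3, function(k) {
        hi <- max(cs[grp == k]); lo <- min(cs[grp == k + 1])
        (hi + lo) / 2
    }, numeric(1))
    q <- rep(1L, length(scores))
    for (b in breaks) q <- q + (scores > b)
    q[isControl] <- grp
    q
}

#' Repeated cross-validated weighted genetic risk score analysis
#'
#' Per replicate: the samples are randomly partitioned into stratified
#' folds; for each fold a multivariable logistic model (selected SNPs +
#' covariates + PCs) is fit on the training folds, each SNP is oriented so
#' its training weight (absolute log-OR) is positive, and held-out samples
#' are scored. Samples are then categorized by the quartiles of the pooled
#' control scores, quartile odds ratios versus the lowest quartile are
#' estimated by logistic regression adjusting for the covariates and PCs
#' (with a 3-df likelihood-ratio global chi-square), and the AUC is
#' recorded. Replicate point estimates are summarized as the mean log-OR /
#' mean AUC with 2.5-97.5 percentile intervals over replicates; an
#' inferential quartile-OR CI that adds the within-replicate Wald sampling
#' variance to the partition spread is reported alongside
#' (\code{or_Q*_infer_ci}).
#'
#' @param dataset a \linkS4class{GenotypeDataset} (mode-imputed internally).
#' @param snpIds SNP set fixed in advance (e.g. from penalized selection).
#' @param covariateNames covariate columns (e.g. infant sex).
#' @param pcs optional \code{\link{computePCs}} result.
#' @param folds number of folds (default 10).
#' @param repeats replicate count (study analysis used 1000).
#' @param seed integer seed; each replicate derives its own sub-seed.
#' @param fixedFolds optional integer fold assignment (one per sample) used
#'   for every replicate instead of random partitions — intended for audits
#'   of the cross-validation structure.
#' @return List with \code{summary} (per-quartile OR and CI, AUC and CI,
#'   mean global p, n replicates), \code{replicates} (per-replicate AUC,
#'   quartile log-ORs, global p) and \code{firstReplicate} (fold
#'   assignment, per-fold models and scores, for auditing).
#' @export
crossvalWGRS <- function(dataset, snpIds, covariateNames = character(),
                         pcs = NULL, folds = 10, repeats = 1000,
                         seed = 1L, fixedFolds = NULL) {
    d <- modeImputeDosage(dosage(dataset))[snpIds, , drop = FALSE]
    y <- phenotype(dataset)
    n <- length(y)
    Xadj <- matrix(0, n, 0)
    if (length(covariateNames))
        Xadj <- as.matrix(covariates(dataset)[covariateNames])
    if (!is.null(pcs)) Xadj <- cbind(Xadj, pcs$scores)
    isCtrl <- y == 0
    reps <- vector("list", repeats)
    firstRep <- NULL
    for (r in seq_len(repeats)) {
        repSeed <- seed + r
        fold <- fixedFolds
        if (is.null(fold)) for (try in 1:20) {
            cand <- makeFolds(y, folds, repSeed * 100 + try)
            ok <- all(vapply(seq_len(folds), function(f)
                length(unique(y[cand != f])) == 2, logical(1)))
            if (ok) { fold <- cand; break }
        }
        if (is.null(fold)) stop("could not form two-class training folds")
        scores <- numeric(n)
        models <- vector("list", folds)
        for (f in seq_len(folds)) {
            tr <- fold != f
            Xtr <- cbind(Intercept = 1, t(d[, tr, drop = FALSE]),
                         Xadj[tr, , drop = FALSE])
            fit <- suppressWarnings(
                glm.fit(Xtr, y[tr], family = binomial(),
                        control = list(epsilon = 1e-8, maxit = 50)))
            b <- fit$coefficients[1 + seq_along(snpIds)]
            b[is.na(b)] <- 0
            model <- data.frame(id = snpIds, riskIsMinor = b > 0,
                                weight = abs(b),
                                meanDosage = rowMeans(d[, tr, drop = FALSE]),
                                stringsAsFactors = FALSE)
            models[[f]] <- model
            te <- which(fold == f)
            scores[te] <- computeScore(d[, te, drop = FALSE], model)
        }
        q <- assignQuartiles(scores, isCtrl)
        Qm <- stats::model.matrix(~ factor(q, levels = 1:4))[, -1,
                                                             drop = FALSE]
        colnames(Qm) <- paste0("Q", 2:4)
        X1 <- cbind(Intercept = 1, Qm, Xadj)
        X0 <- cbind(Intercept = 1, Xadj)
        f1 <- suppressWarnings(glm.fit(X1, y, family = binomial()))
        f0 <- suppressWarnings(glm.fit(X0, y, family = binomial()))
        mu <- f1$fitted.values
        info <- crossprod(X1, X1 * (mu * (1 - mu)))
        se <- tryCatch(sqrt(diag(solve(info)))[2:4],
                       error = function(e) rep(NA_real_, 3))
        lrt <- f0$deviance - f1$deviance
        reps[[r]] <- data.frame(
            replicate = r, auc = rocAUC(scores, y),
            logOR_Q2 = f1$coefficients[["Q2"]],
            logOR_Q3 = f1$coefficients[["Q3"]],
            logOR_Q4 = f1$coefficients[["Q4"]],
            se_Q2 = se[1], se_Q3 = se[2], se_Q4 = se[3],
            globalP = pchisq(lrt, df = 3, lower.tail = FALSE))
        if (r == 1)
            firstRep <- list(fold = fold, models = models, scores = scores,
                             quartile = q)
    }
    repTab <- do.call(rbind, reps)
    summ <- list(nReplicates = repeats, folds = folds)
    for (qq in c("Q2", "Q3", "Q4")) {
        lo <- repTab[[paste0("logOR_", qq)]]
        se <- repTab[[paste0("se_", qq)]]
        summ[[paste0("or_", qq)]] <- exp(mean(lo))
        summ[[paste0("or_", qq, "_ci")]] <-
            exp(quantile(lo, c(0.025, 0.975), names = FALSE))
        ## inferential CI: partition spread plus within-replicate Wald
        ## sampling variance
        seTot <- sqrt(var(lo) + mean(se^2, na.rm = TRUE))
        summ[[paste0("or_", qq, "_infer_ci")]] <-
            exp(mean(lo) + c(-1.96, 1.96) * seTot)
    }
    summ$auc <- mean(repTab$auc)
    summ$auc_ci <- quantile(repTab$auc, c(0.025, 0.975), names = FALSE)
    summ$globalP_mean <- mean(repTab$globalP)
    list(summary = summ, replicates = repTab, firstReplicate = firstRep)
}

#' Write a WGRS summary as TSV
#'
#' One row per quartile (OR, CI low/high) plus AUC and the mean global p.
#' @param wgrs result of \code{\link{crossvalWGRS}}.
#' @param path output path.
#' @export
writeWgrsSummary <- function(wgrs, path) {
    s <- wgrs$summary
    tab <- data.frame(
        quantity = c("OR_Q2", "OR_Q3", "OR_Q4", "AUC", "global_p_mean"),
        estimate = c(s$or_Q2, s$or_Q3, s$or_Q4, s$auc, s$globalP_mean),
        ci_low = c(s$or_Q2_ci[1], s$or_Q3_ci[1], s$or_Q4_ci[1],
                   s$auc_ci[1], NA),
        ci_high = c(s$or_Q2_ci[2], s$or_Q3_ci[2], s$or_Q4_ci[2],
                    s$auc_ci[2], NA))
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(NULL)
}
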