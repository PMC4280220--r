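## Per-SNP logistic association with PC adjustment, FDR, genomic inflation,
## PCA for stratification, and baseline two-group comparisons.

#' Logistic regression by IRLS
#'
#' Maximum-likelihood logistic fit (iteratively reweighted least squares via
#' \code{glm.fit}), converged when the deviance change is below 1e-8 within
#' 50 iterations. Wald standard errors come from the observed information.
#' Perfect separation is flagged rather than raised.
#'
#' @param y binary outcome vector.
#' @param X design matrix (including the intercept column).
#' @return List with \code{coef}, \code{se}, \code{loglik}, \code{converged}
#'   and \code{separated}.
#' @export
fitLogistic <- function(y, X) {
    X <- as.matrix(X)
    stopifnot(nrow(X) == length(y), nrow(X) > ncol(X))
    fit <- suppressWarnings(
        glm.fit(X, y, family = binomial(),
                control = list(epsilon = 1e-8, maxit = 50)))
    mu <- fit$fitted.values
    w <- mu * (1 - mu)
    info <- crossprod(X, X * w)
    se <- tryCatch(sqrt(diag(solve(info))), error = function(e)
        rep(Inf, ncol(X)))
    ll <- sum(y * log(pmax(mu, 1e-300)) +
              (1 - y) * log(pmax(1 - mu, 1e-300)))
    separated <- any(mu > 1 - 1e-8 & y == 1) && any(mu < 1e-8 & y == 0) ||
        any(abs(fit$coefficients[-1]) > 15, na.rm = TRUE)
    list(coef = fit$coefficients, se = se, loglik = ll,
         converged = fit$converged, separated = separated)
}

#' Genotype principal components
#'
#' Dosages are mean-imputed per SNP, centered at twice the allele frequency
#' and scaled by \eqn{\sqrt{2 \hat p (1 - \hat p)}}; zero-variance SNPs are
#' skipped. Scores are the top-k left singular vectors of the standardized
#' samples-by-SNPs matrix, scaled by their singular values.
#'
#' @param dataset a \linkS4class{GenotypeDataset}.
#' @param k number of components (default 4, the usual adjustment depth).
#' @return List with \code{scores} (samples x k matrix, columns PC1..PCk)
#'   and \code{varExplained} (fractions, descending).
#' @export
computePCs <- function(dataset, k = 4) {
    d <- t(dosage(dataset))                 # samples x snps
    stopifnot(k < min(dim(d)))
    p <- colMeans(d, na.rm = TRUE) / 2
    keep <- !is.na(p) & p > 0 & p < 1
    d <- d[, keep, drop = FALSE]; p <- p[keep]
    for (j in seq_len(ncol(d))) {
        miss <- is.na(d[, j])
        if (any(miss)) d[miss, j] <- 2 * p[j]
    }
    z <- sweep(sweep(d, 2, 2 * p), 2, sqrt(2 * p * (1 - p)), "/")
    sv <- svd(z, nu = k, nv = 0)
    scores <- sv$u %*% diag(sv$d[seq_len(k)], k)
    rownames(scores) <- colnames(dosage(dataset))
    colnames(scores) <- paste0("PC", seq_len(k))
    list(scores = scores, varExplained = sv$d^2 / sum(sv$d^2))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values in the input order, capped at 1.
#' @param pValues vector of p-values in (0, 1].
#' @return q-values.
#' @export
bhFDR <- function(pValues) {
    if (!length(pValues)) return(numeric())
    p.adjust(pValues, method = "BH")
}

#' Genomic inflation factor
#'
#' \eqn{\lambda} = median of the 1-df chi-square quantiles of the p-values
#' divided by 0.454936, the null median.
#' @param pValues vector of p-values in (0, 1].
#' @return lambda.
#' @export
genomicInflation <- function(pValues) {
    chisq <- qchisq(pValues, df = 1, lower.tail = FALSE)
    median(chisq) / 0.454936
}

#' Per-SNP logistic association scan
#'
#' Fits, for each SNP, case status on additive minor-allele dosage plus an
#' intercept, any named covariates and the top principal components. Samples
#' missing that SNP's genotype are dropped pairwise. Reports per-SNP OR,
#' Wald 95% CI and p, BH-FDR q, and control-sample MAF; plus a scan summary
#' with the genomic inflation factor and QQ coordinates.
#'
#' @param dataset a QC'd \linkS4class{GenotypeDataset}.
#' @param covariateNames columns of \code{covariates(dataset)} to adjust for.
#' @param pcs optional result of \code{\link{computePCs}}; computed on the
#'   fly when \code{kPCs > 0} and not supplied.
#' @param kPCs number of PCs to adjust for (default 4; 0 disables).
#' @return List with \code{records} (data.frame sorted by ascending p) and
#'   \code{summary} (nTests, lambdaGC, qq data.frame).
#' @export
associationScan <- function(dataset, covariateNames = character(),
                            pcs = NULL, kPCs = 4) {
    d <- dosage(dataset)
    y <- phenotype(dataset)
    cov <- covariates(dataset)
    Xbase <- matrix(1, ncol(d), 1, dimnames = list(NULL, "intercept"))
    if (length(covariateNames))
        Xbase <- cbind(Xbase, as.matrix(cov[covariateNames]))
    if (kPCs > 0) {
        if (is.null(pcs)) pcs <- computePCs(dataset, k = kPCs)
        Xbase <- cbind(Xbase, pcs$scores[, seq_len(kPCs), drop = FALSE])
    }
    isCtrl <- y == 0
    v <- variantInfo(dataset)
    n <- nrow(d)
    res <- data.frame(id = v$id, gene = if ("gene" %in% colnames(v))
        v$gene else NA, mafControls = NA_real_, oddsRatio = NA_real_,
        ciLow = NA_real_, ciHigh = NA_real_, p = NA_real_,
        flag = "", stringsAsFactors = FALSE)
    for (j in seq_len(n)) {
        g <- d[j, ]
        ok <- !is.na(g)
        res$mafControls[j] <- tryCatch(
            computeMAF(g[isCtrl])$maf, error = function(e) NA_real_)
        if (var(g[ok]) == 0 || sum(ok) <= ncol(Xbase) + 1) {
            res$flag[j] <- "monomorphic"
            next
        }
        fit <- fitLogistic(y[ok], cbind(Xbase[ok, , drop = FALSE],
                                        dosage = g[ok]))
        b <- fit$coef[["dosage"]]; se <- fit$se[length(fit$se)]
        if (fit$separated || !is.finite(se)) {
            res$flag[j] <- "separated"
            res$oddsRatio[j] <- if (b > 0) Inf else 0
            next
        }
        res$oddsRatio[j] <- exp(b)
        res$ciLow[j] <- exp(b - 1.96 * se)
        res$ciHigh[j] <- exp(b + 1.96 * se)
        res$p[j] <- 2 * pnorm(-abs(b / se))
    }
    tested <- !is.na(res$p)
    res$q <- NA_real_
    res$q[tested] <- bhFDR(res$p[tested])
    lambda <- genomicInflation(res$p[tested])
    pSort <- sort(res$p[tested])
    qq <- data.frame(
        expected = -log10(stats::ppoints(length(pSort))),
        observed = -log10(pSort))
    res <- res[order(res$p), ]
    list(records = res,
         summary = list(nTests = sum(tested), lambdaGC = lambda, qq = qq))
}

#' Welch two-sample t-test from summary statistics
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 per-group summaries.
#' @return List with \code{statistic}, \code{df}, \code{p} (two-sided).
#' @export
welchTest <- function(mean1, sd1, n1, mean2, sd2, n2) {
    if (sd1 == 0 && sd2 == 0) {
        if (mean1 == mean2) return(list(statistic = 0, df = NA, p = 1,
                                        undefined = FALSE))
        return(list(statistic = NA, df = NA, p = NA, undefined = TRUE))
    }
    se2 <- sd1^2 / n1 + sd2^2 / n2
    t <- (mean1 - mean2) / sqrt(se2)
    df <- se2^2 / ((sd1^2 / n1)^2 / (n1 - 1) + (sd2^2 / n2)^2 / (n2 - 1))
    list(statistic = t, df = df, p = 2 * pt(-abs(t), df), undefined = FALSE)
}

#' Pearson chi-square test on a contingency table
#'
#' Without continuity correction; a table with zero total yields the
#' undefined flag.
#' @param counts 2 x k matrix of counts.
#' @return List with \code{statistic}, \code{df}, \code{p}.
#' @export
chiSquareCountsTest <- function(counts) {
    counts <- as.matrix(counts)
    if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
        return(list(statistic = NA, df = NA, p = NA, undefined = TRUE))
    tst <- suppressWarnings(chisq.test(counts, correct = FALSE))
    list(statistic = unname(tst$statistic), df = unname(tst$parameter),
         p = tst$p.value, undefined = FALSE)
}

#' Baseline group comparison (continuous or categorical)
#'
#' Welch t-test for continuous summaries, Pearson chi-square (no continuity
#' correction) for categorical counts — the standard Table-1 comparisons.
#'
#' @param continuous list(mean1, sd1, n1, mean2, sd2, n2), or NULL.
#' @param counts 2 x k count matrix, or NULL.
#' @return The corresponding test result list.
#' @export
twoGroupTest <- function(continuous = NULL, counts = NULL) {
    if (!is.null(continuous)) do.call(welchTest, continuous)
    else if (!is.null(counts)) chiSquareCountsTest(counts)
    else stop("provide continuous summaries or a count table")
}

#' Write association records as TSV
#' @param records data.frame from \code{\link{associationScan}}.
#' @param path output path.
#' @export
writeAssocRecords <- function(records, path) {
    write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(NULL)
}
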