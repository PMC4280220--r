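## Multivariable SNP selection: lasso with cross-validated penalty (glmnet),
## LD expansion of the selected set, and a hand-rolled bi-level composite-MCP
## / group-lasso penalized logistic engine for candidate-gene selection.

#' Penalized-selection configuration
#'
#' @param method one of \code{"lasso"}, \code{"grouplasso"}, \code{"cmcp"}.
#' @param cvFolds cross-validation folds for the penalty choice (default 20).
#' @param nLambda penalty-grid length (log-spaced from the path maximum down
#'   to 1\% of it).
#' @param mcpGamma MCP concavity parameter (> 1, default 3).
#' @param groups named character vector mapping variant id to gene, required
#'   for grouped methods.
#' @param seed integer seed controlling fold assignment.
#' @return List of class \code{"PenalizedConfig"}.
#' @export
penalizedConfig <- function(method = c("lasso", "grouplasso", "cmcp"),
                            cvFolds = 20, nLambda = 100, mcpGamma = 3,
                            groups = NULL, seed = 1L) {
    method <- match.arg(method)
    stopifnot(cvFolds >= 2, mcpGamma > 1, nLambda >= 2)
    if (method %in% c("grouplasso", "cmcp") && is.null(groups))
        stop(method, " needs a variant-to-gene group map")
    structure(list(method = method, cvFolds = as.integer(cvFolds),
                   nLambda = as.integer(nLambda), mcpGamma = mcpGamma,
                   groups = groups, seed = as.integer(seed)),
              class = "PenalizedConfig")
}

#' Pairwise linkage-disequilibrium r-squared
#'
#' Squared Pearson correlation of two dosage vectors over pairwise-complete
#' samples (composite-LD convention).
#' @param a,b dosage vectors.
#' @return r-squared in [0, 1]; NA if either vector has zero variance.
#' @export
pairwiseR2 <- function(a, b) {
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < 2) stop("need at least two complete pairs")
    if (var(a[ok]) == 0 || var(b[ok]) == 0) return(NA_real_)
    cor(a[ok], b[ok])^2
}

## per-SNP mode imputation of a dosage matrix (variants x samples)
modeImputeDosage <- function(d) {
    for (j in seq_len(nrow(d))) {
        miss <- is.na(d[j, ])
        if (!any(miss)) next
        obs <- d[j, !miss]
        md <- if (length(obs)) as.numeric(names(which.max(table(obs)))) else 0
        d[j, miss] <- md
    }
    d
}

## deterministic fold assignment, stratified by class
makeFolds <- function(y, k, seed) {
    set.seed(seed)
    fold <- integer(length(y))
    for (cls in unique(y)) {
        idx <- sample(which(y == cls))
        fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
}

#' Lasso SNP selection with cross-validated penalty
#'
#' L1-penalized logistic regression over a descending penalty grid
#' (\code{glmnet}); the adjustment covariates and principal components are
#' never penalized. The chosen penalty minimizes mean cross-validated
#' binomial deviance; SNPs with nonzero coefficients at that penalty are
#' returned.
#'
#' @param dataset a \linkS4class{GenotypeDataset}; missing dosages are
#'   mode-imputed first.
#' @param covariateNames covariate columns to include unpenalized.
#' @param pcs optional \code{\link{computePCs}} result (4 PCs used when
#'   supplied).
#' @param config a \code{\link{penalizedConfig}} with method "lasso".
#' @return List of class \code{"PenalizedSelection"}: \code{selected}
#'   (data.frame id, coefficient), \code{chosenPenalty}, \code{cvCurve}
#'   (lambda, mean deviance), \code{ldExpanded} (empty; see
#'   \code{\link{ldExpand}}).
#' @export
lassoSelectCV <- function(dataset, covariateNames = character(), pcs = NULL,
                          config = penalizedConfig("lasso")) {
    d <- modeImputeDosage(dosage(dataset))
    y <- phenotype(dataset)
    X <- t(d)
    nSnp <- ncol(X)
    if (length(covariateNames))
        X <- cbind(X, as.matrix(covariates(dataset)[covariateNames]))
    if (!is.null(pcs)) X <- cbind(X, pcs$scores)
    pf <- c(rep(1, nSnp), rep(0, ncol(X) - nSnp))
    foldid <- makeFolds(y, config$cvFolds, config$seed)
    cv <- glmnet::cv.glmnet(X, y, family = "binomial",
                            type.measure = "deviance",
                            penalty.factor = pf, foldid = foldid,
                            nlambda = config$nLambda,
                            lambda.min.ratio = 0.01)
    co <- coef(cv, s = "lambda.min")[-1][seq_len(nSnp)]
    sel <- which(co != 0)
    structure(list(
        selected = data.frame(id = rownames(d)[sel], coefficient = co[sel],
                              stringsAsFactors = FALSE),
        chosenPenalty = cv$lambda.min,
        cvCurve = data.frame(lambda = cv$lambda, deviance = cv$cvm),
        ldExpanded = data.frame(selected = character(), proxy = character(),
                                r2 = numeric())),
        class = "PenalizedSelection")
}

#' Expand a selection with linkage-disequilibrium proxies
#'
#' For every selected SNP, appends each same-chromosome SNP within
#' \code{windowBp} whose dosage r-squared with it reaches
#' \code{r2Threshold}. Proxies are reported alongside the selection, not
#' added to the model.
#'
#' @param selection a \code{"PenalizedSelection"}.
#' @param dataset the \linkS4class{GenotypeDataset} the selection came from.
#' @param r2Threshold minimum r-squared (default 0.8).
#' @param windowBp maximum distance in base pairs (default 500000).
#' @return The selection with a filled \code{ldExpanded} data.frame.
#' @export
ldExpand <- function(selection, dataset, r2Threshold = 0.8,
                     windowBp = 500000) {
    stopifnot(nrow(selection$selected) > 0)
    v <- variantInfo(dataset)
    d <- dosage(dataset)
    out <- list()
    for (id in selection$selected$id) {
        i <- match(id, v$id)
        near <- which(v$chromosome == v$chromosome[i] &
                      abs(v$position_bp - v$position_bp[i]) <= windowBp &
                      v$id != id)
        for (j in near) {
            r2 <- pairwiseR2(d[i, ], d[j, ])
            if (!is.na(r2) && r2 >= r2Threshold)
                out[[length(out) + 1L]] <-
                    data.frame(selected = id, proxy = v$id[j], r2 = r2,
                               stringsAsFactors = FALSE)
        }
    }
    selection$ldExpanded <- if (length(out)) do.call(rbind, out) else
        data.frame(selected = character(), proxy = character(),
                   r2 = numeric())
    selection
}

## --- penalized logistic engine (MCP / composite MCP / group lasso) -------

## MCP penalty and derivative
mcp <- function(t, lambda, gamma)
    ifelse(t <= gamma * lambda, lambda * t - t^2 / (2 * gamma),
           gamma * lambda^2 / 2)
mcpDeriv <- function(t, lambda, gamma) pmax(0, lambda - t / gamma)

## LLA weights for the composite (outer o inner) MCP penalty: outer MCP has
## unit slope at zero and saturates when all K_g members saturate
## (gamma_out = K_g * gamma * lambda^2 / 2), so the entry threshold at a
## null model equals plain MCP's lambda.
cmcpWeights <- function(beta, lambda, gamma, groupIndex) {
    inner <- mcp(abs(beta), lambda, gamma)
    w <- mcpDeriv(abs(beta), lambda, gamma)
    if (is.null(groupIndex)) return(w)      # plain MCP
    gsum <- tapply(inner, groupIndex, sum)[as.character(groupIndex)]
    K <- table(groupIndex)[as.character(groupIndex)]
    gammaOut <- as.numeric(K) * gamma * lambda^2 / 2
    outer <- ifelse(gammaOut > 0, pmax(0, 1 - as.numeric(gsum) / gammaOut), 1)
    outer * w
}

## Weighted-L1 (or group-L2) penalized logistic regression by proximal
## gradient; penalized columns must be standardized by the caller.
## penaltyFun(beta) -> per-coefficient weights for the soft-threshold prox,
## or NULL for group lasso (groupIndex + lambda used directly).
proxGradLogistic <- function(X, y, penalize, lambda, weightsFun = NULL,
                             groupIndex = NULL, groupLasso = FALSE,
                             beta0 = NULL, tol = 1e-6, maxIter = 10000,
                             step = NULL, family = "binomial") {
    n <- nrow(X); p <- ncol(X)
    beta <- if (is.null(beta0)) rep(0, p) else beta0
    if (is.null(step)) {
        step <- 1 / lipschitzLogistic(X)
        if (family == "gaussian") step <- step / 4
    }
    theta <- beta; tPrev <- 1        # FISTA momentum
    for (it in seq_len(maxIter)) {
        mu <- if (family == "gaussian") as.vector(X %*% theta) else
            plogis(as.vector(X %*% theta))
        grad <- as.vector(-crossprod(X, y - mu) / n)
        z <- theta - step * grad
        newBeta <- z
        if (groupLasso) {
            for (g in unique(groupIndex[penalize])) {
                idx <- which(penalize & groupIndex == g)
                nrm <- sqrt(sum(z[idx]^2))
                thr <- step * lambda * sqrt(length(idx))
                newBeta[idx] <- if (nrm <= thr) 0 else
                    z[idx] * (1 - thr / nrm)
            }
        } else {
            w <- rep(0, p)
            w[penalize] <- weightsFun(beta[penalize])
            newBeta[penalize] <- sign(z[penalize]) *
                pmax(0, abs(z[penalize]) - step * w[penalize])
        }
        delta <- max(abs(newBeta - beta))
        tNew <- (1 + sqrt(1 + 4 * tPrev^2)) / 2
        theta <- newBeta + ((tPrev - 1) / tNew) * (newBeta - beta)
        tPrev <- tNew
        beta <- newBeta
        if (delta < tol) return(list(beta = beta, iter = it,
                                     converged = TRUE))
    }
    list(beta = beta, iter = maxIter, converged = FALSE)
}

## Lipschitz bound for the mean logistic gradient: lambda_max(X'X) / (4n)
lipschitzLogistic <- function(X) {
    v <- rep(1 / sqrt(ncol(X)), ncol(X))
    for (i in 1:25) {
        v <- as.vector(crossprod(X, X %*% v))
        v <- v / sqrt(sum(v^2))
    }
    sum((X %*% v)^2) / (4 * nrow(X))
}

## fit one penalty path point; X already standardized where penalized
ncvLogisticFit <- function(X, y, penalize, lambda, config,
                           groupIndex = NULL, beta0 = NULL, step = NULL) {
    if (config$method == "grouplasso")
        proxGradLogistic(X, y, penalize, lambda, groupIndex = groupIndex,
                         groupLasso = TRUE, beta0 = beta0, step = step)
    else {
        gi <- if (config$method == "cmcp") groupIndex[penalize] else NULL
        wf <- function(b) cmcpWeights(b, lambda, config$mcpGamma, gi)
        proxGradLogistic(X, y, penalize, lambda, weightsFun = wf,
                         beta0 = beta0, step = step)
    }
}

## CV-driven penalized path for the hand-rolled engine
ncvSelectCV <- function(dataset, covariateNames, pcs, config) {
    d <- modeImputeDosage(dosage(dataset))
    y <- phenotype(dataset)
    ids <- rownames(d)
    X <- t(d)
    nSnp <- ncol(X)
    if (length(covariateNames))
        X <- cbind(X, as.matrix(covariates(dataset)[covariateNames]))
    if (!is.null(pcs)) X <- cbind(X, pcs$scores)
    X <- cbind(Intercept = 1, X)
    penalize <- c(FALSE, rep(TRUE, nSnp), rep(FALSE, ncol(X) - 1 - nSnp))
    ## standardize penalized columns (population sd, glmnet-style)
    ctr <- colMeans(X); ctr[1] <- 0
    scl <- rep(1, ncol(X))
    sdp <- apply(X, 2, function(x) sqrt(mean((x - mean(x))^2)))
    scl[penalize] <- ifelse(sdp[penalize] > 0, sdp[penalize], 1)
    Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
    groupIndex <- NULL
    if (config$method %in% c("grouplasso", "cmcp")) {
        gmap <- config$groups[ids]
        if (anyNA(gmap)) stop("every SNP must map to exactly one gene group")
        groupIndex <- c("(unpen)", gmap,
                        rep("(unpen)", ncol(X) - 1 - nSnp))
    }
    lambdaMax <- max(abs(crossprod(Xs[, penalize], y - mean(y)) / nrow(Xs)))
    grid <- exp(seq(log(lambdaMax), log(0.01 * lambdaMax),
                    length.out = config$nLambda))
    foldid <- makeFolds(y, config$cvFolds, config$seed)
    cvm <- rep(0, length(grid)); cvok <- rep(TRUE, length(grid))
    for (f in seq_len(config$cvFolds)) {
        tr <- foldid != f; te <- !tr
        beta <- NULL
        devs <- numeric(length(grid))
        stepF <- 1 / lipschitzLogistic(Xs[tr, , drop = FALSE])
        for (k in seq_along(grid)) {
            fit <- ncvLogisticFit(Xs[tr, , drop = FALSE], y[tr], penalize,
                                  grid[k], config, groupIndex, beta0 = beta,
                                  step = stepF)
            if (!fit$converged) { cvok[k] <- FALSE; next }
            beta <- fit$beta
            mu <- plogis(as.vector(Xs[te, , drop = FALSE] %*% beta))
            mu <- pmin(pmax(mu, 1e-8), 1 - 1e-8)
            devs[k] <- -2 * mean(y[te] * log(mu) + (1 - y[te]) * log(1 - mu))
        }
        cvm <- cvm + devs
    }
    cvm <- cvm / config$cvFolds
    usable <- which(cvok)
    if (!length(usable)) stop("no penalty converged in cross-validation")
    kBest <- usable[which.min(cvm[usable])]
    fit <- ncvLogisticFit(Xs, y, penalize, grid[kBest], config, groupIndex)
    if (!fit$converged)
        stop("penalized fit failed to converge at the chosen penalty")
    betaOrig <- fit$beta / scl
    snpCoefs <- betaOrig[1 + seq_len(nSnp)]
    sel <- which(snpCoefs != 0)
    structure(list(
        selected = data.frame(id = ids[sel], coefficient = snpCoefs[sel],
                              stringsAsFactors = FALSE),
        chosenPenalty = grid[kBest],
        cvCurve = data.frame(lambda = grid[cvok], deviance = cvm[cvok]),
        ldExpanded = data.frame(selected = character(), proxy = character(),
                                r2 = numeric())),
        class = "PenalizedSelection")
}

#' Bi-level gene/SNP selection with the composite minimax concave penalty
#'
#' Penalized logistic regression where an outer MCP is applied to the sum of
#' inner-MCP-penalized absolute coefficients within each gene, so selection
#' acts at the gene level and at the SNP level inside selected genes.
#' Optimized by local-linear-approximation reweighting with proximal-gradient
#' steps (convergence at max coefficient change < 1e-6); the penalty is
#' chosen by the same cross-validated deviance rule as the lasso.
#'
#' @inheritParams lassoSelectCV
#' @param config a \code{\link{penalizedConfig}} with method \code{"cmcp"}
#'   (or \code{"grouplasso"} for the group-penalty variant) and a
#'   \code{groups} map.
#' @return A \code{"PenalizedSelection"} (see \code{\link{lassoSelectCV}}).
#' @export
cmcpBilevelSelect <- function(dataset, covariateNames = character(),
                              pcs = NULL, config) {
    stopifnot(config$method %in% c("cmcp", "grouplasso"))
    ncvSelectCV(dataset, covariateNames, pcs, config)
}

#' Plain MCP SNP selection (no grouping)
#'
#' Same engine and cross-validation rule as
#' \code{\link{cmcpBilevelSelect}} with the minimax concave penalty applied
#' per-coefficient.
#' @inheritParams lassoSelectCV
#' @return A \code{"PenalizedSelection"}.
#' @export
mcpSelectCV <- function(dataset, covariateNames = character(), pcs = NULL,
                        config = penalizedConfig("lasso")) {
    cfg <- config
    cfg$method <- "mcp"
    ncvSelectCV(dataset, covariateNames, pcs, cfg)
}

#' Joint unpenalized refit of a selected SNP set
#'
#' Single multiple logistic regression containing every selected SNP plus
#' the covariates and principal components, reporting per-SNP OR, Wald 95\%
#' CI and p. A rank-deficient design falls back to a small ridge jitter and
#' is flagged.
#'
#' @param dataset a \linkS4class{GenotypeDataset}.
#' @param selectedIds variant ids to refit jointly.
#' @param covariateNames covariate columns.
#' @param pcs optional \code{\link{computePCs}} result.
#' @return data.frame with id, oddsRatio, ciLow, ciHigh, p and a
#'   \code{collinear} attribute/flag column.
#' @export
refitJoint <- function(dataset, selectedIds, covariateNames = character(),
                       pcs = NULL) {
    stopifnot(length(selectedIds) > 0)
    d <- modeImputeDosage(dosage(dataset))
    y <- phenotype(dataset)
    G <- t(d[selectedIds, , drop = FALSE])
    X <- cbind(Intercept = 1, G)
    if (length(covariateNames))
        X <- cbind(X, as.matrix(covariates(dataset)[covariateNames]))
    if (!is.null(pcs)) X <- cbind(X, pcs$scores)
    collinear <- qr(X)$rank < ncol(X)
    if (collinear) {
        ## ridge jitter: augment with sqrt(eps) * I pseudo-observations
        eps <- 1e-6
        Xa <- rbind(X, sqrt(eps) * diag(ncol(X)))
        ya <- c(y, rep(0.5, ncol(X)))
        fit <- suppressWarnings(glm.fit(Xa, ya, family = binomial()))
        mu <- plogis(as.vector(X %*% fit$coefficients))
        info <- crossprod(X, X * (mu * (1 - mu))) + eps * diag(ncol(X))
    } else {
        fit <- fitLogistic(y, X)
        mu <- NULL
        info <- NULL
    }
    if (collinear) {
        co <- fit$coefficients
        se <- sqrt(diag(solve(info)))
    } else {
        co <- fit$coef
        se <- fit$se
    }
    idx <- 1 + seq_along(selectedIds)
    data.frame(id = selectedIds,
               oddsRatio = exp(co[idx]),
               ciLow = exp(co[idx] - 1.96 * se[idx]),
               ciHigh = exp(co[idx] + 1.96 * se[idx]),
               p = 2 * pnorm(-abs(co[idx] / se[idx])),
               collinear = collinear,
               stringsAsFactors = FALSE, row.names = NULL)
}
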