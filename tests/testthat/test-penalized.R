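test_that("pairwise r2 behaves at its boundaries", {
    set.seed(81)
    x <- rbinom(100, 2, 0.3)
    expect_equal(pairwiseR2(x, x), 1)
    expect_true(is.na(pairwiseR2(x, rep(1, 100))))
    y <- rbinom(1e4, 2, 0.3); z <- rbinom(1e4, 2, 0.3)
    expect_lt(pairwiseR2(y, z), 0.01)
    expect_error(pairwiseR2(c(1, NA), c(NA, 1)), "complete pairs")
})

test_that("haplotype-chain LD decays with distance and feeds ld expansion", {
    cfg <- simulationConfig(nCases = 300, nControls = 300, nSnps = 40,
                            ldRho = 0.9, mafRange = c(0.2, 0.4),
                            baselineRisk = 0.5, seed = 83)
    d <- dosage(simulateCaseControl(cfg))
    r2ByLag <- vapply(1:5, function(lag)
        mean(vapply(seq_len(nrow(d) - lag), function(j)
            pairwiseR2(d[j, ], d[j + lag, ]), numeric(1)), na.rm = TRUE),
        numeric(1))
    expect_true(all(diff(r2ByLag) < 0))
})

test_that("no selection survives a penalty at or above the KKT maximum", {
    cfg <- simulationConfig(nCases = 150, nControls = 150, nSnps = 50,
                            causalEffects = data.frame(snp = 1, or = 2),
                            mafRange = c(0.2, 0.4), seed = 85)
    ds <- simulateCaseControl(cfg)
    y <- unname(phenotype(ds))
    X <- t(modeImpute <- dyadGWAS:::modeImputeDosage(dosage(ds)))
    ## KKT oracle: lambda_max = max_j |x_j'(y - ybar)| / n on standardized x
    Xs <- scale(X, center = TRUE,
                scale = apply(X, 2, function(v) sqrt(mean((v - mean(v))^2))))
    lambdaMax <- max(abs(crossprod(Xs, y - mean(y)) / nrow(Xs)))
    fit <- glmnet::glmnet(X, y, family = "binomial",
                          lambda = lambdaMax * c(1.05, 1))
    expect_equal(sum(fit$beta[, 1] != 0), 0)
    ## hand-rolled engine obeys the same threshold
    cfgP <- penalizedConfig("lasso", cvFolds = 3, nLambda = 5, seed = 1)
    cfgP$method <- "mcp"
    eng <- dyadGWAS:::ncvLogisticFit(
        cbind(1, Xs), y, c(FALSE, rep(TRUE, ncol(Xs))),
        lambdaMax * 1.01, cfgP)
    expect_equal(sum(eng$beta[-1] != 0), 0)
})

test_that("the engine matches the closed-form soft threshold on an orthonormal design", {
    set.seed(87)
    n <- 128
    q <- qr.Q(qr(matrix(rnorm(n * 8), n, 8))) * sqrt(n)  # X'X/n = I
    beta <- c(1.2, -0.8, 0.5, 0.25, 0.1, 0, 0, 0)
    y <- as.vector(q %*% beta) + rnorm(n, sd = 0.5)
    bOLS <- as.vector(crossprod(q, y) / n)
    lam <- 0.3
    soft <- sign(bOLS) * pmax(0, abs(bOLS) - lam)
    fit <- dyadGWAS:::proxGradLogistic(
        q, y, penalize = rep(TRUE, 8), lambda = lam,
        weightsFun = function(b) rep(lam, length(b)),
        family = "gaussian", tol = 1e-9)
    expect_equal(fit$beta, soft, tolerance = 1e-6)
})

test_that("lasso cross-validation recovers most causal SNPs", {
    hits <- vapply(1:25, function(i) {
        cfg <- simulationConfig(nCases = 500, nControls = 500, nSnps = 205,
                                mafRange = c(0.3, 0.3),
                                causalEffects = data.frame(snp = 1:5,
                                                           or = 2),
                                seed = 8500 + i)
        ds <- simulateCaseControl(cfg)
        sel <- lassoSelectCV(ds, config = penalizedConfig(
            "lasso", cvFolds = 20, seed = i))
        sum(sprintf("snp%04d", 1:5) %in% sel$selected$id) >= 4
    }, logical(1))
    expect_gte(mean(hits), 0.8)
})

test_that("lasso path selection size is non-increasing in the penalty", {
    cfg <- simulationConfig(nCases = 200, nControls = 200, nSnps = 60,
                            causalEffects = data.frame(snp = 1:3, or = 2),
                            mafRange = c(0.2, 0.4), seed = 89)
    ds <- simulateCaseControl(cfg)
    X <- t(dyadGWAS:::modeImputeDosage(dosage(ds)))
    fit <- glmnet::glmnet(X, unname(phenotype(ds)), family = "binomial")
    sizes <- colSums(as.matrix(fit$beta) != 0)   # lambda descending
    expect_true(all(diff(rev(sizes)) <= 0))
})

test_that("LD expansion finds duplicated columns and grows with LD", {
    cfg <- simulationConfig(nCases = 150, nControls = 150, nSnps = 30,
                            mafRange = c(0.2, 0.4), baselineRisk = 0.5,
                            seed = 91)
    ds <- simulateCaseControl(cfg)
    ## duplicate SNP 1 one bp away
    d <- dosage(ds)
    v <- variantInfo(ds)
    d2 <- rbind(d, d[1, ])
    v2 <- rbind(v, data.frame(id = "dup1", chromosome = v$chromosome[1],
                              position_bp = v$position_bp[1] + 1L,
                              allele_minor = "A", allele_major = "G",
                              gene = NA))
    ds2 <- GenotypeDataset(d2, v2, unname(phenotype(ds)),
                           covariates(ds))
    sel <- structure(list(selected = data.frame(id = "snp0001",
                                                coefficient = 1)),
                     class = "PenalizedSelection")
    ex <- ldExpand(sel, ds2)
    expect_true("dup1" %in% ex$ldExpanded$proxy)
    expect_equal(ex$ldExpanded$r2[ex$ldExpanded$proxy == "dup1"], 1)
    expect_true(all(ex$ldExpanded$r2 >= 0.8))
    ## no same-chromosome SNP within the window -> empty expansion
    vFar <- v; vFar$position_bp <- seq_len(nrow(vFar)) * 10^7
    dsFar <- GenotypeDataset(d, vFar, unname(phenotype(ds)))
    exFar <- ldExpand(sel, dsFar)
    expect_equal(nrow(exFar$ldExpanded), 0)
    ## high-LD chains expand more than independent SNPs (equal MAFs so the
    ## binary-margin bound does not cap the attainable correlation)
    mkSel <- function(rho, seed) {
        cfg <- simulationConfig(nCases = 200, nControls = 200, nSnps = 40,
                                ldRho = rho, mafRange = c(0.3, 0.3),
                                baselineRisk = 0.5, seed = seed)
        dsL <- simulateCaseControl(cfg)
        s <- structure(list(selected = data.frame(id = "snp0020",
                                                  coefficient = 1)),
                       class = "PenalizedSelection")
        nrow(ldExpand(s, dsL)$ldExpanded)
    }
    expect_gt(mkSel(0.97, 93), mkSel(0, 93))
})

test_that("composite MCP selects causal genes and reduces to MCP on singletons", {
    cfg <- simulationConfig(nCases = 400, nControls = 400, nSnps = 120,
                            mafRange = c(0.2, 0.4),
                            causalEffects = data.frame(snp = c(1, 2, 5, 6),
                                                       or = 2),
                            seed = 95)
    ds <- simulateCaseControl(cfg)
    ids <- rownames(dosage(ds))
    groups <- setNames(rep(sprintf("gene%02d", 1:30), each = 4), ids)
    sel <- cmcpBilevelSelect(ds, config = penalizedConfig(
        "cmcp", cvFolds = 5, nLambda = 25, groups = groups, seed = 2))
    selGenes <- unique(unname(groups[sel$selected$id]))
    expect_true(all(c("gene01", "gene02") %in% selGenes))
    ## singleton groups: selection coincides with plain MCP on the same grid
    singles <- setNames(ids, ids)
    selS <- cmcpBilevelSelect(ds, config = penalizedConfig(
        "cmcp", cvFolds = 5, nLambda = 25, groups = singles, seed = 2))
    selM <- mcpSelectCV(ds, config = penalizedConfig(
        "lasso", cvFolds = 5, nLambda = 25, seed = 2))
    expect_setequal(selS$selected$id, selM$selected$id)
})

test_that("cmcp approaches its large-gamma limit monotonically on a toy fit", {
    cfg <- simulationConfig(nCases = 200, nControls = 200, nSnps = 8,
                            mafRange = c(0.3, 0.3),
                            causalEffects = data.frame(snp = 1:2, or = 2.5),
                            seed = 97)
    ds <- simulateCaseControl(cfg)
    ids <- rownames(dosage(ds))
    groups <- setNames(rep(c("g1", "g2"), each = 4), ids)
    coefAt <- function(gam) {
        cfgP <- penalizedConfig("cmcp", cvFolds = 3, nLambda = 2,
                                mcpGamma = gam, groups = groups, seed = 3)
        X <- t(dyadGWAS:::modeImputeDosage(dosage(ds)))
        Xs <- cbind(1, scale(X))
        fit <- dyadGWAS:::ncvLogisticFit(
            Xs, unname(phenotype(ds)), c(FALSE, rep(TRUE, 8)), 0.05, cfgP,
            groupIndex = c("(u)", unname(groups)))
        fit$beta[-1]
    }
    ## as gamma grows both MCP levels flatten toward the L1 penalty: the
    ## distance to the large-gamma (lasso-like) limit shrinks monotonically
    bRef <- coefAt(1e6)
    dist <- vapply(c(3, 30, 300), function(g) max(abs(coefAt(g) - bRef)),
                   numeric(1))
    expect_true(all(diff(dist) < 0))
})

test_that("joint refit matches the scan for one SNP and flags collinearity", {
    cfg <- simulationConfig(nCases = 150, nControls = 150, nSnps = 10,
                            mafRange = c(0.2, 0.4), seed = 99)
    ds <- simulateCaseControl(cfg)
    pcs <- computePCs(ds, 4)
    scan <- associationScan(ds, "sex", pcs = pcs, kPCs = 4)
    id <- scan$records$id[1]
    rf <- refitJoint(ds, id, "sex", pcs)
    expect_equal(rf$oddsRatio, scan$records$oddsRatio[1], tolerance = 1e-6)
    ## duplicated column raises the collinearity flag
    d <- dosage(ds); v <- variantInfo(ds)
    d2 <- rbind(d, d[1, ]); v2 <- rbind(v, within(v[1, ], {
        id <- "dup"; position_bp <- position_bp + 5L }))
    ds2 <- GenotypeDataset(d2, v2, unname(phenotype(ds)), covariates(ds))
    rf2 <- refitJoint(ds2, c("snp0001", "dup"))
    expect_true(all(rf2$collinear))
})

test_that("two independent causal SNPs keep their marginal effects jointly", {
    cfg <- simulationConfig(nCases = 2500, nControls = 2500, nSnps = 2,
                            mafRange = c(0.3, 0.3),
                            causalEffects = data.frame(snp = 1:2, or = 2),
                            seed = 101)
    ds <- simulateCaseControl(cfg)
    rf <- refitJoint(ds, c("snp0001", "snp0002"))
    expect_lt(max(abs(log(rf$oddsRatio) - log(2))), 0.15)
})
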