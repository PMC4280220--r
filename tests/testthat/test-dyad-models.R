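test_that("null multipliers collapse case duos to the population law", {
    pr <- dyadCellProbabilities(dyadParams(q = 0.5))
    expect_equal(unname(pr$case[["0/0"]]), 0.125)
    expect_equal(pr$case, pr$control)
    expect_equal(sum(pr$case), 1, tolerance = 1e-12)
    expect_error(dyadParams(q = 0), "strictly")
    expect_error(dyadParams(q = 0.5, R1 = -1), "positive")
})

test_that("imprinting raises risk only through maternally derived alleles", {
    ## (2,1) children always inherit the risk allele from the mother;
    ## (0,1) children never do
    pr <- dyadCellProbabilities(dyadParams(q = 0.5, Im = 2))
    rr21 <- pr$case[["2/1"]] / pr$control[["2/1"]]
    rr01 <- pr$case[["0/1"]] / pr$control[["0/1"]]
    expect_gt(rr21, rr01)
})

test_that("cell probabilities equal the exhaustive origin enumeration", {
    set.seed(131)
    for (i in 1:500) {
        pa <- dyadParams(q = runif(1, 0.03, 0.97),
                         R1 = exp(rnorm(1, 0, 0.6)),
                         R2 = exp(rnorm(1, 0, 0.6)),
                         S1 = exp(rnorm(1, 0, 0.6)),
                         S2 = exp(rnorm(1, 0, 0.6)),
                         Im = exp(rnorm(1, 0, 0.6)),
                         gamma01 = exp(rnorm(1, 0, 0.6)),
                         gamma21 = exp(rnorm(1, 0, 0.6)))
        pr <- dyadCellProbabilities(pa)
        expect_lt(max(abs(pr$case - enumCaseCells(pa))), 1e-12)
        expect_lt(abs(sum(pr$case) - 1), 1e-12)
        expect_lt(abs(sum(pr$control) - 1), 1e-12)
    }
})

test_that("the duo log-likelihood is multinomial in the counts", {
    pa <- dyadParams(q = 0.5)
    one <- c(1, 0, 0, 0, 0, 0, 0)
    zero <- rep(0, 7)
    expect_equal(dyadLoglik(one, zero, pa), log(0.125))
    cc <- c(5, 3, 2, 8, 1, 2, 4); kc <- c(9, 4, 3, 6, 2, 1, 2)
    expect_equal(dyadLoglik(2 * cc, 2 * kc, pa),
                 2 * dyadLoglik(cc, kc, pa))
})

test_that("counts drawn as expected cell frequencies are maximized at truth", {
    pa <- dyadParams(q = 0.3, S1 = 1.5, S2 = 2.2, R1 = 1.3, R2 = 1.7)
    pr <- dyadCellProbabilities(pa)
    cc <- round(pr$case * 1e5); kc <- round(pr$control * 1e5)
    fit <- fitDyadModel(cc, kc, "M+F", nStarts = 3L)
    ## the fitted maximum cannot fall below the truth's log-likelihood
    expect_gte(fit@loglik, dyadLoglik(cc, kc, pa) - 1e-6)
    ## and the fitted parameters sit essentially at the truth
    free <- c("q", "R1", "R2", "S1", "S2")
    expect_lt(max(abs(log(fit@params[free]) - log(pa[free]))), 0.02)
})

test_that("M+F maximum likelihood recovers simulated parameters", {
    pa <- dyadParams(q = 0.3, R1 = 1.3, R2 = 1.7, S1 = 1.5, S2 = 2.2)
    cfg <- simulationConfig(nCaseDyads = 5000, nControlDyads = 5000,
                            nSnps = 1, dyadParams = pa,
                            baselineRisk = 0.01, seed = 133)
    sim <- simulateDyads(cfg, keepTruth = FALSE)
    fit <- fitDyadModel(caseCounts(sim$dyads)[1, ],
                        controlCounts(sim$dyads)[1, ], "M+F")
    free <- c("R1", "R2", "S1", "S2")
    expect_lt(max(abs(log(fit@params[free]) - log(pa[free]))), 0.15)
    expect_lt(abs(fit@params[["q"]] - 0.3), 0.02)
    expect_equal(fit@k, 5L)
    expect_equal(fit@bic, -2 * fit@loglik + 5 * log(10000))
})

test_that("null-simulated duos give multipliers near one", {
    cfg <- simulationConfig(nCaseDyads = 5000, nControlDyads = 5000,
                            nSnps = 1, dyadParams = dyadParams(q = 0.3),
                            baselineRisk = 0.01, seed = 135)
    sim <- simulateDyads(cfg, keepTruth = FALSE)
    fit <- fitDyadModel(caseCounts(sim$dyads)[1, ],
                        controlCounts(sim$dyads)[1, ], "M+F")
    expect_lt(max(abs(log(fit@params[c("R1", "R2", "S1", "S2")]))), 0.1)
})

test_that("small-table fits agree with a dense grid-search oracle", {
    cc <- c(4, 3, 2, 6, 1, 1, 1); kc <- c(5, 3, 2, 1, 0, 1, 0)
    ## Null model: 1-parameter grid over q
    fitN <- fitDyadModel(cc, kc, "Null")
    gridN <- vapply(seq(0.01, 0.99, length.out = 4000), function(q)
        dyadLoglik(cc, kc, dyadParams(q)), numeric(1))
    expect_lt(abs(fitN@loglik - max(gridN)), 1e-4)
    expect_gte(fitN@loglik, max(gridN) - 1e-6)
    ## M model: local dense grid around the fit finds nothing better
    fitM <- fitDyadModel(cc, kc, "M")
    base <- fitM@params
    better <- 0
    for (q in base[["q"]] * seq(0.9, 1.1, length.out = 11))
        for (s1 in base[["S1"]] * seq(0.8, 1.25, length.out = 11))
            for (s2 in base[["S2"]] * seq(0.8, 1.25, length.out = 11)) {
                if (q <= 0 || q >= 1) next
                ll <- dyadLoglik(cc, kc, dyadParams(q, S1 = s1, S2 = s2))
                if (ll > fitM@loglik + 1e-4) better <- better + 1
            }
    expect_equal(better, 0)
})

test_that("likelihood ratio statistics follow from the log-likelihoods", {
    fitA <- new("DyadModelFit", model = "M+F",
                params = dyadParams(0.3), loglik = -356.546, k = 5L,
                bic = -2 * -356.546 + 5 * log(420), n = 420L,
                converged = TRUE)
    fitB <- new("DyadModelFit", model = "Null",
                params = dyadParams(0.3), loglik = -373.757, k = 1L,
                bic = -2 * -373.757 + 1 * log(420), n = 420L,
                converged = TRUE)
    lr <- likelihoodRatioTest(fitA, fitB)
    expect_equal(lr$statistic, 2 * (-356.546 + 373.757))
    expect_equal(lr$p, pchisq(lr$statistic, 4, lower.tail = FALSE))
    ## identical log-likelihoods: statistic 0, p 1
    lr0 <- likelihoodRatioTest(fitA, fitA, df = 1)
    expect_equal(lr0$statistic, 0)
    expect_equal(lr0$p, 1)
})

test_that("risk-allele relabeling leaves the maximized likelihood unchanged", {
    cc <- c(14, 23, 12, 36, 21, 12, 24); kc <- c(25, 23, 22, 36, 11, 12, 4)
    swap <- function(x) rev(x)   # cell order reverses under 0<->2 relabel
    for (model in c("Null", "F")) {
        f1 <- fitDyadModel(cc, kc, model)
        f2 <- fitDyadModel(swap(cc), swap(kc), model)
        expect_equal(f1@loglik, f2@loglik, tolerance = 1e-6)
    }
})

test_that("BIC selection lays out the standard comparison table", {
    cfg <- simulationConfig(nCaseDyads = 300, nControlDyads = 300,
                            nSnps = 1, dyadParams = dyadParams(q = 0.3),
                            baselineRisk = 0.01, seed = 137)
    sim <- simulateDyads(cfg, keepTruth = FALSE)
    s <- selectBestModel(caseCounts(sim$dyads)[1, ],
                         controlCounts(sim$dyads)[1, ])
    expect_equal(s$table$comparison,
                 c("Model I vs Model M+F", "Model M+F vs Model F",
                   "Model M+F vs Model M", "Model M+F vs Model Null",
                   "Model M vs Model Null", "Model F vs Model Null",
                   "Model Null"))
    expect_true(all(s$table$lrt[-7] >= 0, na.rm = TRUE))
    expect_true(s$selected %in% c("Null", "F", "M", "M+F", "I"))
})

test_that("the imprinting scan reports one usable row per variant", {
    cfg <- simulationConfig(nCaseDyads = 400, nControlDyads = 400,
                            nSnps = 4,
                            dyadParams = dyadParams(q = 0.3, Im = 2.5,
                                                    S1 = 1.2, S2 = 1.4),
                            baselineRisk = 0.01, seed = 139)
    sim <- simulateDyads(cfg, keepTruth = FALSE)
    imp <- imprintingScan(sim$dyads)
    expect_equal(nrow(imp), 4)
    expect_true(all(imp$lrt[!imp$skipped] >= 0))
    expect_true(all(imp$p[!imp$skipped] <= 1))
})
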