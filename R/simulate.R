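## Synthetic case-control genotypes and mother-child duos.
##
## The generator reproduces the statistical structure the analyses assume:
## haplotypes under HWE with a first-order-Markov LD profile, disease assigned
## by a logistic multiplicative model, optional two-subpopulation
## stratification, and duos drawn under HWE + random mating with the duo
## risk-multiplier model of dyad-models.R.

#' Simulation configuration
#'
#' Builds a validated configuration for the synthetic generators. Defaults
#' mirror the motivating study design: 280 case / 244 control placental
#' genomes and 222 case / 198 control mother-child duos.
#'
#' @param nCases,nControls case-control sample quotas.
#' @param nCaseDyads,nControlDyads duo quotas per arm.
#' @param nSnps number of variants.
#' @param mafRange interval within (0, 0.5] from which per-SNP minor allele
#'   frequencies are drawn uniformly.
#' @param ldRho adjacent-SNP haplotype allele correlation in [0, 1).
#' @param causalEffects data.frame with columns \code{snp} (index) and
#'   \code{or} (per-allele odds ratio), or NULL for no genetic effects.
#' @param baselineRisk disease probability at zero dosage on all causal SNPs.
#' @param dyadParams duo risk model parameters (\code{\link{dyadParams}});
#'   its \code{q} is the duo risk-allele frequency.
#' @param stratification NULL, or list(divergence=, mixing=) describing a
#'   two-subpopulation mixture with per-SNP allele-frequency divergence.
#' @param missingRate probability an entry is set missing.
#' @param hweViolation NULL, or list(snp=, f=) adding inbreeding-style excess
#'   homozygosity (coefficient f) at one SNP.
#' @param seed integer; the single seed all sub-streams derive from.
#' @return A list of class \code{"SimulationConfig"}.
#' @export
simulationConfig <- function(nCases = 280, nControls = 244,
                             nCaseDyads = 222, nControlDyads = 198,
                             nSnps = 1000, mafRange = c(0.05, 0.5),
                             ldRho = 0, causalEffects = NULL,
                             baselineRisk = 0.01,
                             dyadParams = dyadGWAS::dyadParams(q = 0.3),
                             stratification = NULL, missingRate = 0,
                             hweViolation = NULL, seed = 1L) {
    stopifnot(nSnps >= 1, nCases >= 0, nControls >= 0,
              length(mafRange) == 2, mafRange[1] > 0, mafRange[2] <= 0.5,
              mafRange[1] <= mafRange[2],
              ldRho >= 0, ldRho < 1,
              baselineRisk >= 0, baselineRisk <= 1,
              missingRate >= 0, missingRate <= 1)
    if (!is.null(causalEffects)) {
        causalEffects <- as.data.frame(causalEffects)
        stopifnot(all(c("snp", "or") %in% colnames(causalEffects)),
                  all(causalEffects$or > 0),
                  all(causalEffects$snp >= 1),
                  all(causalEffects$snp <= nSnps))
    }
    if (!is.null(stratification))
        stopifnot(stratification$mixing > 0, stratification$mixing < 1,
                  stratification$divergence >= 0)
    cfg <- list(nCases = as.integer(nCases), nControls = as.integer(nControls),
                nCaseDyads = as.integer(nCaseDyads),
                nControlDyads = as.integer(nControlDyads),
                nSnps = as.integer(nSnps), mafRange = mafRange,
                ldRho = ldRho, causalEffects = causalEffects,
                baselineRisk = baselineRisk, dyadParams = dyadParams,
                stratification = stratification, missingRate = missingRate,
                hweViolation = hweViolation, seed = as.integer(seed))
    class(cfg) <- "SimulationConfig"
    cfg
}

#' Read a simulation configuration from a YAML file
#'
#' Keys match \code{\link{simulationConfig}} arguments; \code{dyadParams} is
#' given as a mapping of parameter names, \code{causalEffects} as a list of
#' \code{\{snp, or\}} mappings.
#' @param path YAML file path.
#' @return A \code{"SimulationConfig"}.
#' @export
readSimulationConfig <- function(path) {
    raw <- yaml::read_yaml(path)
    if (!is.null(raw$dyadParams))
        raw$dyadParams <- do.call(dyadParams, raw$dyadParams)
    if (!is.null(raw$causalEffects))
        raw$causalEffects <- do.call(rbind,
            lapply(raw$causalEffects, as.data.frame))
    if (!is.null(raw$mafRange)) raw$mafRange <- as.numeric(raw$mafRange)
    do.call(simulationConfig, raw)
}

## one haplotype matrix (n x m): first-order Markov chain across SNPs with
## per-SNP marginal frequency freq (n x m matrix or length-m vector) and
## adjacent-allele correlation rho
simulateHaplotypes <- function(n, freq, rho) {
    if (is.null(dim(freq)))
        freq <- matrix(freq, n, length(freq), byrow = TRUE)
    m <- ncol(freq)
    if (rho == 0)   # independent SNPs: skip the chain
        return(matrix(rbinom(n * m, 1, as.vector(freq)), n, m))
    h <- matrix(0L, n, m)
    h[, 1] <- rbinom(n, 1, freq[, 1])
    if (m > 1) for (j in 2:m) {
        fj <- freq[, j]; fp <- freq[, j - 1]
        cond <- fj + rho * sqrt(fj * (1 - fj) / (fp * (1 - fp))) *
            (h[, j - 1] - fp)
        h[, j] <- rbinom(n, 1, pmin(pmax(cond, 0), 1))
    }
    h
}

## variant metadata for simulated SNPs: one chromosome, 5 kb spacing
simulatedVariants <- function(nSnps, gene = NULL) {
    data.frame(id = sprintf("snp%04d", seq_len(nSnps)),
               chromosome = "1",
               position_bp = seq_len(nSnps) * 5000L,
               allele_minor = "A", allele_major = "G",
               gene = if (is.null(gene)) NA_character_ else gene,
               stringsAsFactors = FALSE)
}

#' Simulate a case-control genotype dataset
#'
#' Draws haplotype pairs from a stationary first-order Markov chain (HWE by
#' construction when stratification is off), assigns disease by the logistic
#' model \eqn{logit P = logit(baseline) + \sum \log(OR_j) dosage_j}, and
#' rejection-samples individuals until the case and control quotas are met.
#' Missingness is then injected completely at random. Fully reproducible from
#' the config seed.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return A \linkS4class{GenotypeDataset} with covariates \code{sex} (1/2)
#'   and, under stratification, \code{subpop} (0/1). The attribute
#'   \code{"popPrevalence"} records the observed disease fraction in the raw
#'   population draws.
#' @export
simulateCaseControl <- function(config) {
    stopifnot(inherits(config, "SimulationConfig"))
    set.seed(config$seed)
    m <- config$nSnps
    f <- runif(m, config$mafRange[1], config$mafRange[2])
    beta <- rep(0, m)
    if (!is.null(config$causalEffects))
        beta[config$causalEffects$snp] <- log(config$causalEffects$or)
    if (config$baselineRisk == 0 && config$nCases > 0)
        stop("unattainable case quota: baseline risk is 0")

    needCase <- config$nCases; needCtrl <- config$nControls
    caseRows <- list(); ctrlRows <- list()
    caseMeta <- list(); ctrlMeta <- list()
    popN <- 0; popAff <- 0
    maxAttempts <- 200L
    for (att in seq_len(maxAttempts)) {
        if (needCase <= 0 && needCtrl <= 0) break
        ## adapt the batch to the running prevalence estimate so rare-disease
        ## case quotas fill without excess draws
        prev <- if (popN > 0) max(popAff / popN, 1e-4) else
            max(config$baselineRisk, 1e-4)
        batch <- as.integer(min(2e5, max(1000, 2 * (needCase + needCtrl),
                                         ceiling(1.3 * needCase / prev))))
        if (!is.null(config$stratification)) {
            z <- rbinom(batch, 1, config$stratification$mixing)
            d <- config$stratification$divergence
            f1 <- pmin(pmax(f - d / 2, 0.01), 0.99)
            f2 <- pmin(pmax(f + d / 2, 0.01), 0.99)
            fr <- matrix(f1, batch, m, byrow = TRUE)
            fr[z == 1, ] <- matrix(f2, sum(z == 1), m, byrow = TRUE)
        } else {
            z <- rep(0L, batch)
            fr <- matrix(f, batch, m, byrow = TRUE)
        }
        g <- simulateHaplotypes(batch, fr, config$ldRho) +
             simulateHaplotypes(batch, fr, config$ldRho)
        if (!is.null(config$hweViolation)) {
            j <- config$hweViolation$snp
            fc <- config$hweViolation$f
            qj <- f[j]; pj <- 1 - qj
            probs <- c(pj^2 + fc * pj * qj, 2 * pj * qj * (1 - fc),
                       qj^2 + fc * pj * qj)
            g[, j] <- sample(0:2, batch, replace = TRUE, prob = probs)
        }
        eta <- qlogis(config$baselineRisk) + as.vector(g %*% beta)
        y <- rbinom(batch, 1, plogis(eta))
        popN <- popN + batch; popAff <- popAff + sum(y)
        sex <- sample(1:2, batch, replace = TRUE)
        takeCase <- head(which(y == 1), needCase)
        takeCtrl <- head(which(y == 0), needCtrl)
        if (length(takeCase)) {
            caseRows[[length(caseRows) + 1L]] <- g[takeCase, , drop = FALSE]
            caseMeta[[length(caseMeta) + 1L]] <-
                cbind(sex[takeCase], z[takeCase])
            needCase <- needCase - length(takeCase)
        }
        if (length(takeCtrl)) {
            ctrlRows[[length(ctrlRows) + 1L]] <- g[takeCtrl, , drop = FALSE]
            ctrlMeta[[length(ctrlMeta) + 1L]] <-
                cbind(sex[takeCtrl], z[takeCtrl])
            needCtrl <- needCtrl - length(takeCtrl)
        }
    }
    if (needCase > 0 || needCtrl > 0)
        stop("case/control quota not reached after bounded attempts; ",
             "check baselineRisk")
    dos <- t(do.call(rbind, c(caseRows, ctrlRows)))
    meta <- do.call(rbind, c(caseMeta, ctrlMeta))
    pheno <- rep(c(1L, 0L), c(config$nCases, config$nControls))
    cov <- data.frame(sex = meta[, 1])
    if (!is.null(config$stratification)) cov$subpop <- meta[, 2]
    ds <- GenotypeDataset(dos, simulatedVariants(m), pheno, cov)
    if (config$missingRate > 0)
        ds <- injectMissingness(ds, globalRate = config$missingRate,
                                seed = config$seed + 1L)
    attr(ds, "popPrevalence") <- popAff / popN
    attr(ds, "popDraws") <- popN
    ds
}

## duo risk multiplier mu(m, c, maternal-origin flag)
dyadMu <- function(m, ch, matOrigin, pa) {
    S <- c(1, pa[["S1"]], pa[["S2"]])[m + 1]
    R <- c(1, pa[["R1"]], pa[["R2"]])[ch + 1]
    mu <- S * R
    mu <- mu * ifelse(ch == 1 & matOrigin, pa[["Im"]], 1)
    mu <- mu * ifelse(m == 0 & ch == 1, pa[["gamma01"]], 1)
    mu * ifelse(m == 2 & ch == 1, pa[["gamma21"]], 1)
}

#' Simulate mother-child duos under the duo risk model
#'
#' Mothers are drawn under HWE at frequency \code{q}; the transmitted maternal
#' allele is uniform over her two alleles and the paternal allele is
#' Bernoulli(\code{q}) (random mating). The pregnancy is affected with
#' probability \code{baselineRisk} times the risk multiplier
#' \eqn{\mu(m, c, origin)}; case duos are sampled conditional on affected and
#' control duos conditional on unaffected.
#'
#' Each of \code{nSnps} variants is generated as an independent set of duos
#' sharing the same parameters (independent-replicate design, not a shared
#' cohort across variants).
#'
#' @param config a \code{\link{simulationConfig}}; uses \code{nCaseDyads},
#'   \code{nControlDyads}, \code{nSnps}, \code{baselineRisk},
#'   \code{dyadParams} and \code{seed}.
#' @param keepTruth set FALSE to skip building the per-duo truth record
#'   (cheaper for large calibration runs).
#' @return List with \code{dyads} (a \linkS4class{DyadDataset}) and
#'   \code{truth}: a data.frame of every sampled duo (variant, family id,
#'   arm, mother and child dosages, parental-origin flag), or NULL when
#'   \code{keepTruth} is FALSE.
#' @export
simulateDyads <- function(config, keepTruth = TRUE) {
    stopifnot(inherits(config, "SimulationConfig"))
    pa <- config$dyadParams
    q <- pa[["q"]]
    grid <- expand.grid(m = 0:2, ch = 0:2, og = c(TRUE, FALSE))
    maxMu <- max(dyadMu(grid$m, grid$ch, grid$og, pa))
    if (config$baselineRisk * maxMu > 1)
        stop("invalid risk model: baselineRisk x max multiplier exceeds 1")
    set.seed(config$seed)
    nv <- config$nSnps
    caseM <- matrix(0L, nv, 7); ctrlM <- matrix(0L, nv, 7)
    truth <- vector("list", nv)
    cellIndex <- function(m, ch) match(paste0(m, "/", ch), DYAD_CELLS)
    for (v in seq_len(nv)) {
        needCase <- config$nCaseDyads; needCtrl <- config$nControlDyads
        recs <- list()
        for (att in 1:200) {
            if (needCase <= 0 && needCtrl <= 0) break
            b <- as.integer(min(2e6, max(500, 4 * (needCase + needCtrl),
                                         ceiling(1.2 * needCase /
                                                 config$baselineRisk))))
            m <- rbinom(b, 2, q)
            tA <- integer(b)
            het <- m == 1
            tA[m == 2] <- 1L
            tA[het] <- rbinom(sum(het), 1, 0.5)
            patA <- rbinom(b, 1, q)
            ch <- tA + patA
            matOrigin <- tA == 1L
            risk <- config$baselineRisk * dyadMu(m, ch, matOrigin, pa)
            aff <- rbinom(b, 1, risk)
            takeCase <- head(which(aff == 1), needCase)
            takeCtrl <- head(which(aff == 0), needCtrl)
            take <- c(takeCase, takeCtrl)
            if (length(take))
                recs[[length(recs) + 1L]] <- data.frame(
                    variant = v,
                    arm = rep(c("case", "control"),
                              c(length(takeCase), length(takeCtrl))),
                    mother = m[take], child = ch[take],
                    maternalOrigin = matOrigin[take])
            needCase <- needCase - length(takeCase)
            needCtrl <- needCtrl - length(takeCtrl)
        }
        if (needCase > 0 || needCtrl > 0)
            stop("dyad quota not reached after bounded attempts")
        tr <- do.call(rbind, recs)
        k <- cellIndex(tr$mother, tr$child)
        isCase <- tr$arm == "case"
        caseM[v, ] <- tabulate(k[isCase], 7)
        ctrlM[v, ] <- tabulate(k[!isCase], 7)
        if (keepTruth) {
            tr$family <- sprintf("v%d_f%06d", v, seq_len(nrow(tr)))
            truth[[v]] <- tr
        }
    }
    vars <- simulatedVariants(nv)
    dy <- DyadDataset(vars, caseM, ctrlM,
                      config$nCaseDyads, config$nControlDyads)
    list(dyads = dy,
         truth = if (keepTruth) do.call(rbind, truth) else NULL)
}

#' Inject missingness into a GenotypeDataset
#'
#' Entries are set missing independently; an entry is missing if flagged by
#' its sample's rate, its SNP's rate, or the global rate.
#'
#' @param dataset a \linkS4class{GenotypeDataset}.
#' @param perSampleRates named numeric vector (by sample id) of rates.
#' @param perSnpRates named numeric vector (by variant id) of rates.
#' @param globalRate rate applied to every entry.
#' @param seed integer seed.
#' @return The dataset with additional missing entries.
#' @export
injectMissingness <- function(dataset, perSampleRates = NULL,
                              perSnpRates = NULL, globalRate = 0,
                              seed = 1L) {
    stopifnot(globalRate >= 0, globalRate <= 1)
    d <- dosage(dataset)
    set.seed(seed)
    rs <- rep(0, ncol(d)); rv <- rep(0, nrow(d))
    if (!is.null(perSampleRates))
        rs[match(names(perSampleRates), colnames(d))] <- perSampleRates
    if (!is.null(perSnpRates))
        rv[match(names(perSnpRates), rownames(d))] <- perSnpRates
    pmiss <- 1 - outer(1 - rv, 1 - rs) * (1 - globalRate)
    if (any(pmiss < 0 | pmiss > 1)) stop("rates must lie in [0, 1]")
    hit <- matrix(runif(length(d)) < pmiss, nrow(d), ncol(d))
    d[hit] <- NA
    SummarizedExperiment::assay(dataset, "dosage") <- d
    dataset
}
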