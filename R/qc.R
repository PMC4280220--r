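## Genotype quality control: call rate, minor allele frequency, and the
## Hardy-Weinberg exact test among controls.

#' QC thresholds
#'
#' @param maxSampleMissing drop samples missing more than this fraction of
#'   SNPs (default 0.10).
#' @param maxSnpMissing drop SNPs missing in more than this fraction of
#'   samples (default 0.10).
#' @param minMaf drop SNPs with minor allele frequency below this (default
#'   0.01).
#' @param hweAlpha drop SNPs whose HWE exact p among controls falls below
#'   this (default 1e-4; the conventional GWAS choice).
#' @return List of class \code{"QCThresholds"}.
#' @export
qcThresholds <- function(maxSampleMissing = 0.10, maxSnpMissing = 0.10,
                         minMaf = 0.01, hweAlpha = 1e-4) {
    th <- list(maxSampleMissing = maxSampleMissing,
               maxSnpMissing = maxSnpMissing,
               minMaf = minMaf, hweAlpha = hweAlpha)
    if (any(unlist(th) <= 0) || any(unlist(th) >= 1))
        stop("QC thresholds must lie strictly in (0, 1)")
    class(th) <- "QCThresholds"
    th
}

#' Minor allele frequency of a dosage vector
#'
#' @param dosages numeric vector of minor-allele counts (0/1/2/NA).
#' @return List with \code{maf} (allele count over 2 x non-missing samples,
#'   re-oriented to be at most 0.5) and \code{flipped} (TRUE if the stored
#'   orientation had frequency above 0.5).
#' @export
computeMAF <- function(dosages) {
    ok <- !is.na(dosages)
    if (!any(ok)) stop("all genotypes missing: MAF undefined")
    f <- sum(dosages[ok]) / (2 * sum(ok))
    if (f > 0.5) list(maf = 1 - f, flipped = TRUE)
    else list(maf = f, flipped = FALSE)
}

#' Hardy-Weinberg exact test
#'
#' Two-sided exact test from genotype counts, enumerating every heterozygote
#' count consistent with the observed allele counts and summing the
#' probabilities of configurations no more probable than the observed one
#' (Wigginton-style convention).
#'
#' @param nHomMajor,nHet,nHomMinor genotype counts.
#' @return Exact p-value.
#' @export
hweExactTest <- function(nHomMajor, nHet, nHomMinor) {
    stopifnot(nHomMajor >= 0, nHet >= 0, nHomMinor >= 0)
    n <- nHomMajor + nHet + nHomMinor
    if (n < 1) stop("need at least one genotype")
    nMinor <- 2 * nHomMinor + nHet
    nMajor <- 2 * nHomMajor + nHet
    rare <- min(nMinor, nMajor)
    if (rare == 0) return(1)
    hets <- seq(rare %% 2, rare, by = 2)
    ## unnormalized probabilities via the standard recurrence
    ## P(het+2)/P(het) = 4 * homRare * homCommon / ((het+2) * (het+1))
    lp <- numeric(length(hets))
    for (i in seq_along(hets)[-1]) {
        h <- hets[i - 1]
        hr <- (rare - h) / 2
        hc <- (n - h - hr)
        lp[i] <- lp[i - 1] + log(4 * hr * hc) - log((h + 2) * (h + 1))
    }
    pr <- exp(lp - max(lp))
    pr <- pr / sum(pr)
    obs <- pr[match(nHet, hets)]
    if (is.na(obs)) stop("heterozygote count inconsistent with allele counts")
    min(1, sum(pr[pr <= obs * (1 + 1e-10)]))
}

#' Apply quality-control filters
#'
#' Filters in narrative order: (1) drop samples missing more than
#' \code{maxSampleMissing} of SNPs; (2) drop SNPs missing in more than
#' \code{maxSnpMissing} of remaining samples or with MAF (over all remaining
#' samples) below \code{minMaf} — one combined tally; (3) drop SNPs whose HWE
#' exact p among remaining controls falls below \code{hweAlpha}.
#'
#' @param dataset a \linkS4class{GenotypeDataset}.
#' @param thresholds a \code{\link{qcThresholds}} list.
#' @return List with \code{dataset} (filtered) and \code{report} (a
#'   \code{"QCReport"} with the per-step removal tallies).
#' @export
applyQC <- function(dataset, thresholds = qcThresholds()) {
    d <- dosage(dataset)
    nSnps0 <- nrow(d); nSamples0 <- ncol(d)

    sampleMiss <- colMeans(is.na(d))
    keepSample <- sampleMiss <= thresholds$maxSampleMissing
    ds1 <- dataset[, keepSample]
    d1 <- dosage(ds1)

    snpMiss <- rowMeans(is.na(d1))
    maf <- apply(d1, 1, function(x) {
        ok <- !is.na(x)
        if (!any(ok)) return(0)
        computeMAF(x)$maf
    })
    dropMafMiss <- snpMiss > thresholds$maxSnpMissing |
        maf < thresholds$minMaf
    ds2 <- ds1[!dropMafMiss, ]

    ctrl <- dosage(ds2)[, phenotype(ds2) == 0, drop = FALSE]
    hweP <- apply(ctrl, 1, function(x) {
        x <- x[!is.na(x)]
        if (!length(x)) return(1)
        hweExactTest(sum(x == 0), sum(x == 1), sum(x == 2))
    })
    dropHwe <- hweP < thresholds$hweAlpha
    ds3 <- ds2[!dropHwe, ]

    report <- qcReport(
        nSnpsInput = nSnps0, nSamplesInput = nSamples0,
        nSamplesRemovedMissing = sum(!keepSample),
        nSnpsRemovedMafOrMissing = sum(dropMafMiss),
        nSnpsRemovedHwe = sum(dropHwe))
    if (nrow(ds3) == 0 || ncol(ds3) == 0)
        warning("QC removed every SNP or sample")
    list(dataset = ds3, report = report)
}

#' Assemble a QC accounting report
#'
#' Retained counts follow by additivity from the input counts and per-step
#' removal tallies, as in a standard GWAS QC narrative.
#'
#' @param nSnpsInput,nSamplesInput input dimensions.
#' @param nSamplesRemovedMissing samples dropped for low call rate.
#' @param nSnpsRemovedMafOrMissing SNPs dropped for low MAF or call rate
#'   (combined tally).
#' @param nSnpsRemovedHwe SNPs dropped by the HWE exact test in controls.
#' @return List of class \code{"QCReport"} including \code{nSnpsRetained}
#'   and \code{nSamplesRetained}.
#' @export
qcReport <- function(nSnpsInput, nSamplesInput, nSamplesRemovedMissing,
                     nSnpsRemovedMafOrMissing, nSnpsRemovedHwe) {
    rep <- list(nSnpsInput = nSnpsInput, nSamplesInput = nSamplesInput,
                nSamplesRemovedMissing = nSamplesRemovedMissing,
                nSnpsRemovedMafOrMissing = nSnpsRemovedMafOrMissing,
                nSnpsRemovedHwe = nSnpsRemovedHwe,
                nSnpsRetained = nSnpsInput - nSnpsRemovedMafOrMissing -
                    nSnpsRemovedHwe,
                nSamplesRetained = nSamplesInput - nSamplesRemovedMissing)
    class(rep) <- "QCReport"
    rep
}

#' @export
print.QCReport <- function(x, ...) {
    cat("QC report\n")
    cat("  samples:", x$nSamplesInput, "->", x$nSamplesRetained,
        sprintf("(%d removed, call rate)\n", x$nSamplesRemovedMissing))
    cat("  SNPs:   ", x$nSnpsInput, "->", x$nSnpsRetained,
        sprintf("(%d removed MAF/call rate, %d removed HWE)\n",
                x$nSnpsRemovedMafOrMissing, x$nSnpsRemovedHwe))
    invisible(x)
}

#' Write a QC report as JSON
#' @param report a \code{"QCReport"}.
#' @param path output path.
#' @export
writeQCReport <- function(report, path) {
    jsonlite::write_json(unclass(report), path, auto_unbox = TRUE)
    invisible(NULL)
}
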