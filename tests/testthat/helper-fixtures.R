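## Shared fixtures and independent oracles used across the suite.

## Brute-force enumeration of case duo cell probabilities over
## (mother genotype) x (maternal transmitted allele) x (paternal allele),
## weighted by the risk multiplier. Independent of dyadCellProbabilities.
enumCaseCells <- function(pa) {
    q <- pa[["q"]]; p <- 1 - q
    cells <- setNames(numeric(7),
                      c("0/0", "0/1", "1/0", "1/1", "1/2", "2/1", "2/2"))
    for (m in 0:2) for (tA in 0:1) for (patA in 0:1) {
        pTrans <- if (m == 0) as.numeric(tA == 0) else
            if (m == 2) as.numeric(tA == 1) else 0.5
        if (pTrans == 0) next
        ch <- tA + patA
        S <- c(1, pa[["S1"]], pa[["S2"]])[m + 1]
        R <- c(1, pa[["R1"]], pa[["R2"]])[ch + 1]
        mu <- S * R *
            (if (ch == 1 && tA == 1) pa[["Im"]] else 1) *
            (if (m == 0 && ch == 1) pa[["gamma01"]] else 1) *
            (if (m == 2 && ch == 1) pa[["gamma21"]] else 1)
        w <- dbinom(m, 2, q) * pTrans * (if (patA == 1) q else p) * mu
        key <- paste0(m, "/", ch)
        cells[key] <- cells[key] + w
    }
    cells / sum(cells)
}

## Brute-force HWE exact p from the conditional haplotype-count distribution
## (log-factorial form, independent of the package's recurrence).
hweExactBruteForce <- function(nHomMajor, nHet, nHomMinor) {
    n <- nHomMajor + nHet + nHomMinor
    nMinor <- 2 * nHomMinor + nHet
    rare <- min(nMinor, 2 * n - nMinor)
    if (rare == 0) return(1)
    hets <- seq(rare %% 2, rare, by = 2)
    lp <- vapply(hets, function(h) {
        hr <- (rare - h) / 2; hc <- n - h - hr
        lfactorial(n) - lfactorial(hr) - lfactorial(hc) - lfactorial(h) +
            h * log(2)
    }, numeric(1))
    pr <- exp(lp - max(lp)); pr <- pr / sum(pr)
    obs <- pr[match(nHet, hets)]
    min(1, sum(pr[pr <= obs * (1 + 1e-10)]))
}

## A tiny hand-built genotype dataset (deterministic).
tinyDataset <- function(nVariants = 3, nSamples = 8) {
    set.seed(99)
    dos <- matrix(sample(0:2, nVariants * nSamples, replace = TRUE),
                  nVariants, nSamples)
    vars <- data.frame(id = paste0("rs", seq_len(nVariants)),
                       chromosome = "2",
                       position_bp = seq_len(nVariants) * 1000L,
                       allele_minor = "A", allele_major = "C",
                       stringsAsFactors = FALSE)
    GenotypeDataset(dos, vars, rep_len(c(1L, 0L), nSamples))
}

## Build GenotypeDataset + pedigree + status from a simulateDyads truth
## record (single- or multi-variant), for extractDyads round-trips.
truthToPedigree <- function(truth, variantIdx = 1) {
    tr <- truth[truth$variant == variantIdx, ]
    n <- nrow(tr)
    dos <- matrix(NA_real_, 1, 2 * n)
    dos[1, seq(1, 2 * n, 2)] <- tr$mother
    dos[1, seq(2, 2 * n, 2)] <- tr$child
    ids <- as.vector(rbind(paste0(tr$family, "_m"), paste0(tr$family, "_c")))
    colnames(dos) <- ids
    vars <- data.frame(id = "snp1", chromosome = "1", position_bp = 1L,
                       allele_minor = "A", allele_major = "G",
                       stringsAsFactors = FALSE)
    gd <- GenotypeDataset(dos, vars, rep(0L, 2 * n), sampleIds = ids)
    ped <- data.frame(
        family_id = rep(tr$family, each = 2),
        individual_id = ids,
        mother_id = as.vector(rbind(NA, paste0(tr$family, "_m"))),
        role = rep(c("mother", "child"), n),
        stringsAsFactors = FALSE)
    list(genotypes = gd, pedigree = ped,
         status = setNames(tr$arm, tr$family))
}
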