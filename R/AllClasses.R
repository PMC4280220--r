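#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importClassesFrom S4Vectors DataFrame
#' @importFrom SummarizedExperiment assay assayNames rowData colData
#' @importFrom S4Vectors DataFrame
#' @importFrom methods new validObject is setClass setGeneric setMethod setValidity show slot callNextMethod representation
#' @importFrom stats glm.fit binomial pchisq pnorm pt qchisq qnorm quantile
#'   median rbinom rnorm runif sd var complete.cases p.adjust optim plogis
#'   qlogis coef dbinom rmultinom chisq.test ks.test setNames cor predict
#' @importFrom utils read.table write.table head modifyList
NULL

## The seven Mendelian-compatible (mother, child) dosage cells, in fixed order.
## (0,2) and (2,0) are impossible: a child of a homozygous mother must carry
## at least (resp. at most) one copy of her allele.
DYAD_CELLS <- c("0/0", "0/1", "1/0", "1/1", "1/2", "2/1", "2/2")
DYAD_CELL_M <- c(0L, 0L, 1L, 1L, 1L, 2L, 2L)
DYAD_CELL_C <- c(0L, 1L, 0L, 1L, 2L, 1L, 2L)

#' GenotypeDataset: samples-by-variants minor-allele dosages
#'
#' A thin extension of \linkS4class{SummarizedExperiment} holding a single
#' \code{"dosage"} assay of minor-allele counts (variants in rows, samples in
#' columns; entries 0, 1, 2 or \code{NA}), variant metadata in \code{rowData}
#' (\code{chromosome}, \code{position_bp}, \code{allele_minor},
#' \code{allele_major}, optional \code{gene}) and per-sample phenotype and
#' covariates in \code{colData} (\code{phenotype} coded 1 = case, 0 = control).
#'
#' @aliases GenotypeDataset-class
#' @export
setClass("GenotypeDataset", contains = "SummarizedExperiment")

setValidity("GenotypeDataset", function(object) {
    msg <- character()
    if (!"dosage" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'dosage' is required")
    else {
        d <- SummarizedExperiment::assay(object, "dosage")
        bad <- d[!is.na(d)]
        if (length(bad) && !all(bad %in% c(0, 1, 2)))
            msg <- c(msg, "non-missing dosages must be 0, 1 or 2")
    }
    rd <- SummarizedExperiment::rowData(object)
    need <- c("chromosome", "position_bp", "allele_minor", "allele_major")
    miss <- setdiff(need, colnames(rd))
    if (length(miss))
        msg <- c(msg, paste("rowData lacks:", paste(miss, collapse = ", ")))
    if ("position_bp" %in% colnames(rd) && nrow(rd) &&
        any(rd$position_bp < 1))
        msg <- c(msg, "position_bp must be >= 1 (1-based)")
    if (all(c("allele_minor", "allele_major") %in% colnames(rd)) && nrow(rd) &&
        any(rd$allele_minor == rd$allele_major))
        msg <- c(msg, "allele_minor must differ from allele_major")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "variant ids must be unique")
    cd <- SummarizedExperiment::colData(object)
    if (!"phenotype" %in% colnames(cd))
        msg <- c(msg, "colData lacks 'phenotype'")
    else if (ncol(object) && (anyNA(cd$phenotype) ||
                              !all(cd$phenotype %in% c(0, 1))))
        msg <- c(msg, "phenotype must be 0 (control) or 1 (case) for every sample")
    if (length(msg)) msg else TRUE
})

#' Construct a GenotypeDataset
#'
#' @param dosage numeric matrix of minor-allele counts, variants x samples;
#'   entries 0/1/2/NA.
#' @param variants data.frame (or DataFrame) with columns \code{id},
#'   \code{chromosome}, \code{position_bp}, \code{allele_minor},
#'   \code{allele_major} and optionally \code{gene}; one row per dosage row.
#' @param phenotype integer/numeric vector, 1 = case, 0 = control, one per
#'   sample; or a character vector of \code{"case"}/\code{"control"}.
#' @param covariates optional data.frame of per-sample numeric covariates
#'   (e.g. infant sex, principal-component scores).
#' @param sampleIds optional character vector of sample ids (defaults to
#'   dosage column names, then S1..Sn).
#' @return A \linkS4class{GenotypeDataset}.
#' @export
GenotypeDataset <- function(dosage, variants, phenotype, covariates = NULL,
                            sampleIds = NULL) {
    dosage <- as.matrix(dosage)
    variants <- as.data.frame(variants)
    if (nrow(variants) != nrow(dosage))
        stop("variants rows must match dosage rows")
    if (is.character(phenotype))
        phenotype <- phenotypeFromStatus(phenotype)
    if (length(phenotype) != ncol(dosage))
        stop("phenotype length must match sample count")
    if (is.null(sampleIds))
        sampleIds <- colnames(dosage)
    if (is.null(sampleIds))
        sampleIds <- paste0("S", seq_len(ncol(dosage)))
    colnames(dosage) <- sampleIds
    rownames(dosage) <- variants$id
    cd <- S4Vectors::DataFrame(phenotype = as.integer(phenotype),
                               row.names = sampleIds)
    if (!is.null(covariates)) {
        covariates <- as.data.frame(covariates)
        for (nm in colnames(covariates)) cd[[nm]] <- covariates[[nm]]
    }
    rd <- S4Vectors::DataFrame(variants[setdiff(colnames(variants), "id")],
                               row.names = variants$id)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(dosage = dosage), rowData = rd, colData = cd)
    new("GenotypeDataset", se)
}

## map case/control strings to 1/0, strictly
phenotypeFromStatus <- function(status) {
    s <- tolower(trimws(as.character(status)))
    ok <- s %in% c("case", "control")
    if (!all(ok))
        stop("status outside vocabulary {case, control}: ",
             paste(unique(status[!ok]), collapse = ", "))
    as.integer(s == "case")
}

#' DyadDataset: mother-child genotype pair counts
#'
#' Per-variant counts of mother-child dosage pairs over the seven
#' Mendelian-compatible cells (0,0),(0,1),(1,0),(1,1),(1,2),(2,1),(2,2),
#' tabulated separately for case (affected-pregnancy) and control dyads.
#'
#' @slot variants DataFrame of variant metadata (row names are variant ids).
#' @slot caseCounts,controlCounts integer matrices, variants x 7 cells.
#' @slot nCaseDyads,nControlDyads total dyads genotyped per arm.
#' @slot exclusions integer matrix (variants x 2, columns case/control) of
#'   Mendelian-incompatible pairs dropped per variant.
#' @aliases DyadDataset-class
#' @export
setClass("DyadDataset",
    representation(variants = "DataFrame",
                   caseCounts = "matrix", controlCounts = "matrix",
                   nCaseDyads = "integer", nControlDyads = "integer",
                   exclusions = "matrix"))

setValidity("DyadDataset", function(object) {
    msg <- character()
    for (nm in c("caseCounts", "controlCounts")) {
        m <- slot(object, nm)
        if (ncol(m) != 7L)
            msg <- c(msg, paste(nm, "must have 7 columns"))
        if (length(m) && any(m < 0))
            msg <- c(msg, paste(nm, "must be non-negative"))
    }
    if (nrow(object@caseCounts) != nrow(object@variants))
        msg <- c(msg, "count rows must match variants")
    if (length(object@caseCounts) &&
        any(rowSums(object@caseCounts) > object@nCaseDyads))
        msg <- c(msg, "case cell sums exceed nCaseDyads")
    if (length(object@controlCounts) &&
        any(rowSums(object@controlCounts) > object@nControlDyads))
        msg <- c(msg, "control cell sums exceed nControlDyads")
    if (length(msg)) msg else TRUE
})

#' Construct a DyadDataset
#'
#' @param variants data.frame of variant metadata with an \code{id} column.
#' @param caseCounts,controlCounts matrices (variants x 7) of dyad counts in
#'   the cell order (0,0),(0,1),(1,0),(1,1),(1,2),(2,1),(2,2).
#' @param nCaseDyads,nControlDyads total dyads per arm.
#' @param exclusions optional variants x 2 matrix of Mendelian exclusions.
#' @return A \linkS4class{DyadDataset}.
#' @export
DyadDataset <- function(variants, caseCounts, controlCounts,
                        nCaseDyads, nControlDyads, exclusions = NULL) {
    variants <- as.data.frame(variants)
    caseCounts <- as.matrix(caseCounts)
    controlCounts <- as.matrix(controlCounts)
    storage.mode(caseCounts) <- "integer"
    storage.mode(controlCounts) <- "integer"
    colnames(caseCounts) <- colnames(controlCounts) <- DYAD_CELLS
    rownames(caseCounts) <- rownames(controlCounts) <- variants$id
    if (is.null(exclusions))
        exclusions <- matrix(0L, nrow(caseCounts), 2,
                             dimnames = list(variants$id, c("case", "control")))
    rd <- S4Vectors::DataFrame(variants[setdiff(colnames(variants), "id")],
                               row.names = variants$id)
    new("DyadDataset", variants = rd,
        caseCounts = caseCounts, controlCounts = controlCounts,
        nCaseDyads = as.integer(nCaseDyads),
        nControlDyads = as.integer(nControlDyads),
        exclusions = exclusions)
}

#' DyadModelFit: maximum-likelihood fit of a duo risk model
#'
#' @slot model one of "Null", "F", "M", "M+F", "I", "M+F+Im".
#' @slot params named numeric vector (q, R1, R2, S1, S2, Im, gamma01, gamma21);
#'   multipliers outside the model are fixed at 1.
#' @slot loglik maximized multinomial log-likelihood.
#' @slot k free-parameter count (q plus free multipliers).
#' @slot bic -2 loglik + k log(n) with n = total dyads.
#' @slot n total dyads used.
#' @slot converged logical.
#' @aliases DyadModelFit-class
#' @export
setClass("DyadModelFit",
    representation(model = "character", params = "numeric", loglik = "numeric",
                   k = "integer", bic = "numeric", n = "integer",
                   converged = "logical"))

setValidity("DyadModelFit", function(object) {
    kexp <- dyadModelFreeParams(object@model)
    if (object@k != length(kexp) + 1L)
        return("k inconsistent with model's free-parameter mask")
    if (is.finite(object@loglik) &&
        abs(object@bic - (-2 * object@loglik + object@k * log(object@n))) > 1e-6)
        return("bic != -2*loglik + k*log(n)")
    TRUE
})
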