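#' @name dyadGWAS-accessors
#' @title Accessors for dyadGWAS containers
#' @param object a \linkS4class{GenotypeDataset} or \linkS4class{DyadDataset}.
#' @param x same as \code{object} (indexing methods).
NULL

#' @describeIn dyadGWAS-accessors variants-by-samples minor-allele dosage matrix.
#' @export
setGeneric("dosage", function(object) standardGeneric("dosage"))

#' @export
setMethod("dosage", "GenotypeDataset", function(object)
    SummarizedExperiment::assay(object, "dosage"))

#' @describeIn dyadGWAS-accessors variant metadata as a data.frame with an
#'   \code{id} column.
#' @export
setGeneric("variantInfo", function(object) standardGeneric("variantInfo"))

#' @export
setMethod("variantInfo", "GenotypeDataset", function(object) {
    df <- as.data.frame(SummarizedExperiment::rowData(object))
    cbind(id = rownames(object), df)
})

#' @export
setMethod("variantInfo", "DyadDataset", function(object) {
    df <- as.data.frame(object@variants)
    cbind(id = rownames(object@variants), df)
})

#' @describeIn dyadGWAS-accessors case indicator (1 = case, 0 = control) per sample.
#' @export
setGeneric("phenotype", function(object) standardGeneric("phenotype"))

#' @export
setMethod("phenotype", "GenotypeDataset", function(object)
    setNames(SummarizedExperiment::colData(object)$phenotype, colnames(object)))

#' @describeIn dyadGWAS-accessors per-sample covariates (everything in colData
#'   except the phenotype).
#' @export
setGeneric("covariates", function(object) standardGeneric("covariates"))

#' @export
setMethod("covariates", "GenotypeDataset", function(object) {
    cd <- as.data.frame(SummarizedExperiment::colData(object))
    cd[setdiff(colnames(cd), "phenotype")]
})

#' @describeIn dyadGWAS-accessors case dyad cell counts (variants x 7).
#' @export
setGeneric("caseCounts", function(object) standardGeneric("caseCounts"))

#' @export
setMethod("caseCounts", "DyadDataset", function(object) object@caseCounts)

#' @describeIn dyadGWAS-accessors control dyad cell counts (variants x 7).
#' @export
setGeneric("controlCounts", function(object) standardGeneric("controlCounts"))

#' @export
setMethod("controlCounts", "DyadDataset", function(object) object@controlCounts)

#' @describeIn dyadGWAS-accessors Mendelian-incompatibility exclusion tallies.
#' @export
setGeneric("exclusions", function(object) standardGeneric("exclusions"))

#' @export
setMethod("exclusions", "DyadDataset", function(object) object@exclusions)

#' @export
setMethod("show", "GenotypeDataset", function(object) {
    ph <- phenotype(object)
    cat("GenotypeDataset:", nrow(object), "variants x", ncol(object),
        "samples\n")
    cat("  cases:", sum(ph == 1), " controls:", sum(ph == 0), "\n")
    d <- dosage(object)
    cat(sprintf("  missing dosages: %.2f%%\n", 100 * mean(is.na(d))))
    cv <- setdiff(colnames(SummarizedExperiment::colData(object)), "phenotype")
    if (length(cv)) cat("  covariates:", paste(cv, collapse = ", "), "\n")
})

#' @export
setMethod("show", "DyadDataset", function(object) {
    cat("DyadDataset:", nrow(object@caseCounts), "variants;",
        object@nCaseDyads, "case dyads,", object@nControlDyads,
        "control dyads\n")
    cat("  cells:", paste(DYAD_CELLS, collapse = " "), "\n")
    if (sum(object@exclusions) > 0)
        cat("  Mendelian exclusions:", sum(object@exclusions), "\n")
})

#' @export
setMethod("show", "DyadModelFit", function(object) {
    cat(sprintf("DyadModelFit [%s]  loglik = %.4f  k = %d  BIC = %.4f%s\n",
                object@model, object@loglik, object@k, object@bic,
                if (object@converged) "" else "  (NOT converged)"))
    free <- c("q", dyadModelFreeParams(object@model))
    print(round(object@params[free], 4))
})

#' Subset a GenotypeDataset
#'
#' Standard two-index subsetting (variants, samples) inherited from
#' SummarizedExperiment; the result is re-validated.
#' @rdname dyadGWAS-accessors
#' @param i,j,... variant and sample indices.
#' @param drop ignored.
#' @export
setMethod("[", "GenotypeDataset", function(x, i, j, ..., drop = FALSE) {
    out <- callNextMethod()
    validObject(out)
    out
})
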