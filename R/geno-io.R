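## PLINK-style PED/MAP text input/output and pedigree-to-duo extraction.
##
## PED dialect: whitespace-separated, six leading pedigree columns
## (FID IID PID MID SEX PHENO; PHENO 1 = control, 2 = case) then two allele
## columns per MAP variant. Alleles are A/C/G/T or 1/2; "0" is missing.
## MAP: chromosome, variant id, genetic distance (ignored), 1-based position.

PED_ALLELES <- c("A", "C", "G", "T", "1", "2")

#' Read genotypes from PED/MAP files
#'
#' Alleles are converted to minor-allele dosages; the minor allele at each
#' variant is the less frequent allele among control samples (ties broken
#' lexicographically), so reported control MAF is always at most 0.5. Allele
#' pairs containing "0" become missing.
#'
#' @param pedPath,mapPath file paths.
#' @return A \linkS4class{GenotypeDataset}.
#' @export
readPedMap <- function(pedPath, mapPath) {
    map <- read.table(mapPath, header = FALSE, stringsAsFactors = FALSE,
                      colClasses = c("character", "character", "numeric",
                                     "integer"))
    colnames(map) <- c("chromosome", "id", "cm", "position_bp")
    m <- nrow(map)
    lines <- readLines(pedPath)
    lines <- lines[nzchar(trimws(lines))]
    fields <- strsplit(trimws(lines), "[ \t]+")
    widths <- lengths(fields)
    bad <- which(widths != 6 + 2 * m)
    if (length(bad))
        stop("malformed PED row width at line ", bad[1], ": got ",
             widths[bad[1]], " fields, expected ", 6 + 2 * m)
    ped <- do.call(rbind, fields)
    ids <- ped[, 2]
    status <- ped[, 6]
    pheno <- ifelse(status == "2", 1L, ifelse(status == "1", 0L, NA_integer_))
    if (anyNA(pheno))
        stop("PED phenotype column must be 1 (control) or 2 (case)")
    al <- ped[, -(1:6), drop = FALSE]
    known <- al %in% c(PED_ALLELES, "0")
    if (!all(known)) {
        bad <- which(!known)[1]
        stop("allele symbol outside {A,C,G,T,1,2,0}: '",
             al[bad], "' (PED line ", (bad - 1) %% nrow(al) + 1, ")")
    }
    n <- nrow(al)
    dos <- matrix(NA_real_, m, n)
    minor <- character(m); major <- character(m)
    isCtrl <- pheno == 0L
    for (j in seq_len(m)) {
        a1 <- al[, 2 * j - 1]; a2 <- al[, 2 * j]
        missing <- a1 == "0" | a2 == "0"
        obs <- c(a1[!missing], a2[!missing])
        alleles <- sort(unique(obs))
        if (length(alleles) > 2)
            stop("variant ", map$id[j], " has more than two alleles")
        ## minor = less frequent among controls; ties fall back to overall
        ## frequency, then to lexicographic order
        ctrlObs <- c(a1[isCtrl & !missing], a2[isCtrl & !missing])
        counts <- table(factor(if (length(ctrlObs)) ctrlObs else obs,
                               levels = alleles))
        overall <- table(factor(obs, levels = alleles))
        ord <- order(counts, overall, names(counts))
        if (length(alleles) == 2) {
            minor[j] <- names(counts)[ord[1]]
            major[j] <- names(counts)[ord[2]]
        } else if (length(alleles) == 1) {
            major[j] <- alleles
            minor[j] <- setdiff(PED_ALLELES, alleles)[1]
        } else {
            major[j] <- "G"; minor[j] <- "A"   # fully missing column
        }
        dj <- (a1 == minor[j]) + (a2 == minor[j])
        dj[missing] <- NA
        dos[j, ] <- dj
    }
    variants <- data.frame(id = map$id, chromosome = map$chromosome,
                           position_bp = map$position_bp,
                           allele_minor = minor, allele_major = major,
                           stringsAsFactors = FALSE)
    GenotypeDataset(dos, variants, pheno, sampleIds = ids)
}

#' Write genotypes to PED/MAP files
#'
#' Emits files re-readable by \code{\link{readPedMap}} with identical
#' dosages, variant order and sample order (provided control MAF is at most
#' 0.5 at every variant, the reader's orientation convention). Missing
#' dosages are written as "0 0".
#'
#' @param dataset a \linkS4class{GenotypeDataset}.
#' @param pedPath,mapPath output paths.
#' @export
writePedMap <- function(dataset, pedPath, mapPath) {
    v <- variantInfo(dataset)
    map <- if (nrow(v))
        data.frame(v$chromosome, v$id, 0, v$position_bp) else
        data.frame()
    write.table(map, mapPath, quote = FALSE, row.names = FALSE,
                col.names = FALSE, sep = "\t")
    d <- dosage(dataset)
    ph <- phenotype(dataset)
    n <- ncol(d); m <- nrow(d)
    rows <- character(n)
    for (i in seq_len(n)) {
        di <- d[, i]
        a1 <- ifelse(is.na(di), "0", ifelse(di >= 1, v$allele_minor,
                                            v$allele_major))
        a2 <- ifelse(is.na(di), "0", ifelse(di == 2, v$allele_minor,
                                            v$allele_major))
        geno <- character(2 * m)
        if (m) {
            geno[seq(1, 2 * m, 2)] <- a1
            geno[seq(2, 2 * m, 2)] <- a2
        }
        rows[i] <- paste(c(colnames(d)[i], colnames(d)[i], "0", "0", "0",
                           ifelse(ph[i] == 1, "2", "1"), geno),
                         collapse = " ")
    }
    writeLines(rows, pedPath)
    invisible(NULL)
}

#' Read a sample table (phenotype + covariates)
#'
#' Delimited text (comma or tab/whitespace, autodetected) with a header
#' containing a sample id column (\code{sample} or \code{id}) and a
#' \code{status} column with values \code{case}/\code{control}. Numeric
#' covariates are parsed; other columns are preserved as-is.
#'
#' @param path file path.
#' @return data.frame with columns \code{sample}, \code{phenotype} (1/0) and
#'   any covariates.
#' @export
readSampleTable <- function(path) {
    header <- readLines(path, n = 1)
    sep <- if (grepl(",", header)) "," else ""
    tab <- read.table(path, header = TRUE, sep = sep,
                      stringsAsFactors = FALSE)
    idCol <- intersect(c("sample", "id"), colnames(tab))[1]
    if (is.na(idCol)) stop("sample table needs a 'sample' or 'id' column")
    if (!"status" %in% colnames(tab))
        stop("sample table needs a 'status' column")
    if (anyDuplicated(tab[[idCol]]))
        stop("duplicate sample ids in sample table")
    out <- data.frame(sample = as.character(tab[[idCol]]),
                      phenotype = phenotypeFromStatus(tab$status),
                      stringsAsFactors = FALSE)
    for (nm in setdiff(colnames(tab), c(idCol, "status")))
        out[[nm]] <- tab[[nm]]
    out
}

#' Read a gene-membership map
#'
#' Delimited text with header columns \code{snp} and \code{gene}, mapping
#' variants to candidate genes for grouped selection.
#' @param path file path.
#' @return data.frame with columns \code{snp}, \code{gene}.
#' @export
readGeneMap <- function(path) {
    header <- readLines(path, n = 1)
    sep <- if (grepl(",", header)) "," else ""
    tab <- read.table(path, header = TRUE, sep = sep,
                      stringsAsFactors = FALSE)
    if (!all(c("snp", "gene") %in% colnames(tab)))
        stop("gene map needs 'snp' and 'gene' columns")
    tab[c("snp", "gene")]
}

#' Extract mother-child duo counts from genotypes and pedigree records
#'
#' Each family contributes at most one genotyped mother-child pair. Per
#' variant, the (mother, child) dosage pair is tallied into the seven
#' Mendelian-compatible cells by the family's case status; pairs with a
#' missing genotype at a variant are skipped for that variant, and
#' Mendelian-incompatible pairs ((0,2) or (2,0)) are excluded and counted in
#' the exclusion report.
#'
#' @param genotypes a \linkS4class{GenotypeDataset} whose sample ids are
#'   pedigree individual ids.
#' @param pedigree data.frame with columns \code{family_id},
#'   \code{individual_id}, \code{mother_id}, \code{role}
#'   (\code{mother}/\code{child}).
#' @param dyadStatus named character vector (by family id):
#'   \code{"case"}/\code{"control"} status of the pregnancy.
#' @return A \linkS4class{DyadDataset}.
#' @export
extractDyads <- function(genotypes, pedigree, dyadStatus) {
    pedigree <- as.data.frame(pedigree)
    d <- dosage(genotypes)
    fams <- unique(pedigree$family_id)
    pairs <- list()
    for (f in fams) {
        recs <- pedigree[pedigree$family_id == f, ]
        mothers <- recs[recs$role == "mother", ]
        if (nrow(mothers) > 1)
            stop("family ", f, " has two mothers")
        children <- recs[recs$role == "child", ]
        if (!nrow(mothers) || !nrow(children)) next
        child <- children[1, ]
        if (is.na(child$mother_id) ||
            !child$mother_id %in% recs$individual_id) next
        if (!mothers$individual_id %in% colnames(d) ||
            !child$individual_id %in% colnames(d)) next
        st <- dyadStatus[[f]]
        if (is.null(st) || is.na(st)) next
        pairs[[length(pairs) + 1L]] <-
            c(mothers$individual_id, child$individual_id, st)
    }
    nv <- nrow(d)
    caseM <- matrix(0L, nv, 7); ctrlM <- matrix(0L, nv, 7)
    excl <- matrix(0L, nv, 2, dimnames = list(rownames(d),
                                              c("case", "control")))
    nCase <- 0L; nCtrl <- 0L
    for (p in pairs) {
        isCase <- p[3] == "case"
        if (isCase) nCase <- nCase + 1L else nCtrl <- nCtrl + 1L
        mg <- d[, p[1]]; cg <- d[, p[2]]
        ok <- !is.na(mg) & !is.na(cg)
        incompat <- ok & ((mg == 0 & cg == 2) | (mg == 2 & cg == 0))
        excl[incompat, if (isCase) 1 else 2] <-
            excl[incompat, if (isCase) 1 else 2] + 1L
        usable <- which(ok & !incompat)
        k <- match(paste0(mg[usable], "/", cg[usable]), DYAD_CELLS)
        tgt <- if (isCase) "caseM" else "ctrlM"
        inc <- tabulate2(usable, k, nv)
        if (isCase) caseM <- caseM + inc else ctrlM <- ctrlM + inc
    }
    DyadDataset(variantInfo(genotypes), caseM, ctrlM, nCase, nCtrl, excl)
}

## scatter-add one pair's cell hits into a variants x 7 matrix
tabulate2 <- function(rows, cells, nv) {
    m <- matrix(0L, nv, 7)
    m[cbind(rows, cells)] <- 1L
    m
}

#' Export dyad cell counts as TSV
#'
#' One row per variant: id, the 7 case cells, the 7 control cells.
#' @param dyads a \linkS4class{DyadDataset}.
#' @param path output path.
#' @export
writeDyadCounts <- function(dyads, path) {
    cc <- caseCounts(dyads); kc <- controlCounts(dyads)
    tab <- data.frame(id = rownames(cc), cc, kc, check.names = FALSE)
    colnames(tab) <- c("id", paste0("case_", DYAD_CELLS),
                       paste0("control_", DYAD_CELLS))
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(NULL)
}
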