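## Config-driven orchestration of the analysis stages. Stages communicate
## only through plain-text artifacts in the output directory, so any stage
## can be re-run in isolation and runs are diffable.

#' Read and validate a pipeline configuration
#'
#' YAML with optional sections: \code{paths} (ped, map, sampleTable,
#' geneMap, dyadCounts), \code{qc} (thresholds passed to
#' \code{\link{qcThresholds}}), \code{penalized}
#' (\code{\link{penalizedConfig}} arguments), \code{wgrs} (folds, repeats),
#' \code{simulation} (\code{\link{simulationConfig}} arguments),
#' \code{kPCs}, \code{seed}, \code{outDir}.
#'
#' @param path YAML config path, or a pre-built list.
#' @return Validated list of class \code{"PipelineConfig"}.
#' @export
readPipelineConfig <- function(path) {
    cfg <- if (is.character(path)) yaml::read_yaml(path) else path
    cfg$seed <- as.integer(cfg$seed %||% 1L)
    cfg$kPCs <- cfg$kPCs %||% 4
    cfg$outDir <- cfg$outDir %||% "."
    cfg$qc <- do.call(qcThresholds, cfg$qc %||% list())
    wg <- cfg$wgrs %||% list()
    cfg$wgrs <- list(folds = wg$folds %||% 10, repeats = wg$repeats %||% 50)
    if (!is.null(cfg$simulation))
        cfg$simulation <- do.call(simulationConfig,
                                  c(cfg$simulation, list(seed = cfg$seed)))
    pen <- cfg$penalized %||% list()
    cfg$penalizedArgs <- pen
    class(cfg) <- "PipelineConfig"
    cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

logLine <- function(con, ...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
    writeLines(msg, con)
}

#' Run pipeline stages
#'
#' Subcommands: \code{simulate} writes synthetic PED/MAP, sample table and
#' dyad-count artifacts; \code{qc} filters genotypes and writes the QC
#' report; \code{scan} runs the PC-adjusted association scan; \code{select}
#' runs lasso selection, LD expansion and the joint refit; \code{wgrs} runs
#' the repeated cross-validated risk-score analysis on the selected SNPs;
#' \code{dyad} runs BIC model selection and the imprinting scan on dyad
#' counts; \code{all} chains qc, scan, select, wgrs and dyad. A run log
#' (\code{run_log.txt}) records the package version, seeds and thresholds.
#'
#' @param subcommand one of simulate, qc, scan, select, wgrs, dyad, all.
#' @param config a \code{"PipelineConfig"} (or path to one).
#' @return Invisibly, the paths of the artifacts written.
#' @export
runPipeline <- function(subcommand = c("simulate", "qc", "scan", "select",
                                       "wgrs", "dyad", "all"),
                        config) {
    subcommand <- match.arg(subcommand)
    if (!inherits(config, "PipelineConfig"))
        config <- readPipelineConfig(config)
    out <- config$outDir
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    log <- file(file.path(out, "run_log.txt"), "a")
    on.exit(close(log))
    logLine(log, "dyadGWAS ", as.character(utils::packageVersion("dyadGWAS")),
            " | stage=", subcommand, " | seed=", config$seed)
    logLine(log, "qc thresholds: ",
            paste(names(config$qc), unlist(config$qc), sep = "=",
                  collapse = " "))
    artifacts <- character()
    pedQC <- file.path(out, "qc.ped"); mapQC <- file.path(out, "qc.map")

    if (subcommand == "simulate") {
        stopifnot(!is.null(config$simulation))
        ds <- simulateCaseControl(config$simulation)
        writePedMap(ds, file.path(out, "sim.ped"), file.path(out, "sim.map"))
        st <- data.frame(sample = colnames(dosage(ds)),
                         status = ifelse(phenotype(ds) == 1, "case",
                                         "control"),
                         covariates(ds))
        write.table(st, file.path(out, "sim_samples.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        dy <- simulateDyads(config$simulation)
        writeDyadCounts(dy$dyads, file.path(out, "sim_dyads.tsv"))
        write.table(dy$truth, file.path(out, "sim_dyad_truth.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        logLine(log, "simulate: ", ncol(dosage(ds)), " samples x ",
                nrow(dosage(ds)), " SNPs; dyad seed=",
                config$simulation$seed)
        return(invisible(file.path(out, c("sim.ped", "sim.map",
                                          "sim_samples.tsv",
                                          "sim_dyads.tsv"))))
    }

    stages <- if (subcommand == "all")
        c("qc", "scan", "select", "wgrs", "dyad") else subcommand
    for (stage in stages) {
        res <- tryCatch(
            runStage(stage, config, out, pedQC, mapQC, log),
            error = function(e)
                stop("stage '", stage, "' failed: ", conditionMessage(e),
                     call. = FALSE))
        artifacts <- c(artifacts, res)
    }
    invisible(artifacts)
}

runStage <- function(stage, config, out, pedQC, mapQC, log) {
    if (stage == "qc") {
        ds <- readPedMap(config$paths$ped, config$paths$map)
        if (!is.null(config$paths$sampleTable)) {
            st <- readSampleTable(config$paths$sampleTable)
            idx <- match(colnames(dosage(ds)), st$sample)
            for (nm in setdiff(colnames(st), c("sample", "phenotype")))
                SummarizedExperiment::colData(ds)[[nm]] <- st[[nm]][idx]
        }
        qc <- applyQC(ds, config$qc)
        writePedMap(qc$dataset, pedQC, mapQC)
        st <- data.frame(sample = colnames(dosage(qc$dataset)),
                         status = ifelse(phenotype(qc$dataset) == 1,
                                         "case", "control"),
                         covariates(qc$dataset))
        write.table(st, file.path(out, "qc_samples.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        writeQCReport(qc$report, file.path(out, "qc_report.json"))
        logLine(log, "qc: retained ", qc$report$nSnpsRetained, "/",
                qc$report$nSnpsInput, " SNPs, ",
                qc$report$nSamplesRetained, "/", qc$report$nSamplesInput,
                " samples")
        return(file.path(out, c("qc.ped", "qc.map", "qc_report.json")))
    }
    ## downstream stages read the QC'd artifacts
    ds <- readPedMap(pedQC, mapQC)
    st <- readSampleTable(file.path(out, "qc_samples.tsv"))
    idx <- match(colnames(dosage(ds)), st$sample)
    for (nm in setdiff(colnames(st), c("sample", "phenotype")))
        SummarizedExperiment::colData(ds)[[nm]] <- st[[nm]][idx]
    covNames <- intersect("sex", colnames(covariates(ds)))
    pcs <- if (config$kPCs > 0) computePCs(ds, k = config$kPCs) else NULL

    if (stage == "scan") {
        scan <- associationScan(ds, covNames, pcs = pcs,
                                kPCs = config$kPCs)
        writeAssocRecords(scan$records, file.path(out, "scan_records.tsv"))
        write.table(scan$summary$qq, file.path(out, "scan_qq.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        writeLines(sprintf("lambda_gc\t%.6f", scan$summary$lambdaGC),
                   file.path(out, "scan_lambda.tsv"))
        logLine(log, "scan: ", scan$summary$nTests, " tests, lambda=",
                sprintf("%.3f", scan$summary$lambdaGC))
        return(file.path(out, c("scan_records.tsv", "scan_qq.tsv",
                                "scan_lambda.tsv")))
    }
    if (stage == "select") {
        penCfg <- do.call(penalizedConfig,
                          modifyList(list(method = "lasso",
                                          seed = config$seed),
                                     config$penalizedArgs))
        sel <- lassoSelectCV(ds, covNames, pcs, penCfg)
        if (nrow(sel$selected)) {
            sel <- ldExpand(sel, ds)
            refit <- refitJoint(ds, sel$selected$id, covNames, pcs)
        } else {
            refit <- data.frame()
        }
        write.table(sel$selected, file.path(out, "select_snps.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        write.table(sel$ldExpanded, file.path(out, "select_ld_proxies.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        write.table(refit, file.path(out, "select_joint_fit.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        logLine(log, "select: ", nrow(sel$selected), " SNPs, penalty=",
                sprintf("%.5f", sel$chosenPenalty))
        return(file.path(out, c("select_snps.tsv", "select_ld_proxies.tsv",
                                "select_joint_fit.tsv")))
    }
    if (stage == "wgrs") {
        selTab <- read.table(file.path(out, "select_snps.tsv"),
                             header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
        if (!nrow(selTab)) {
            logLine(log, "wgrs: skipped, empty selection")
            return(character())
        }
        wg <- crossvalWGRS(ds, selTab$id, covNames, pcs,
                           folds = config$wgrs$folds,
                           repeats = config$wgrs$repeats,
                           seed = config$seed)
        writeWgrsSummary(wg, file.path(out, "wgrs_summary.tsv"))
        write.table(wg$replicates, file.path(out, "wgrs_replicates.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        logLine(log, "wgrs: AUC=", sprintf("%.3f", wg$summary$auc),
                " over ", config$wgrs$repeats, " replicates, seed=",
                config$seed)
        return(file.path(out, c("wgrs_summary.tsv", "wgrs_replicates.tsv")))
    }
    if (stage == "dyad") {
        dyPath <- config$paths$dyadCounts %||% file.path(out,
                                                         "sim_dyads.tsv")
        if (!file.exists(dyPath)) {
            logLine(log, "dyad: skipped, no dyad counts at ", dyPath)
            return(character())
        }
        dy <- readDyadCounts(dyPath)
        selRows <- lapply(rownames(caseCounts(dy)), function(v) {
            s <- selectBestModel(caseCounts(dy)[v, ],
                                 controlCounts(dy)[v, ], nStarts = 2L)
            data.frame(id = v, selected = s$selected,
                       bic = s$fits[[s$selected]]@bic)
        })
        selTab <- do.call(rbind, selRows)
        write.table(selTab, file.path(out, "dyad_model_selection.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        imp <- imprintingScan(dy)
        write.table(imp, file.path(out, "dyad_imprinting.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        logLine(log, "dyad: ", nrow(selTab), " variants, ",
                sum(imp$significant, na.rm = TRUE),
                " imprinting hits at 0.05")
        return(file.path(out, c("dyad_model_selection.tsv",
                                "dyad_imprinting.tsv")))
    }
    stop("unknown stage: ", stage)
}

#' Read dyad counts written by \code{\link{writeDyadCounts}}
#' @param path TSV path.
#' @return A \linkS4class{DyadDataset}.
#' @export
readDyadCounts <- function(path) {
    tab <- read.table(path, header = TRUE, sep = "\t",
                      check.names = FALSE, stringsAsFactors = FALSE)
    cc <- as.matrix(tab[paste0("case_", DYAD_CELLS)])
    kc <- as.matrix(tab[paste0("control_", DYAD_CELLS)])
    vars <- data.frame(id = tab$id, chromosome = "1",
                       position_bp = seq_len(nrow(tab)),
                       allele_minor = "A", allele_major = "G",
                       stringsAsFactors = FALSE)
    DyadDataset(vars, cc, kc, max(rowSums(cc)), max(rowSums(kc)))
}
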