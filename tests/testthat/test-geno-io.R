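test_that("PED alleles convert to control-oriented minor-allele dosages", {
    td <- withr::local_tempdir()
    ## 2 samples, 1 SNP: "A A" and "A G"; G is rarer -> dosages (0, 1)
    writeLines(c("f1 s1 0 0 0 2 A A",
                 "f2 s2 0 0 0 1 A G"), file.path(td, "t.ped"))
    writeLines("1\trs1\t0\t100", file.path(td, "t.map"))
    ds <- readPedMap(file.path(td, "t.ped"), file.path(td, "t.map"))
    expect_equal(unname(dosage(ds)[1, ]), c(0, 1))
    expect_equal(variantInfo(ds)$allele_minor, "G")
    expect_equal(unname(phenotype(ds)), c(1L, 0L))
})

test_that("malformed PED rows and foreign allele symbols raise parse errors", {
    td <- withr::local_tempdir()
    writeLines("1\trs1\t0\t100", file.path(td, "t.map"))
    writeLines(c("f1 s1 0 0 0 2 A A",
                 "f2 s2 0 0 0 1 A"), file.path(td, "t.ped"))
    expect_error(readPedMap(file.path(td, "t.ped"), file.path(td, "t.map")),
                 "line 2")
    writeLines("f1 s1 0 0 0 2 A X", file.path(td, "t.ped"))
    expect_error(readPedMap(file.path(td, "t.ped"), file.path(td, "t.map")),
                 "allele symbol")
})

test_that("injected '0 0' pairs come back as exactly the injected missing set", {
    cfg <- simulationConfig(nCases = 50, nControls = 50, nSnps = 20,
                            seed = 8)
    ds <- simulateCaseControl(cfg)
    d <- dosage(ds)
    set.seed(4)
    hit <- matrix(runif(length(d)) < 0.05, nrow(d), ncol(d))
    d[hit] <- NA
    SummarizedExperiment::assay(ds, "dosage") <- d
    td <- withr::local_tempdir()
    writePedMap(ds, file.path(td, "m.ped"), file.path(td, "m.map"))
    ds2 <- readPedMap(file.path(td, "m.ped"), file.path(td, "m.map"))
    expect_identical(is.na(dosage(ds2)), is.na(d))
    expect_equal(mean(is.na(dosage(ds2))), mean(hit))
})

test_that("write -> read round-trips dosage, order and missingness", {
    cfg <- simulationConfig(nCases = 25, nControls = 25, nSnps = 12,
                            missingRate = 0.04, seed = 3)
    ds0 <- simulateCaseControl(cfg)
    td <- withr::local_tempdir()
    p1 <- file.path(td, "a.ped"); m1 <- file.path(td, "a.map")
    p2 <- file.path(td, "b.ped"); m2 <- file.path(td, "b.map")
    writePedMap(ds0, p1, m1)
    ds1 <- readPedMap(p1, m1)     # control-minor orientation by construction
    writePedMap(ds1, p2, m2)
    ds2 <- readPedMap(p2, m2)
    expect_identical(is.na(dosage(ds1)), is.na(dosage(ds2)))
    expect_true(all(dosage(ds1) == dosage(ds2), na.rm = TRUE))
    expect_identical(phenotype(ds1), phenotype(ds2))
    expect_identical(variantInfo(ds1), variantInfo(ds2))
    ## control MAF is at most 0.5 at every variant after reading
    ctrl <- dosage(ds2)[, phenotype(ds2) == 0, drop = FALSE]
    maf <- apply(ctrl, 1, function(x) sum(x, na.rm = TRUE) /
                     (2 * sum(!is.na(x))))
    expect_true(all(maf <= 0.5))
})

test_that("empty datasets and missing genotypes follow the PED format rules", {
    td <- withr::local_tempdir()
    dos <- matrix(numeric(), 0, 3)
    vars <- data.frame(id = character(), chromosome = character(),
                       position_bp = integer(), allele_minor = character(),
                       allele_major = character())
    ds <- GenotypeDataset(dos, vars, c(1L, 0L, 1L),
                          sampleIds = c("a", "b", "c"))
    writePedMap(ds, file.path(td, "e.ped"), file.path(td, "e.map"))
    expect_length(readLines(file.path(td, "e.map")), 0)
    pedRows <- strsplit(readLines(file.path(td, "e.ped")), " ")
    expect_true(all(lengths(pedRows) == 6))
    ## a missing genotype is emitted as "0 0"
    ds3 <- tinyDataset()
    d <- dosage(ds3); d[1, 1] <- NA
    SummarizedExperiment::assay(ds3, "dosage") <- d
    writePedMap(ds3, file.path(td, "x.ped"), file.path(td, "x.map"))
    first <- strsplit(readLines(file.path(td, "x.ped"))[1], " ")[[1]]
    expect_equal(first[7:8], c("0", "0"))
})

test_that("sample tables parse statuses and reject bad input", {
    td <- withr::local_tempdir()
    f <- file.path(td, "s.csv")
    writeLines(c("sample,status,sex", "s1,case,1", "s2,control,2",
                 "s3,case,1"), f)
    st <- readSampleTable(f)
    expect_equal(st$phenotype, c(1L, 0L, 1L))
    expect_true(is.numeric(st$sex))
    writeLines(c("sample,sex", "s1,1"), f)
    expect_error(readSampleTable(f), "status")
    writeLines(c("sample,status", "s1,case", "s1,control"), f)
    expect_error(readSampleTable(f), "duplicate")
    writeLines(c("sample,status", "s1,weird"), f)
    expect_error(readSampleTable(f), "vocabulary")
})

test_that("extractDyads tallies cells, excludes Mendelian-impossible pairs", {
    vars <- data.frame(id = "snp1", chromosome = "1", position_bp = 1L,
                       allele_minor = "A", allele_major = "G")
    mkGd <- function(mother, child) {
        dos <- matrix(c(mother, child), 1, 2)
        colnames(dos) <- c("m1", "c1")
        GenotypeDataset(dos, vars, c(0L, 0L), sampleIds = c("m1", "c1"))
    }
    ped <- data.frame(family_id = c("f1", "f1"),
                      individual_id = c("m1", "c1"),
                      mother_id = c(NA, "m1"),
                      role = c("mother", "child"))
    dd <- extractDyads(mkGd(1, 2), ped, c(f1 = "case"))
    expect_equal(unname(caseCounts(dd)[1, ]), c(0, 0, 0, 0, 1, 0, 0))
    expect_equal(sum(controlCounts(dd)), 0)
    ## (0,2) is impossible: excluded and reported
    dd2 <- extractDyads(mkGd(0, 2), ped, c(f1 = "case"))
    expect_equal(sum(caseCounts(dd2)), 0)
    expect_equal(unname(exclusions(dd2)[1, "case"]), 1L)
    ## two mothers in one family is a structural error
    ped2 <- rbind(ped, data.frame(family_id = "f1", individual_id = "m2",
                                  mother_id = NA, role = "mother"))
    expect_error(extractDyads(mkGd(1, 1), ped2, c(f1 = "case")),
                 "two mothers")
})

test_that("extractDyads reproduces the simulator's own cell tallies", {
    cfg <- simulationConfig(nCaseDyads = 250, nControlDyads = 250,
                            nSnps = 1, baselineRisk = 0.01,
                            dyadParams = dyadParams(0.3, S1 = 2, S2 = 3),
                            seed = 6)
    sim <- simulateDyads(cfg)
    fix <- truthToPedigree(sim$truth)
    dd <- extractDyads(fix$genotypes, fix$pedigree, fix$status)
    expect_identical(caseCounts(dd)[1, ], caseCounts(sim$dyads)[1, ])
    expect_identical(controlCounts(dd)[1, ], controlCounts(sim$dyads)[1, ])
    ## accounting: cell sums + exclusions + missing-skips = input pairs
    expect_equal(sum(caseCounts(dd)) + sum(controlCounts(dd)) +
                     sum(exclusions(dd)), nrow(sim$truth))
})

test_that("dyad counts round-trip through the TSV exporter", {
    cfg <- simulationConfig(nCaseDyads = 60, nControlDyads = 60, nSnps = 3,
                            seed = 11)
    sim <- simulateDyads(cfg, keepTruth = FALSE)
    td <- withr::local_tempdir()
    f <- file.path(td, "dy.tsv")
    writeDyadCounts(sim$dyads, f)
    dy2 <- readDyadCounts(f)
    expect_identical(caseCounts(dy2), caseCounts(sim$dyads))
    expect_identical(controlCounts(dy2), controlCounts(sim$dyads))
})
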