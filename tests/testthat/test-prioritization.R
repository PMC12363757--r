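test_that("consequence filter keeps the allowed classes in input order", {
    ds <- readToyCohort()
    kept <- filterConsequence(ds)
    expect_equal(nrow(kept), 9)  # 3 synonymous records drop
    expect_false(any(SummarizedExperiment::rowData(kept)$consequence ==
                     "synonymous"))
    ## order preserved
    expect_equal(variantKeys(kept),
                 variantKeys(ds)[SummarizedExperiment::rowData(ds)$consequence
                                 %in% c("stop_gain", "missense",
                                        "splice_altering")])
    ## allowing every class is the identity
    expect_equal(variantKeys(filterConsequence(ds, consequenceClasses())),
                 variantKeys(ds))
})

test_that("deleteriousness filter is strict and treats absent scores as failing", {
    v <- data.frame(chrom = "1", pos = 1:4, ref = "A", alt = "G",
                    gene = "X",
                    consequence = c("missense", "missense", "stop_gain",
                                    "missense"),
                    cadd = c(25.0, 25.1, NA, 40))
    g <- matrix("0/1", 4, 1, dimnames = list(NULL, "P1"))
    ds <- CohortDataset(v, g, data.frame(sample_id = "P1",
                                         stratum = "PROTECTED"))
    kept <- filterDeleteriousness(ds, 25)
    expect_equal(SummarizedExperiment::rowData(kept)$pos, c(2L, 4L))
    ## the stop-gain exemption readmits unscored stop-gains only
    exempt <- filterDeleteriousness(ds, 25, stopgainExempt = TRUE)
    expect_equal(SummarizedExperiment::rowData(exempt)$pos, c(2L, 3L, 4L))
})

test_that("qualifying configurations: hom-alt and phase-unaware compound hets", {
    v <- data.frame(chrom = "1", pos = 1:5, ref = "A", alt = "G",
                    gene = c("GA", "GA", "GB", "GB", "GB"),
                    consequence = "missense", cadd = 30)
    g <- matrix(c("0/1", "0/0", "1/1", "0/1", "0|1"), ncol = 1,
                dimnames = list(NULL, "P1"))
    ds <- CohortDataset(v, g, data.frame(sample_id = "P1",
                                         stratum = "PROTECTED"))
    cfg <- qualifyingConfigurations(ds, "P1")
    ## GA has a single het -> nothing; GB yields one HOM_ALT and one
    ## COMPOUND_HET over its two het variants
    expect_equal(sort(cfg$kind), c("COMPOUND_HET", "HOM_ALT"))
    ch <- cfg$variant_keys[[which(cfg$kind == "COMPOUND_HET")]]
    expect_equal(sort(ch), c("1:4:A:G", "1:5:A:G"))
    expect_equal(cfg$variant_keys[[which(cfg$kind == "HOM_ALT")]], "1:3:A:G")
})

test_that("qualifying configurations match the brute-force oracle exhaustively", {
    ## every genotype assignment of 3 variants (two genes) in one sample
    pool <- c("0/0", "0/1", "1/0", "1/1", "./.")
    grid <- expand.grid(g1 = pool, g2 = pool, g3 = pool,
                        stringsAsFactors = FALSE)
    v <- data.frame(chrom = "1", pos = 1:3, ref = "A", alt = "G",
                    gene = c("GA", "GA", "GB"),
                    consequence = "missense", cadd = 30)
    s <- data.frame(sample_id = "P1", stratum = "PROTECTED")
    for (i in seq_len(nrow(grid))) {
        g <- matrix(unlist(grid[i, ]), ncol = 1, dimnames = list(NULL, "P1"))
        ds <- CohortDataset(v, g, s)
        expect_equal(canonConfigsDf(qualifyingConfigurations(ds, "P1")),
                     canonConfigs(bruteForceConfigs(ds, "P1")),
                     info = paste(grid[i, ], collapse = " "))
    }
})

test_that("qualifying configurations match the oracle on random small cohorts", {
    set.seed(99)
    for (rep in 1:200) {
        nv <- sample(1:6, 1)
        ns <- sample(1:4, 1)
        strata <- c("PROTECTED", sample(cohortStrata(), max(0, ns - 1),
                                        replace = TRUE))
        ds <- randomCohort(nVariants = nv, strata = strata,
                           nGenes = sample(1:3, 1))
        for (s in colnames(ds))
            expect_equal(canonConfigsDf(qualifyingConfigurations(ds, s)),
                         canonConfigs(bruteForceConfigs(ds, s)))
    }
})

test_that("exclusivity requires protected carriage and full absence elsewhere", {
    v <- data.frame(chrom = "1", pos = 1:3, ref = "A", alt = "G", gene = "X",
                    consequence = "missense", cadd = 30)
    s <- data.frame(sample_id = c("P1", "M1", "C1"),
                    stratum = c("PROTECTED", "CASE_MUTANT", "CONTROL"),
                    aao_years = c(NA, 60, NA))
    ## v1 shared with a case -> out; v2 exclusive -> in, unflagged;
    ## v3 exclusive but control genotype missing -> in, flagged
    g <- matrix(c("0/1", "0/1", "0/0",
                  "1/1", "0/0", "0/0",
                  "0/1", "0/0", "./."),
                nrow = 3, byrow = TRUE, dimnames = list(NULL, s$sample_id))
    ds <- CohortDataset(v, g, s)
    kept <- groupExclusive(ds)
    expect_equal(SummarizedExperiment::rowData(kept)$pos, c(2L, 3L))
    expect_equal(SummarizedExperiment::rowData(kept)$exclusivity_uncertain,
                 c(FALSE, TRUE))
    ## a missing protected genotype is not carriage
    g2 <- g; g2[2, "P1"] <- "./."
    ds2 <- CohortDataset(v, g2, s)
    expect_equal(SummarizedExperiment::rowData(groupExclusive(ds2))$pos, 3L)
})

test_that("adding protected carriage to a non-protected sample never grows the exclusive set", {
    set.seed(7)
    for (rep in 1:25) {
        ds <- randomCohort(nVariants = 20)
        kept0 <- variantKeys(groupExclusive(ds))
        gt <- SummarizedExperiment::assay(ds, "GT")
        strata <- SummarizedExperiment::colData(ds)$stratum
        protCol <- which(strata == "PROTECTED")[1]
        otherCol <- which(strata != "PROTECTED")[1]
        row <- sample(nrow(ds), 1)
        gt[row, otherCol] <- gt[row, protCol]
        ds2 <- ds
        SummarizedExperiment::assay(ds2, "GT") <- gt
        kept1 <- variantKeys(groupExclusive(ds2))
        expect_true(all(kept1 %in% kept0))
    }
})

test_that("candidate-gene intersection is case-insensitive and guards emptiness", {
    ds <- readToyCohort()
    expect_equal(variantKeys(intersectGenes(ds, c("gak"))), "4:843508:C:T")
    expect_equal(nrow(intersectGenes(ds, "NOSUCHGENE")), 0)
    genes <- unique(SummarizedExperiment::rowData(ds)$gene)
    expect_equal(variantKeys(intersectGenes(ds, genes)), variantKeys(ds))
    expect_error(intersectGenes(ds, character(0)), "empty")
})

test_that("the funnel reproduces the hand-counted toy stage profile", {
    ds <- readToyCohort()
    report <- runFunnel(ds, readGeneList(toyGenes()))
    expect_equal(unname(stageCounts(report)), c(12L, 9L, 6L, 4L, 2L, 1L))
    expect_equal(stageKeys(report)$candidate_genes, "4:843508:C:T")
    expect_equal(stageKeys(report)$group_exclusive,
                 c("4:843508:C:T", "6:900:A:C"))
    ## stage 4 exports the qualifying configurations
    cfg <- configurations(report)
    expect_setequal(cfg$kind, c("HOM_ALT", "COMPOUND_HET"))
    expect_equal(sort(unique(unlist(cfg$variant_keys))),
                 sort(stageKeys(report)$qualifying_zygosity))
    expect_length(uncertainKeys(report), 0)
})

test_that("the funnel requires a protected stratum and honors a universal gene set", {
    ds <- readToyCohort()
    noProt <- ds[, SummarizedExperiment::colData(ds)$stratum != "PROTECTED"]
    expect_error(runFunnel(noProt, "GAK"), "no protected stratum")
    allGenes <- unique(SummarizedExperiment::rowData(ds)$gene)
    rep2 <- runFunnel(ds, allGenes)
    expect_equal(stageKeys(rep2)$candidate_genes,
                 stageKeys(rep2)$group_exclusive)
})

test_that("funnel counts are monotone and stages 2/3 commute on random cohorts", {
    set.seed(2024)
    genes <- c("G01", "G02", "G03")
    for (rep in 1:60) {
        ds <- randomCohort(nVariants = sample(5:30, 1))
        report <- runFunnel(ds, genes)
        expect_true(all(diff(unname(stageCounts(report))) <= 0))
        ## consequence and deleteriousness filters commute
        a <- filterDeleteriousness(filterConsequence(ds), 25)
        b <- filterConsequence(filterDeleteriousness(ds, 25))
        expect_equal(variantKeys(a), variantKeys(b))
    }
})
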