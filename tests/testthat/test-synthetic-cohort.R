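test_that("simulateGenotypes hits the Hardy-Weinberg class proportions", {
    expect_equal(unique(simulateGenotypes(50, 0, seed = 1)), "0/0")
    expect_equal(unique(simulateGenotypes(50, 1, seed = 1)), "1/1")
    n <- 50000
    q <- 0.161
    st <- genotypeState(simulateGenotypes(n, q, seed = 42))
    expected <- c(HOM_REF = (1 - q)^2, HET = 2 * q * (1 - q), HOM_ALT = q^2)
    for (cls in names(expected)) {
        pHat <- mean(st == cls)
        se <- sqrt(expected[[cls]] * (1 - expected[[cls]]) / n)
        expect_lt(abs(pHat - expected[[cls]]), 3 * se)
    }
    ## at q chosen as sqrt(0.0258), the hom-alt fraction sits at the scale
    ## of the cohort's observed 2.58% T/T carriers
    expect_lt(abs(mean(st == "HOM_ALT") - q^2), 3 * sqrt(q^2 * (1 - q^2) / n))
    ## determinism under a fixed seed
    expect_identical(simulateGenotypes(100, 0.3, seed = 9),
                     simulateGenotypes(100, 0.3, seed = 9))
})

test_that("simulateAao applies the genotype shift on Gaussian noise", {
    ## sigma -> 0 limit: protective homozygotes sit exactly at mu + delta
    cfg0 <- simulationConfig(aaoSd = 1e-9, effectDeltaYears = 8.8)
    y <- simulateAao(c("1/1", "0/0", "0/1"), cfg0, seed = 4)
    expect_equal(y, c(60 + 8.8, 60, 60), tolerance = 1e-6)
    ## recessive: het carries no shift (checked above); group means at
    ## realistic sigma recover delta within 3 SE
    cfg <- simulationConfig(aaoSd = 10, effectDeltaYears = 8.8)
    g <- simulateGenotypes(20000, sqrt(0.026), seed = 8)
    y <- simulateAao(g, cfg, seed = 9)
    dose <- encodeDosage(genotypeState(g), "RECESSIVE")
    diff <- mean(y[dose == 1]) - mean(y[dose == 0])
    se <- 10 * sqrt(1 / sum(dose == 1) + 1 / sum(dose == 0))
    expect_lt(abs(diff - 8.8), 3 * se)
    ## delta = 0: no systematic group difference
    cfgNull <- simulationConfig(effectDeltaYears = 0)
    y0 <- simulateAao(g, cfgNull, seed = 10)
    d0 <- mean(y0[dose == 1]) - mean(y0[dose == 0])
    expect_lt(abs(d0), 3 * se)
    ## truncation keeps ages positive
    cfgT <- simulationConfig(aaoMu = 5, aaoSd = 10, truncateAtZero = TRUE)
    expect_true(all(simulateAao(rep("0/0", 2000), cfgT, seed = 3) > 0))
})

test_that("simulateExomeCohort implants a recoverable exclusive protective variant", {
    cfg <- simulationConfig(nBackgroundVariants = 300L)
    sim <- simulateExomeCohort(cfg, seed = 123)
    ds <- sim$dataset
    expect_equal(nrow(ds), 301)
    expect_equal(ncol(ds), 17)  # 3 + 4 + 7 + 3
    key <- sim$truth$key
    rd <- SummarizedExperiment::rowData(ds)
    idx <- which(variantKeys(ds) == key)
    expect_equal(rd$gene[idx], "GAK")
    st <- genotypeStateMatrix(ds)[idx, ]
    strata <- SummarizedExperiment::colData(ds)$stratum
    expect_equal(unname(st[colnames(ds) == "P1"]), "HOM_ALT")
    expect_true(all(st[strata != "PROTECTED"] == "HOM_REF"))
    ## the implant survives the funnel whenever its gene is a candidate
    report <- runFunnel(ds, c("GAK", "DNAJC6"))
    expect_true(key %in% stageKeys(report)$candidate_genes)
    ## AAO present exactly for case strata
    aao <- SummarizedExperiment::colData(ds)$aao_years
    expect_equal(!is.na(aao),
                 strata %in% c("CASE_MUTANT", "CASE_IDIOPATHIC"))
})

test_that("a cohort with no background variants funnels down to the implant alone", {
    cfg <- simulationConfig(nBackgroundVariants = 0L)
    sim <- simulateExomeCohort(cfg, seed = 5)
    report <- runFunnel(sim$dataset, "GAK")
    expect_equal(unname(stageCounts(report)), rep(1L, 6))
    expect_equal(stageKeys(report)$candidate_genes, sim$truth$key)
})

test_that("identically seeded simulations serialize to byte-identical VCFs", {
    cfg <- simulationConfig(nBackgroundVariants = 120L)
    d1 <- tempfile(); d2 <- tempfile(); d3 <- tempfile()
    simulateExomeCohort(cfg, seed = 77, dir = d1)
    simulateExomeCohort(cfg, seed = 77, dir = d2)
    simulateExomeCohort(cfg, seed = 78, dir = d3)
    read1 <- readLines(file.path(d1, "cohort.vcf"))
    read2 <- readLines(file.path(d2, "cohort.vcf"))
    expect_identical(read1, read2)
    expect_false(identical(read1, readLines(file.path(d3, "cohort.vcf"))))
    ## truth sidecar round-trips
    truth <- jsonlite::read_json(file.path(d1, "truth.json"),
                                 simplifyVector = TRUE)
    expect_equal(truth$gene, "GAK")
})

test_that("estimatePower is calibrated at the null and monotone in the effect", {
    base <- list(nPerStratum = c(PROTECTED = 0L, CASE_MUTANT = 233L,
                                 CASE_IDIOPATHIC = 263L, CONTROL = 0L),
                 reps = 200L)
    powerAt <- function(delta) {
        cfg <- simulationConfig(nPerStratum = base$nPerStratum,
                                reps = base$reps,
                                effectDeltaYears = delta)
        estimatePower(cfg, alpha = 0.05, seed = 31)@power
    }
    p0 <- powerAt(0); p4 <- powerAt(4); p9 <- powerAt(8.8)
    ## null rejection near alpha (99% binomial CI at 200 reps)
    expect_lt(abs(p0 - 0.05), 2.576 * sqrt(0.05 * 0.95 / 200))
    expect_true(p0 <= p4 && p4 <= p9)
    ## at the study's conditions the simulated power agrees with the
    ## analytic noncentral-t two-sample approximation at expected group sizes
    n <- 496; qHom <- 0.026
    n2 <- n * qHom; n1 <- n - n2; df <- n - 2
    ncp <- 8.8 / (10 * sqrt(1 / n1 + 1 / n2))
    analytic <- 1 - pt(qt(0.975, df), df, ncp) + pt(qt(0.025, df), df, ncp)
    expect_lt(abs(p9 - analytic), 0.08)
    ## degenerate replicates are tallied, not crashed, when hom-alts are
    ## essentially never drawn
    cfgDeg <- simulationConfig(nPerStratum = c(PROTECTED = 0L,
                                               CASE_MUTANT = 5L,
                                               CASE_IDIOPATHIC = 5L,
                                               CONTROL = 0L),
                               protectiveAlleleFreq = 0.01, reps = 40L)
    pd <- estimatePower(cfgDeg, alpha = 0.05, seed = 2)
    expect_equal(pd@degenerateReps + pd@rejections +
                 (pd@reps - pd@degenerateReps - pd@rejections), pd@reps)
    expect_gt(pd@degenerateReps, 0)
})

test_that("infeasible generator configurations error out", {
    cfg <- simulationConfig(nPerStratum = c(PROTECTED = 0L, CASE_MUTANT = 4L,
                                            CASE_IDIOPATHIC = 7L,
                                            CONTROL = 3L))
    expect_error(simulateExomeCohort(cfg, seed = 1), "PROTECTED")
    expect_error(simulationConfig(consequenceProportions = c(missense = 0.5,
                                                             synonymous = 0.4)),
                 "sum to 1")
    expect_error(simulationConfig(aaoSd = 0), "aaoSd")
})
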