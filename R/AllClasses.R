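#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<-
#' @importFrom IRanges DataFrameList
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

## Controlled vocabularies used throughout the package.
.CONSEQUENCES <- c("stop_gain", "missense", "splice_altering", "synonymous",
                   "other")
.STRATA       <- c("PROTECTED", "CASE_MUTANT", "CASE_IDIOPATHIC", "CONTROL")
.CASE_STRATA  <- c("CASE_MUTANT", "CASE_IDIOPATHIC")
.GT_STATES    <- c("HOM_REF", "HET", "HOM_ALT", "MISSING")
.CODING_MODELS <- c("ADDITIVE", "DOMINANT", "RECESSIVE")

#' Consequence classes, cohort strata and genotype codings
#'
#' Controlled vocabularies used by the package: the variant consequence
#' classes accepted in the `consequence` annotation, the cohort stratum
#' labels (resilient carriers are `PROTECTED`, affected carriers of the
#' risk mutation `CASE_MUTANT`, idiopathic cases `CASE_IDIOPATHIC`, and
#' unaffected non-carriers `CONTROL`), and the genotype-dosage coding
#' models for association.
#'
#' @return A character vector of allowed tags.
#' @examples
#' consequenceClasses()
#' cohortStrata()
#' codingModels()
#' @export
consequenceClasses <- function() .CONSEQUENCES

#' @rdname consequenceClasses
#' @export
cohortStrata <- function() .STRATA

#' @rdname consequenceClasses
#' @export
codingModels <- function() .CODING_MODELS

## ---------------------------------------------------------------------------
## CohortDataset
## ---------------------------------------------------------------------------

#' CohortDataset: variants x samples container for an exome cohort
#'
#' A `CohortDataset` extends [SummarizedExperiment::SummarizedExperiment].
#' Rows are biallelic variant records (multiallelic sites must be split
#' before construction; see [splitMultiallelic()]), columns are samples.
#' The single assay `"GT"` holds VCF-style genotype strings (`"0/1"`,
#' `"1|0"`, `"./."`; phase separators are accepted but ignored by all
#' zygosity logic). `rowData` carries the variant annotations `chrom`,
#' `pos` (1-based), `ref`, `alt`, `rsid`, `gene`, `consequence` and
#' `cadd` (`NA` means the score is absent, which is distinct from 0).
#' `colData` carries `stratum`, `aao_years` (age at disease onset, years;
#' only case strata may have one) and any covariate columns.
#'
#' @aliases CohortDataset-class
#' @exportClass CohortDataset
setClass("CohortDataset", contains = "SummarizedExperiment")

.validCohortDataset <- function(object) {
    msg <- character(0)
    if (!("GT" %in% SummarizedExperiment::assayNames(object)))
        return("assay 'GT' is required")
    gt <- SummarizedExperiment::assay(object, "GT")
    if (!is.character(gt))
        msg <- c(msg, "assay 'GT' must be a character matrix")
    rd <- SummarizedExperiment::rowData(object)
    need <- c("chrom", "pos", "ref", "alt", "gene", "consequence")
    miss <- setdiff(need, colnames(rd))
    if (length(miss))
        return(paste0("rowData lacks column(s): ", paste(miss, collapse = ", ")))
    if (nrow(rd)) {
        if (any(rd$pos < 1L)) msg <- c(msg, "pos must be >= 1")
        if (!all(grepl("^[ACGT]+$", rd$ref)) || !all(grepl("^[ACGT]+$", rd$alt)))
            msg <- c(msg, "ref/alt must be non-empty uppercase strings over {A,C,G,T}")
        if (any(grepl(",", rd$alt)))
            msg <- c(msg, "records must be biallelic (exactly one alt); split multiallelics first")
        if (!all(rd$consequence %in% .CONSEQUENCES))
            msg <- c(msg, paste0("consequence must be one of: ",
                                 paste(.CONSEQUENCES, collapse = ", ")))
        if ("cadd" %in% colnames(rd) && any(rd$cadd < 0, na.rm = TRUE))
            msg <- c(msg, "cadd must be non-negative where present")
    }
    cd <- SummarizedExperiment::colData(object)
    if (!("stratum" %in% colnames(cd)))
        return("colData lacks 'stratum'")
    if (!all(cd$stratum %in% .STRATA))
        msg <- c(msg, paste0("stratum must be one of: ",
                             paste(.STRATA, collapse = ", ")))
    if ("aao_years" %in% colnames(cd)) {
        nonCase <- !(cd$stratum %in% .CASE_STRATA)
        if (any(nonCase & !is.na(cd$aao_years)))
            msg <- c(msg, "aao_years must be NA for non-case strata")
        if (any(cd$aao_years <= 0, na.rm = TRUE))
            msg <- c(msg, "aao_years must be positive where present")
    }
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "sample ids must be unique")
    if (length(msg)) msg else TRUE
}
setValidity("CohortDataset", .validCohortDataset)

#' Construct a CohortDataset
#'
#' @param variants `data.frame` of variant annotations with columns
#'   `chrom`, `pos`, `ref`, `alt`, `gene`, `consequence` and optionally
#'   `rsid` and `cadd` (`NA` = score absent).
#' @param genotypes character matrix of VCF genotype strings,
#'   `nrow(variants)` rows; column names are the sample ids.
#' @param samples `data.frame` with columns `sample_id`, `stratum`,
#'   optionally `aao_years` and numeric covariate columns; one row per
#'   genotype column.
#' @return A [CohortDataset-class] object.
#' @examples
#' v <- data.frame(chrom = "1", pos = 100L, ref = "A", alt = "G",
#'                 gene = "GAK", consequence = "missense", cadd = 30)
#' g <- matrix(c("0/1", "0/0"), nrow = 1,
#'             dimnames = list(NULL, c("P1", "C1")))
#' s <- data.frame(sample_id = c("P1", "C1"),
#'                 stratum = c("PROTECTED", "CONTROL"))
#' CohortDataset(v, g, s)
#' @export
CohortDataset <- function(variants, genotypes, samples) {
    variants <- as.data.frame(variants)
    samples <- as.data.frame(samples)
    if (!("rsid" %in% colnames(variants))) variants$rsid <- NA_character_
    if (!("cadd" %in% colnames(variants))) variants$cadd <- NA_real_
    variants$pos <- as.integer(variants$pos)
    variants$cadd <- as.numeric(variants$cadd)
    genotypes <- as.matrix(genotypes)
    if (is.null(colnames(genotypes))) colnames(genotypes) <- samples$sample_id
    if (!identical(colnames(genotypes), samples$sample_id))
        stop("genotype columns must match samples$sample_id, in order")
    if (!("aao_years" %in% colnames(samples))) samples$aao_years <- NA_real_
    cd <- DataFrame(samples[setdiff(colnames(samples), "sample_id")],
                    row.names = samples$sample_id)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = SimpleList(GT = unname(genotypes)),
        rowData = DataFrame(variants), colData = cd)
    colnames(se) <- samples$sample_id
    new("CohortDataset", se)
}

setMethod("show", "CohortDataset", function(object) {
    cat(sprintf("CohortDataset: %d biallelic variant(s) x %d sample(s)\n",
                nrow(object), ncol(object)))
    st <- table(factor(SummarizedExperiment::colData(object)$stratum,
                       levels = .STRATA))
    cat("  strata:", paste(sprintf("%s=%d", names(st), st), collapse = " "), "\n")
    if (nrow(object)) {
        cq <- table(factor(SummarizedExperiment::rowData(object)$consequence,
                           levels = .CONSEQUENCES))
        cat("  consequences:",
            paste(sprintf("%s=%d", names(cq), cq), collapse = " "), "\n")
    }
})

## ---------------------------------------------------------------------------
## FunnelReport
## ---------------------------------------------------------------------------

#' FunnelReport: per-stage audit of the prioritization funnel
#'
#' Ordered record of the variant-prioritization funnel: stage names,
#' retained-variant counts (monotonically non-increasing), the retained
#' variant keys (`"chrom:pos:ref:alt"`) per stage, the qualifying
#' homozygous / compound-heterozygous configurations found at the
#' zygosity stage, and the keys whose stratum exclusivity rests on a
#' missing genotype in a non-protected sample (`uncertainKeys`).
#'
#' @aliases FunnelReport-class
#' @exportClass FunnelReport
setClass("FunnelReport",
         representation(stageNames = "character",
                        counts = "integer",
                        keys = "list",
                        configurations = "data.frame",
                        uncertainKeys = "character"))

setValidity("FunnelReport", function(object) {
    msg <- character(0)
    n <- length(object@stageNames)
    if (length(object@counts) != n || length(object@keys) != n)
        return("stageNames, counts and keys must have equal length")
    if (!identical(object@counts, vapply(object@keys, length, 1L)))
        msg <- c(msg, "each count must equal the number of retained keys")
    if (n > 1L && any(diff(object@counts) > 0L))
        msg <- c(msg, "counts must be monotonically non-increasing")
    if (length(msg)) msg else TRUE
})

setMethod("show", "FunnelReport", function(object) {
    cat("FunnelReport:\n")
    for (i in seq_along(object@stageNames))
        cat(sprintf("  %d. %-22s %6d retained\n", i,
                    object@stageNames[i], object@counts[i]))
    cat(sprintf("  qualifying configurations: %d; exclusivity-uncertain keys: %d\n",
                nrow(object@configurations), length(object@uncertainKeys)))
})

#' @describeIn FunnelReport stage names in funnel order.
#' @param x,object A `FunnelReport`.
#' @export
stageNames <- function(x) x@stageNames

#' @describeIn FunnelReport retained-variant count per stage (named).
#' @export
stageCounts <- function(x) stats::setNames(x@counts, x@stageNames)

#' @describeIn FunnelReport list of retained variant keys per stage.
#' @export
stageKeys <- function(x) stats::setNames(x@keys, x@stageNames)

#' @describeIn FunnelReport qualifying configurations (`data.frame` with
#'   `sample_id`, `gene`, `kind`, and list column `variant_keys`).
#' @export
configurations <- function(x) x@configurations

#' @describeIn FunnelReport keys retained at the exclusivity stage whose
#'   exclusivity rests on at least one missing non-protected genotype.
#' @export
uncertainKeys <- function(x) x@uncertainKeys

## ---------------------------------------------------------------------------
## RegressionResult
## ---------------------------------------------------------------------------

#' RegressionResult: one genotype-coded AAO linear model
#'
#' Ordinary-least-squares fit of age at onset on a genotype dosage under
#' one coding model. `beta` is the modeled AAO shift (years) per dosage
#' unit; `p` is the two-sided t-test p-value on the dosage coefficient.
#' `degenerate` flags a fit that could not be performed because the
#' dosage had no variance among usable samples (e.g. no homozygous-alt
#' carrier under recessive coding).
#'
#' @aliases RegressionResult-class
#' @exportClass RegressionResult
setClass("RegressionResult",
         representation(model = "character", beta = "numeric", se = "numeric",
                        tStat = "numeric", p = "numeric", n = "integer",
                        df = "integer", nDropped = "integer",
                        covariateBetas = "numeric", degenerate = "logical"))

setMethod("show", "RegressionResult", function(object) {
    if (object@degenerate) {
        cat(sprintf("RegressionResult [%s]: degenerate coding (no dosage variance), n = %d\n",
                    object@model, object@n))
    } else {
        cat(sprintf("RegressionResult [%s]: beta = %.3f years (SE %.3f), t = %.3f, p = %.4g, n = %d, df = %d\n",
                    object@model, object@beta, object@se, object@tStat,
                    object@p, object@n, object@df))
    }
    if (object@nDropped > 0L)
        cat(sprintf("  %d sample(s) dropped (missing dosage or AAO)\n",
                    object@nDropped))
})

## ---------------------------------------------------------------------------
## FrequencyTestResult
## ---------------------------------------------------------------------------

#' FrequencyTestResult: cohort vs reference genotype-frequency comparison
#'
#' A 2 x k contingency-table test of genotype counts. `method` is
#' `"CHI_SQUARE"` (Pearson, no continuity correction) unless any expected
#' cell is below 5, in which case Fisher's exact test is used.
#'
#' @aliases FrequencyTestResult-class
#' @exportClass FrequencyTestResult
setClass("FrequencyTestResult",
         representation(table = "matrix", statistic = "numeric",
                        p = "numeric", method = "character"))

setMethod("show", "FrequencyTestResult", function(object) {
    cat(sprintf("FrequencyTestResult [%s]: p = %.4g\n", object@method, object@p))
    print(object@table)
})

## ---------------------------------------------------------------------------
## ReferenceCounts
## ---------------------------------------------------------------------------

#' ReferenceCounts: gnomAD-style population genotype counts
#'
#' Describes one reference population by its total allele number and the
#' number of homozygous-alternate individuals, following the gnomAD
#' convention that the number of individuals equals `totalAlleles / 2`.
#'
#' @aliases ReferenceCounts-class
#' @exportClass ReferenceCounts
setClass("ReferenceCounts",
         representation(population = "character",
                        homAltIndividuals = "integer",
                        totalAlleles = "integer",
                        hetIndividuals = "integer",
                        homRefIndividuals = "integer"))

setValidity("ReferenceCounts", function(object) {
    msg <- character(0)
    if (object@homAltIndividuals < 0L)
        msg <- c(msg, "homAltIndividuals must be non-negative")
    if (object@totalAlleles <= 0L)
        msg <- c(msg, "totalAlleles must be positive")
    if (object@totalAlleles %% 2L != 0L)
        msg <- c(msg, "totalAlleles must be even (2 alleles per individual)")
    if (2L * object@homAltIndividuals > object@totalAlleles)
        msg <- c(msg, "2 * homAltIndividuals must not exceed totalAlleles")
    if (length(msg)) msg else TRUE
})

#' @param population population label.
#' @param homAltIndividuals number of homozygous-alternate individuals.
#' @param totalAlleles total allele number (positive, even).
#' @param hetIndividuals,homRefIndividuals optional further genotype-class
#'   counts (`NA` if unknown).
#' @return `ReferenceCounts()` returns a [ReferenceCounts-class] object.
#' @describeIn ReferenceCounts constructor.
#' @examples
#' referenceCounts("overall", 2812, 280488)
#' @export
referenceCounts <- function(population, homAltIndividuals, totalAlleles,
                            hetIndividuals = NA_integer_,
                            homRefIndividuals = NA_integer_) {
    new("ReferenceCounts", population = as.character(population),
        homAltIndividuals = as.integer(homAltIndividuals),
        totalAlleles = as.integer(totalAlleles),
        hetIndividuals = as.integer(hetIndividuals),
        homRefIndividuals = as.integer(homRefIndividuals))
}

setMethod("show", "ReferenceCounts", function(object) {
    cat(sprintf("ReferenceCounts [%s]: %d hom-alt individuals / %d alleles (%d individuals)\n",
                object@population, object@homAltIndividuals,
                object@totalAlleles, object@totalAlleles %/% 2L))
})

## ---------------------------------------------------------------------------
## SimulationConfig
## ---------------------------------------------------------------------------

#' SimulationConfig: study conditions for the synthetic cohort generator
#'
#' Bundles every parameter of the synthetic exome-cohort generator and of
#' the association/power simulations. Defaults describe the discovery
#' exome cohort (3 resilient carriers, 4 affected carriers, 7 idiopathic
#' cases, 3 controls; ~65,700 background variants per cohort) and an
#' association cohort drawn with a recessive protective effect of
#' `effectDeltaYears` on a Gaussian age-at-onset with mean `aaoMu` and
#' standard deviation `aaoSd`.
#'
#' @aliases SimulationConfig-class
#' @exportClass SimulationConfig
setClass("SimulationConfig",
         representation(nPerStratum = "integer",
                        nBackgroundVariants = "integer",
                        alleleFreqBeta = "numeric",
                        caddMixture = "list",
                        consequenceProportions = "numeric",
                        protectiveGene = "character",
                        protectiveAlleleFreq = "numeric",
                        requireHomInProtected = "logical",
                        aaoMu = "numeric", aaoSd = "numeric",
                        effectDeltaYears = "numeric",
                        codingModel = "character",
                        truncateAtZero = "logical",
                        reps = "integer"))

setValidity("SimulationConfig", function(object) {
    msg <- character(0)
    if (!identical(sort(names(object@nPerStratum)), sort(.STRATA)))
        msg <- c(msg, "nPerStratum must name every cohort stratum")
    if (any(object@nPerStratum < 0L))
        msg <- c(msg, "nPerStratum entries must be non-negative")
    if (abs(sum(object@consequenceProportions) - 1) > 1e-9)
        msg <- c(msg, "consequenceProportions must sum to 1")
    if (!all(names(object@consequenceProportions) %in% .CONSEQUENCES))
        msg <- c(msg, "consequenceProportions names must be consequence classes")
    if (object@aaoSd <= 0) msg <- c(msg, "aaoSd must be positive")
    if (object@protectiveAlleleFreq < 0 || object@protectiveAlleleFreq > 1)
        msg <- c(msg, "protectiveAlleleFreq must lie in [0, 1]")
    if (!(object@codingModel %in% .CODING_MODELS))
        msg <- c(msg, "codingModel must be ADDITIVE, DOMINANT or RECESSIVE")
    if (object@reps < 1L) msg <- c(msg, "reps must be >= 1")
    if (length(msg)) msg else TRUE
})

#' @param nPerStratum named integer vector of sample counts per stratum
#'   (names `PROTECTED`, `CASE_MUTANT`, `CASE_IDIOPATHIC`, `CONTROL`).
#' @param nBackgroundVariants number of background exome variants.
#' @param alleleFreqBeta `c(shape1, shape2)` of the Beta distribution the
#'   background alternate-allele frequencies are drawn from.
#' @param caddMixture CADD PHRED mixture: `pHigh` (mass above the default
#'   filter threshold), `pMissing` (annotation absent), and uniform
#'   `low`/`high` score ranges.
#' @param consequenceProportions named fractions over the consequence
#'   classes (must sum to 1).
#' @param protectiveGene gene symbol of the implanted protective variant.
#' @param protectiveAlleleFreq population frequency of the protective
#'   allele (used for Hardy-Weinberg genotype draws in the association
#'   cohort and in protected samples beyond the guaranteed carrier).
#' @param requireHomInProtected guarantee a homozygous-alternate protected
#'   sample for the implanted variant.
#' @param aaoMu,aaoSd mean and SD of age at onset, years.
#' @param effectDeltaYears AAO shift per dosage unit of the protective
#'   genotype (years; positive = later onset).
#' @param codingModel coding under which the effect acts
#'   (`"RECESSIVE"`, `"DOMINANT"` or `"ADDITIVE"`).
#' @param truncateAtZero truncate simulated AAO at 0 years.
#' @param reps default number of Monte Carlo replicates.
#' @return `simulationConfig()` returns a [SimulationConfig-class] object.
#' @describeIn SimulationConfig constructor with the default study
#'   conditions.
#' @examples
#' cfg <- simulationConfig(nBackgroundVariants = 500L)
#' cfg
#' @export
simulationConfig <- function(nPerStratum = c(PROTECTED = 3L, CASE_MUTANT = 4L,
                                             CASE_IDIOPATHIC = 7L, CONTROL = 3L),
                             nBackgroundVariants = 65696L,
                             alleleFreqBeta = c(0.5, 5),
                             caddMixture = list(pHigh = 0.1, pMissing = 0.05,
                                                low = c(0, 25), high = c(25, 50)),
                             consequenceProportions = c(stop_gain = 0.02,
                                                        missense = 0.40,
                                                        splice_altering = 0.03,
                                                        synonymous = 0.40,
                                                        other = 0.15),
                             protectiveGene = "GAK",
                             protectiveAlleleFreq = sqrt(0.026),
                             requireHomInProtected = TRUE,
                             aaoMu = 60, aaoSd = 10,
                             effectDeltaYears = 8.8,
                             codingModel = "RECESSIVE",
                             truncateAtZero = FALSE,
                             reps = 1000L) {
    np <- as.integer(nPerStratum)
    names(np) <- names(nPerStratum)
    new("SimulationConfig", nPerStratum = np,
        nBackgroundVariants = as.integer(nBackgroundVariants),
        alleleFreqBeta = as.numeric(alleleFreqBeta),
        caddMixture = caddMixture,
        consequenceProportions = consequenceProportions,
        protectiveGene = as.character(protectiveGene),
        protectiveAlleleFreq = as.numeric(protectiveAlleleFreq),
        requireHomInProtected = isTRUE(requireHomInProtected),
        aaoMu = as.numeric(aaoMu), aaoSd = as.numeric(aaoSd),
        effectDeltaYears = as.numeric(effectDeltaYears),
        codingModel = as.character(codingModel),
        truncateAtZero = isTRUE(truncateAtZero),
        reps = as.integer(reps))
}

setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig:\n")
    cat("  samples/stratum:",
        paste(sprintf("%s=%d", names(object@nPerStratum), object@nPerStratum),
              collapse = " "), "\n")
    cat(sprintf("  background variants: %d; protective gene %s (q = %.4f)\n",
                object@nBackgroundVariants, object@protectiveGene,
                object@protectiveAlleleFreq))
    cat(sprintf("  AAO ~ N(%.1f, %.1f^2) + %.1f y x %s dosage%s\n",
                object@aaoMu, object@aaoSd, object@effectDeltaYears,
                object@codingModel,
                if (object@truncateAtZero) " (truncated at 0)" else ""))
})

## ---------------------------------------------------------------------------
## PowerEstimate
## ---------------------------------------------------------------------------

#' PowerEstimate: Monte Carlo power of the genotype-AAO association
#'
#' Fraction of simulated cohorts in which the dosage coefficient of the
#' AAO linear model is rejected at level `alpha`. Replicates in which the
#' coding was degenerate (no variance in dosage, e.g. no homozygous-alt
#' carrier drawn) count as non-rejections and are reported separately in
#' `degenerateReps`. `mcSe` is the binomial Monte Carlo standard error.
#'
#' @aliases PowerEstimate-class
#' @exportClass PowerEstimate
setClass("PowerEstimate",
         representation(alpha = "numeric", reps = "integer",
                        rejections = "integer", degenerateReps = "integer",
                        power = "numeric", mcSe = "numeric"))

setMethod("show", "PowerEstimate", function(object) {
    cat(sprintf("PowerEstimate: power = %.3f (MC SE %.3f) at alpha = %g over %d reps (%d degenerate)\n",
                object@power, object@mcSe, object@alpha, object@reps,
                object@degenerateReps))
})
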