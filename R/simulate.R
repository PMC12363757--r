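## Synthetic exome-cohort generator and Monte Carlo power machinery.
##
## Reproducibility: every entry point takes one integer seed. Internally
## each stage of a simulation draws under its own child seed derived by
## `.childSeed(seed, k)` (a fixed affine map modulo 2^31 - 1), so a
## stage's stream does not depend on how many numbers an earlier stage
## consumed.

.childSeed <- function(seed, k) {
    ## deterministic, collision-scarce child streams; 69621 is a classic
    ## Lehmer multiplier, modulus 2^31 - 1 keeps the value a valid seed
    as.integer((as.double(seed %% 2147483647L) * 69621 + k) %% 2147483647)
}

#' Simulate Hardy-Weinberg genotypes
#'
#' Draws `n` diploid genotypes at a biallelic site with alternate-allele
#' frequency `q`: each of the two alleles is an independent Bernoulli(q)
#' draw, so genotype classes occur with the Hardy-Weinberg proportions
#' (1-q)^2, 2q(1-q), q^2.
#'
#' @param n number of individuals.
#' @param q alternate-allele frequency in \[0, 1\].
#' @param seed optional integer seed (deterministic output when set).
#' @return character vector of `n` genotype strings (`"0/0"`, `"0/1"`,
#'   `"1/0"`, `"1/1"`).
#' @examples
#' table(genotypeState(simulateGenotypes(1000, 0.16, seed = 1)))
#' @export
simulateGenotypes <- function(n, q, seed = NULL) {
    stopifnot(q >= 0, q <= 1, n >= 0)
    if (!is.null(seed)) set.seed(seed)
    a1 <- stats::rbinom(n, 1L, q)
    a2 <- stats::rbinom(n, 1L, q)
    paste0(a1, "/", a2)
}

#' Simulate ages at onset under a genotype effect
#'
#' Draws AAO for each individual as Gaussian noise around `aaoMu` plus a
#' genotype shift: `AAO_i = N(aaoMu, aaoSd^2) + delta * dosage_i`, where
#' the dosage is the coding of the genotype under `codingModel`. With
#' `truncateAtZero` the Gaussian is replaced by its left-truncation at 0
#' (drawn by inverse-CDF), since an age cannot be negative.
#'
#' @param genotypes character vector of genotype strings.
#' @param cfg A [SimulationConfig-class] supplying `aaoMu`, `aaoSd`,
#'   `effectDeltaYears`, `codingModel` and `truncateAtZero`.
#' @param seed optional integer seed.
#' @return numeric vector of ages at onset (years); `NA` for missing
#'   genotypes.
#' @examples
#' cfg <- simulationConfig()
#' simulateAao(c("0/0", "1/1", "0/1"), cfg, seed = 1)
#' @export
simulateAao <- function(genotypes, cfg, seed = NULL) {
    stopifnot(is(cfg, "SimulationConfig"))
    if (!is.null(seed)) set.seed(seed)
    n <- length(genotypes)
    dosage <- encodeDosage(genotypeState(genotypes), cfg@codingModel)
    shift <- cfg@effectDeltaYears * dosage
    if (cfg@truncateAtZero) {
        m <- cfg@aaoMu + shift
        lo <- stats::pnorm(0, mean = m, sd = cfg@aaoSd)
        stats::qnorm(stats::runif(n, lo, 1), mean = m, sd = cfg@aaoSd)
    } else {
        stats::rnorm(n, mean = cfg@aaoMu, sd = cfg@aaoSd) + shift
    }
}

## sample ids per stratum: P1..,M1..,I1..,C1..
.strataIds <- function(nPerStratum) {
    pre <- c(PROTECTED = "P", CASE_MUTANT = "M", CASE_IDIOPATHIC = "I",
             CONTROL = "C")
    unlist(lapply(.STRATA, function(s) {
        n <- nPerStratum[[s]]
        if (n > 0L) paste0(pre[[s]], seq_len(n)) else character(0)
    }), use.names = FALSE)
}

#' Simulate an annotated exome cohort with an implanted protective variant
#'
#' Generates a full [CohortDataset-class] with the statistical structure
#' the prioritization funnel assumes: `nBackgroundVariants` background
#' exome variants with Hardy-Weinberg genotypes at Beta-distributed
#' allele frequencies, consequence classes and CADD PHRED scores drawn
#' from the configured mixtures — plus one implanted protective variant
#' in `protectiveGene` that is homozygous-alternate in the first
#' protected sample and, by construction, absent from every non-protected
#' sample. The implanted variant always passes the consequence and
#' deleteriousness filters (missense, CADD 35), so its recovery at the
#' funnel's final stage is a construction guarantee the funnel can be
#' audited against. The ground-truth key is returned alongside the data.
#'
#' Ages at onset are generated for case-stratum samples only, as plain
#' Gaussian draws — the protective variant is absent from cases, so no
#' effect applies in the discovery cohort.
#'
#' @param cfg A [SimulationConfig-class].
#' @param seed integer seed; the output is fully deterministic given
#'   `(cfg, seed)`, including the serialized VCF.
#' @param dir optional output directory; when given, writes
#'   `cohort.vcf`, `metadata.tsv` and `truth.json` there.
#' @return list with elements `dataset` (the [CohortDataset-class]) and
#'   `truth` (list: `key`, `gene`, `carrierSamples`).
#' @examples
#' sim <- simulateExomeCohort(simulationConfig(nBackgroundVariants = 50L),
#'                            seed = 1)
#' sim$truth$key
#' @export
simulateExomeCohort <- function(cfg, seed, dir = NULL) {
    stopifnot(is(cfg, "SimulationConfig"))
    np <- cfg@nPerStratum
    if (np[["PROTECTED"]] < 1L)
        stop("at least one PROTECTED sample is required to implant a ",
             "protective variant")
    if (cfg@requireHomInProtected && cfg@protectiveAlleleFreq == 0 &&
        np[["PROTECTED"]] < 1L)
        stop("infeasible: homozygous protected carrier required at allele frequency 0")
    ids <- .strataIds(np)
    strata <- rep(.STRATA, times = np[.STRATA])
    ns <- length(ids)
    nv <- cfg@nBackgroundVariants

    ## stage streams
    set.seed(.childSeed(seed, 1L))   # variant annotations
    chrom <- sort(sample(1:22, nv, replace = TRUE))
    pos <- unlist(lapply(split(seq_len(nv), chrom), function(i)
        sort(sample.int(5e7, length(i)))), use.names = FALSE)
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, nv, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
    nGenes <- max(1L, ceiling(nv / 8))
    gene <- sprintf("BG%05d", sample.int(nGenes, nv, replace = TRUE))
    consequence <- sample(names(cfg@consequenceProportions), nv,
                          replace = TRUE, prob = cfg@consequenceProportions)
    mix <- cfg@caddMixture
    u <- stats::runif(nv)
    cadd <- ifelse(u < mix$pHigh,
                   stats::runif(nv, mix$high[1], mix$high[2]),
                   stats::runif(nv, mix$low[1], mix$low[2]))
    cadd[stats::runif(nv) < mix$pMissing] <- NA_real_

    set.seed(.childSeed(seed, 2L))   # background genotypes at HWE
    qv <- stats::rbeta(nv, cfg@alleleFreqBeta[1], cfg@alleleFreqBeta[2])
    a1 <- matrix(stats::rbinom(nv * ns, 1L, qv), nrow = nv, ncol = ns)
    a2 <- matrix(stats::rbinom(nv * ns, 1L, qv), nrow = nv, ncol = ns)
    gt <- matrix(paste0(a1, "/", a2), nrow = nv, ncol = ns,
                 dimnames = list(NULL, ids))

    set.seed(.childSeed(seed, 3L))   # implanted protective variant
    protIdx <- which(strata == "PROTECTED")
    implantGt <- rep("0/0", ns)
    extra <- setdiff(protIdx, protIdx[1L])
    if (length(extra))
        implantGt[extra] <- simulateGenotypes(length(extra),
                                              cfg@protectiveAlleleFreq)
    implantGt[protIdx[1L]] <- if (cfg@requireHomInProtected) "1/1" else "0/1"
    implant <- data.frame(chrom = "4", pos = 843508L, ref = "C", alt = "T",
                          rsid = NA_character_, gene = cfg@protectiveGene,
                          consequence = "missense", cadd = 35)

    set.seed(.childSeed(seed, 4L))   # ages at onset for case samples
    isCase <- strata %in% .CASE_STRATA
    aao <- rep(NA_real_, ns)
    aao[isCase] <- simulateAao(rep("0/0", sum(isCase)), cfg)

    variants <- rbind(
        data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   ref = ref, alt = alt, rsid = rep(NA_character_, nv),
                   gene = gene, consequence = consequence, cadd = cadd),
        implant)
    gt <- rbind(gt, matrix(implantGt, nrow = 1,
                           dimnames = list(NULL, ids)))
    ord <- order(suppressWarnings(as.integer(variants$chrom)), variants$pos)
    variants <- variants[ord, , drop = FALSE]
    rownames(variants) <- NULL
    gt <- gt[ord, , drop = FALSE]

    samples <- data.frame(sample_id = ids, stratum = strata,
                          aao_years = aao)
    dataset <- CohortDataset(variants, gt, samples)
    truthKey <- paste(implant$chrom, implant$pos, implant$ref, implant$alt,
                      sep = ":")
    carriers <- ids[genotypeState(implantGt) %in% c("HET", "HOM_ALT")]
    truth <- list(key = truthKey, gene = cfg@protectiveGene,
                  carrierSamples = carriers)
    if (!is.null(dir)) {
        if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
        writeCohortVcf(dataset, file.path(dir, "cohort.vcf"),
                       file.path(dir, "metadata.tsv"))
        jsonlite::write_json(truth, file.path(dir, "truth.json"),
                             auto_unbox = TRUE, pretty = TRUE)
    }
    list(dataset = dataset, truth = truth)
}

#' Monte Carlo power of the genotype-AAO association
#'
#' Simulates `cfg@reps` association cohorts — each of size equal to the
#' configured case strata, with Hardy-Weinberg genotypes at the
#' protective-allele frequency and AAO drawn under the configured effect
#' — fits the AAO linear model under `cfg@codingModel`, and reports the
#' rejection fraction at level `alpha`. Replicates whose coding is
#' degenerate (no homozygous-alternate carrier drawn, say) count as
#' non-rejections and are tallied separately.
#'
#' @param cfg A [SimulationConfig-class]; the association cohort size is
#'   `sum` of the case strata of `nPerStratum`.
#' @param alpha significance level.
#' @param seed integer seed.
#' @param reps number of replicates (defaults to `cfg@reps`).
#' @return A [PowerEstimate-class].
#' @examples
#' cfg <- simulationConfig(nPerStratum = c(PROTECTED = 0L, CASE_MUTANT = 233L,
#'                                         CASE_IDIOPATHIC = 263L, CONTROL = 0L),
#'                         reps = 50L)
#' estimatePower(cfg, alpha = 0.05, seed = 1)
#' @export
estimatePower <- function(cfg, alpha = 0.05, seed = 1L, reps = cfg@reps) {
    stopifnot(is(cfg, "SimulationConfig"), alpha > 0, alpha < 1)
    n <- sum(cfg@nPerStratum[.CASE_STRATA])
    if (n < 3L) stop("case strata too small for an association cohort")
    rejections <- 0L
    degenerate <- 0L
    for (r in seq_len(reps)) {
        g <- simulateGenotypes(n, cfg@protectiveAlleleFreq,
                               seed = .childSeed(seed, 2L * r))
        y <- simulateAao(g, cfg, seed = .childSeed(seed, 2L * r + 1L))
        fit <- fitAao(y, encodeDosage(genotypeState(g), cfg@codingModel),
                      model = cfg@codingModel)
        if (fit@degenerate) degenerate <- degenerate + 1L
        else if (isTRUE(fit@p < alpha)) rejections <- rejections + 1L
    }
    power <- rejections / reps
    new("PowerEstimate", alpha = alpha, reps = as.integer(reps),
        rejections = rejections, degenerateReps = degenerate,
        power = power, mcSe = sqrt(power * (1 - power) / reps))
}
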