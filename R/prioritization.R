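## The prioritization funnel.
##
## Fixed stage order: (1) variants carried by at least one protected
## sample; (2) consequence-class filter; (3) deleteriousness (CADD)
## filter; (4) qualifying zygosity configurations in protected samples
## (homozygous-alt, or two or more heterozygous filtered variants in one
## gene — compound heterozygosity, phase-unaware); (5) stratum
## exclusivity; (6) candidate-gene intersection.

.DEFAULT_CONSEQUENCES <- c("stop_gain", "missense", "splice_altering")

.FUNNEL_STAGES <- c("carried_by_protected", "consequence",
                    "deleteriousness", "qualifying_zygosity",
                    "group_exclusive", "candidate_genes")

#' Consequence-class filter
#'
#' Retains variants whose consequence class is in `allowed`, preserving
#' input order. The default keeps stop-gain and code-altering classes
#' (missense and splice-altering) and drops synonymous and other.
#'
#' @param x A [CohortDataset-class].
#' @param allowed character vector of consequence tags to keep.
#' @return The filtered [CohortDataset-class].
#' @export
filterConsequence <- function(x, allowed = .DEFAULT_CONSEQUENCES) {
    stopifnot(all(allowed %in% .CONSEQUENCES))
    x[SummarizedExperiment::rowData(x)$consequence %in% allowed, ]
}

#' Deleteriousness (CADD PHRED) filter
#'
#' Retains variants whose CADD PHRED score is present and strictly
#' greater than `threshold`. A variant with no score is removed: absence
#' of annotation is not evidence of deleteriousness. Optionally,
#' stop-gain variants can be exempted from the score requirement
#' (`stopgainExempt`, off by default), since truncating alleles are
#' sometimes prioritized regardless of score.
#'
#' @param x A [CohortDataset-class].
#' @param threshold scores must exceed this value (strictly).
#' @param stopgainExempt keep stop-gain variants regardless of score.
#' @return The filtered [CohortDataset-class].
#' @export
filterDeleteriousness <- function(x, threshold = 25, stopgainExempt = FALSE) {
    stopifnot(threshold >= 0)
    rd <- SummarizedExperiment::rowData(x)
    keep <- !is.na(rd$cadd) & rd$cadd > threshold
    if (isTRUE(stopgainExempt))
        keep <- keep | rd$consequence == "stop_gain"
    x[keep, ]
}

#' Qualifying zygosity configurations of one sample
#'
#' For one sample, lists every configuration under which already-filtered
#' variants qualify as potentially biallelic loss or gain of function:
#' one `HOM_ALT` configuration per homozygous-alternate variant, and one
#' `COMPOUND_HET` configuration per gene in which the sample is
#' heterozygous for two or more distinct filtered variants
#' (phase-unaware: the two alleles are not required to be in trans).
#' A gene may yield both kinds.
#'
#' @param x A [CohortDataset-class], typically already consequence- and
#'   CADD-filtered.
#' @param sampleId the sample to inspect.
#' @return `data.frame` with columns `sample_id`, `gene`, `kind`
#'   (`"HOM_ALT"` or `"COMPOUND_HET"`) and list column `variant_keys`.
#' @export
qualifyingConfigurations <- function(x, sampleId) {
    if (!(sampleId %in% colnames(x)))
        stop("unknown sample '", sampleId, "'")
    keys <- variantKeys(x)
    genes <- toupper(SummarizedExperiment::rowData(x)$gene)
    st <- genotypeState(SummarizedExperiment::assay(x, "GT")[, sampleId])
    out <- list()
    for (g in unique(genes[st %in% c("HET", "HOM_ALT")])) {
        inGene <- genes == g
        homKeys <- keys[inGene & st == "HOM_ALT"]
        for (k in homKeys)
            out[[length(out) + 1L]] <- list(gene = g, kind = "HOM_ALT",
                                            variant_keys = k)
        hetKeys <- keys[inGene & st == "HET"]
        if (length(hetKeys) >= 2L)
            out[[length(out) + 1L]] <- list(gene = g, kind = "COMPOUND_HET",
                                            variant_keys = hetKeys)
    }
    res <- data.frame(sample_id = rep(sampleId, length(out)),
                      gene = vapply(out, `[[`, "", "gene"),
                      kind = vapply(out, `[[`, "", "kind"))
    res$variant_keys <- lapply(out, `[[`, "variant_keys")
    res
}

#' Stratum-exclusivity filter
#'
#' Retains a variant iff at least one protected-stratum sample carries
#' the alternate allele (heterozygous or homozygous-alternate) and no
#' sample of any other stratum does. Missing genotypes never count as
#' carriage; a missing genotype in a non-protected sample is treated as
#' absence, but every variant whose exclusivity rests on such a missing
#' call is flagged in the rowData column `exclusivity_uncertain` so the
#' decision stays auditable.
#'
#' @param x A [CohortDataset-class].
#' @param protectedStratum stratum label regarded as protected.
#' @return The filtered [CohortDataset-class], with logical rowData
#'   column `exclusivity_uncertain` on the retained rows.
#' @export
groupExclusive <- function(x, protectedStratum = "PROTECTED") {
    strata <- SummarizedExperiment::colData(x)$stratum
    prot <- strata == protectedStratum
    if (!any(prot))
        stop("no sample in protected stratum '", protectedStratum, "'")
    st <- genotypeStateMatrix(x)
    carrier <- st == "HET" | st == "HOM_ALT"
    inProt <- if (nrow(x)) rowSums(carrier[, prot, drop = FALSE]) > 0 else logical(0)
    inOther <- if (nrow(x)) rowSums(carrier[, !prot, drop = FALSE]) > 0 else logical(0)
    keep <- inProt & !inOther
    uncertain <- if (nrow(x))
        keep & rowSums(st[, !prot, drop = FALSE] == "MISSING") > 0
    else logical(0)
    out <- x[keep, ]
    SummarizedExperiment::rowData(out)$exclusivity_uncertain <-
        uncertain[keep]
    out
}

#' Candidate-gene intersection
#'
#' Retains variants whose gene symbol is in the candidate set
#' (case-insensitive).
#'
#' @param x A [CohortDataset-class].
#' @param genes non-empty character vector of gene symbols, e.g. from
#'   [readGeneList()].
#' @return The filtered [CohortDataset-class].
#' @export
intersectGenes <- function(x, genes) {
    if (!length(genes))
        stop("empty candidate gene set would discard every variant")
    x[toupper(SummarizedExperiment::rowData(x)$gene) %in% toupper(genes), ]
}

#' Run the full prioritization funnel
#'
#' Applies the six funnel stages in fixed order and returns a
#' [FunnelReport-class] with per-stage retained counts and variant keys.
#' The zygosity stage additionally records every qualifying configuration
#' of every protected sample, and the exclusivity stage records which
#' retained keys rest on a missing non-protected genotype.
#'
#' @param x A [CohortDataset-class].
#' @param genes candidate gene symbols (case-insensitive).
#' @param caddMin CADD PHRED threshold (strictly exceeded to pass).
#' @param allowedConsequences consequence classes passing stage 2.
#' @param stopgainExempt exempt stop-gain variants from the CADD filter.
#' @param protectedStratum stratum label regarded as protected.
#' @return A [FunnelReport-class].
#' @examples
#' vcf <- system.file("extdata", "toy_cohort.vcf", package = "protectscan")
#' meta <- system.file("extdata", "toy_metadata.tsv", package = "protectscan")
#' genes <- readGeneList(system.file("extdata", "toy_genes.txt",
#'                                   package = "protectscan"))
#' runFunnel(readCohortVcf(vcf, meta), genes)
#' @export
runFunnel <- function(x, genes, caddMin = 25,
                      allowedConsequences = .DEFAULT_CONSEQUENCES,
                      stopgainExempt = FALSE,
                      protectedStratum = "PROTECTED") {
    strata <- SummarizedExperiment::colData(x)$stratum
    protSamples <- colnames(x)[strata == protectedStratum]
    if (!length(protSamples))
        stop("no protected stratum: no sample is labelled '",
             protectedStratum, "'")

    ## stage 1: carried by >= 1 protected sample
    st <- genotypeStateMatrix(x)
    carrier <- st == "HET" | st == "HOM_ALT"
    s1 <- x[if (nrow(x))
        rowSums(carrier[, protSamples, drop = FALSE]) > 0 else logical(0), ]
    ## stage 2: consequence
    s2 <- filterConsequence(s1, allowedConsequences)
    ## stage 3: deleteriousness
    s3 <- filterDeleteriousness(s2, caddMin, stopgainExempt)
    ## stage 4: qualifying zygosity configurations among protected samples
    cfgs <- do.call(rbind, lapply(protSamples, function(s)
        qualifyingConfigurations(s3, s)))
    if (is.null(cfgs)) {
        cfgs <- data.frame(sample_id = character(0), gene = character(0),
                           kind = character(0))
        cfgs$variant_keys <- list()
    }
    qualKeys <- unique(unlist(cfgs$variant_keys))
    s4 <- s3[variantKeys(s3) %in% qualKeys, ]
    ## stage 5: exclusivity
    s5 <- groupExclusive(s4, protectedStratum)
    uncertain <- variantKeys(s5)[
        SummarizedExperiment::rowData(s5)$exclusivity_uncertain]
    ## stage 6: candidate genes
    s6 <- intersectGenes(s5, genes)

    keys <- list(variantKeys(s1), variantKeys(s2), variantKeys(s3),
                 variantKeys(s4), variantKeys(s5), variantKeys(s6))
    new("FunnelReport",
        stageNames = .FUNNEL_STAGES,
        counts = vapply(keys, length, 1L),
        keys = keys,
        configurations = cfgs,
        uncertainKeys = as.character(uncertain))
}
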