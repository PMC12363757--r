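## Genotype parsing and the biallelic variant model.
##
## Genotypes are kept as VCF strings throughout ("0/1", "1|0", "./."). All
## zygosity logic is phase-unaware: "|" is read but treated exactly like "/".
## A genotype with any missing allele (".") is MISSING as a whole; it is
## never silently coerced to homozygous reference.

## Parse a vector of diploid genotype strings into a 2-column matrix of
## allele indices (NA for "."). Errors name the offending entry.
.GT_REGEX <- "^(\\.|[0-9]+)[/|](\\.|[0-9]+)$"

.parseGT <- function(gt, what = "genotype") {
    nm <- names(gt)
    gt <- as.character(gt)
    ok <- !is.na(gt) & grepl(.GT_REGEX, gt)
    if (!all(ok)) {
        bad <- which(!ok)[1L]
        lab <- if (!is.null(nm)) nm[bad] else bad
        stop(sprintf("malformed %s '%s' (%s)", what, gt[bad], lab))
    }
    a <- sub("[/|].*$", "", gt)
    b <- sub("^.*[/|]", "", gt)
    cbind(suppressWarnings(as.integer(a)), suppressWarnings(as.integer(b)))
}

.stateFromAlleles <- function(al) {
    miss <- is.na(al[, 1L]) | is.na(al[, 2L])
    nalt <- al[, 1L] + al[, 2L]
    out <- rep("MISSING", nrow(al))
    out[!miss & nalt == 0L] <- "HOM_REF"
    out[!miss & nalt == 1L] <- "HET"
    out[!miss & nalt == 2L] <- "HOM_ALT"
    out
}

#' Classify diploid genotypes
#'
#' Maps biallelic VCF genotype strings to zygosity states. The order of
#' the two alleles and the phase separator are irrelevant; any genotype
#' containing a missing allele is `MISSING`.
#'
#' @param gt character vector of genotype strings over allele indices 0
#'   (reference) and 1 (alternate), e.g. `"0/1"`, `"1|1"`, `"./."`.
#' @return character vector over `HOM_REF`, `HET`, `HOM_ALT`, `MISSING`.
#' @examples
#' genotypeState(c("0/1", "1|0", "1/1", "./.", "0/0"))
#' @export
genotypeState <- function(gt) {
    if (!length(gt)) return(character(0))
    gtc <- as.character(gt)
    bad <- which(is.na(gtc) | !grepl(.GT_REGEX, gtc))
    if (length(bad)) {
        b <- bad[1L]
        lab <- if (!is.null(names(gt))) names(gt)[b] else b
        stop(sprintf("malformed genotype '%s' (%s)", gtc[b], lab))
    }
    ## classify each distinct string once, then look the results up
    u <- unique(gtc)
    al <- .parseGT(u)
    if (any(al > 1L, na.rm = TRUE))
        stop("genotype references an alternate allele index > 1; ",
             "split multiallelic records first")
    st <- .stateFromAlleles(al)
    st[match(gtc, u)]
}

#' Genotype-state matrix of a cohort
#'
#' @param x A [CohortDataset-class].
#' @return character matrix (variants x samples) of zygosity states.
#' @export
genotypeStateMatrix <- function(x) {
    gt <- SummarizedExperiment::assay(x, "GT")
    matrix(genotypeState(gt), nrow = nrow(gt), ncol = ncol(gt),
           dimnames = dimnames(gt))
}

#' Variant keys
#'
#' Canonical `"chrom:pos:ref:alt"` identifiers of the variants of a
#' cohort, used throughout funnel reports.
#'
#' @param x A [CohortDataset-class].
#' @return character vector, one key per variant row.
#' @export
variantKeys <- function(x) {
    rd <- SummarizedExperiment::rowData(x)
    paste(rd$chrom, rd$pos, rd$ref, rd$alt, sep = ":")
}

#' Split a multiallelic variant record into biallelic records
#'
#' Decomposes a raw VCF-style record with `k` alternate alleles into `k`
#' biallelic records. In the record for alternate allele `i`, each
#' original allele index maps to 1 if it equals `i` and to 0 otherwise;
#' missing alleles stay missing. Phase separators are normalized to `/`.
#'
#' @param record a list with fields `chrom`, `pos`, `ref`,
#'   `alt` (character vector of `k >= 1` alternates), `gt` (named
#'   character vector of genotype strings, one per sample), and
#'   optionally `rsid`, `gene`, `consequence`, `cadd`.
#' @return list of `k` records of the same shape, each with a single
#'   `alt` and remapped genotypes.
#' @examples
#' rec <- list(chrom = "1", pos = 200L, ref = "C", alt = c("T", "G"),
#'             gt = c(S1 = "1/2", S2 = "0/1", S3 = "./."))
#' splitMultiallelic(rec)
#' @export
splitMultiallelic <- function(record) {
    stopifnot(is.list(record), length(record$alt) >= 1L)
    al <- .parseGT(record$gt, what = sprintf("genotype at %s:%s",
                                             record$chrom, record$pos))
    lapply(seq_along(record$alt), function(i) {
        a1 <- ifelse(is.na(al[, 1L]), ".", ifelse(al[, 1L] == i, "1", "0"))
        a2 <- ifelse(is.na(al[, 2L]), ".", ifelse(al[, 2L] == i, "1", "0"))
        out <- record
        out$alt <- record$alt[[i]]
        out$gt <- stats::setNames(paste0(a1, "/", a2), names(record$gt))
        out
    })
}
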