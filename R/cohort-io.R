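## Cohort I/O: VCF + metadata in, reports out.
##
## Annotation dialect: one variant-level INFO key each for the gene symbol
## (GENE), the consequence class (CSQ_CLASS) and the CADD PHRED score
## (CADD). Input annotated with a full VEP-style CSQ string must be
## reduced to these keys upstream (e.g. `bcftools +split-vep`); the reader
## is the single adapter point. A missing CADD key is stored as NA —
## "score absent" — which the deleteriousness filter treats differently
## from a score of 0.

#' Read an annotated multi-sample VCF and its sample metadata
#'
#' Reads a VCF (v4.2, plain or bgzipped) carrying per-variant INFO keys
#' `GENE`, `CSQ_CLASS` and `CADD`, together with a sample-metadata TSV,
#' into a [CohortDataset-class]. Multiallelic records are split into
#' biallelic records on the way in (see [splitMultiallelic()]). The VCF
#' sample set and the metadata `sample_id` column must match exactly;
#' any mismatch is fatal and reports the symmetric difference.
#'
#' @param path VCF file.
#' @param metadataPath tab-separated metadata with columns `sample_id`,
#'   `stratum`, optionally `aao_years` and numeric covariate columns.
#' @param genome genome label recorded on the parsed ranges.
#' @return A [CohortDataset-class] with all records biallelic.
#' @examples
#' vcf <- system.file("extdata", "toy_cohort.vcf", package = "protectscan")
#' meta <- system.file("extdata", "toy_metadata.tsv", package = "protectscan")
#' readCohortVcf(vcf, meta)
#' @export
readCohortVcf <- function(path, metadataPath, genome = "unknown") {
    meta <- readSampleMetadata(metadataPath)
    vcf <- VariantAnnotation::readVcf(path, genome = genome)
    vcfSamples <- rownames(SummarizedExperiment::colData(vcf))
    if (!setequal(vcfSamples, meta$sample_id) ||
        anyDuplicated(meta$sample_id)) {
        onlyVcf <- setdiff(vcfSamples, meta$sample_id)
        onlyMeta <- setdiff(meta$sample_id, vcfSamples)
        stop("VCF header and metadata sample sets differ; only in VCF: {",
             paste(onlyVcf, collapse = ", "), "}; only in metadata: {",
             paste(onlyMeta, collapse = ", "), "}")
    }
    meta <- meta[match(vcfSamples, meta$sample_id), , drop = FALSE]

    rr <- SummarizedExperiment::rowRanges(vcf)
    chrom <- as.character(GenomicRanges::seqnames(rr))
    pos <- GenomicRanges::start(rr)
    ref <- as.character(VariantAnnotation::ref(vcf))
    altList <- VariantAnnotation::alt(vcf)
    nAlt <- S4Vectors::elementNROWS(altList)
    info <- VariantAnnotation::info(vcf)
    gene <- if ("GENE" %in% colnames(info)) as.character(info$GENE)
            else rep(NA_character_, length(rr))
    csq <- if ("CSQ_CLASS" %in% colnames(info)) as.character(info$CSQ_CLASS)
           else rep(NA_character_, length(rr))
    cadd <- if ("CADD" %in% colnames(info)) as.numeric(info$CADD)
            else rep(NA_real_, length(rr))
    csq[is.na(csq)] <- "other"
    gene[is.na(gene)] <- ""
    ## readVcf names unidentified records "chrom:pos_REF/ALT"
    ids <- names(rr)
    rsid <- ifelse(is.na(ids) | ids == "." |
                   startsWith(ids, paste0(chrom, ":", pos, "_")),
                   NA_character_, ids)
    gt <- VariantAnnotation::geno(vcf)$GT
    if (is.null(gt)) stop("VCF carries no GT genotypes")

    rows <- vector("list", length(rr))
    gtRows <- vector("list", length(rr))
    for (j in seq_along(rr)) {
        rec <- list(chrom = chrom[j], pos = pos[j], ref = ref[j],
                    alt = as.character(altList[[j]]),
                    gt = stats::setNames(gt[j, ], vcfSamples))
        split <- splitMultiallelic(rec)
        rows[[j]] <- data.frame(
            chrom = chrom[j], pos = pos[j], ref = ref[j],
            alt = vapply(split, `[[`, "", "alt"),
            rsid = rsid[j], gene = gene[j], consequence = csq[j],
            cadd = cadd[j])
        gtRows[[j]] <- do.call(rbind, lapply(split, `[[`, "gt"))
    }
    variants <- do.call(rbind, rows)
    gtMat <- do.call(rbind, gtRows)
    if (is.null(variants)) {
        variants <- data.frame(chrom = character(0), pos = integer(0),
                               ref = character(0), alt = character(0),
                               rsid = character(0), gene = character(0),
                               consequence = character(0), cadd = numeric(0))
        gtMat <- matrix(character(0), nrow = 0, ncol = length(vcfSamples),
                        dimnames = list(NULL, vcfSamples))
    }
    colnames(gtMat) <- vcfSamples
    CohortDataset(variants, gtMat, meta)
}

#' Read a sample-metadata table
#'
#' @param path TSV with columns `sample_id`, `stratum`, optionally
#'   `aao_years` and numeric covariate columns.
#' @return `data.frame` with one row per sample.
#' @export
readSampleMetadata <- function(path) {
    meta <- utils::read.delim(path, stringsAsFactors = FALSE,
                              check.names = FALSE)
    need <- c("sample_id", "stratum")
    miss <- setdiff(need, colnames(meta))
    if (length(miss))
        stop("metadata lacks column(s): ", paste(miss, collapse = ", "))
    if ("aao_years" %in% colnames(meta))
        meta$aao_years <- as.numeric(meta$aao_years)
    meta
}

#' Read a candidate-gene list
#'
#' One gene symbol per line; `#` starts a comment; blank lines are
#' skipped. Symbols are upper-cased and de-duplicated so that matching is
#' case-insensitive. An empty list is an error — as a funnel filter it
#' would silently discard every variant.
#'
#' @param path text file of gene symbols.
#' @return character vector of unique upper-case symbols.
#' @examples
#' f <- tempfile(); writeLines(c("# candidates", "GAK", "gak", "DNAJC6"), f)
#' readGeneList(f)
#' @export
readGeneList <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    symbols <- unique(toupper(lines[nzchar(lines)]))
    if (!length(symbols))
        stop("gene list '", path, "' contains no symbols; an empty ",
             "candidate filter would discard every variant")
    symbols
}

#' Read gnomAD-style reference genotype counts
#'
#' @param path TSV with columns `population`, `hom_alt_individuals`,
#'   `total_alleles` (optionally `het_individuals`,
#'   `hom_ref_individuals`).
#' @return list of [ReferenceCounts-class], named by population.
#' @examples
#' f <- system.file("extdata", "gnomad_style_counts.tsv",
#'                  package = "protectscan")
#' readReferenceCounts(f)
#' @export
readReferenceCounts <- function(path) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("population", "hom_alt_individuals", "total_alleles")
    miss <- setdiff(need, colnames(tab))
    if (length(miss))
        stop("reference counts lack column(s): ", paste(miss, collapse = ", "))
    out <- lapply(seq_len(nrow(tab)), function(i)
        referenceCounts(tab$population[i], tab$hom_alt_individuals[i],
                        tab$total_alleles[i],
                        if ("het_individuals" %in% colnames(tab))
                            tab$het_individuals[i] else NA_integer_,
                        if ("hom_ref_individuals" %in% colnames(tab))
                            tab$hom_ref_individuals[i] else NA_integer_))
    stats::setNames(out, tab$population)
}

#' Write a cohort to VCF and metadata TSV
#'
#' Serializes a [CohortDataset-class] as a VCF v4.2 with the package's
#' annotation dialect (INFO keys `GENE`, `CSQ_CLASS`, `CADD`; FORMAT
#' `GT`), plus an optional metadata TSV. The output is deterministic for
#' a given dataset, so identically seeded simulations serialize to
#' byte-identical files (apart from the VCF `fileDate` header line, which
#' records the calendar date).
#'
#' @param x A [CohortDataset-class].
#' @param path output VCF path.
#' @param metadataPath optional output TSV path for the sample table.
#' @return `path`, invisibly.
#' @export
writeCohortVcf <- function(x, path, metadataPath = NULL) {
    rd <- SummarizedExperiment::rowData(x)
    samples <- colnames(x)
    gr <- GenomicRanges::GRanges(rd$chrom,
                                 IRanges::IRanges(rd$pos, width = nchar(rd$ref)))
    names(gr) <- ifelse(is.na(rd$rsid), ".", rd$rsid)
    hdr <- VariantAnnotation::VCFHeader(samples = samples)
    VariantAnnotation::meta(hdr) <- DataFrameList(
        fileformat = DataFrame(Value = "VCFv4.2", row.names = "fileformat"))
    VariantAnnotation::geno(hdr) <- DataFrame(
        Number = "1", Type = "String", Description = "Genotype",
        row.names = "GT")
    VariantAnnotation::info(hdr) <- DataFrame(
        Number = c("1", "1", "1"),
        Type = c("String", "String", "Float"),
        Description = c("Gene symbol", "Consequence class",
                        "CADD PHRED deleteriousness score"),
        row.names = c("GENE", "CSQ_CLASS", "CADD"))
    vcf <- VariantAnnotation::VCF(
        rowRanges = gr,
        colData = DataFrame(Samples = seq_along(samples),
                            row.names = samples),
        exptData = list(header = hdr),
        fixed = DataFrame(
            REF = Biostrings::DNAStringSet(rd$ref),
            ALT = Biostrings::DNAStringSetList(as.list(rd$alt)),
            QUAL = rep(NA_real_, nrow(x)),
            FILTER = rep(".", nrow(x))),
        info = DataFrame(GENE = rd$gene, CSQ_CLASS = rd$consequence,
                         CADD = rd$cadd),
        geno = SimpleList(GT = SummarizedExperiment::assay(x, "GT")))
    VariantAnnotation::writeVcf(vcf, path)
    if (!is.null(metadataPath)) {
        cd <- as.data.frame(SummarizedExperiment::colData(x))
        out <- cbind(sample_id = colnames(x), cd)
        utils::write.table(out, metadataPath, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    }
    invisible(path)
}

## ---------------------------------------------------------------------------
## Funnel report serialization
## ---------------------------------------------------------------------------

#' Write / read a funnel report
#'
#' `writeFunnelReport()` emits two files under `dir`: a two-column TSV
#' `funnel_stages.tsv` (stage, count) for quick inspection, and a JSON
#' `funnel_report.json` carrying the retained variant keys per stage, the
#' qualifying configurations and the exclusivity-uncertain keys.
#' `readFunnelReport()` reconstructs the identical [FunnelReport-class]
#' from that directory.
#'
#' @param report A [FunnelReport-class].
#' @param dir output (input) directory; created if absent.
#' @return `writeFunnelReport()` returns `dir` invisibly;
#'   `readFunnelReport()` returns the [FunnelReport-class].
#' @export
writeFunnelReport <- function(report, dir) {
    stopifnot(is(report, "FunnelReport"))
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    tsv <- data.frame(stage = report@stageNames, count = report@counts)
    utils::write.table(tsv, file.path(dir, "funnel_stages.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    cfg <- report@configurations
    cfgList <- lapply(seq_len(nrow(cfg)), function(i)
        list(sample_id = cfg$sample_id[i], gene = cfg$gene[i],
             kind = cfg$kind[i],
             variant_keys = as.list(cfg$variant_keys[[i]])))
    payload <- list(
        stages = lapply(seq_along(report@stageNames), function(i)
            list(stage = report@stageNames[i],
                 count = report@counts[i],
                 retained_keys = as.list(report@keys[[i]]))),
        configurations = cfgList,
        uncertain_keys = as.list(report@uncertainKeys))
    jsonlite::write_json(payload, file.path(dir, "funnel_report.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    invisible(dir)
}

#' @rdname writeFunnelReport
#' @export
readFunnelReport <- function(dir) {
    payload <- jsonlite::read_json(file.path(dir, "funnel_report.json"))
    stages <- payload$stages
    keys <- lapply(stages, function(s)
        as.character(unlist(s$retained_keys)))
    cfg <- payload$configurations
    configurations <- data.frame(
        sample_id = vapply(cfg, function(q) q$sample_id, ""),
        gene = vapply(cfg, function(q) q$gene, ""),
        kind = vapply(cfg, function(q) q$kind, ""))
    configurations$variant_keys <- lapply(cfg, function(q)
        as.character(unlist(q$variant_keys)))
    new("FunnelReport",
        stageNames = vapply(stages, function(s) s$stage, ""),
        counts = vapply(stages, function(s) as.integer(s$count), 1L),
        keys = keys,
        configurations = configurations,
        uncertainKeys = as.character(unlist(payload$uncertain_keys)))
}
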