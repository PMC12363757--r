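## Shared fixtures and independent oracles for the test suite.

toyVcf <- function() system.file("extdata", "toy_cohort.vcf",
                                 package = "protectscan")
toyMeta <- function() system.file("extdata", "toy_metadata.tsv",
                                  package = "protectscan")
toyGenes <- function() system.file("extdata", "toy_genes.txt",
                                   package = "protectscan")

readToyCohort <- function() readCohortVcf(toyVcf(), toyMeta())

## Random small cohort built directly from parts (independent of the
## exome generator), with missing genotypes mixed in.
randomCohort <- function(nVariants = 25, strata = c("PROTECTED", "PROTECTED",
                                                    "CASE_MUTANT", "CASE_MUTANT",
                                                    "CASE_IDIOPATHIC", "CONTROL"),
                         nGenes = 6, pMissing = 0.05) {
    ns <- length(strata)
    ids <- sprintf("S%02d", seq_len(ns))
    gtPool <- c("0/0", "0/1", "1/0", "1/1")
    gt <- matrix(sample(gtPool, nVariants * ns, replace = TRUE,
                        prob = c(0.55, 0.17, 0.08, 0.2)),
                 nrow = nVariants, dimnames = list(NULL, ids))
    gt[sample(length(gt), round(pMissing * length(gt)))] <- "./."
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, nVariants, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
    variants <- data.frame(
        chrom = as.character(sample(1:5, nVariants, replace = TRUE)),
        pos = sample.int(1e6, nVariants),
        ref = ref, alt = alt,
        gene = sprintf("G%02d", sample.int(nGenes, nVariants, replace = TRUE)),
        consequence = sample(consequenceClasses(), nVariants, replace = TRUE),
        cadd = ifelse(runif(nVariants) < 0.1, NA_real_,
                      runif(nVariants, 0, 50)))
    samples <- data.frame(
        sample_id = ids, stratum = strata,
        aao_years = ifelse(strata %in% c("CASE_MUTANT", "CASE_IDIOPATHIC"),
                           round(runif(ns, 40, 80)), NA_real_))
    CohortDataset(variants, gt, samples)
}

## ---------------------------------------------------------------------
## Independent oracles
## ---------------------------------------------------------------------

## Naive per-sample, per-gene enumeration of qualifying configurations,
## parsing genotype strings character by character.
bruteForceConfigs <- function(x, sampleId) {
    gt <- SummarizedExperiment::assay(x, "GT")[, sampleId]
    rd <- SummarizedExperiment::rowData(x)
    keys <- paste(rd$chrom, rd$pos, rd$ref, rd$alt, sep = ":")
    state <- character(length(gt))
    for (i in seq_along(gt)) {
        parts <- strsplit(gt[[i]], "[/|]")[[1]]
        if (any(parts == ".")) state[i] <- "MISSING"
        else state[i] <- c("HOM_REF", "HET", "HOM_ALT")[
            sum(as.integer(parts)) + 1L]
    }
    out <- list()
    for (g in unique(toupper(rd$gene))) {
        idx <- which(toupper(rd$gene) == g)
        for (i in idx)
            if (state[i] == "HOM_ALT")
                out[[length(out) + 1L]] <- list(gene = g, kind = "HOM_ALT",
                                                keys = keys[i])
        hets <- idx[state[idx] == "HET"]
        if (length(hets) >= 2)
            out[[length(out) + 1L]] <- list(gene = g, kind = "COMPOUND_HET",
                                            keys = keys[hets])
    }
    out
}

## canonical string form of a configuration set, for set comparison
canonConfigs <- function(lst) {
    if (!length(lst)) return(character(0))
    sort(vapply(lst, function(q)
        paste(q$gene, q$kind, paste(sort(q$keys), collapse = ","),
              sep = "|"), ""))
}

canonConfigsDf <- function(df) {
    if (!nrow(df)) return(character(0))
    sort(vapply(seq_len(nrow(df)), function(i)
        paste(df$gene[i], df$kind[i],
              paste(sort(df$variant_keys[[i]]), collapse = ","),
              sep = "|"), ""))
}

## closed-form OLS via the normal equations
olsOracle <- function(y, X) {
    XtX <- crossprod(X)
    beta <- solve(XtX, crossprod(X, y))
    res <- y - X %*% beta
    df <- length(y) - ncol(X)
    sigma2 <- sum(res^2) / df
    se <- sqrt(diag(solve(XtX)) * sigma2)
    t <- as.vector(beta) / se
    list(beta = as.vector(beta), se = se, t = t,
         p = 2 * pt(-abs(t), df), df = df)
}

## exhaustive hypergeometric enumeration of the two-sided Fisher p for a
## 2x2 table (sum of probabilities of tables as or less probable)
fisherEnumOracle <- function(tab) {
    m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
    xs <- max(0, k - n):min(k, m)
    probs <- dhyper(xs, m, n, k)
    pObs <- dhyper(tab[1, 1], m, n, k)
    sum(probs[probs <= pObs * (1 + 1e-7)])
}
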