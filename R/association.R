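## Genotype-coded association of a variant with age at onset, and
## genotype-frequency comparisons against reference populations.

#' Encode genotype states as model dosages
#'
#' Additive coding counts alternate alleles (0/1/2); dominant coding is 1
#' for any carrier; recessive coding is 1 only for homozygous-alternate
#' genotypes. `MISSING` propagates as `NA`.
#'
#' @param state character vector over `HOM_REF`, `HET`, `HOM_ALT`,
#'   `MISSING` (see [genotypeState()]).
#' @param model `"ADDITIVE"`, `"DOMINANT"` or `"RECESSIVE"`.
#' @return integer dosage vector with `NA` for missing genotypes.
#' @examples
#' encodeDosage(c("HOM_REF", "HET", "HOM_ALT", "MISSING"), "RECESSIVE")
#' @export
encodeDosage <- function(state, model = c("RECESSIVE", "DOMINANT", "ADDITIVE")) {
    model <- match.arg(model)
    bad <- setdiff(unique(state), .GT_STATES)
    if (length(bad))
        stop("unknown genotype state(s): ", paste(bad, collapse = ", "))
    map <- switch(model,
        ADDITIVE  = c(HOM_REF = 0L, HET = 1L, HOM_ALT = 2L, MISSING = NA_integer_),
        DOMINANT  = c(HOM_REF = 0L, HET = 1L, HOM_ALT = 1L, MISSING = NA_integer_),
        RECESSIVE = c(HOM_REF = 0L, HET = 0L, HOM_ALT = 1L, MISSING = NA_integer_))
    unname(map[state])
}

#' Linear model of age at onset on genotype dosage
#'
#' Ordinary least squares of AAO (years) on a genotype dosage, with
#' optional covariates. Samples with missing dosage or missing AAO are
#' dropped pairwise and counted. The dosage coefficient is tested with a
#' two-sided t-test. If, after dropping, the dosage has no variance
#' (e.g. no homozygous-alternate carrier under recessive coding), a
#' degenerate result is returned rather than an error — this is the
#' expected outcome for rare protective genotypes in small cohorts.
#'
#' @param aao numeric vector of ages at onset (years).
#' @param dosage integer dosage vector (see [encodeDosage()]); `NA` =
#'   missing genotype.
#' @param covariates optional numeric matrix or data.frame of covariates,
#'   one row per sample.
#' @param model label stored on the result (coding under which `dosage`
#'   was produced).
#' @return A [RegressionResult-class].
#' @examples
#' fitAao(c(50, 60, 50, 60), c(0, 0, 1, 1))
#' @export
fitAao <- function(aao, dosage, covariates = NULL, model = "RECESSIVE") {
    stopifnot(length(aao) == length(dosage))
    dat <- data.frame(aao = as.numeric(aao), dosage = as.numeric(dosage))
    if (!is.null(covariates)) {
        covariates <- as.data.frame(covariates)
        stopifnot(nrow(covariates) == length(aao))
        dat <- cbind(dat, covariates)
    }
    keep <- stats::complete.cases(dat)
    nDropped <- sum(!keep)
    dat <- dat[keep, , drop = FALSE]
    n <- nrow(dat)
    p <- ncol(dat)  # intercept + dosage + covariates
    degenerate <- function() new("RegressionResult", model = model,
        beta = NA_real_, se = NA_real_, tStat = NA_real_, p = NA_real_,
        n = as.integer(n), df = NA_integer_, nDropped = as.integer(nDropped),
        covariateBetas = stats::setNames(numeric(0), character(0)),
        degenerate = TRUE)
    if (n < p + 1L || length(unique(dat$dosage)) < 2L)
        return(degenerate())
    fit <- stats::lm(aao ~ ., data = dat)
    sm <- summary(fit)$coefficients
    if (!("dosage" %in% rownames(sm)) ||
        is.na(sm["dosage", "Estimate"]) || is.na(sm["dosage", "Std. Error"]))
        return(degenerate())
    covNames <- setdiff(rownames(sm), c("(Intercept)", "dosage"))
    new("RegressionResult", model = model,
        beta = unname(sm["dosage", "Estimate"]),
        se = unname(sm["dosage", "Std. Error"]),
        tStat = unname(sm["dosage", "t value"]),
        p = unname(sm["dosage", "Pr(>|t|)"]),
        n = as.integer(n),
        df = as.integer(fit$df.residual),
        nDropped = as.integer(nDropped),
        covariateBetas = stats::setNames(sm[covNames, "Estimate"], covNames),
        degenerate = FALSE)
}

#' Genotype-coded association table across models
#'
#' Convenience wrapper fitting the AAO linear model under each requested
#' coding for one variant, mirroring the three-model association-table
#' layout (per-genotype counts, effect, SE, p).
#'
#' @param state genotype states of the cohort (see [genotypeState()]).
#' @param aao ages at onset (years), same length.
#' @param covariates optional covariates (see [fitAao()]).
#' @param models codings to fit.
#' @return `data.frame` with one row per model: genotype-class counts,
#'   `beta`, `se`, `t`, `p`, `n`, `degenerate`.
#' @export
associationTable <- function(state, aao, covariates = NULL,
                             models = c("ADDITIVE", "DOMINANT", "RECESSIVE")) {
    counts <- table(factor(state, levels = .GT_STATES))
    do.call(rbind, lapply(models, function(m) {
        r <- fitAao(aao, encodeDosage(state, m), covariates, model = m)
        data.frame(model = m,
                   n_hom_ref = as.integer(counts["HOM_REF"]),
                   n_het = as.integer(counts["HET"]),
                   n_hom_alt = as.integer(counts["HOM_ALT"]),
                   n_missing = as.integer(counts["MISSING"]),
                   beta = r@beta, se = r@se, t = r@tStat, p = r@p,
                   n = r@n, degenerate = r@degenerate)
    }))
}

#' Genotype-frequency comparison between a cohort and a reference
#'
#' Tests a 2 x k table of genotype-class counts (cohort row vs reference
#' row). Uses the Pearson chi-square test without continuity correction,
#' switching to Fisher's exact test whenever any expected cell count
#' falls below 5.
#'
#' @param caseCounts integer vector of k genotype-class counts (k = 2 or
#'   3) in the study cohort.
#' @param referenceCounts integer vector of the same k class counts in
#'   the reference cohort.
#' @return A [FrequencyTestResult-class].
#' @examples
#' genotypeFrequencyTest(c(227, 6), c(2910, 58))
#' @export
genotypeFrequencyTest <- function(caseCounts, referenceCounts) {
    k <- length(caseCounts)
    stopifnot(k %in% c(2L, 3L), length(referenceCounts) == k)
    tab <- rbind(cohort = as.integer(caseCounts),
                 reference = as.integer(referenceCounts))
    if (any(tab < 0)) stop("counts must be non-negative")
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
        stop("every table margin must be positive")
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected < 5)) {
        ft <- stats::fisher.test(tab)
        new("FrequencyTestResult", table = tab, statistic = NA_real_,
            p = ft$p.value, method = "FISHER_EXACT")
    } else {
        ct <- stats::chisq.test(tab, correct = FALSE)
        new("FrequencyTestResult", table = tab,
            statistic = unname(ct$statistic), p = ct$p.value,
            method = "CHI_SQUARE")
    }
}

#' Homozygote frequency from gnomAD-style allele counts
#'
#' gnomAD describes populations by total allele number; the number of
#' individuals is `totalAlleles / 2`. The homozygote frequency is the
#' number of homozygous-alternate individuals divided by the number of
#' individuals.
#'
#' @param counts A [ReferenceCounts-class], or the number of
#'   homozygous-alternate individuals.
#' @param totalAlleles total allele number (even), when `counts` is
#'   given as a number.
#' @return fraction of individuals homozygous for the alternate allele.
#' @examples
#' homozygoteFrequency(referenceCounts("overall", 2812, 280488))
#' percentHalfUp(homozygoteFrequency(979, 35218))
#' @export
homozygoteFrequency <- function(counts, totalAlleles = NULL) {
    if (is(counts, "ReferenceCounts")) {
        hom <- counts@homAltIndividuals
        totalAlleles <- counts@totalAlleles
    } else {
        hom <- counts
        counts <- referenceCounts("ad hoc", hom, totalAlleles)  # validates
    }
    hom / (totalAlleles / 2)
}

#' Cohort homozygote fraction
#'
#' @param nHom number of homozygous-alternate individuals in the cohort.
#' @param nTotal cohort size (individuals).
#' @return `nHom / nTotal`.
#' @examples
#' percentHalfUp(cohortHomozygoteFraction(6, 233))
#' @export
cohortHomozygoteFraction <- function(nHom, nTotal) {
    stopifnot(nTotal > 0, nHom >= 0, nHom <= nTotal)
    nHom / nTotal
}

#' Round a fraction to a percent, half-up
#'
#' Reporting helper: converts a fraction to percent and rounds half-up
#' (2.575 -> 2.58), the convention of clinical reporting, rather than
#' R's round-half-to-even.
#'
#' @param fraction numeric fraction(s) in \[0, 1\].
#' @param digits decimal places to keep.
#' @return numeric percent value(s).
#' @examples
#' percentHalfUp(6 / 233)  # 2.58
#' @export
percentHalfUp <- function(fraction, digits = 2) {
    scale <- 10^digits
    ## nudge by an ulp-scale epsilon so that values decimally exactly at
    ## .5 but stored just below it still round up
    x <- fraction * 100 * scale
    floor(x + 0.5 + sign(x) * .Machine$double.eps * abs(x)) / scale
}
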