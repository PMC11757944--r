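#' Allele-count table for a biallelic variant, by sex
#'
#' Counts reference (allele1) and alternate (allele2) alleles per sex over
#' non-missing genotypes. Missing genotypes contribute nothing.
#'
#' @param dosages_f,dosages_m integer dosage vectors (codes 0/1/2/NA) for
#'   female and male samples.
#' @return 2x2 integer matrix, rows `female`/`male`, columns
#'   `allele1`/`allele2`; each row sums to twice the non-missing genotype
#'   count in that sex.
#' @examples
#' allele_count_table(rep(1L, 40), rep(0L, 40))
#' @export
allele_count_table <- function(dosages_f, dosages_m) {
  check_dosages(dosages_f); check_dosages(dosages_m)
  nf <- sum(!is.na(dosages_f)); nm <- sum(!is.na(dosages_m))
  if (nf == 0) stop("no non-missing genotypes in female group")
  if (nm == 0) stop("no non-missing genotypes in male group")
  a2f <- sum(dosages_f, na.rm = TRUE); a2m <- sum(dosages_m, na.rm = TRUE)
  matrix(c(2 * nf - a2f, 2 * nm - a2m, a2f, a2m), nrow = 2,
         dimnames = list(c("female", "male"), c("allele1", "allele2")))
}

check_dosages <- function(d) {
  if (!all(d %in% c(0L, 1L, 2L, NA))) stop("dosage codes must be in {0,1,2,NA}")
  invisible(d)
}

#' Allelic chi-square test on a 2x2 allele-count table
#'
#' The basic 1-df Pearson chi-square on allele counts (the classic allelic
#' case-control association test), without continuity correction. The
#' statistic is evaluated in the closed form
#' \deqn{\chi^2 = N (ad - bc)^2 / (r_1 r_2 c_1 c_2)}
#' and the p-value is the upper-tail chi-square(1) probability. If either
#' allele is absent from both sexes combined (monomorphic site) the test
#' is undefined and `NA` is returned for both values.
#'
#' @param table non-negative 2x2 count matrix (sexes x alleles).
#' @return named numeric vector `c(chi2 = , p = )` (both `NA` when
#'   monomorphic).
#' @examples
#' allelic_chisq(matrix(c(40, 80, 40, 0), 2))  # fully sex-linked, 40F/40M
#' @export
allelic_chisq <- function(table) {
  stopifnot(identical(dim(as.matrix(table)), c(2L, 2L)))
  tab <- as.matrix(table)
  if (any(tab < 0)) stop("counts must be non-negative")
  if (any(colSums(tab) == 0)) return(c(chi2 = NA_real_, p = NA_real_))
  n <- sum(tab)
  num <- n * (tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1])^2
  den <- prod(rowSums(tab)) * prod(colSums(tab))
  chi2 <- num / den
  c(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Genome-wide allelic association of binary sex
#'
#' Runs the allelic chi-square test at every variant and assigns
#' significance tiers against fixed genome-wide thresholds (no
#' multiple-testing correction; the thresholds are the contract):
#' `significant` (p < `sig`), `suggestive` (`sig` <= p < `sugg`), `ns`.
#' Monomorphic variants are flagged `undefined`, never silently dropped,
#' and excluded from tier counts.
#'
#' @param gm a QC-filtered [genotype_matrix()].
#' @param sheet a [sample_sheet()] with both sexes present.
#' @param sig,sugg significance / suggestive p-value thresholds
#'   (defaults 1e-8 and 1e-4).
#' @return data.frame of class `assoc_result` with one row per variant:
#'   `chrom, pos, id, a1_f, a2_f, a1_m, a2_m, chi2, p, tier`; attribute
#'   `summary` holds the tier counts and the per-chromosome count of
#'   significant variants; attribute `thresholds` echoes `sig`/`sugg`.
#' @export
run_gwas <- function(gm, sheet, sig = 1e-8, sugg = 1e-4) {
  idx <- sex_index(sheet, gm$samples)
  if (length(idx$female) == 0 || length(idx$male) == 0) {
    stop("both sexes must be present")
  }
  D <- gm$dosage
  cnt <- sex_allele_counts(D, idx)
  with(cnt, {
    mono <- (a2f + a2m == 0) | (a1f + a1m == 0)
    n <- a1f + a2f + a1m + a2m
    num <- n * (a1f * a2m - a2f * a1m)^2
    den <- (a1f + a2f) * (a1m + a2m) * (a1f + a1m) * (a2f + a2m)
    chi2 <- ifelse(mono, NA_real_, num / den)
    p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
    tier <- ifelse(is.na(p), "undefined",
                   ifelse(p < sig, "significant",
                          ifelse(p < sugg, "suggestive", "ns")))
    res <- data.frame(gm$variants[, c("chrom", "pos", "id")],
                      a1_f = a1f, a2_f = a2f, a1_m = a1m, a2_m = a2m,
                      chi2 = chi2, p = p, tier = tier,
                      stringsAsFactors = FALSE, row.names = NULL)
    sig_chrom <- table(res$chrom[res$tier == "significant"])
    attr(res, "summary") <- list(
      n_variants = nrow(res),
      n_significant = sum(tier == "significant"),
      n_suggestive = sum(tier == "suggestive"),
      n_undefined = sum(tier == "undefined"),
      significant_by_chrom = sig_chrom)
    attr(res, "thresholds") <- c(sig = sig, sugg = sugg)
    class(res) <- c("assoc_result", "data.frame")
    res
  })
}

sex_allele_counts <- function(D, idx) {
  Df <- D[idx$female, , drop = FALSE]
  Dm <- D[idx$male, , drop = FALSE]
  nf <- colSums(!is.na(Df)); nm <- colSums(!is.na(Dm))
  if (ncol(D) > 0 && (any(nf == 0) || any(nm == 0))) {
    stop("variant(s) with all genotypes missing in one sex; QC-filter first")
  }
  a2f <- colSums(Df, na.rm = TRUE); a2m <- colSums(Dm, na.rm = TRUE)
  list(a1f = 2 * nf - a2f, a2f = a2f, a1m = 2 * nm - a2m, a2m = a2m)
}

#' Expected-vs-observed quantiles for a QQ plot
#'
#' @param pvalues p-values in (0, 1].
#' @return data.frame with `expected` and `observed` -log10 quantiles,
#'   aligned by rank: observed sorted descending, expected rank `i` equal
#'   to `-log10((i - 0.5) / n)`.
#' @export
qq_data <- function(pvalues) {
  pvalues <- as.numeric(pvalues)
  if (length(pvalues) == 0) {
    return(data.frame(expected = numeric(0), observed = numeric(0)))
  }
  if (any(is.na(pvalues)) || any(pvalues <= 0) || any(pvalues > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  n <- length(pvalues)
  data.frame(expected = -log10((seq_len(n) - 0.5) / n),
             observed = sort(-log10(pvalues), decreasing = TRUE))
}
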