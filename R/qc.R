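#' SNP quality-control thresholds
#'
#' Defaults mirror a standard vcftools-style hard-filter set for ~10x
#' re-sequencing data: `--maf 0.05 --min-meanDP 6 --max-meanDP 300
#' --minGQ 20 --max-missing 0.9 --min-alleles 2 --max-alleles 2`.
#' `min_call_rate` is the vcftools `--max-missing` convention: the value is
#' the minimum proportion of non-missing genotypes required at a site.
#'
#' @param min_maf minimum minor-allele frequency over non-missing calls.
#' @param min_mean_depth,max_mean_depth bounds on the per-site mean of
#'   per-genotype DP over non-missing genotypes.
#' @param min_gq per-genotype quality below which a call is set missing.
#' @param min_call_rate minimum fraction of non-missing genotypes.
#' @param biallelic_only keep biallelic SNPs only (enforced at VCF read).
#' @return a list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_maf = 0.05, min_mean_depth = 6,
                          max_mean_depth = 300, min_gq = 20,
                          min_call_rate = 0.9, biallelic_only = TRUE) {
  stopifnot(min_maf >= 0, min_maf <= 0.5,
            min_mean_depth <= max_mean_depth,
            min_call_rate >= 0, min_call_rate <= 1)
  structure(list(min_maf = min_maf, min_mean_depth = min_mean_depth,
                 max_mean_depth = max_mean_depth, min_gq = min_gq,
                 min_call_rate = min_call_rate,
                 biallelic_only = biallelic_only),
            class = "qc_thresholds")
}

#' Apply hard QC filters to a genotype matrix
#'
#' Order of operations (fixed):
#' 1. genotypes with GQ below `min_gq` are set missing;
#' 2. variants whose mean DP over non-missing genotypes falls outside
#'    `[min_mean_depth, max_mean_depth]` are dropped;
#' 3. variants with call rate below `min_call_rate` are dropped;
#' 4. variants with MAF (over non-missing genotypes) below `min_maf`
#'    are dropped.
#'
#' Per-filter removal counts are returned alongside the filtered matrix.
#' The filter is idempotent: re-filtering a filtered matrix removes
#' nothing. Removing every variant yields an empty matrix with a warning,
#' not an error.
#'
#' @param gm a [genotype_matrix()]. A depth layer is required when the
#'   depth filter is active, a qual layer when the GQ filter is active
#'   (set the corresponding thresholds to `-Inf`/`Inf`/0 to deactivate).
#' @param thresholds a [qc_thresholds()].
#' @return list with elements `gm` (filtered matrix) and `removed`
#'   (named integer vector: `gq_masked_genotypes`, `mean_depth`,
#'   `call_rate`, `maf`).
#' @export
apply_qc_filters <- function(gm, thresholds = qc_thresholds()) {
  t <- thresholds
  removed <- c(gq_masked_genotypes = 0L, mean_depth = 0L,
               call_rate = 0L, maf = 0L)
  D <- gm$dosage

  gq_active <- t$min_gq > 0
  if (gq_active) {
    if (is.null(gm$qual)) stop("GQ filter active but gm has no qual layer")
    mask <- !is.na(gm$qual) & gm$qual < t$min_gq & !is.na(D)
    removed["gq_masked_genotypes"] <- sum(mask)
    D[mask] <- NA_integer_
  }

  depth_active <- is.finite(t$max_mean_depth) || t$min_mean_depth > 0
  keep <- rep(TRUE, ncol(D))
  if (depth_active) {
    if (is.null(gm$depth)) stop("depth filter active but gm has no depth layer")
    dp <- gm$depth
    dp[is.na(D)] <- NA
    mean_dp <- colMeans(dp, na.rm = TRUE)
    ok <- !is.nan(mean_dp) & mean_dp >= t$min_mean_depth &
      mean_dp <= t$max_mean_depth
    removed["mean_depth"] <- sum(!ok)
    keep <- keep & ok
  }

  call_rate <- colMeans(!is.na(D))
  ok <- call_rate >= t$min_call_rate
  removed["call_rate"] <- sum(keep & !ok)
  keep <- keep & ok

  maf <- variant_maf(D)
  ok <- !is.na(maf) & maf >= t$min_maf
  removed["maf"] <- sum(keep & !ok)
  keep <- keep & ok

  out <- gm
  out$dosage <- D
  out <- gm_subset(out, variants = which(keep))
  if (ncol(out$dosage) == 0 && ncol(gm$dosage) > 0) {
    warning("all variants removed by QC filters")
  }
  list(gm = out, removed = removed)
}

#' Per-variant minor-allele frequency over non-missing genotypes
#' @param dosage samples x variants dosage matrix.
#' @return numeric vector of MAFs (`NA` for all-missing variants).
#' @export
variant_maf <- function(dosage) {
  nn <- colSums(!is.na(dosage))
  p <- colSums(dosage, na.rm = TRUE) / (2 * nn)
  maf <- pmin(p, 1 - p)
  maf[nn == 0] <- NA_real_
  maf
}

#' Modal imputation of missing genotypes
#'
#' Replaces each missing call by the per-variant modal dosage among
#' non-missing calls, with the deterministic tie-break 0 > 1 > 2 (lower
#' code wins). This is a simple documented stand-in for statistical
#' imputation, OFF by default in the pipeline; the sex-specific-locus
#' screen always runs on unimputed genotypes so that no heterozygotes are
#' fabricated. Variants with every genotype missing are left missing with
#' a warning.
#'
#' @param gm a [genotype_matrix()].
#' @return the imputed `genotype_matrix`.
#' @export
impute_missing <- function(gm) {
  D <- gm$dosage
  miss_cols <- which(colSums(is.na(D)) > 0)
  all_missing <- 0L
  for (j in miss_cols) {
    d <- D[, j]
    obs <- d[!is.na(d)]
    if (length(obs) == 0) { all_missing <- all_missing + 1L; next }
    counts <- tabulate(obs + 1L, nbins = 3L)
    mode <- which.max(counts) - 1L  # which.max takes the first max: 0 > 1 > 2
    D[is.na(d), j] <- mode
  }
  if (all_missing > 0) {
    warning(all_missing, " variant(s) with all genotypes missing left unimputed")
  }
  gm$dosage <- D
  gm
}
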