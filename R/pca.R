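#' GCTA-style standardization of a dosage matrix
#'
#' Centers each variant by `2 * p` and scales by `sqrt(2 p (1 - p))`
#' where `p` is the alt-allele frequency over non-missing genotypes;
#' missing genotypes are mean-filled (zero after centering). Variants
#' with zero variance (p = 0 or 1, or all missing) are dropped.
#'
#' @param dosage samples x variants dosage matrix.
#' @return standardized numeric matrix; attribute `kept` gives the
#'   retained column indices.
#' @keywords internal
standardize_dosage <- function(dosage) {
  nn <- colSums(!is.na(dosage))
  p <- colSums(dosage, na.rm = TRUE) / (2 * nn)
  keep <- which(nn > 0 & p > 0 & p < 1)
  X <- dosage[, keep, drop = FALSE]
  p <- p[keep]
  X <- sweep(X, 2, 2 * p, "-")
  X <- sweep(X, 2, sqrt(2 * p * (1 - p)), "/")
  X[is.na(X)] <- 0
  attr(X, "kept") <- keep
  X
}

#' Genotype PCA on standardized dosages
#'
#' Principal components of the samples from the singular decomposition of
#' the GCTA-standardized genotype matrix (computed via the eigen
#' decomposition of the sample-by-sample Gram matrix, which gives the
#' same leading components as a genetic-relationship-matrix
#' eigendecomposition). The sign convention is deterministic: each
#' component is flipped so that its largest-magnitude variant loading is
#' positive.
#'
#' @param gm a [genotype_matrix()].
#' @param subset optional variant selector (indices, ids, or logical).
#' @param k number of components (default 2).
#' @param label text recorded as `variant_subset_label`.
#' @return list of class `pca_result`: `scores` (samples x k, named),
#'   `loadings` (variants x k), `explained_variance_fraction`,
#'   `variant_subset_label`.
#' @export
genotype_pca <- function(gm, subset = NULL, k = 2, label = "all") {
  if (!is.null(subset)) gm <- gm_subset(gm, variants = subset)
  X <- standardize_dosage(gm$dosage)
  if (ncol(X) < 1) stop("no variant with non-zero variance in subset")
  eg <- eigen(tcrossprod(X), symmetric = TRUE)
  pos <- which(eg$values > max(eg$values, 0) * 1e-12)
  k_eff <- min(k, length(pos), ncol(X))
  if (k_eff < 1) stop("no non-degenerate component")
  d <- sqrt(eg$values[seq_len(k_eff)])
  U <- eg$vectors[, seq_len(k_eff), drop = FALSE]
  V <- crossprod(X, U) %*% diag(1 / d, k_eff)
  for (j in seq_len(k_eff)) {
    if (V[which.max(abs(V[, j])), j] < 0) {
      V[, j] <- -V[, j]; U[, j] <- -U[, j]
    }
  }
  scores <- U %*% diag(d, k_eff)
  dimnames(scores) <- list(gm$samples, paste0("PC", seq_len(k_eff)))
  structure(list(scores = scores, loadings = V,
                 explained_variance_fraction =
                   eg$values[seq_len(k_eff)] / sum(pmax(eg$values, 0)),
                 variant_subset_label = label),
            class = "pca_result")
}

#' Quantitative sex-separation score of a PCA
#'
#' The maximum, over the first two components, of the absolute
#' point-biserial correlation between component coordinate and sex label.
#' A degenerate (constant) component contributes 0. The score is
#' invariant to which sex is coded 1. Values near 1 mean the component
#' splits the cohort cleanly by sex.
#'
#' @param pca a `pca_result` from [genotype_pca()], or any samples x k
#'   score matrix with sample-id rownames.
#' @param sheet a [sample_sheet()].
#' @return score in `[0, 1]`.
#' @export
separation_score <- function(pca, sheet) {
  scores <- if (inherits(pca, "pca_result")) pca$scores else as.matrix(pca)
  y <- as.numeric(sheet$sex[match(rownames(scores), sheet$sample_id)] ==
                    "female")
  if (anyNA(y)) stop("score rows do not match the sample sheet")
  k <- min(2L, ncol(scores))
  vals <- vapply(seq_len(k), function(j) {
    s <- scores[, j]
    if (stats::sd(s) == 0 || stats::sd(y) == 0) return(0)
    abs(stats::cor(s, y))
  }, numeric(1))
  max(vals)
}

#' Per-chromosome PCA sex-separation scan
#'
#' For every chromosome, computes the separation score of a PCA on its
#' variants alone and on all variants excluding it. A chromosome carrying
#' the sex-determination region scores high alone, and excluding it
#' collapses the genome-wide score. Chromosomes with fewer than two
#' usable (non-zero-variance) variants get `NA`.
#'
#' @param gm a [genotype_matrix()].
#' @param sheet a [sample_sheet()].
#' @param k components per PCA (default 2).
#' @return data.frame: `chrom, n_variants, score_chrom, score_excluded`.
#' @export
per_chromosome_scan <- function(gm, sheet, k = 2) {
  X <- standardize_dosage(gm$dosage)
  kept_chrom <- gm$variants$chrom[attr(X, "kept")]
  chroms <- unique(gm$variants$chrom)
  chroms <- chroms[order_chromosomes(chroms)]
  G_full <- tcrossprod(X)
  score_from_gram <- function(G) {
    eg <- eigen(G, symmetric = TRUE)
    pos <- eg$values > max(eg$values, 0) * 1e-12
    if (!any(pos)) return(NA_real_)
    kk <- min(k, sum(pos))
    scores <- eg$vectors[, seq_len(kk), drop = FALSE] %*%
      diag(sqrt(eg$values[seq_len(kk)]), kk)
    rownames(scores) <- gm$samples
    separation_score(scores, sheet)
  }
  rows <- lapply(chroms, function(ch) {
    sel <- kept_chrom == ch
    n_ch <- sum(gm$variants$chrom == ch)
    Gc <- if (sum(sel) >= 1) tcrossprod(X[, sel, drop = FALSE]) else NULL
    sc <- if (sum(sel) >= 2) score_from_gram(Gc) else NA_real_
    n_excl <- sum(!sel)
    se <- if (n_excl >= 2) {
      score_from_gram(if (is.null(Gc)) G_full else G_full - Gc)
    } else NA_real_
    data.frame(chrom = ch, n_variants = n_ch,
               score_chrom = sc, score_excluded = se,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
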