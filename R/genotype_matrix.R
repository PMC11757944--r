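#' Construct a genotype matrix
#'
#' The central container of the package: an integer samples x variants
#' matrix of alt-allele dosages (0 = hom-ref, 1 = het, 2 = hom-alt,
#' `NA` = missing call), plus the variant table and optional same-shape
#' per-genotype depth (DP) and genotype-quality (GQ) layers.
#'
#' @param samples character vector of sample ids (rows).
#' @param variants data.frame with columns `chrom`, `pos` (1-based bp),
#'   `id`, `ref`, `alt`; one row per variant (columns of `dosage`).
#' @param dosage integer matrix, samples x variants, values in
#'   \{0, 1, 2, NA\}.
#' @param depth optional non-negative integer matrix, same shape.
#' @param qual optional genotype-quality matrix, same shape.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(samples, variants, dosage,
                            depth = NULL, qual = NULL) {
  samples <- as.character(samples)
  stopifnot(is.data.frame(variants))
  req <- c("chrom", "pos", "id", "ref", "alt")
  if (!all(req %in% names(variants))) {
    stop("variants must have columns: ", paste(req, collapse = ", "))
  }
  if (any(variants$pos < 1)) stop("variant pos must be >= 1")
  same <- !is.na(variants$ref) & variants$ref == variants$alt
  if (any(same)) stop("ref and alt alleles must differ")
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (nrow(dosage) != length(samples) || ncol(dosage) != nrow(variants)) {
    stop("dosage must be length(samples) x nrow(variants)")
  }
  bad <- !(dosage %in% c(DOSAGE_CODES, NA))
  if (any(bad)) stop("dosage codes must be in {0,1,2,NA}")
  dimnames(dosage) <- list(samples, variants$id)
  for (layer in list(depth, qual)) {
    if (!is.null(layer) && !identical(dim(layer), dim(dosage))) {
      stop("depth/qual layers must match dosage shape")
    }
  }
  if (!is.null(depth)) dimnames(depth) <- dimnames(dosage)
  if (!is.null(qual)) dimnames(qual) <- dimnames(dosage)
  structure(list(samples = samples, variants = variants,
                 dosage = dosage, depth = depth, qual = qual),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants\n",
              length(x$samples), nrow(x$variants)))
  cat(sprintf("  chromosomes: %d; missing genotypes: %d (%.2f%%)\n",
              length(unique(x$variants$chrom)),
              sum(is.na(x$dosage)),
              100 * mean(is.na(x$dosage))))
  cat(sprintf("  layers: dosage%s%s\n",
              if (!is.null(x$depth)) ", depth" else "",
              if (!is.null(x$qual)) ", qual" else ""))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix by variants and/or samples
#'
#' @param gm a [genotype_matrix()].
#' @param variants logical/integer/character index into variants.
#' @param samples logical/integer/character index into samples.
#' @return the subset `genotype_matrix`.
#' @export
gm_subset <- function(gm, variants = NULL, samples = NULL) {
  vi <- if (is.null(variants)) seq_len(nrow(gm$variants)) else variants
  if (is.character(vi)) vi <- match(vi, gm$variants$id)
  si <- if (is.null(samples)) seq_along(gm$samples) else samples
  if (is.character(si)) si <- match(si, gm$samples)
  genotype_matrix(
    gm$samples[si],
    gm$variants[vi, , drop = FALSE],
    gm$dosage[si, vi, drop = FALSE],
    depth = if (!is.null(gm$depth)) gm$depth[si, vi, drop = FALSE],
    qual  = if (!is.null(gm$qual))  gm$qual[si, vi, drop = FALSE]
  )
}
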