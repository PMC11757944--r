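#' Per-site Weir-Cockerham (1984) FST between two groups
#'
#' The classic two-level variance-component estimator for a biallelic site
#' scored in diploid individuals from two groups of (possibly unequal)
#' size, using observed heterozygote frequencies:
#' \deqn{\hat\theta = a / (a + b + c)}
#' with `a` the among-group, `b` the among-individual-within-group and `c`
#' the within-individual component. Negative estimates are retained (not
#' clamped to zero). `NA` is returned when the total variance `a + b + c`
#' is zero, i.e. the site is monomorphic.
#'
#' Here the two "populations" are the two sexes: sex-linked loci mimic
#' population differentiation and high FST between the sexes is a
#' selection-signature track for the sex-determination region.
#'
#' @param dosages_f,dosages_m integer dosage vectors (0/1/2/NA) for the
#'   two groups; missing genotypes are removed per group.
#' @return the per-site FST estimate, or `NA` for a monomorphic site.
#' @examples
#' weir_cockerham_fst(rep(2L, 40), rep(0L, 40))  # fixed difference: 1
#' weir_cockerham_fst(rep(1L, 40), rep(0L, 40))  # ZW pattern: > 0.25
#' @export
weir_cockerham_fst <- function(dosages_f, dosages_m) {
  check_dosages(dosages_f); check_dosages(dosages_m)
  df <- dosages_f[!is.na(dosages_f)]; dm <- dosages_m[!is.na(dosages_m)]
  if (length(df) == 0 || length(dm) == 0) {
    warning("a group is empty after removing missing genotypes")
    return(NA_real_)
  }
  comp <- wc_components(length(df), length(dm),
                        sum(df) / (2 * length(df)), sum(dm) / (2 * length(dm)),
                        mean(df == 1L), mean(dm == 1L))
  tot <- comp$a + comp$b + comp$c
  if (tot == 0) return(NA_real_)
  comp$a / tot
}

# Weir & Cockerham 1984 per-site components for r = 2 groups, vectorized.
# n1, n2: diploid sample sizes; p1, p2: alt-allele frequencies;
# h1, h2: observed heterozygote proportions.
wc_components <- function(n1, n2, p1, p2, h1, h2) {
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) *
       (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
       ((2 * nbar - 1) / (4 * nbar)) * hbar)
  c <- hbar / 2
  list(a = a, b = b, c = c)
}

#' Genome-wide per-site FST scan between the sexes
#'
#' @param gm a QC-filtered [genotype_matrix()].
#' @param sheet a [sample_sheet()].
#' @param threshold FST above which a site is flagged as a selection
#'   signature (default 0.25).
#' @return data.frame of class `fst_result`: `chrom, pos, id, fst,
#'   is_signature`; attribute `signature_by_chrom` holds per-chromosome
#'   signature counts.
#' @export
fst_scan <- function(gm, sheet, threshold = 0.25) {
  idx <- sex_index(sheet, gm$samples)
  D <- gm$dosage
  Df <- D[idx$female, , drop = FALSE]; Dm <- D[idx$male, , drop = FALSE]
  n1 <- colSums(!is.na(Df)); n2 <- colSums(!is.na(Dm))
  if (ncol(D) > 0 && (any(n1 == 0) || any(n2 == 0))) {
    warning("variant(s) with a sex entirely missing get NA fst")
  }
  p1 <- colSums(Df, na.rm = TRUE) / (2 * n1)
  p2 <- colSums(Dm, na.rm = TRUE) / (2 * n2)
  h1 <- colSums(Df == 1L, na.rm = TRUE) / n1
  h2 <- colSums(Dm == 1L, na.rm = TRUE) / n2
  comp <- wc_components(n1, n2, p1, p2, h1, h2)
  tot <- comp$a + comp$b + comp$c
  fst <- ifelse(is.na(tot) | tot == 0, NA_real_, comp$a / tot)
  res <- data.frame(gm$variants[, c("chrom", "pos", "id")],
                    fst = fst,
                    is_signature = !is.na(fst) & fst > threshold,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "threshold") <- threshold
  attr(res, "signature_by_chrom") <- table(res$chrom[res$is_signature])
  class(res) <- c("fst_result", "data.frame")
  res
}

#' Length-normalized per-chromosome enrichment of selected loci
#'
#' For each chromosome, density = loci count per Mb; the reported
#' percentage is each chromosome's share of the summed densities (so the
#' percentages sum to 100 and are invariant to rescaling all lengths by a
#' constant). The raw share of loci is also returned.
#'
#' @param loci data.frame with a `chrom` column (e.g. the significant rows
#'   of an `assoc_result`), or a character vector of chromosome labels.
#' @param lengths named numeric vector chrom -> length in bp; every locus
#'   chromosome must be present, and all lengths positive.
#' @return data.frame: `chrom, n, density_per_mb, percentage`, one row per
#'   chromosome in `lengths` (natural order), zero-count chromosomes
#'   included.
#' @export
chromosome_enrichment <- function(loci, lengths) {
  chroms <- if (is.data.frame(loci)) loci$chrom else as.character(loci)
  if (any(lengths <= 0)) stop("chromosome lengths must be positive")
  missing_chrom <- setdiff(unique(chroms), names(lengths))
  if (length(missing_chrom)) {
    stop("loci on chromosome(s) absent from lengths: ",
         paste(missing_chrom, collapse = ", "))
  }
  lengths <- lengths[order_chromosomes(names(lengths))]
  n <- as.integer(table(factor(chroms, levels = names(lengths))))
  density <- n / (lengths / 1e6)
  pct <- if (sum(density) > 0) 100 * density / sum(density) else rep(0, length(n))
  data.frame(chrom = names(lengths), n = n,
             density_per_mb = as.numeric(density),
             percentage = as.numeric(pct),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-window locus counts over non-overlapping tiling windows
#'
#' Windows are 0-based half-open tiles `[k*w, (k+1)*w)`; every window up
#' to the chromosome length is reported, empty ones as 0. Positions are
#' 0-based (convert VCF coordinates with `pos - 1`).
#'
#' @param loci data.frame with `chrom` and 0-based `pos0` columns.
#' @param lengths named numeric vector chrom -> length in bp.
#' @param window_bp window width (default 1 Mb).
#' @return data.frame: `chrom, win_start, win_end, count`.
#' @export
window_density <- function(loci, lengths, window_bp = 1e6) {
  stopifnot(window_bp > 0)
  lengths <- lengths[order_chromosomes(names(lengths))]
  out <- lapply(names(lengths), function(ch) {
    L <- lengths[[ch]]
    nw <- ceiling(L / window_bp)
    pos0 <- loci$pos0[loci$chrom == ch]
    if (any(pos0 >= L | pos0 < 0)) {
      stop("locus beyond chromosome length on ", ch)
    }
    counts <- tabulate(floor(pos0 / window_bp) + 1L, nbins = nw)
    data.frame(chrom = ch,
               win_start = (seq_len(nw) - 1) * window_bp,
               win_end = pmin(seq_len(nw) * window_bp, L),
               count = counts, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
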