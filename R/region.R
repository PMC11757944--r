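#' Rank chromosomes by a composite of the evidence tracks
#'
#' Each available track (enrichment percentages at the significant and
#' suggestive thresholds, FST-signature percentage, sex-specific-locus
#' count, PCA separation score) is min-max-rescaled to `[0, 1]` across
#' chromosomes; the composite is the mean of the rescaled tracks (tracks
#' with no spread contribute a constant 0.5 to every chromosome). Ties
#' break by PCA score, then by natural chromosome order. The tracks have
#' incommensurate units, which is why a rank-free min-max normalization
#' is used; per-track values are retained in the output.
#'
#' @param evidence data.frame with column `chrom` plus any of
#'   `pct_sig_snps, pct_sugg_snps, pct_fst_signatures,
#'   n_sex_specific_loci, pca_separation_score`.
#' @return `evidence` with an added `composite` column, ordered by
#'   decreasing composite (tie rules above), plus a `rank` column.
#' @export
rank_chromosomes <- function(evidence) {
  stopifnot(is.data.frame(evidence), "chrom" %in% names(evidence))
  if (nrow(evidence) == 0) stop("empty evidence table")
  tracks <- intersect(c("pct_sig_snps", "pct_sugg_snps",
                        "pct_fst_signatures", "n_sex_specific_loci",
                        "pca_separation_score"), names(evidence))
  if (length(tracks) == 0) stop("no evidence track present")
  norm <- vapply(tracks, function(tr) {
    v <- as.numeric(evidence[[tr]])
    v[is.na(v)] <- 0
    rng <- range(v)
    if (diff(rng) == 0) rep(0.5, length(v)) else (v - rng[1]) / diff(rng)
  }, numeric(nrow(evidence)))
  if (nrow(evidence) == 1) norm <- matrix(norm, nrow = 1)
  evidence$composite <- rowMeans(norm)
  pca <- if ("pca_separation_score" %in% names(evidence)) {
    v <- evidence$pca_separation_score; v[is.na(v)] <- -Inf; v
  } else rep(0, nrow(evidence))
  ord <- order(-evidence$composite, -pca,
               order_chromosomes(evidence$chrom))
  evidence <- evidence[ord, , drop = FALSE]
  evidence$rank <- seq_len(nrow(evidence))
  row.names(evidence) <- NULL
  evidence
}

#' Localize the candidate region as the shortest window run holding most
#' significant SNPs
#'
#' Tiles the chromosome into fixed windows and finds the shortest
#' contiguous run of windows containing at least `min_contained` of the
#' chromosome's significant positions. Among runs of equal (minimal)
#' length the one with the highest contained fraction wins, then the
#' leftmost. This is a reproducible formalization of "the sex-associated
#' SNPs are mainly located in ..." descriptions.
#'
#' @param pos0 0-based positions of the significant SNPs on one
#'   chromosome.
#' @param chrom_length chromosome length in bp.
#' @param window_bp window width (default 1 Mb).
#' @param min_contained minimum fraction of positions the run must hold
#'   (default 0.9).
#' @return list: `interval` (0-based half-open, clipped to the chromosome),
#'   `contained_fraction`, `n` (positions used); `NULL` when `pos0` is
#'   empty (no-call).
#' @export
localize_region <- function(pos0, chrom_length, window_bp = 1e6,
                            min_contained = 0.9) {
  pos0 <- as.numeric(pos0)
  if (length(pos0) == 0) return(NULL)
  if (any(pos0 < 0 | pos0 >= chrom_length)) {
    stop("position beyond chromosome length")
  }
  nw <- ceiling(chrom_length / window_bp)
  counts <- tabulate(floor(pos0 / window_bp) + 1L, nbins = nw)
  n <- length(pos0)
  csum <- c(0, cumsum(counts))
  for (len in seq_len(nw)) {
    starts <- seq_len(nw - len + 1L)
    contained <- csum[starts + len] - csum[starts]
    ok <- contained / n >= min_contained
    if (any(ok)) {
      best <- starts[ok][which.max(contained[ok])]
      lo <- (best - 1) * window_bp
      hi <- min(best + len - 1, nw) * window_bp
      hi <- min(hi, chrom_length)
      return(list(interval = c(lo, hi),
                  contained_fraction = contained[best] / n,
                  n = n))
    }
  }
  list(interval = c(0, chrom_length), contained_fraction = 1, n = n)
}

#' Build the per-chromosome evidence summary table
#'
#' @param gwas an `assoc_result` from [run_gwas()].
#' @param fst an `fst_result` from [fst_scan()].
#' @param sex_calls a `sex_locus_calls` data.frame (or `NULL`).
#' @param pca_scan output of [per_chromosome_scan()] (or `NULL`).
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @return data.frame with one row per chromosome: the four percentage /
#'   count tracks plus the PCA separation score.
#' @export
evidence_summary <- function(gwas, fst, sex_calls, pca_scan,
                             chrom_lengths) {
  enr <- function(tab, sel) {
    chromosome_enrichment(tab[sel, , drop = FALSE], chrom_lengths)$percentage
  }
  base <- chromosome_enrichment(gwas[gwas$tier == "significant", ,
                                     drop = FALSE], chrom_lengths)
  out <- data.frame(chrom = base$chrom,
                    pct_sig_snps = base$percentage,
                    pct_sugg_snps = enr(gwas, !is.na(gwas$p) &
                        gwas$p < attr(gwas, "thresholds")[["sugg"]]),
                    pct_fst_signatures = enr(fst, fst$is_signature),
                    stringsAsFactors = FALSE)
  out$n_sex_specific_loci <- if (is.null(sex_calls)) 0L else
    as.integer(table(factor(sex_calls$chrom, levels = out$chrom)))
  out$pca_separation_score <- if (is.null(pca_scan)) NA_real_ else
    pca_scan$score_chrom[match(out$chrom, pca_scan$chrom)]
  out
}

#' Call the candidate sex-determination region
#'
#' Integrates the evidence tracks: ranks chromosomes by the composite
#' score, localizes the candidate interval on the top chromosome from its
#' genome-wide-significant SNP positions, attaches the heterogamety
#' inference, and reports secondary candidate chromosomes whose composite
#' is within `secondary_frac` of the top. A no-call is returned when
#' there is no genome-wide-significant SNP at all, or when no chromosome
#' reaches the PCA separation cutoff.
#'
#' @param gwas an `assoc_result` from [run_gwas()].
#' @param fst an `fst_result` from [fst_scan()].
#' @param sex_calls a `sex_locus_calls` data.frame (may be empty).
#' @param pca_scan output of [per_chromosome_scan()].
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param window_bp,min_contained localization parameters (see
#'   [localize_region()]).
#' @param pca_cutoff separation score a chromosome must reach for a call
#'   (default 0.9).
#' @param majority_frac,seq_evidence passed to [infer_system()].
#' @param secondary_frac secondary candidates are chromosomes with
#'   composite >= `secondary_frac` x top composite (default 0.7).
#' @return list of class `region_call`: `status` ("call"/"no_call"),
#'   `reasons` (for no-calls), `chromosome`, `interval` (0-based
#'   half-open), `contained_fraction`, `system` (a `system_inference`),
#'   `evidence` (ranked table), `secondary` (chromosome labels).
#' @export
call_sex_region <- function(gwas, fst, sex_calls, pca_scan, chrom_lengths,
                            window_bp = 1e6, min_contained = 0.9,
                            pca_cutoff = 0.9, majority_frac = 0.8,
                            seq_evidence = "none", secondary_frac = 0.7) {
  ev <- evidence_summary(gwas, fst, sex_calls, pca_scan, chrom_lengths)
  system <- infer_system(sex_calls, majority_frac = majority_frac,
                         seq_evidence = seq_evidence)
  reasons <- character(0)
  n_sig <- sum(gwas$tier == "significant")
  if (n_sig == 0) reasons <- c(reasons, "no genome-wide-significant SNP")
  pca_ok <- !is.null(pca_scan) &&
    any(!is.na(pca_scan$score_chrom) & pca_scan$score_chrom >= pca_cutoff)
  if (!pca_ok) {
    reasons <- c(reasons, sprintf(
      "no chromosome reaches the PCA separation cutoff (%.2f)", pca_cutoff))
  }
  if (length(reasons)) {
    return(structure(list(status = "no_call", reasons = reasons,
                          chromosome = NA_character_, interval = NULL,
                          contained_fraction = NA_real_, system = system,
                          evidence = rank_chromosomes(ev),
                          secondary = character(0)),
                     class = "region_call"))
  }
  ranked <- rank_chromosomes(ev)
  top <- ranked$chrom[1]
  sig_pos0 <- gwas$pos[gwas$tier == "significant" & gwas$chrom == top] - 1
  loc <- localize_region(sig_pos0, chrom_lengths[[top]],
                         window_bp = window_bp,
                         min_contained = min_contained)
  secondary <- setdiff(
    ranked$chrom[ranked$composite >= secondary_frac * ranked$composite[1]],
    top)
  structure(list(status = "call", reasons = character(0),
                 chromosome = top, interval = loc$interval,
                 contained_fraction = loc$contained_fraction,
                 system = system, evidence = ranked,
                 secondary = secondary),
            class = "region_call")
}

#' @export
print.region_call <- function(x, ...) {
  if (x$status == "no_call") {
    cat("region_call: NO CALL\n  reasons:",
        paste(x$reasons, collapse = "; "), "\n")
  } else {
    cat(sprintf("region_call: %s [%.0f, %.0f) bp (%.1f%% of significant SNPs contained)\n",
                x$chromosome, x$interval[1], x$interval[2],
                100 * x$contained_fraction))
    cat(sprintf("  inferred system: %s", x$system$system))
    if (length(x$secondary)) {
      cat("; secondary candidates:", paste(x$secondary, collapse = ", "))
    }
    cat("\n")
  }
  invisible(x)
}
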