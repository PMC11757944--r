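#' Parameters of the heterozygote-count sex-specific-locus screen
#'
#' A locus is sex-specific when at least `min_het_focal` individuals of
#' one sex are heterozygous while at most `max_het_other` individuals of
#' the other sex are. The defaults (25 and 0, for 40 individuals per sex)
#' are deliberately tolerant on the focal side because low-depth
#' sequencing under-calls heterozygotes, and strict on the other side.
#' Missing genotypes count as neither het nor hom: they cannot defeat the
#' `max_het_other` bound nor contribute to the focal count.
#'
#' @param min_het_focal minimum heterozygote count in the focal sex (c).
#' @param max_het_other maximum heterozygote count in the other sex (e).
#' @return a list of class `screen_params`.
#' @export
screen_params <- function(min_het_focal = 25, max_het_other = 0) {
  stopifnot(min_het_focal >= 0, max_het_other >= 0)
  structure(list(min_het_focal = as.integer(min_het_focal),
                 max_het_other = as.integer(max_het_other)),
            class = "screen_params")
}

#' Screen for sex-specific loci by heterozygote counts
#'
#' Flags a variant with orientation `female_het` iff the heterozygote
#' count among females is at least `min_het_focal` AND the heterozygote
#' count among males is at most `max_het_other` (with `max_het_other = 0`
#' this means every non-missing male genotype is homozygous);
#' `male_het` is the mirror. When `min_het_focal > max_het_other` a
#' variant can match at most one orientation. Run this screen on
#' unimputed genotypes so no heterozygotes are fabricated.
#'
#' @param gm a [genotype_matrix()].
#' @param sheet a [sample_sheet()] with both sexes present.
#' @param params a [screen_params()]; `min_het_focal` must not exceed
#'   either sex's sample size.
#' @return data.frame of class `sex_locus_calls`: `chrom, pos, id,
#'   orientation, n_het_female, n_het_male, n_hom_other_sex`.
#' @export
screen_sex_specific <- function(gm, sheet, params = screen_params()) {
  idx <- sex_index(sheet, gm$samples)
  c_ <- params$min_het_focal; e_ <- params$max_het_other
  if (c_ > length(idx$female) || c_ > length(idx$male)) {
    stop("min_het_focal (", c_, ") exceeds a sex's sample size")
  }
  D <- gm$dosage
  Df <- D[idx$female, , drop = FALSE]; Dm <- D[idx$male, , drop = FALSE]
  het_f <- as.integer(colSums(Df == 1L, na.rm = TRUE))
  het_m <- as.integer(colSums(Dm == 1L, na.rm = TRUE))
  hom_f <- as.integer(colSums(Df != 1L, na.rm = TRUE))
  hom_m <- as.integer(colSums(Dm != 1L, na.rm = TRUE))
  f_or <- het_f >= c_ & het_m <= e_
  m_or <- het_m >= c_ & het_f <= e_
  build <- function(sel, orientation, hom_other) {
    data.frame(gm$variants[sel, c("chrom", "pos", "id"), drop = FALSE],
               orientation = rep(orientation, sum(sel)),
               n_het_female = het_f[sel], n_het_male = het_m[sel],
               n_hom_other_sex = hom_other[sel],
               stringsAsFactors = FALSE, row.names = NULL)
  }
  res <- rbind(build(f_or, "female_het", hom_m),
               build(m_or, "male_het", hom_f))
  res <- res[order(match(res$id, gm$variants$id)), , drop = FALSE]
  row.names(res) <- NULL
  class(res) <- c("sex_locus_calls", "data.frame")
  res
}

#' Restrict the sex-locus screen input to sex-associated variants
#'
#' Mirrors the usual order of operations: the heterozygote screen is run
#' on the GWAS-selected variants (p below the suggestive threshold), with
#' a genome-wide mode available.
#'
#' @param assoc an `assoc_result` from [run_gwas()].
#' @param mode `"sex_associated_only"` (default) or `"genome_wide"`.
#' @return character vector of variant ids to screen, with attribute
#'   `mode`.
#' @export
screen_input_selection <- function(assoc,
                                   mode = c("sex_associated_only",
                                            "genome_wide")) {
  mode <- match.arg(mode)
  ids <- if (mode == "sex_associated_only") {
    sugg <- attr(assoc, "thresholds")[["sugg"]]
    assoc$id[!is.na(assoc$p) & assoc$p < sugg]
  } else {
    assoc$id
  }
  attr(ids, "mode") <- mode
  ids
}

#' Infer the heterogametic system from sex-locus orientations
#'
#' A large majority of female-het loci indicates female heterogamety (ZW);
#' male-het the mirror (XY). Independent sequence-level evidence
#' (sex-specific contigs from the coverage screen) can establish or
#' corroborate the call: female-specific sequences with no male-specific
#' ones support ZW. When both tracks are present their agreement is
#' reported.
#'
#' @param calls a `sex_locus_calls` data.frame (may be empty).
#' @param majority_frac fraction of one orientation required to call a
#'   system from loci alone (default 0.8).
#' @param seq_evidence `"none"`, `"female_specific"`, `"male_specific"`
#'   or `"both"`.
#' @return list of class `system_inference`: `system` (ZW/XY/
#'   inconclusive), `n_female_het_loci`, `n_male_het_loci`,
#'   `fraction_majority`, `sequence_evidence`, `consistent` (`NA` when
#'   only one track is informative).
#' @export
infer_system <- function(calls, majority_frac = 0.8,
                         seq_evidence = c("none", "female_specific",
                                          "male_specific", "both")) {
  seq_evidence <- match.arg(seq_evidence)
  nf <- if (is.null(calls)) 0L else sum(calls$orientation == "female_het")
  nm <- if (is.null(calls)) 0L else sum(calls$orientation == "male_het")
  frac_f <- if (nf + nm > 0) nf / (nf + nm) else NA_real_
  loci_system <- if (nf + nm == 0) "inconclusive"
    else if (frac_f >= majority_frac) "ZW"
    else if (1 - frac_f >= majority_frac) "XY"
    else "inconclusive"
  seq_system <- switch(seq_evidence, female_specific = "ZW",
                       male_specific = "XY", "inconclusive")
  system <- if (loci_system != "inconclusive") loci_system else seq_system
  consistent <- if (loci_system != "inconclusive" &&
                    seq_system != "inconclusive") {
    loci_system == seq_system
  } else NA
  structure(list(system = system,
                 n_female_het_loci = nf, n_male_het_loci = nm,
                 fraction_majority = if (is.na(frac_f)) NA_real_
                                     else max(frac_f, 1 - frac_f),
                 sequence_evidence = seq_evidence,
                 consistent = consistent),
            class = "system_inference")
}

#' @export
print.system_inference <- function(x, ...) {
  cat(sprintf("system: %s (%d female-het vs %d male-het loci; sequence evidence: %s)\n",
              x$system, x$n_female_het_loci, x$n_male_het_loci,
              x$sequence_evidence))
  invisible(x)
}
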