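#' Breadth of coverage from a per-base depth track
#'
#' Breadth = fraction of a contig's positions with depth at least
#' `min_depth`. Positions absent from the track count as depth 0.
#'
#' @param depth_track data.frame with columns `contig`, `pos0` (0-based
#'   position) and `depth` (non-negative), for one sample.
#' @param contig_lengths named numeric vector contig -> length in bp.
#' @param min_depth minimum depth for a position to count as covered
#'   (default 1).
#' @return named numeric vector of breadth values in `[0, 1]`, one per
#'   contig in `contig_lengths`.
#' @export
breadth_from_depth <- function(depth_track, contig_lengths, min_depth = 1) {
  if (nrow(depth_track) == 0) stop("empty depth track")
  if (any(depth_track$depth < 0)) stop("depths must be non-negative")
  covered <- depth_track[depth_track$depth >= min_depth, , drop = FALSE]
  n_cov <- table(factor(covered$contig, levels = names(contig_lengths)))
  out <- as.numeric(n_cov) / as.numeric(contig_lengths)
  stats::setNames(pmin(out, 1), names(contig_lengths))
}

#' First-round presence/absence screen for sex-specific contigs
#'
#' A contig is called `female_specific` iff its breadth is at least
#' `present_min` in EVERY female sample and at most `absent_max` in EVERY
#' male sample; `male_specific` is the mirror. Both screens run
#' symmetrically. The thresholds make the qualitative "covered by all
#' samples of one sex, by none of the other" rule quantitative.
#'
#' @param cov a `coverage_table` (list with `breadth` contigs x samples
#'   matrix) or a bare breadth matrix with contig rownames and sample-id
#'   colnames.
#' @param sheet a [sample_sheet()]; its samples must all be columns of
#'   the breadth matrix.
#' @param present_min minimum breadth in every same-sex sample (0.9).
#' @param absent_max maximum breadth in every opposite-sex sample (0.05).
#' @return data.frame of class `contig_calls`: `contig, specificity,
#'   round_passed`.
#' @export
round1_screen <- function(cov, sheet, present_min = 0.9,
                          absent_max = 0.05) {
  B <- if (inherits(cov, "coverage_table")) cov$breadth else as.matrix(cov)
  missing_smp <- setdiff(sheet$sample_id, colnames(B))
  if (length(missing_smp)) {
    stop("sample(s) absent from coverage table: ",
         paste(missing_smp, collapse = ", "))
  }
  fcols <- sheet$sample_id[sheet$sex == "female"]
  mcols <- sheet$sample_id[sheet$sex == "male"]
  if (length(fcols) == 0 || length(mcols) == 0) {
    stop("both sexes must be present")
  }
  min_f <- apply(B[, fcols, drop = FALSE], 1, min)
  max_f <- apply(B[, fcols, drop = FALSE], 1, max)
  min_m <- apply(B[, mcols, drop = FALSE], 1, min)
  max_m <- apply(B[, mcols, drop = FALSE], 1, max)
  fspec <- min_f >= present_min & max_m <= absent_max
  mspec <- min_m >= present_min & max_f <= absent_max
  res <- data.frame(
    contig = c(rownames(B)[fspec], rownames(B)[mspec]),
    specificity = c(rep("female_specific", sum(fspec)),
                    rep("male_specific", sum(mspec))),
    round_passed = rep(1L, sum(fspec) + sum(mspec)),
    stringsAsFactors = FALSE)
  res <- res[order(match(res$contig, rownames(B))), , drop = FALSE]
  row.names(res) <- NULL
  class(res) <- c("contig_calls", "data.frame")
  res
}

#' Second-round screen against pooled opposite-sex coverage
#'
#' Retains a round-1 candidate iff its breadth in the pooled
#' opposite-sex data is at most `absent_max`; removals are annotated.
#' Round-2 output is always a subset of round 1.
#'
#' @param candidates a `contig_calls` data.frame from [round1_screen()].
#' @param pooled contigs x pools breadth matrix (a `coverage_table`'s
#'   `pooled` element), pool columns named `female_pool`/`male_pool`;
#'   every candidate contig must be a row.
#' @param absent_max maximum pooled opposite-sex breadth (default 0.05).
#' @return retained `contig_calls` (`round_passed = 2`); attribute
#'   `removed` is a data.frame of removals with `exclusion_reason`.
#' @export
round2_screen <- function(candidates, pooled, absent_max = 0.05) {
  pooled <- as.matrix(pooled)
  if (nrow(candidates) == 0) {
    out <- candidates
    attr(out, "removed") <- data.frame(contig = character(0),
                                       specificity = character(0),
                                       exclusion_reason = character(0))
    return(out)
  }
  absent <- setdiff(candidates$contig, rownames(pooled))
  if (length(absent)) {
    stop("candidate(s) missing from pooled table: ",
         paste(absent, collapse = ", "))
  }
  pool_col <- ifelse(candidates$specificity == "female_specific",
                     "male_pool", "female_pool")
  if (!all(unique(pool_col) %in% colnames(pooled))) {
    stop("pooled table lacks column(s): ",
         paste(setdiff(unique(pool_col), colnames(pooled)), collapse = ", "))
  }
  pb <- pooled[cbind(candidates$contig, pool_col)]
  keep <- pb <= absent_max
  removed <- data.frame(
    contig = candidates$contig[!keep],
    specificity = candidates$specificity[!keep],
    exclusion_reason = sprintf(
      "pooled opposite-sex breadth %.3f > %.3f", pb[!keep], absent_max),
    stringsAsFactors = FALSE)
  out <- candidates[keep, , drop = FALSE]
  out$round_passed <- 2L
  row.names(out) <- NULL
  class(out) <- c("contig_calls", "data.frame")
  attr(out, "removed") <- removed
  out
}

#' Filter screened contigs down to marker candidates
#'
#' Keeps contigs long enough for primer design and free of assembly
#' artifacts: length strictly greater than `min_len`, N-fraction at most
#' `max_n_fraction`, and mean dinucleotide Shannon entropy at least
#' `min_entropy_bits` (removing homopolymer/repeat-like sequences). Each
#' exclusion is annotated with its reason.
#'
#' @param calls a `contig_calls` data.frame (typically round-2 output).
#' @param contigs a `contig_set` (list with `info` data.frame holding
#'   `id, length, n_fraction, entropy`).
#' @param min_len minimum length in bp, exclusive (default 1000).
#' @param max_n_fraction maximum fraction of N bases (default 0.1).
#' @param min_entropy_bits minimum dinucleotide entropy (default 1.5).
#' @return retained `contig_calls` joined with contig info; attribute
#'   `excluded` annotates removals.
#' @export
filter_marker_candidates <- function(calls, contigs, min_len = 1000,
                                     max_n_fraction = 0.1,
                                     min_entropy_bits = 1.5) {
  info <- contigs$info
  i <- match(calls$contig, info$id)
  if (anyNA(i)) {
    stop("contig(s) absent from contig set: ",
         paste(calls$contig[is.na(i)], collapse = ", "))
  }
  len <- info$length[i]; nf <- info$n_fraction[i]; ent <- info$entropy[i]
  reason <- rep(NA_character_, nrow(calls))
  reason[ent < min_entropy_bits] <- sprintf(
    "low complexity (entropy %.2f < %.2f bits)",
    ent[ent < min_entropy_bits], min_entropy_bits)
  reason[nf > max_n_fraction] <- sprintf(
    "N-fraction %.2f > %.2f", nf[nf > max_n_fraction], max_n_fraction)
  reason[len <= min_len] <- sprintf(
    "length %d bp <= %d bp", len[len <= min_len], min_len)
  keep <- is.na(reason)
  out <- cbind(calls[keep, , drop = FALSE],
               data.frame(length = len[keep], n_fraction = nf[keep],
                          entropy = ent[keep]))
  row.names(out) <- NULL
  class(out) <- c("contig_calls", "data.frame")
  attr(out, "excluded") <- data.frame(
    contig = calls$contig[!keep], exclusion_reason = reason[!keep],
    stringsAsFactors = FALSE)
  out
}

#' Run the full two-round sequence screen plus marker filters
#'
#' @param contigs a `contig_set`.
#' @param cov a `coverage_table` with `breadth` and `pooled` matrices.
#' @param sheet a [sample_sheet()].
#' @param present_min,absent_max round-1/round-2 breadth thresholds.
#' @param min_len,max_n_fraction,min_entropy_bits marker filters.
#' @return list: `round1`, `round2`, `markers` (each `contig_calls`).
#' @export
seq_screen <- function(contigs, cov, sheet, present_min = 0.9,
                       absent_max = 0.05, min_len = 1000,
                       max_n_fraction = 0.1, min_entropy_bits = 1.5) {
  r1 <- round1_screen(cov, sheet, present_min = present_min,
                      absent_max = absent_max)
  r2 <- round2_screen(r1, cov$pooled, absent_max = absent_max)
  mk <- filter_marker_candidates(r2, contigs, min_len = min_len,
                                 max_n_fraction = max_n_fraction,
                                 min_entropy_bits = min_entropy_bits)
  list(round1 = r1, round2 = r2, markers = mk)
}

#' Write a contig set as FASTA
#' @param contigs a `contig_set` with a `seqs` `DNAStringSet`.
#' @param path output FASTA path.
#' @param ids optional subset of contig ids to write.
#' @return `path`, invisibly.
#' @export
write_contigs_fasta <- function(contigs, path, ids = NULL) {
  seqs <- contigs$seqs
  if (!is.null(ids)) seqs <- seqs[ids]
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a breadth table TSV (contig, sample, breadth) into a matrix
#' @param path TSV path with a header.
#' @return contigs x samples breadth matrix.
#' @export
read_breadth_tsv <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  contigs <- unique(tab$contig); samples <- unique(tab$sample)
  B <- matrix(0, nrow = length(contigs), ncol = length(samples),
              dimnames = list(contigs, samples))
  B[cbind(tab$contig, tab$sample)] <- tab$breadth
  B
}
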