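#' Simulation configuration for a sexed re-sequencing cohort
#'
#' Defaults emulate the study design the analysis is built for: 40 females
#' and 40 males genotyped at ~10x depth over 22 chromosomes, with a
#' recombination-suppressed ZW region on one chromosome carrying fully and
#' partially sex-linked SNPs on a Hardy-Weinberg neutral background. The
#' genome is a desk-scale stand-in (22 x 5 Mb); all window parameters
#' scale through configuration.
#'
#' @param n_female,n_male sample counts per sex.
#' @param chrom_lengths named numeric vector, chromosome -> length in bp.
#' @param n_background_snps neutral SNPs placed uniformly over the genome.
#' @param sd_system `"ZW"`, `"XY"` or `"none"` (null cohort, no
#'   genetic sex determination).
#' @param sd_chrom chromosome carrying the sex-determination region.
#' @param sd_interval 0-based half-open bp interval of the region.
#' @param n_sd_full fully sex-linked SNPs: heterozygous in every
#'   heterogametic-sex individual, hom-ref in the other sex.
#' @param n_sd_partial partially linked SNPs: heterogametic-sex
#'   individuals are het with a per-SNP probability drawn from
#'   `partial_linkage_range`; the other sex is hom-ref.
#' @param partial_linkage_range range of the per-SNP linkage probability.
#' @param maf_background `c(lo, hi)` of the uniform allele-frequency
#'   distribution for background SNPs.
#' @param het_miscall_rate probability a true heterozygote is recorded as
#'   hom-ref (the depth-driven under-calling of hets at ~10x).
#' @param missing_rate per-genotype missing probability.
#' @param mean_depth Poisson mean of the per-genotype DP layer.
#' @param seed integer RNG seed; identical configs give identical output.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_female = 40, n_male = 40,
                       chrom_lengths = stats::setNames(rep(5e6, 22),
                                                       paste0("chr", 1:22)),
                       n_background_snps = 30000,
                       sd_system = c("ZW", "XY", "none"),
                       sd_chrom = "chr10",
                       sd_interval = c(2e6, 3e6),
                       n_sd_full = 100, n_sd_partial = 100,
                       partial_linkage_range = c(0.5, 0.95),
                       maf_background = c(0.05, 0.5),
                       het_miscall_rate = 0.02, missing_rate = 0.02,
                       mean_depth = 10, seed = 1) {
  sd_system <- match.arg(sd_system)
  if (sd_system == "none") {
    n_sd_full <- 0
    n_sd_partial <- 0
  } else {
    if (!sd_chrom %in% names(chrom_lengths)) stop("sd_chrom not in chrom_lengths")
    if (sd_interval[1] < 0 || sd_interval[2] > chrom_lengths[[sd_chrom]] ||
        sd_interval[1] >= sd_interval[2]) {
      stop("sd_interval must be a non-empty interval within sd_chrom")
    }
  }
  stopifnot(n_female >= 1, n_male >= 1,
            het_miscall_rate >= 0, het_miscall_rate <= 1,
            missing_rate >= 0, missing_rate <= 1,
            all(partial_linkage_range >= 0), all(partial_linkage_range <= 1))
  structure(list(n_female = n_female, n_male = n_male,
                 chrom_lengths = chrom_lengths,
                 n_background_snps = n_background_snps,
                 sd_system = sd_system, sd_chrom = sd_chrom,
                 sd_interval = as.numeric(sd_interval),
                 n_sd_full = n_sd_full, n_sd_partial = n_sd_partial,
                 partial_linkage_range = partial_linkage_range,
                 maf_background = maf_background,
                 het_miscall_rate = het_miscall_rate,
                 missing_rate = missing_rate,
                 mean_depth = mean_depth, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a sexed genotype cohort with a planted sex-determination region
#'
#' Background SNPs draw an allele frequency from `maf_background` and
#' genotypes in Hardy-Weinberg proportions independent of sex. In a ZW
#' system, fully linked SNPs are truly heterozygous in every female and
#' hom-ref in every male; partially linked SNPs are het in a female with a
#' per-SNP probability and hom-ref in males. XY mirrors with the sexes
#' swapped. True heterozygotes then flip to hom-ref with probability
#' `het_miscall_rate` (the ref side, so the homogametic-sex hom-ref
#' pattern is never spuriously broken), and genotypes are set missing with
#' probability `missing_rate`. DP ~ Poisson(`mean_depth`), GQ = 99.
#'
#' @param cfg a [sim_config()].
#' @return list with elements `gm` ([genotype_matrix()]),
#'   `sheet` ([sample_sheet()]) and `truth` (list of class `truth_record`:
#'   planted system, chromosome, interval and linked-variant ids).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n_f <- cfg$n_female; n_m <- cfg$n_male; n <- n_f + n_m
  sheet <- sample_sheet(
    c(sprintf("F%02d", seq_len(n_f)), sprintf("M%02d", seq_len(n_m))),
    c(rep("female", n_f), rep("male", n_m)))
  is_f <- sheet$sex == "female"
  het_sex <- if (cfg$sd_system == "XY") !is_f else is_f  # heterogametic rows

  chroms <- names(cfg$chrom_lengths)
  lens <- as.numeric(cfg$chrom_lengths)
  n_bg <- cfg$n_background_snps
  bg_chrom_idx <- sample.int(length(chroms), n_bg, replace = TRUE,
                             prob = lens / sum(lens))
  bg_pos <- integer(n_bg)
  for (ci in unique(bg_chrom_idx)) {
    sel <- bg_chrom_idx == ci
    bg_pos[sel] <- sample.int(lens[ci], sum(sel))
  }
  bg_chrom <- chroms[bg_chrom_idx]

  n_sd <- cfg$n_sd_full + cfg$n_sd_partial
  sd_chrom <- character(0); sd_pos <- integer(0)
  if (n_sd > 0) {
    lo <- cfg$sd_interval[1]; hi <- cfg$sd_interval[2]
    avail <- setdiff(seq.int(lo + 1, hi),
                     bg_pos[bg_chrom == cfg$sd_chrom])
    if (length(avail) < n_sd) {
      stop("sd_interval too small to place ", n_sd, " SNPs without collision")
    }
    sd_pos <- sort(sample(avail, n_sd))
    sd_chrom <- rep(cfg$sd_chrom, n_sd)
  }

  # background genotypes: HW, independent of sex
  p_bg <- stats::runif(n_bg, cfg$maf_background[1], cfg$maf_background[2])
  G_bg <- matrix(stats::rbinom(n * n_bg, 2L, rep(p_bg, each = n)),
                 nrow = n, ncol = n_bg)

  G_sd <- matrix(integer(0), nrow = n, ncol = 0)
  full_idx <- partial_idx <- integer(0)
  if (n_sd > 0) {
    G_sd <- matrix(0L, nrow = n, ncol = n_sd)
    which_full <- sort(sample.int(n_sd, cfg$n_sd_full))
    full_idx <- which_full
    partial_idx <- setdiff(seq_len(n_sd), which_full)
    G_sd[het_sex, full_idx] <- 1L
    if (length(partial_idx)) {
      q <- stats::runif(length(partial_idx),
                        cfg$partial_linkage_range[1],
                        cfg$partial_linkage_range[2])
      G_sd[het_sex, partial_idx] <-
        matrix(stats::rbinom(sum(het_sex) * length(q), 1L,
                             rep(q, each = sum(het_sex))),
               nrow = sum(het_sex))
    }
  }

  chrom_all <- c(bg_chrom, sd_chrom)
  pos_all <- c(bg_pos, sd_pos)
  G <- cbind(G_bg, G_sd)
  is_sd_full <- c(rep(FALSE, n_bg), seq_len(n_sd) %in% full_idx)
  is_sd_partial <- c(rep(FALSE, n_bg), seq_len(n_sd) %in% partial_idx)

  chrom_rank <- match(chrom_all, chroms[order_chromosomes(chroms)])
  ord <- order(chrom_rank, pos_all)
  chrom_all <- chrom_all[ord]; pos_all <- pos_all[ord]
  G <- G[, ord, drop = FALSE]
  is_sd_full <- is_sd_full[ord]; is_sd_partial <- is_sd_partial[ord]

  # genotyping noise: het -> hom-ref miscall, then missingness
  het <- which(G == 1L)
  if (length(het) && cfg$het_miscall_rate > 0) {
    flip <- het[stats::rbinom(length(het), 1L, cfg$het_miscall_rate) == 1L]
    G[flip] <- 0L
  }
  if (cfg$missing_rate > 0) {
    drop <- stats::rbinom(length(G), 1L, cfg$missing_rate) == 1L
    G[drop] <- NA_integer_
  }

  nv <- length(pos_all)
  ref_alt <- replicate(nv, sample(c("A", "C", "G", "T"), 2))
  ids <- paste0(chrom_all, "_", pos_all)
  variants <- data.frame(chrom = chrom_all, pos = pos_all, id = ids,
                         ref = ref_alt[1, ], alt = ref_alt[2, ],
                         stringsAsFactors = FALSE)
  depth <- matrix(stats::rpois(n * nv, cfg$mean_depth), nrow = n)
  qual <- matrix(99, nrow = n, ncol = nv)
  gm <- genotype_matrix(sheet$sample_id, variants, G,
                        depth = depth, qual = qual)
  truth <- structure(list(sd_system = cfg$sd_system,
                          sd_chrom = if (n_sd > 0) cfg$sd_chrom else NA_character_,
                          sd_interval = if (n_sd > 0) cfg$sd_interval else NULL,
                          full_ids = ids[is_sd_full],
                          partial_ids = ids[is_sd_partial],
                          w_contig_ids = character(0)),
                     class = "truth_record")
  list(gm = gm, sheet = sheet, truth = truth)
}

#' Simulate per-contig per-sample coverage breadth with planted
#' sex-specific contigs
#'
#' Emulates the input of a two-round presence/absence screen: shared
#' contigs are covered in every sample (breadth ~ Beta(20, 1)); contigs
#' specific to the heterogametic sex (W in a ZW system, Y in XY) have high
#' breadth (Uniform(0.95, 1)) in every heterogametic-sex sample and
#' breadth 0 (plus optional contamination noise) in the other sex; decoy
#' contigs are covered in all but one heterogametic-sex sample, to
#' exercise the stringency of the "every sample" rule. A pooled
#' opposite-sex breadth column is emitted for the second screening round;
#' optional "false positive" contigs pass round 1 but show pooled
#' opposite-sex coverage. Planted marker-filter violators (short, N-rich,
#' low-complexity) can be added to exercise the candidate filters.
#'
#' @param cfg a [sim_config()] with `sd_system` `"ZW"` or `"XY"`.
#' @param n_w_contigs planted sex-specific contigs.
#' @param n_shared_contigs contigs covered in both sexes.
#' @param n_decoys contigs covered by all-but-one heterogametic-sex sample.
#' @param n_false contigs that pass round 1 but have pooled opposite-sex
#'   breadth in (0.2, 0.6) (removed in round 2).
#' @param n_short,n_high_n,n_low_complexity planted sex-specific contigs
#'   violating the length (< 1000 bp), N-fraction (30% N) and complexity
#'   (poly-A) marker filters respectively.
#' @param noise upper bound of the uniform contamination breadth in
#'   opposite-sex samples at sex-specific contigs (default 0).
#' @return list with `contigs` (a `contig_set`: info data.frame + `seqs`
#'   `DNAStringSet`), `coverage` (a `coverage_table`: `breadth` contigs x
#'   samples matrix, `pooled` contigs x 1 matrix), `sheet` and `truth`
#'   (ids of planted specific/decoy/false/violator contigs).
#' @export
simulate_contig_coverage <- function(cfg, n_w_contigs = 20,
                                     n_shared_contigs = 2000,
                                     n_decoys = 20, n_false = 0,
                                     n_short = 0, n_high_n = 0,
                                     n_low_complexity = 0, noise = 0) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$sd_system == "none") stop("a ZW or XY system must be configured")
  counts <- c(n_w_contigs, n_shared_contigs, n_decoys, n_false,
              n_short, n_high_n, n_low_complexity)
  if (any(counts < 0)) stop("contig counts must be non-negative")
  set.seed(bitwXor(cfg$seed, 74747L))
  n_f <- cfg$n_female; n_m <- cfg$n_male
  sheet <- sample_sheet(
    c(sprintf("F%02d", seq_len(n_f)), sprintf("M%02d", seq_len(n_m))),
    c(rep("female", n_f), rep("male", n_m)))
  het_sex_name <- if (cfg$sd_system == "ZW") "female" else "male"
  prefix <- if (cfg$sd_system == "ZW") "W" else "Y"
  het_cols <- which(sheet$sex == het_sex_name)
  hom_cols <- which(sheet$sex != het_sex_name)

  ids <- c(sprintf("%s%04d", prefix, seq_len(n_w_contigs)),
           sprintf("S%05d", seq_len(n_shared_contigs)),
           sprintf("D%04d", seq_len(n_decoys)),
           sprintf("FP%03d", seq_len(n_false)),
           sprintf("%sshort%03d", prefix, seq_len(n_short)),
           sprintf("%snrich%03d", prefix, seq_len(n_high_n)),
           sprintf("%slowc%03d", prefix, seq_len(n_low_complexity)))
  type <- rep(c("specific", "shared", "decoy", "false_positive",
                "short", "high_n", "low_complexity"), counts)
  nc <- length(ids)
  len <- as.integer(round(stats::runif(nc, 500, 3000)))
  # planted specific contigs are marker-filter clean by construction; the
  # short/high-N/low-complexity classes are the designated violators
  marker_clean <- type %in% c("specific", "false_positive")
  len[marker_clean] <- as.integer(round(stats::runif(sum(marker_clean),
                                                     1100, 3000)))
  len[type == "short"] <- as.integer(round(stats::runif(sum(type == "short"),
                                                        300, 999)))
  len[type %in% c("high_n", "low_complexity")] <-
    pmax(len[type %in% c("high_n", "low_complexity")], 1200L)

  seqs <- vapply(seq_len(nc), function(i) {
    switch(type[i],
      low_complexity = strrep("A", len[i]),
      high_n = {
        s <- sample(c("A", "C", "G", "T", "N"), len[i], replace = TRUE,
                    prob = c(0.175, 0.175, 0.175, 0.175, 0.3))
        paste(s, collapse = "")
      },
      paste(sample(c("A", "C", "G", "T"), len[i], replace = TRUE),
            collapse = ""))
  }, character(1))
  seqset <- Biostrings::DNAStringSet(seqs)
  names(seqset) <- ids
  info <- data.frame(
    id = ids, length = len, type = type,
    n_fraction = vapply(seqs, function(s)
      mean(strsplit(s, "")[[1]] == "N"), numeric(1)),
    entropy = vapply(seqs, dinucleotide_entropy, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)

  breadth <- matrix(0, nrow = nc, ncol = n_f + n_m,
                    dimnames = list(ids, sheet$sample_id))
  specific_like <- type %in% c("specific", "false_positive", "short",
                               "high_n", "low_complexity")
  breadth[type == "shared", ] <-
    stats::rbeta(sum(type == "shared") * (n_f + n_m), 20, 1)
  breadth[specific_like, het_cols] <-
    stats::runif(sum(specific_like) * length(het_cols), 0.95, 1)
  if (noise > 0) {
    breadth[specific_like, hom_cols] <-
      stats::runif(sum(specific_like) * length(hom_cols), 0, noise)
  }
  di <- which(type == "decoy")
  if (length(di)) {
    breadth[di, het_cols] <-
      stats::runif(length(di) * length(het_cols), 0.95, 1)
    skip <- sample(het_cols, length(di), replace = TRUE)
    breadth[cbind(di, skip)] <- 0
  }

  pooled <- matrix(0, nrow = nc, ncol = 1,
                   dimnames = list(ids, paste0(
                     if (het_sex_name == "female") "male" else "female",
                     "_pool")))
  pooled[type == "shared", 1] <- stats::rbeta(sum(type == "shared"), 20, 1)
  pooled[type == "decoy", 1] <- 0
  pooled[type == "false_positive", 1] <-
    stats::runif(sum(type == "false_positive"), 0.2, 0.6)
  if (noise > 0) {
    pooled[type %in% c("specific", "short", "high_n", "low_complexity"), 1] <-
      stats::runif(sum(type %in% c("specific", "short", "high_n",
                                   "low_complexity")), 0, noise)
  }

  contigs <- structure(list(info = info, seqs = seqset),
                       class = "contig_set")
  coverage <- structure(list(breadth = breadth, pooled = pooled),
                        class = "coverage_table")
  truth <- structure(list(
    sd_system = cfg$sd_system,
    specific_ids = ids[type == "specific"],
    decoy_ids = ids[type == "decoy"],
    false_positive_ids = ids[type == "false_positive"],
    violator_ids = ids[type %in% c("short", "high_n", "low_complexity")]),
    class = "truth_record")
  list(contigs = contigs, coverage = coverage, sheet = sheet, truth = truth)
}

#' Mean Shannon entropy of the overlapping-dinucleotide distribution
#'
#' Computed over the 16 ACGT dinucleotides (pairs containing N or other
#' ambiguity codes are skipped), in bits. A homopolymer scores 0; random
#' sequence approaches 4 bits. Used as the low-complexity/repeat filter in
#' marker-candidate selection.
#'
#' @param seq a single character string (DNA).
#' @return entropy in bits.
#' @export
dinucleotide_entropy <- function(seq) {
  s <- strsplit(toupper(as.character(seq)), "")[[1]]
  if (length(s) < 2) return(0)
  di <- paste0(s[-length(s)], s[-1])
  di <- di[grepl("^[ACGT][ACGT]$", di)]
  if (length(di) == 0) return(0)
  p <- table(di) / length(di)
  max(0, -sum(p * log2(p)))
}
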