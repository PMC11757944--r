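#' Configuration for an end-to-end pipeline run
#'
#' Either `sim` (a [sim_config()]; the cohort is simulated) or
#' `vcf`/`sheet`/`chrom_lengths` paths must be provided. Every threshold
#' is echoed into the run's summary for reproducibility.
#'
#' @param out_dir run directory (created if needed).
#' @param sim optional [sim_config()].
#' @param vcf,sheet_path,chrom_lengths_path input paths when not
#'   simulating.
#' @param qc a [qc_thresholds()].
#' @param screen a [screen_params()].
#' @param screen_mode `"sex_associated_only"` or `"genome_wide"`.
#' @param impute run modal imputation before GWAS/FST/PCA (default
#'   `FALSE`; the sex-locus screen always uses unimputed genotypes).
#' @param sig,sugg,fst_threshold,present_min,absent_max,min_contained,
#'   pca_cutoff,majority_frac,secondary_frac,window_bp stage thresholds.
#' @param coverage optional list of arguments for
#'   [simulate_contig_coverage()] (e.g. `list(n_w_contigs = 20,
#'   n_shared_contigs = 2000, n_decoys = 20)`), or `NULL` to skip the
#'   sequence screen.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, sim = NULL, vcf = NULL,
                            sheet_path = NULL, chrom_lengths_path = NULL,
                            qc = qc_thresholds(), screen = screen_params(),
                            screen_mode = "sex_associated_only",
                            impute = FALSE, sig = 1e-8, sugg = 1e-4,
                            fst_threshold = 0.25, present_min = 0.9,
                            absent_max = 0.05, min_contained = 0.9,
                            pca_cutoff = 0.9, majority_frac = 0.8,
                            secondary_frac = 0.7, window_bp = 1e6,
                            coverage = NULL) {
  if (is.null(sim) && (is.null(vcf) || is.null(sheet_path) ||
                       is.null(chrom_lengths_path))) {
    stop("provide either sim or vcf + sheet_path + chrom_lengths_path")
  }
  structure(list(out_dir = out_dir, sim = sim, vcf = vcf,
                 sheet_path = sheet_path,
                 chrom_lengths_path = chrom_lengths_path, qc = qc,
                 screen = screen, screen_mode = screen_mode,
                 impute = impute, sig = sig, sugg = sugg,
                 fst_threshold = fst_threshold, present_min = present_min,
                 absent_max = absent_max, min_contained = min_contained,
                 pca_cutoff = pca_cutoff, majority_frac = majority_frac,
                 secondary_frac = secondary_frac, window_bp = window_bp,
                 coverage = coverage),
            class = "pipeline_config")
}

#' Run the full sex-determination-region discovery pipeline
#'
#' Stage order: simulate/load -> QC -> (optional modal imputation) ->
#' GWAS -> FST scan -> sex-locus screen (on unimputed genotypes) ->
#' per-chromosome PCA -> region call -> (optional) two-round sequence
#' screen. Every stage writes its table into the run directory and the
#' machine-readable `summary.json` aggregates the headline numbers.
#' Identical config and seed give an identical summary.
#'
#' @param cfg a [pipeline_config()].
#' @param quiet suppress stage messages.
#' @return the summary list, invisibly; artifacts under `cfg$out_dir`.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[sexscan] ", sprintf(...))
  tsv <- function(x, name) {
    utils::write.table(x, file.path(cfg$out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  if (!is.null(cfg$sim)) {
    say("simulating cohort (seed %d)", cfg$sim$seed)
    sim <- simulate_cohort(cfg$sim)
    gm <- sim$gm; sheet <- sim$sheet; truth <- sim$truth
    chrom_lengths <- cfg$sim$chrom_lengths
    write_vcf(gm, file.path(cfg$out_dir, "genotypes.vcf"))
    write_sample_sheet(sheet, file.path(cfg$out_dir, "sample_sheet.tsv"))
    jsonlite::write_json(unclass(truth),
                         file.path(cfg$out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  } else {
    say("reading %s", cfg$vcf)
    sheet <- read_sample_sheet(cfg$sheet_path)
    gm <- read_vcf(cfg$vcf, sheet)
    chrom_lengths <- read_chrom_lengths(cfg$chrom_lengths_path)
    truth <- NULL
  }
  n_pre_qc <- ncol(gm$dosage)

  say("QC filtering %d variants", n_pre_qc)
  qc_res <- apply_qc_filters(gm, cfg$qc)
  gm_qc <- qc_res$gm
  gm_assoc <- if (cfg$impute) impute_missing(gm_qc) else gm_qc
  n_post_qc <- ncol(gm_qc$dosage)

  say("GWAS on %d variants", n_post_qc)
  gwas <- run_gwas(gm_assoc, sheet, sig = cfg$sig, sugg = cfg$sugg)
  tsv(gwas, "gwas.tsv")
  sig_tab <- gwas[gwas$tier == "significant", , drop = FALSE]
  qq <- qq_data(pmax(gwas$p[!is.na(gwas$p)], 1e-300))
  tsv(qq, "qq.tsv")

  say("FST scan")
  fst <- fst_scan(gm_assoc, sheet, threshold = cfg$fst_threshold)
  tsv(fst, "fst.tsv")

  say("sex-locus screen (%s)", cfg$screen_mode)
  ids <- screen_input_selection(gwas, mode = cfg$screen_mode)
  calls <- if (length(ids)) {
    screen_sex_specific(gm_subset(gm_qc, variants = ids), sheet,
                        cfg$screen)
  } else {
    screen_sex_specific(gm_subset(gm_qc, variants = integer(0)), sheet,
                        cfg$screen)
  }
  tsv(calls, "sex_loci.tsv")

  say("per-chromosome PCA")
  pca_scan <- per_chromosome_scan(gm_assoc, sheet)
  tsv(pca_scan, "pca_scores.tsv")

  enrich <- evidence_summary(gwas, fst, calls, pca_scan, chrom_lengths)
  tsv(enrich, "evidence.tsv")
  wd <- window_density(
    data.frame(chrom = sig_tab$chrom, pos0 = sig_tab$pos - 1),
    chrom_lengths, window_bp = cfg$window_bp)
  tsv(wd, "window_density.tsv")

  seq_res <- NULL
  seq_evidence <- "none"
  if (!is.null(cfg$coverage)) {
    if (is.null(cfg$sim)) {
      stop("the coverage stage currently requires a simulation config")
    }
    say("sequence screen")
    cov_sim <- do.call(simulate_contig_coverage,
                       c(list(cfg = cfg$sim), cfg$coverage))
    seq_res <- seq_screen(cov_sim$contigs, cov_sim$coverage,
                          cov_sim$sheet, present_min = cfg$present_min,
                          absent_max = cfg$absent_max)
    tsv(seq_res$round2, "seq_calls.tsv")
    write_contigs_fasta(cov_sim$contigs,
                        file.path(cfg$out_dir, "marker_candidates.fasta"),
                        ids = seq_res$markers$contig)
    spec <- unique(seq_res$round2$specificity)
    seq_evidence <- if (length(spec) == 0) "none"
      else if (setequal(spec, "female_specific")) "female_specific"
      else if (setequal(spec, "male_specific")) "male_specific"
      else "both"
  }

  say("region call")
  region <- call_sex_region(gwas, fst, calls, pca_scan, chrom_lengths,
                            window_bp = cfg$window_bp,
                            min_contained = cfg$min_contained,
                            pca_cutoff = cfg$pca_cutoff,
                            majority_frac = cfg$majority_frac,
                            seq_evidence = seq_evidence,
                            secondary_frac = cfg$secondary_frac)
  jsonlite::write_json(region_call_as_list(region),
                       file.path(cfg$out_dir, "region_call.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)

  summary <- list(
    thresholds = cfg[c("sig", "sugg", "fst_threshold", "present_min",
                       "absent_max", "min_contained", "pca_cutoff",
                       "majority_frac", "secondary_frac", "window_bp",
                       "screen_mode", "impute")],
    qc = list(n_variants_pre_qc = n_pre_qc,
              n_variants_post_qc = n_post_qc,
              removed = as.list(qc_res$removed)),
    gwas = attr(gwas, "summary")[c("n_significant", "n_suggestive",
                                   "n_undefined")],
    fst = list(n_signatures = sum(fst$is_signature, na.rm = TRUE)),
    sex_loci = list(
      n_total = nrow(calls),
      n_female_het = sum(calls$orientation == "female_het"),
      n_male_het = sum(calls$orientation == "male_het")),
    pca = list(best_chrom =
                 pca_scan$chrom[which.max(pca_scan$score_chrom)],
               best_score = max(pca_scan$score_chrom, na.rm = TRUE)),
    seq_screen = if (is.null(seq_res)) NULL else list(
      n_round1 = nrow(seq_res$round1), n_round2 = nrow(seq_res$round2),
      n_markers = nrow(seq_res$markers)),
    region = region_call_as_list(region))
  jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  say("done: %s", cfg$out_dir)
  invisible(summary)
}

region_call_as_list <- function(region) {
  list(status = region$status, reasons = region$reasons,
       chromosome = region$chromosome,
       interval = region$interval,
       contained_fraction = region$contained_fraction,
       system = region$system$system,
       n_female_het_loci = region$system$n_female_het_loci,
       n_male_het_loci = region$system$n_male_het_loci,
       fraction_majority = region$system$fraction_majority,
       sequence_evidence = region$system$sequence_evidence,
       secondary = region$secondary)
}

#' Render a plain-text report of a completed run
#'
#' Mirrors the evidence figures as tables: Manhattan/QQ inputs,
#' per-chromosome enrichment, PCA separation scores, window densities
#' and the region call. Sections whose inputs are missing from the run
#' directory are marked absent.
#'
#' @param run_dir directory written by [run_pipeline()].
#' @param path output file (default `report.txt` inside `run_dir`).
#' @return `path`, invisibly.
#' @export
make_report <- function(run_dir, path = file.path(run_dir, "report.txt")) {
  lines <- c("sexscan run report", strrep("=", 60))
  section <- function(title, file, render) {
    f <- file.path(run_dir, file)
    if (!file.exists(f)) {
      return(c("", title, strrep("-", nchar(title)),
               sprintf("  [section absent: %s not found]", file)))
    }
    c("", title, strrep("-", nchar(title)), render(f))
  }
  fmt_tab <- function(tab, n = 25) {
    utils::capture.output(print(utils::head(tab, n), row.names = FALSE))
  }
  read_tsv <- function(f) utils::read.table(f, sep = "\t", header = TRUE,
                                            stringsAsFactors = FALSE)
  lines <- c(
    lines,
    section("Association summary (Manhattan/QQ data)", "gwas.tsv", function(f) {
      tab <- read_tsv(f)
      c(sprintf("  %d variants tested; %d significant, %d suggestive",
                nrow(tab), sum(tab$tier == "significant"),
                sum(tab$tier == "suggestive")),
        "  top hits:",
        fmt_tab(tab[order(tab$p), c("chrom", "pos", "id", "chi2", "p")], 10))
    }),
    section("Per-chromosome evidence (enrichment, FST, loci, PCA)",
            "evidence.tsv", function(f) fmt_tab(read_tsv(f))),
    section("PCA sex-separation scores", "pca_scores.tsv",
            function(f) fmt_tab(read_tsv(f))),
    section("Window density of significant SNPs", "window_density.tsv",
            function(f) {
              tab <- read_tsv(f)
              fmt_tab(tab[tab$count > 0, , drop = FALSE], 20)
            }),
    section("Sequence screen", "seq_calls.tsv", function(f) {
      tab <- read_tsv(f)
      sprintf("  %d sex-specific contig(s) after round 2 (%s)",
              nrow(tab), paste(unique(tab$specificity), collapse = ", "))
    }),
    section("Region call", "region_call.json", function(f) {
      rc <- jsonlite::read_json(f)
      if (identical(rc$status, "no_call")) {
        sprintf("  NO CALL: %s", paste(unlist(rc$reasons), collapse = "; "))
      } else {
        c(sprintf("  %s [%s, %s) bp; contained fraction %.3f; system %s",
                  rc$chromosome, format(rc$interval[[1]], big.mark = ","),
                  format(rc$interval[[2]], big.mark = ","),
                  rc$contained_fraction, rc$system),
          if (length(rc$secondary))
            sprintf("  secondary candidates: %s",
                    paste(unlist(rc$secondary), collapse = ", ")))
      }
    }))
  writeLines(lines, path)
  invisible(path)
}
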