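#' Read a VCF into a genotype matrix
#'
#' Parses a VCF v4.x file (via vcfR) and returns the dosage matrix for the
#' samples named in the sheet, in sheet order. GT is required; DP and GQ
#' layers are populated when declared in FORMAT. Phased separators (`|`)
#' are accepted and treated as unphased.
#'
#' Dosage mapping: `0/0 -> 0`, `0/1` or `1/0 -> 1`, `1/1 -> 2`,
#' `./.` (or `.`) -> missing. Any other GT string is treated as malformed:
#' the genotype is set missing and a count is reported in a message.
#'
#' @param path path to a VCF (plain text or gzipped).
#' @param sheet a [sample_sheet()]; all its sample_ids must appear in the
#'   VCF header (a missing sample is an error naming it).
#' @param biallelic_only if `TRUE` (default) records with more than one ALT
#'   allele are skipped with a message; if `FALSE` they are an error.
#' @return a [genotype_matrix()].
#' @export
read_vcf <- function(path, sheet, biallelic_only = TRUE) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    if (!biallelic_only) stop(sum(multi), " multi-allelic record(s) present")
    message("skipped ", sum(multi), " multi-allelic record(s)")
    vcf <- vcf[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  if (nrow(fix) == 0) {
    return(genotype_matrix(sheet$sample_id,
                           empty_variant_table(),
                           matrix(integer(0), nrow = nrow(sheet), ncol = 0)))
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  missing_smp <- setdiff(sheet$sample_id, colnames(gt))
  if (length(missing_smp)) {
    stop("sample(s) absent from VCF header: ",
         paste(missing_smp, collapse = ", "))
  }
  gt <- gt[, sheet$sample_id, drop = FALSE]
  gt_clean <- gsub("|", "/", gt, fixed = TRUE)
  dosage <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt))
  dosage[gt_clean %in% c("0/0")] <- 0L
  dosage[gt_clean %in% c("0/1", "1/0")] <- 1L
  dosage[gt_clean %in% c("1/1")] <- 2L
  known <- gt_clean %in% c("0/0", "0/1", "1/0", "1/1", "./.", ".") | is.na(gt)
  if (any(!known)) {
    message("set ", sum(!known), " malformed genotype(s) to missing")
  }
  fmt_keys <- unique(unlist(strsplit(vcf@gt[, "FORMAT"], ":", fixed = TRUE)))
  depth <- qual <- NULL
  if ("DP" %in% fmt_keys) {
    depth <- t(vcfR::extract.gt(vcf, "DP", as.numeric = TRUE)[,
                sheet$sample_id, drop = FALSE])
  }
  if ("GQ" %in% fmt_keys) {
    qual <- t(vcfR::extract.gt(vcf, "GQ", as.numeric = TRUE)[,
               sheet$sample_id, drop = FALSE])
  }
  variants <- data.frame(chrom = fix$CHROM,
                         pos = as.integer(fix$POS),
                         id = ifelse(is.na(fix$ID) | fix$ID == ".",
                                     paste0(fix$CHROM, "_", fix$POS), fix$ID),
                         ref = fix$REF, alt = fix$ALT,
                         stringsAsFactors = FALSE)
  genotype_matrix(sheet$sample_id, variants, t(dosage),
                  depth = depth, qual = qual)
}

empty_variant_table <- function() {
  data.frame(chrom = character(0), pos = integer(0), id = character(0),
             ref = character(0), alt = character(0),
             stringsAsFactors = FALSE)
}

#' Write a genotype matrix as a plain-text VCF v4.2
#'
#' Emits GT (plus DP/GQ when the layers are present); missing genotypes
#' become `./.`. `write_vcf` then `read_vcf` round-trips to an identical
#' dosage matrix. An empty variant list yields a header-only VCF.
#'
#' @param gm a [genotype_matrix()].
#' @param path output path (`.vcf`).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=sexscan",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  fmt <- "GT"
  if (!is.null(gm$depth)) {
    hdr <- c(hdr, '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">')
    fmt <- paste0(fmt, ":DP")
  }
  if (!is.null(gm$qual)) {
    hdr <- c(hdr, '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">')
    fmt <- paste0(fmt, ":GQ")
  }
  for (chrom in unique(gm$variants$chrom)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s>", chrom))
  }
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", gm$samples),
                      collapse = "\t"))
  n_var <- nrow(gm$variants)
  if (n_var == 0) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  gt_map <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  body <- vapply(seq_len(n_var), function(j) {
    d <- gm$dosage[, j]
    cells <- ifelse(is.na(d), "./.", gt_map[as.character(d)])
    if (!is.null(gm$depth)) {
      cells <- paste(cells, ifelse(is.na(gm$depth[, j]), ".",
                                   gm$depth[, j]), sep = ":")
    }
    if (!is.null(gm$qual)) {
      cells <- paste(cells, ifelse(is.na(gm$qual[, j]), ".",
                                   gm$qual[, j]), sep = ":")
    }
    v <- gm$variants[j, ]
    paste(c(v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", ".",
            fmt, cells), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}
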