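#' Construct a sample sheet of phenotypic sexes
#'
#' The sample sheet pairs each sequenced individual with its phenotypic sex
#' and (optionally) its cohort role. Every two-sex operation in the package
#' takes a sample sheet alongside the genotype or coverage data.
#'
#' @param sample_id character vector of unique sample labels.
#' @param sex character vector, one of `"female"`/`"male"` (or `"F"`/`"M"`).
#' @param cohort_role character, `"discovery"` (default) or `"validation"`.
#' @return A `data.frame` of class `sample_sheet` with columns
#'   `sample_id`, `sex`, `cohort_role`.
#' @examples
#' sample_sheet(c("F01", "M01"), c("F", "M"))
#' @export
sample_sheet <- function(sample_id, sex, cohort_role = "discovery") {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) {
    stop("duplicate sample_id: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  }
  sex <- normalize_sex(sex)
  if (length(sex) != length(sample_id)) stop("sex and sample_id lengths differ")
  cohort_role <- rep_len(as.character(cohort_role), length(sample_id))
  if (!all(cohort_role %in% c("discovery", "validation"))) {
    stop("cohort_role must be 'discovery' or 'validation'")
  }
  out <- data.frame(sample_id = sample_id, sex = sex,
                    cohort_role = cohort_role, stringsAsFactors = FALSE)
  class(out) <- c("sample_sheet", "data.frame")
  out
}

normalize_sex <- function(sex) {
  sex <- tolower(as.character(sex))
  sex[sex == "f"] <- "female"
  sex[sex == "m"] <- "male"
  if (!all(sex %in% c("female", "male"))) {
    stop("sex must be one of female/male (or F/M)")
  }
  sex
}

#' Read a sample sheet from a two/three-column TSV
#'
#' Expected columns: `sample_id`, `sex` (F/M or female/male), optional
#' `cohort_role`. A header line is detected automatically.
#'
#' @param path path to a TSV file.
#' @return a [sample_sheet()].
#' @export
read_sample_sheet <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("sample_id", first, fixed = TRUE)
  tab <- utils::read.table(path, sep = "\t", header = has_header,
                           stringsAsFactors = FALSE)
  if (!has_header) {
    names(tab)[1:2] <- c("sample_id", "sex")
    if (ncol(tab) >= 3) names(tab)[3] <- "cohort_role"
  }
  role <- if ("cohort_role" %in% names(tab)) tab$cohort_role else "discovery"
  sample_sheet(tab$sample_id, tab$sex, role)
}

#' Write a sample sheet as TSV
#' @param sheet a [sample_sheet()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(sheet, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a chromosome-length table (chrom, length_bp) from TSV
#' @param path path to a two-column TSV (header optional).
#' @return named numeric vector of lengths in bp, natural chromosome order.
#' @export
read_chrom_lengths <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("chrom", first, fixed = TRUE)
  tab <- utils::read.table(path, sep = "\t", header = has_header,
                           stringsAsFactors = FALSE)
  lens <- stats::setNames(as.numeric(tab[[2]]), as.character(tab[[1]]))
  lens[order_chromosomes(names(lens))]
}

#' Natural-order chromosome sorting
#'
#' Orders labels such as `chr2 < chr10` by their numeric suffix, falling
#' back to lexicographic order for non-numeric labels.
#'
#' @param chroms character vector of chromosome labels.
#' @return integer permutation ordering `chroms` naturally.
#' @export
order_chromosomes <- function(chroms) {
  chroms <- as.character(chroms)
  prefix <- sub("[0-9]+$", "", chroms)
  num <- suppressWarnings(as.numeric(sub("^.*?([0-9]+)$", "\\1", chroms)))
  num[!grepl("[0-9]+$", chroms)] <- Inf
  order(prefix, num, chroms)
}

sex_index <- function(sheet, samples) {
  i <- match(sheet$sample_id, samples)
  if (anyNA(i)) {
    stop("sample(s) in sheet absent from genotype data: ",
         paste(sheet$sample_id[is.na(i)], collapse = ", "))
  }
  list(female = i[sheet$sex == "female"], male = i[sheet$sex == "male"])
}
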