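test_that("read_vcf maps GT strings to dosages, accepting phased separators", {
  sheet <- sample_sheet(c("A", "B"), c("F", "M"))
  vcf <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tA\tB",
           "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/0\t0|1",
           "chr1\t200\t.\tC\tT\t.\tPASS\t.\tGT\t1/1\t./.")
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, f)
  gm <- read_vcf(f, sheet)
  # rows = samples (A, B), columns = variants (pos 100, 200)
  expect_identical(unname(gm$dosage),
                   matrix(c(0L, 1L, 2L, NA), nrow = 2))
  expect_identical(gm$variants$pos, c(100L, 200L))
})

test_that("read_vcf errors on sheet samples absent from the header and skips multi-allelics", {
  sheet <- sample_sheet(c("A", "C"), c("F", "M"))
  vcf <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tA\tB",
           "chr1\t100\t.\tA\tG,T\t.\tPASS\t.\tGT\t0/0\t1/2",
           "chr1\t200\t.\tC\tT\t.\tPASS\t.\tGT\t0/1\t1/1")
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, f)
  expect_error(read_vcf(f, sheet), "absent from VCF header.*C")
  sheet2 <- sample_sheet(c("A", "B"), c("F", "M"))
  expect_message(gm <- read_vcf(f, sheet2), "multi-allelic")
  expect_equal(ncol(gm$dosage), 1)
  expect_identical(unname(gm$dosage[, 1]), c(1L, 2L))
})

test_that("write_vcf / read_vcf round-trips the dosage layer (property)", {
  set.seed(11)
  sheet8 <- make_sheet(4, 4)
  for (rep in 1:5) {
    gm <- random_gm(8, 15)
    f <- withr::local_tempfile(fileext = ".vcf")
    write_vcf(gm, f)
    back <- read_vcf(f, sheet8)
    expect_identical(back$dosage, gm$dosage)
    expect_equal(back$variants$pos, gm$variants$pos)
  }
  # DP/GQ layers round-trip too
  gm <- make_gm(matrix(c(0L, 1L, 2L, NA), 2),
                depth = matrix(5:8, 2), qual = matrix(99, 2, 2))
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(gm, f)
  back <- read_vcf(f, make_sheet(1, 1))
  expect_identical(back$dosage, gm$dosage)
  expect_equal(unname(back$depth), unname(matrix(as.numeric(5:8), 2)))
  expect_equal(unname(back$qual), matrix(99, 2, 2))
})

test_that("write_vcf emits ./. for missing and a header-only file for zero variants", {
  gm <- make_gm(matrix(c(NA, 1L), 1))
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(gm, f)
  expect_true(any(grepl("\\./\\.", readLines(f))))
  gm0 <- genotype_matrix("S01",
                         data.frame(chrom = character(0), pos = integer(0),
                                    id = character(0), ref = character(0),
                                    alt = character(0)),
                         matrix(integer(0), 1, 0))
  write_vcf(gm0, f)
  lines <- readLines(f)
  expect_true(all(startsWith(lines, "#")))
})

test_that("QC filters remove exactly the constructed violators, in order", {
  # 8 samples, 6 variants: one per failure mode, two clean
  d <- cbind(
    c(0, 1, 1, 0, 1, 0, 1, 0),   # v1: two GQ-masked -> call rate 6/8
    c(0, 1, 1, 0, 1, 0, 1, 0),   # v2: mean depth 5 (low)
    c(0, 1, 1, 0, 1, 0, 1, 0),   # v3: mean depth 400 (high)
    c(0, 0, 0, 0, 0, 0, 0, 0),   # v4: MAF 0 < 0.05
    c(0, 1, 1, 0, 1, 0, 1, 0),   # v5: clean
    c(2, 1, 1, 2, 1, 0, 1, 0))   # v6: clean
  depth <- matrix(10, 8, 6); depth[, 2] <- 5; depth[, 3] <- 400
  qual <- matrix(99, 8, 6); qual[1:2, 1] <- 10
  gm <- make_gm(d, depth = depth, qual = qual)
  res <- apply_qc_filters(gm, qc_thresholds())
  expect_identical(res$gm$variants$id, gm$variants$id[5:6])
  expect_identical(res$removed,
                   c(gq_masked_genotypes = 2L, mean_depth = 2L,
                     call_rate = 1L, maf = 1L))
})

test_that("QC filtering is idempotent and its output satisfies the thresholds", {
  set.seed(21)
  cfg <- sim_config(n_background_snps = 800, seed = 21,
                    maf_background = c(0.02, 0.5), missing_rate = 0.06)
  sim <- simulate_cohort(cfg)
  t <- qc_thresholds()
  res <- apply_qc_filters(sim$gm, t)
  expect_true(all(variant_maf(res$gm$dosage) >= t$min_maf))
  expect_true(all(colMeans(!is.na(res$gm$dosage)) >= t$min_call_rate))
  res2 <- apply_qc_filters(res$gm, t)
  expect_identical(sum(res2$removed[-1]), 0L)
  expect_identical(res2$gm$variants$id, res$gm$variants$id)
})

test_that("boundary variants fall on the documented side of each threshold", {
  # MAF 0.04 among non-missing calls is removed; mean depth 5.0 is removed
  d <- cbind(c(1L, rep(0L, 11), NA), rep(c(0L, 1L), c(6, 7)))
  # first column: 1 het of 12.5 non-missing -> maf 1/24 = 0.042
  depth <- matrix(10, 13, 2)
  gm <- make_gm(d, depth = depth, qual = matrix(99, 13, 2))
  res <- apply_qc_filters(gm, qc_thresholds(min_call_rate = 0.5))
  expect_identical(unname(res$removed["maf"]), 1L)
  gm2 <- make_gm(cbind(rep(c(0L, 1L), 4)), depth = matrix(5, 8, 1),
                 qual = matrix(99, 8, 1))
  expect_warning(res2 <- apply_qc_filters(gm2, qc_thresholds()),
                 "all variants removed")
  expect_identical(unname(res2$removed["mean_depth"]), 1L)
})

test_that("modal imputation fills by per-variant mode with the 0>1>2 tie-break", {
  gm <- make_gm(cbind(c(0L, 0L, 1L, NA),
                      c(0L, 1L, 2L, 2L),
                      c(0L, 0L, 1L, 1L)))
  gm$dosage[4, 3] <- NA
  out <- impute_missing(gm)
  expect_identical(unname(out$dosage[4, 1]), 0L)     # mode 0
  expect_identical(unname(out$dosage[, 2]), c(0L, 1L, 2L, 2L))  # untouched
  expect_identical(unname(out$dosage[4, 3]), 0L)     # 2-2 tie on {0,1}: 0 wins
  gm_all_na <- make_gm(cbind(c(NA, NA, NA)))
  expect_warning(out2 <- impute_missing(gm_all_na), "all genotypes missing")
  expect_true(all(is.na(out2$dosage)))
})

test_that("sample sheets validate sexes and reject duplicate ids", {
  expect_error(sample_sheet(c("a", "a"), c("F", "M")), "duplicate")
  expect_error(sample_sheet("a", "x"), "sex must be")
  sh <- sample_sheet(c("a", "b"), c("F", "male"))
  expect_identical(sh$sex, c("female", "male"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_sample_sheet(sh, f)
  expect_identical(read_sample_sheet(f)$sex, sh$sex)
})

test_that("chromosome labels sort naturally (chr2 before chr10)", {
  x <- c("chr10", "chr2", "chr1", "chr22")
  expect_identical(x[order_chromosomes(x)],
                   c("chr1", "chr2", "chr10", "chr22"))
})
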