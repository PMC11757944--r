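test_that("identical configs give identical cohorts; different seeds differ", {
  cfg <- sim_config(n_background_snps = 500, seed = 9)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$gm$dosage, b$gm$dosage)
  expect_identical(a$gm$depth, b$gm$depth)
  expect_identical(a$truth, b$truth)
  c_ <- simulate_cohort(sim_config(n_background_snps = 500, seed = 10))
  expect_false(identical(a$gm$dosage, c_$gm$dosage))
})

test_that("noiseless ZW cohorts have every fully linked SNP het in females, hom-ref in males", {
  cfg <- sim_config(n_background_snps = 200, het_miscall_rate = 0,
                    missing_rate = 0, seed = 4)
  sim <- simulate_cohort(cfg)
  fi <- match(sim$truth$full_ids, sim$gm$variants$id)
  f_rows <- sim$sheet$sex == "female"
  expect_true(all(sim$gm$dosage[f_rows, fi] == 1L))
  expect_true(all(sim$gm$dosage[!f_rows, fi] == 0L))
  expect_true(all(sim$gm$variants$chrom[fi] == cfg$sd_chrom))
  pos0 <- sim$gm$variants$pos[fi] - 1
  expect_true(all(pos0 >= cfg$sd_interval[1] & pos0 < cfg$sd_interval[2]))
})

test_that("XY mirrors ZW with the sexes swapped", {
  mk <- function(sys) simulate_cohort(
    sim_config(n_background_snps = 100, sd_system = sys,
               het_miscall_rate = 0, missing_rate = 0, seed = 8))
  zw <- mk("ZW"); xy <- mk("XY")
  fi_zw <- match(zw$truth$full_ids, zw$gm$variants$id)
  fi_xy <- match(xy$truth$full_ids, xy$gm$variants$id)
  m_rows <- xy$sheet$sex == "male"
  expect_true(all(xy$gm$dosage[m_rows, fi_xy] == 1L))
  expect_true(all(xy$gm$dosage[!m_rows, fi_xy] == 0L))
})

test_that("the observed female het rate at fully linked SNPs matches the miscall model", {
  cfg <- sim_config(n_background_snps = 0, n_sd_full = 200, n_sd_partial = 0,
                    het_miscall_rate = 0.02, missing_rate = 0, seed = 12)
  sim <- simulate_cohort(cfg)
  fi <- match(sim$truth$full_ids, sim$gm$variants$id)
  f_rows <- sim$sheet$sex == "female"
  rate <- mean(sim$gm$dosage[f_rows, fi] == 1L)
  n <- sum(f_rows) * length(fi)
  se <- sqrt(0.98 * 0.02 / n)
  expect_lt(abs(rate - 0.98), 3 * se)
})

test_that("null cohorts carry no linked variants and genotypes are sex-independent", {
  cfg <- sim_config(sd_system = "none", n_background_snps = 300, seed = 3)
  sim <- simulate_cohort(cfg)
  expect_length(sim$truth$full_ids, 0)
  expect_length(sim$truth$partial_ids, 0)
  expect_equal(ncol(sim$gm$dosage), 300)
})

test_that("an interval too small for the requested linked SNPs errors", {
  cfg <- sim_config(n_background_snps = 10, sd_interval = c(0, 150),
                    n_sd_full = 100, n_sd_partial = 100, seed = 1)
  expect_error(simulate_cohort(cfg), "too small")
})

test_that("contig coverage simulation plants the documented structure", {
  cfg <- sim_config(n_female = 5, n_male = 5, seed = 6)
  cs <- simulate_contig_coverage(cfg, n_w_contigs = 20,
                                 n_shared_contigs = 50, n_decoys = 10,
                                 noise = 0)
  B <- cs$coverage$breadth
  f_cols <- cs$sheet$sample_id[cs$sheet$sex == "female"]
  m_cols <- cs$sheet$sample_id[cs$sheet$sex == "male"]
  w <- cs$truth$specific_ids
  expect_length(w, 20)
  expect_true(all(B[w, f_cols] > 0.9))
  expect_true(all(B[w, m_cols] == 0))
  for (d in cs$truth$decoy_ids) {
    expect_equal(sum(B[d, f_cols] == 0), 1)  # exactly one female uncovered
  }
  # XY mirror: male-specific contigs instead
  cfg_xy <- sim_config(n_female = 5, n_male = 5, sd_system = "XY",
                       sd_chrom = "chr10", seed = 6)
  cs_xy <- simulate_contig_coverage(cfg_xy, n_w_contigs = 4,
                                    n_shared_contigs = 10, n_decoys = 0)
  Bxy <- cs_xy$coverage$breadth
  expect_true(all(Bxy[cs_xy$truth$specific_ids,
                      cs_xy$sheet$sample_id[cs_xy$sheet$sex == "male"]] > 0.9))
  expect_true(all(Bxy[cs_xy$truth$specific_ids, f_cols] == 0))
  expect_error(simulate_contig_coverage(cfg, n_w_contigs = -1),
               "non-negative")
  expect_error(simulate_contig_coverage(sim_config(sd_system = "none")),
               "ZW or XY")
})

test_that("contig sequences carry their annotated length, N-fraction and entropy", {
  cfg <- sim_config(n_female = 3, n_male = 3, seed = 2)
  cs <- simulate_contig_coverage(cfg, n_w_contigs = 3, n_shared_contigs = 5,
                                 n_decoys = 0, n_high_n = 2,
                                 n_low_complexity = 2)
  info <- cs$contigs$info
  expect_identical(info$length,
                   unname(Biostrings::width(cs$contigs$seqs[info$id])))
  expect_true(all(info$n_fraction[info$type == "high_n"] > 0.1))
  expect_true(all(info$entropy[info$type == "low_complexity"] == 0))
  expect_true(all(info$entropy[info$type == "specific"] > 3))
})

test_that("dinucleotide entropy is 0 for homopolymers and ~4 bits for random sequence", {
  expect_equal(dinucleotide_entropy(strrep("A", 500)), 0)
  expect_equal(dinucleotide_entropy("ATATATATAT"), 1, tolerance = 0.1)
  set.seed(1)
  rnd <- paste(sample(c("A", "C", "G", "T"), 5000, replace = TRUE),
               collapse = "")
  expect_gt(dinucleotide_entropy(rnd), 3.9)
  expect_equal(dinucleotide_entropy("ANNA"), 0)  # no clean ACGT pair except none
})
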