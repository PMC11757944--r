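test_that("breadth from a depth track counts positions at or above min_depth", {
  track <- data.frame(contig = rep("c1", 10), pos0 = 0:9,
                      depth = c(rep(3, 5), rep(0, 5)))
  lens <- c(c1 = 10, c2 = 4)
  b <- breadth_from_depth(track, lens)
  expect_equal(unname(b), c(0.5, 0))
  expect_equal(unname(breadth_from_depth(
    data.frame(contig = "c1", pos0 = 0:9, depth = rep(1, 10)),
    lens, min_depth = 2)["c1"]), 0)
  expect_equal(unname(breadth_from_depth(
    data.frame(contig = "c1", pos0 = 0:9, depth = rep(3, 10)),
    c(c1 = 10))["c1"]), 1)
  expect_error(breadth_from_depth(track[0, ], lens), "empty")
  track$depth[1] <- -1
  expect_error(breadth_from_depth(track, lens), "non-negative")
})

test_that("round 1 requires presence in every same-sex and absence in every other-sex sample", {
  sheet <- make_sheet(5, 5)
  B <- matrix(0, 4, 10, dimnames = list(paste0("c", 1:4), sheet$sample_id))
  B["c1", 1:5] <- 0.95                      # clean female-specific
  B["c2", 1:5] <- c(0.95, 0.95, 0.95, 0.95, 0.5)  # one female below present_min
  B["c3", 1:5] <- 0.95; B["c3", 6] <- 0.2   # one male above absent_max
  B["c4", 6:10] <- 0.98                     # clean male-specific
  res <- round1_screen(B, sheet)
  expect_identical(res$contig, c("c1", "c4"))
  expect_identical(res$specificity, c("female_specific", "male_specific"))
  expect_error(round1_screen(B[, 1:9], sheet), "absent from coverage")
})

test_that("round 2 removes candidates with pooled opposite-sex coverage, with reasons", {
  calls <- data.frame(contig = c("c1", "c2"),
                      specificity = "female_specific", round_passed = 1L)
  class(calls) <- c("contig_calls", "data.frame")
  pooled <- matrix(c(0, 0.3), 2, 1,
                   dimnames = list(c("c1", "c2"), "male_pool"))
  res <- round2_screen(calls, pooled)
  expect_identical(res$contig, "c1")
  expect_identical(res$round_passed, 2L)
  removed <- attr(res, "removed")
  expect_identical(removed$contig, "c2")
  expect_match(removed$exclusion_reason, "pooled opposite-sex breadth")
  expect_error(round2_screen(calls, pooled[1, , drop = FALSE]),
               "missing from pooled")
  empty <- round2_screen(calls[0, ], pooled)
  expect_identical(nrow(empty), 0L)
})

test_that("zero-noise screens are exact against the truth record, decoys never called", {
  for (seed in 1:3) {
    cfg <- sim_config(n_female = 5, n_male = 5, seed = seed)
    cs <- simulate_contig_coverage(cfg, n_w_contigs = 20,
                                   n_shared_contigs = 300, n_decoys = 20)
    res <- seq_screen(cs$contigs, cs$coverage, cs$sheet)
    expect_setequal(res$round2$contig, cs$truth$specific_ids)
    expect_setequal(res$markers$contig, cs$truth$specific_ids)
    expect_length(intersect(res$round1$contig, cs$truth$decoy_ids), 0)
    expect_true(all(res$round2$contig %in% res$round1$contig))
  }
})

test_that("the XY mirror produces male-specific calls at the same construction indices", {
  mk <- function(sys) {
    cfg <- sim_config(n_female = 5, n_male = 5, sd_system = sys, seed = 50)
    simulate_contig_coverage(cfg, n_w_contigs = 10, n_shared_contigs = 50,
                             n_decoys = 5)
  }
  zw <- mk("ZW"); xy <- mk("XY")
  res_zw <- seq_screen(zw$contigs, zw$coverage, zw$sheet)
  res_xy <- seq_screen(xy$contigs, xy$coverage, xy$sheet)
  expect_true(all(res_zw$round2$specificity == "female_specific"))
  expect_true(all(res_xy$round2$specificity == "male_specific"))
  expect_identical(sub("^W", "", res_zw$round2$contig),
                   sub("^Y", "", res_xy$round2$contig))
})

test_that("raising present_min or lowering absent_max never adds a round-1 call", {
  cfg <- sim_config(n_female = 5, n_male = 5, seed = 60)
  cs <- simulate_contig_coverage(cfg, n_w_contigs = 10,
                                 n_shared_contigs = 100, n_decoys = 10,
                                 noise = 0.04)
  calls_at <- function(pm, am)
    round1_screen(cs$coverage, cs$sheet, present_min = pm,
                  absent_max = am)$contig
  base <- calls_at(0.9, 0.05)
  expect_true(all(calls_at(0.95, 0.05) %in% base))
  expect_true(all(calls_at(0.9, 0.02) %in% base))
  expect_true(all(base %in% calls_at(0.85, 0.05)))
})

test_that("marker filters exclude exactly the planted length/N/complexity violators", {
  cfg <- sim_config(n_female = 5, n_male = 5, seed = 70)
  cs <- simulate_contig_coverage(cfg, n_w_contigs = 15,
                                 n_shared_contigs = 100, n_decoys = 5,
                                 n_short = 3, n_high_n = 3,
                                 n_low_complexity = 3)
  res <- seq_screen(cs$contigs, cs$coverage, cs$sheet)
  expect_setequal(res$round2$contig,
                  c(cs$truth$specific_ids, cs$truth$violator_ids))
  expect_setequal(res$markers$contig, cs$truth$specific_ids)
  excl <- attr(res$markers, "excluded")
  expect_setequal(excl$contig, cs$truth$violator_ids)
  expect_match(excl$exclusion_reason[grep("short", excl$contig)], "length")
  expect_match(excl$exclusion_reason[grep("nrich", excl$contig)], "N-fraction")
  expect_match(excl$exclusion_reason[grep("lowc", excl$contig)], "low complexity")
  # a 999 bp clean contig is excluded by the length rule, 1500 bp retained
  toy_calls <- data.frame(contig = c("a", "b"),
                          specificity = "female_specific",
                          round_passed = 2L)
  toy_set <- list(info = data.frame(id = c("a", "b"),
                                    length = c(1500L, 999L),
                                    n_fraction = 0, entropy = 3.8))
  kept <- filter_marker_candidates(toy_calls, toy_set)
  expect_identical(kept$contig, "a")
})
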