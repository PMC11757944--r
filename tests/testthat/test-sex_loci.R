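test_that("the heterozygote-count screen enforces both bounds with missing excluded", {
  sheet <- make_sheet(6, 6)
  d_flag <- c(rep(1L, 6), rep(0L, 6))        # 6 female hets, 0 male hets
  d_boundary <- c(rep(1L, 3), rep(0L, 9))    # 3 female hets: below c = 4
  d_leak <- c(rep(1L, 6), 1L, rep(0L, 5))    # one male het defeats e = 0
  d_missing <- c(rep(1L, 4), NA, NA, rep(NA, 2), rep(0L, 4))
  gm <- make_gm(cbind(d_flag, d_boundary, d_leak, d_missing))
  res <- screen_sex_specific(gm, sheet, screen_params(4, 0))
  expect_identical(res$id, gm$variants$id[c(1, 4)])
  expect_true(all(res$orientation == "female_het"))
  expect_identical(res$n_het_female, c(6L, 4L))
  expect_identical(res$n_hom_other_sex, c(6L, 4L))
  # mirrored male orientation
  gm_m <- make_gm(cbind(rev(d_flag)))
  res_m <- screen_sex_specific(gm_m, sheet, screen_params(4, 0))
  expect_identical(res_m$orientation, "male_het")
  expect_error(screen_sex_specific(gm, sheet, screen_params(7, 0)),
               "exceeds a sex's sample size")
})

test_that("screen output equals direct evaluation over systematic small matrices", {
  sheet <- make_sheet(4, 4)
  patterns <- expand.grid(f_het = 0:4, m_het = 0:4, f_miss = 0:1)
  patterns <- patterns[patterns$f_het + patterns$f_miss <= 4, ]
  set.seed(55)
  for (cc in c(2, 3)) for (ee in c(0, 1)) {
    cols <- lapply(seq_len(nrow(patterns)), function(k) {
      p <- patterns[k, ]
      f <- c(rep(1L, p$f_het), rep(NA_integer_, p$f_miss),
             rep(0L, 4 - p$f_het - p$f_miss))
      m <- c(rep(1L, p$m_het), rep(2L, 4 - p$m_het))
      c(sample(f), sample(m))
    })
    gm <- make_gm(do.call(cbind, cols))
    got <- screen_sex_specific(gm, sheet, screen_params(cc, ee))
    want <- oracle_screen(gm, sheet, cc, ee)
    if (is.null(want)) {
      expect_identical(nrow(got), 0L)
    } else {
      expect_identical(got$id, want$id)
      expect_identical(got$orientation, want$orientation)
    }
  }
})

test_that("raising c or lowering e never adds a flagged locus", {
  set.seed(77)
  sheet <- make_sheet(6, 6)
  d <- matrix(sample(c(0:2, NA), 12 * 60, replace = TRUE,
                     prob = c(0.3, 0.4, 0.2, 0.1)), 12, 60)
  gm <- make_gm(d)
  flagged <- function(cc, ee)
    screen_sex_specific(gm, sheet, screen_params(cc, ee))$id
  for (ee in 0:2) {
    prev <- flagged(1, ee)
    for (cc in 2:5) {
      cur <- flagged(cc, ee)
      expect_true(all(cur %in% prev))
      prev <- cur
    }
  }
  for (cc in 2:4) {
    expect_true(all(flagged(cc, 0) %in% flagged(cc, 1)))
    expect_true(all(flagged(cc, 1) %in% flagged(cc, 2)))
  }
})

test_that("fully linked SNPs survive the screen under realistic het miscall", {
  for (seed in 1:3) {
    cfg <- sim_config(n_background_snps = 300, het_miscall_rate = 0.1,
                      missing_rate = 0, seed = seed)
    sim <- simulate_cohort(cfg)
    res <- screen_sex_specific(sim$gm, sim$sheet, screen_params(25, 0))
    expect_true(all(sim$truth$full_ids %in% res$id))
  }
})

test_that("screen input selection restricts to sex-associated variants", {
  d <- cbind(c(rep(1L, 4), rep(0L, 4)), rep(c(0L, 1L), 4), rep(c(0L, 2L), 4))
  gm <- make_gm(d)
  assoc <- run_gwas(gm, make_sheet(4, 4), sig = 0.01, sugg = 0.05)
  ids <- screen_input_selection(assoc)
  expect_identical(as.character(ids), assoc$id[1])
  expect_identical(attr(ids, "mode"), "sex_associated_only")
  all_ids <- screen_input_selection(assoc, "genome_wide")
  expect_identical(as.character(all_ids), assoc$id)
  empty <- run_gwas(gm_subset(gm, variants = integer(0)), make_sheet(4, 4))
  expect_length(screen_input_selection(empty), 0)
})

test_that("heterogamety is inferred from locus orientation and sequence evidence", {
  calls <- data.frame(orientation = rep(c("female_het", "male_het"),
                                        c(118, 1)))
  inf <- infer_system(calls, seq_evidence = "female_specific")
  expect_identical(inf$system, "ZW")
  expect_equal(inf$fraction_majority, 118 / 119, tolerance = 1e-12)
  expect_true(inf$consistent)
  # mirrored counts -> XY
  calls_xy <- data.frame(orientation = rep(c("female_het", "male_het"),
                                           c(1, 118)))
  expect_identical(infer_system(calls_xy)$system, "XY")
  # even split -> inconclusive; sequence evidence alone can decide
  split <- data.frame(orientation = rep(c("female_het", "male_het"), 60))
  expect_identical(infer_system(split)$system, "inconclusive")
  expect_identical(infer_system(split[0, , drop = FALSE],
                                seq_evidence = "female_specific")$system,
                   "ZW")
  expect_identical(infer_system(NULL)$system, "inconclusive")
})
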