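# Independent oracles and small fixture builders used across the suite.

# Brute-force Pearson chi-square on a 2x2 table via expected counts.
oracle_chisq <- function(tab) {
  tab <- as.matrix(tab)
  if (any(colSums(tab) == 0)) return(c(chi2 = NA_real_, p = NA_real_))
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chi2 <- sum((tab - E)^2 / E)
  c(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE))
}

# Weir-Cockerham per-site FST via the nested ANOVA route (sums of squares
# over gene copies within individuals within groups), independent of the
# closed-form coefficients used by the implementation.
oracle_wc_fst <- function(df, dm) {
  df <- df[!is.na(df)]; dm <- dm[!is.na(dm)]
  groups <- list(df, dm); r <- 2
  n <- vapply(groups, length, numeric(1)); N <- sum(n)
  x <- lapply(groups, function(g) g / 2)
  xbar_i <- vapply(x, mean, numeric(1))
  xbar <- sum(n * xbar_i) / N
  SSG <- 0.5 * sum(vapply(groups, function(g) sum(g == 1), numeric(1)))
  SSI <- 2 * sum(mapply(function(xi, m) sum((xi - m)^2), x, xbar_i))
  SSP <- 2 * sum(n * (xbar_i - xbar)^2)
  MSG <- SSG / N; MSI <- SSI / (N - r); MSP <- SSP / (r - 1)
  nc <- (N - sum(n^2) / N) / (r - 1)
  a <- (MSP - MSI) / (2 * nc); b <- (MSI - MSG) / 2; c <- MSG
  if (a + b + c == 0) return(NA_real_)
  a / (a + b + c)
}

# Direct evaluation of the sex-specific-locus inequality, one variant and
# orientation at a time.
oracle_screen <- function(gm, sheet, c_, e_) {
  out <- NULL
  for (j in seq_len(ncol(gm$dosage))) {
    d <- gm$dosage[, j]
    hf <- hm <- 0
    for (i in seq_along(gm$samples)) {
      sex <- sheet$sex[sheet$sample_id == gm$samples[i]]
      if (!is.na(d[i]) && d[i] == 1) {
        if (sex == "female") hf <- hf + 1 else hm <- hm + 1
      }
    }
    if (hf >= c_ && hm <= e_) {
      out <- rbind(out, data.frame(id = gm$variants$id[j],
                                   orientation = "female_het"))
    }
    if (hm >= c_ && hf <= e_) {
      out <- rbind(out, data.frame(id = gm$variants$id[j],
                                   orientation = "male_het"))
    }
  }
  out
}

# Small genotype-matrix builder from a dosage matrix (samples x variants).
make_gm <- function(dosage, chrom = NULL, pos = NULL,
                    depth = NULL, qual = NULL) {
  dosage <- as.matrix(dosage)
  n <- nrow(dosage); m <- ncol(dosage)
  samples <- sprintf("S%02d", seq_len(n))
  if (is.null(chrom)) chrom <- rep("chr1", m)
  if (is.null(pos)) pos <- seq_len(m) * 100L
  variants <- data.frame(chrom = chrom, pos = pos,
                         id = paste0(chrom, "_", pos),
                         ref = "A", alt = "G", stringsAsFactors = FALSE)
  genotype_matrix(samples, variants, dosage, depth = depth, qual = qual)
}

make_sheet <- function(n_f, n_m) {
  sample_sheet(sprintf("S%02d", seq_len(n_f + n_m)),
               c(rep("female", n_f), rep("male", n_m)))
}

# Random dosage matrix with optional missingness, for round-trip tests.
random_gm <- function(n = 8, m = 12, miss = 0.1) {
  d <- matrix(sample(c(0:2, NA), n * m, replace = TRUE,
                     prob = c((1 - miss) / 3, (1 - miss) / 3,
                              (1 - miss) / 3, miss)), n, m)
  make_gm(d, chrom = sample(c("chr1", "chr2"), m, replace = TRUE),
          pos = sample.int(1e6, m))
}
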