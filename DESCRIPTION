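Package: sexscan
Title: Sex-Determination Region Discovery from Re-Sequencing Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Maps candidate sex-determination regions from a genotype matrix
    of phenotypically sexed diploid individuals. Implements the allelic
    chi-square genome-wide association test of binary sex, per-site
    Weir-Cockerham fixation index between the sexes, a heterozygote-count
    screen for sex-specific loci, per-chromosome enrichment and 1-Mb window
    densities, genotype PCA with a quantitative sex-separation score, an
    integrated candidate-region caller with ZW/XY heterogamety inference,
    and a two-round coverage presence/absence screen for sex-specific
    sequences. A seeded synthetic-cohort generator produces genotype and
    contig-coverage data with planted sex-linked structure for power and
    recovery analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
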