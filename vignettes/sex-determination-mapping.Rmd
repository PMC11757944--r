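---
title: "Mapping a sex-determination region from re-sequencing genotypes"
author: "sexscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a sex-determination region from re-sequencing genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sexscan)
```

## The problem

Many marine invertebrates have no morphologically distinguishable sexes
and no heteromorphic sex chromosomes visible in karyotypes. When a
species nevertheless has genetic sex determination (GSD), the signal is
written into its genotypes: in a female-heterogametic (ZW) system, SNPs
inside the recombination-suppressed sex-determining region are
heterozygous in females (Z/W) and homozygous in males (Z/Z); in a
male-heterogametic (XY) system the pattern mirrors. Whole-genome
re-sequencing of a few dozen phenotypically sexed individuals is enough
to find that region — provided the statistics respect the quirks of
~10x short-read data, above all the tendency of low coverage to
under-call heterozygotes as homozygotes.

sexscan implements the full desk-side analysis for this design: from a
VCF of sexed diploids to a ranked candidate chromosome, a localized
candidate interval, an inferred heterogametic system, and (from
coverage tables) candidate sex-specific marker sequences. A seeded
simulator generates cohorts with planted sex-linked structure so every
stage can be exercised and verified without raw sequencing data.

## Evidence tracks

Four independent tracks are computed from the same genotype matrix and
then integrated.

**Allelic association.** For each variant, alleles are counted per sex
over non-missing genotypes and tested with the basic 1-df allelic
chi-square (no continuity correction),

$$\chi^2 = \frac{N\,(ad - bc)^2}{r_1 r_2 c_1 c_2},$$

the classic case-control allelic test. A fully sex-linked SNP in a
40-vs-40 cohort gives the table `[[40, 40], [80, 0]]`, hence
$\chi^2 = 160/3 \approx 53.3$ and $p \approx 2.8\times 10^{-13}$ —
comfortably below the genome-wide `1e-8` threshold used for the
"significant" tier (`1e-4` marks the "suggestive" tier). No
multiple-testing correction is applied: fixed genome-wide thresholds
are the convention for this design and both are configuration. Sites
monomorphic across both sexes have no defined test and are flagged
`undefined` rather than dropped.

**Between-sex FST.** Sex-linked loci mimic population differentiation
between the sexes. sexscan computes the per-site Weir–Cockerham (1984)
variance-component estimator for two groups of unequal size
($\theta = a/(a+b+c)$, with the within-individual component taken from
observed heterozygote frequencies), retains negative estimates, and
flags sites with $F_{ST} > 0.25$ as selection signatures. The all-het
female / all-hom male ZW pattern at 40v40 gives exactly 0.5; a fixed
difference gives 1. The test suite checks the closed-form coefficients
against an independent nested-ANOVA evaluation (sums of squares over
gene copies within individuals within groups) to 1e-12.

**Heterozygote-count screen.** A locus is *sex-specific* when at least
`c` individuals of one sex are heterozygous and at most `e` of the
other sex are (defaults `c = 25`, `e = 0` for 40 per sex). The
asymmetry is deliberate: under-called heterozygotes make the focal-sex
count conservative, so `c` sits well below the sample size, while the
other-sex bound stays strict. Missing genotypes count as neither het
nor hom — they can neither defeat the `e` bound nor help reach `c`.
The screen always runs on **unimputed** genotypes: modal imputation is
available (`impute_missing()`, off by default) as a documented simple
stand-in for statistical imputation, but fabricating heterozygotes
upstream of this screen would corrupt its logic. The orientation of
the flagged loci (female-het vs male-het) is what identifies the
heterogametic sex: a majority fraction of at least 0.8 calls ZW or XY,
and sex-specific sequence evidence can corroborate or substitute. The
0.8 default is far below the near-unanimity seen in clean data
(planted regions give fractions near 1) but high enough that a
balanced split stays inconclusive.

**Genotype PCA.** Dosages are standardized GCTA-style (center $2\hat p$,
scale $\sqrt{2\hat p(1-\hat p)}$, mean-fill missing) and the sample
components are taken from the eigendecomposition of the sample-Gram
matrix — equivalent to the SVD of the standardized matrix and to the
leading eigenvectors of a genetic relationship matrix, but cheap enough
to repeat per chromosome. "Clearly distinguishes the sexes" is made
quantitative as the **separation score**: the maximum absolute
point-biserial correlation between either of the first two components
and the sex label. The per-chromosome scan computes each chromosome's
score alone and with the chromosome excluded; a genuine
sex-determination chromosome scores high alone (cutoff 0.9) and its
exclusion collapses the genome-wide score. The 0.9 cutoff is this
package's operationalization of "clear" separation; it is configurable
and reported with every call.

## Integration and localization

Per-chromosome evidence (length-normalized enrichment percentages of
significant and suggestive SNPs, FST-signature percentage,
sex-specific-locus count, PCA score) is combined by min–max-normalizing
each track across chromosomes and averaging — the tracks have
incommensurate units, so a common `[0, 1]` scale is the least
structured choice; ties break by PCA score, then natural chromosome
order. Enrichment percentages are densities per Mb normalized to sum
to 100 across chromosomes, which makes them invariant to rescaling all
chromosome lengths.

The candidate interval is localized with a reproducible rule replacing
the visual "mainly located in ..." reading of a Manhattan plot: tile
the top chromosome into 1-Mb windows and take the **shortest**
contiguous run of windows containing at least 90% of that chromosome's
significant SNPs (ties: highest contained fraction, then leftmost). On
a constructed distribution with 23 of 24 significant positions spread
over 7–12 Mb and one stray at 20.5 Mb, the rule returns exactly
[7, 12) Mb with 95.8% contained — the pattern that motivates it. Two
guards produce an explicit no-call instead of a forced answer: zero
genome-wide-significant SNPs, or no chromosome reaching the PCA
cutoff. Chromosomes whose composite is within 0.7 of the top are
reported as secondary candidates, never silently dropped — real data
can show a second chromosome with similar (possibly translocated or
paralogous) features.

## The coverage screen for sex-specific sequences

Sequences private to the W (or Y) chromosome are absent from the other
sex's reads entirely. Given per-contig per-sample breadth of coverage
(fraction of positions with depth ≥ 1; `breadth_from_depth()` builds
it from a depth track), round 1 keeps contigs with breadth ≥ 0.9 in
*every* same-sex sample and ≤ 0.05 in *every* opposite-sex sample;
round 2 re-checks candidates against pooled opposite-sex data with the
same absence bound and annotates every removal. The 0.9/0.05 defaults
quantify "covered"/"not covered", which otherwise have no fixed
definition for short-read data; both are configuration and echoed in
the output. Marker candidates are then filtered to length > 1000 bp
(enough for robust PCR primer design), N-fraction ≤ 0.1, and mean
dinucleotide Shannon entropy ≥ 1.5 bits — an automated, reproducible
proxy for the manual removal of gappy and repetitive assembly
artifacts (a homopolymer scores 0 bits, random sequence ~4, so 1.5
removes only near-degenerate repeats).

## The simulator: what it emulates, and what it does not

`simulate_cohort()` generates the study design the analysis assumes:
40 females + 40 males; a desk-scale genome of 22 chromosomes × 5 Mb
standing in for a ~490-Mb assembly (all window parameters scale via
configuration); 30,000 background SNPs with allele frequencies
~Uniform(0.05, 0.5) in Hardy–Weinberg proportions independent of sex;
and on one chromosome a 1-Mb recombination-suppressed region with 100
fully sex-linked SNPs (het in every heterogametic-sex individual,
hom-ref otherwise) and 100 partially linked SNPs whose per-SNP
female-het probability is drawn from Uniform(0.5, 0.95) — a simple
stand-in for recombination-distance decay that produces the
characteristic association flanks around the fully linked core.
Genotyping noise mirrors ~10x data: true heterozygotes are recorded
hom-ref with probability 0.02 (the ref side, so the homogametic sex's
hom-ref pattern is never spuriously broken), genotypes go missing with
probability 0.02, DP ~ Poisson(10), GQ = 99. The W chromosome is
represented only through its observable consequences — the diploid
het/hom signature and W-specific contigs — because that is exactly
what this analysis consumes; there is no sequence evolution, linkage
disequilibrium, demography or read-level error model. The miscall and
missingness defaults are plausible placeholders, not estimates from
any real dataset. Passing recovery tests therefore show the
*statistics and integration logic* are correct under the stated noise
model, not that the pipeline is robust to every artifact of real
resequencing data.

`simulate_contig_coverage()` plants W-specific contigs (high breadth
~Uniform(0.95, 1) in all heterogametic-sex samples, zero — plus
optional contamination ≤ 0.02 — in the other sex), a large shared
background (breadth ~Beta(20, 1) everywhere), decoys covered by
all-but-one same-sex sample (exercising the "every sample" rule), and
optional round-2 false positives and marker-filter violators (short,
N-rich, low-complexity), each recorded in the truth record. Planted
specific contigs draw lengths from [1100, 3000] bp so the designated
violator classes are the only filter casualties; shared and decoy
contigs use [500, 3000] bp. Shared contigs use Beta(20, 1) deliberately
*because* it leaves mass below 0.9 — they are never candidates anyway —
while planted positives must clear the documented presence threshold
deterministically for truth-record comparisons to be exact.

Determinism is a contract: one integer seed fixes every byte of every
output, and the contig simulator derives its stream from the same seed
(XOR-offset) so cohort and coverage simulations in one run do not
reuse an identical stream.

## Worked example

```{r example, eval = FALSE}
cfg <- pipeline_config(
  out_dir = "zw_run",
  sim = sim_config(seed = 7),
  coverage = list(n_w_contigs = 20, n_shared_contigs = 2000,
                  n_decoys = 20))
summary <- run_pipeline(cfg)
make_report("zw_run")
```

The run directory contains the VCF and sample sheet, per-stage TSVs
(GWAS, FST, sex loci, PCA scores, enrichment, window densities), the
region call and summary JSONs, a FASTA of marker candidates, and a
plain-text report. The summary is byte-identical across reruns of the
same configuration.

## Numerical choices and degenerate inputs

* QC order is fixed: GQ-mask genotypes, then drop variants by mean
  depth (over non-missing genotypes, vcftools `--min-meanDP`
  semantics), call rate (`--max-missing` convention: the value is the
  required non-missing proportion), then MAF — with per-filter removal
  counts. The filter is idempotent; an all-removed result warns
  instead of erroring. Counts are reported before and after optional
  imputation, since retained-SNP totals depend on that choice.
* Coordinates are 0-based half-open internally (windows, intervals);
  VCF positions are converted at the I/O boundary only.
* Modal imputation ties break deterministically low (0 > 1 > 2).
* Monomorphic sites: chi-square and FST are `NA` by definition
  (zero denominator), flagged and excluded from tier counts.
* PCA drops zero-variance variants; a degenerate (constant) component
  contributes 0 to the separation score; component signs follow the
  largest-magnitude-loading-positive convention.
* Empty inputs propagate as empty tables or explicit no-calls, never
  as errors, except where a contract is violated (unknown samples,
  negative counts, positions beyond chromosome ends).

The test-suite problem sizes are the package's chosen verification
conditions: 10 seeds per arm at the full 30,000-SNP design for
recovery and type-I behaviour, 500/200-replicate oracle comparisons
for the chi-square and FST estimators, and 2,040-contig coverage
screens — large enough for the binomial margins asserted, small
enough to run routinely.

## Limitations

The package does not call variants, align reads, phase or impute
statistically, model linkage disequilibrium, or fine-map genes; the
screen consumes breadth tables, not BAMs. Association is a plain
allelic test without covariates or relatedness correction — appropriate
for a balanced two-group design of unrelated individuals, not for
structured cohorts. Heterogamety inference assumes a single
chromosomal GSD system; polygenic or environmental sex determination
yields (correctly) a no-call, but mixed systems are outside the model.
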