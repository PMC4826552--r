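---
title: "Methods: collapsed SNP-pair association scans for compound heterozygosity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: collapsed SNP-pair association scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcdh)
```

## The problem

Classical compound heterozygosity (CH) is the co-occurrence of two different
recessive mutations at one locus, one on each parental chromosome, jointly
abolishing gene function. A relaxed, *generalized* form — where the two
variants need not be rare, coding or individually deleterious — plausibly
contributes to the heritability of many polygenic traits that single-marker
genome-wide association scans fail to capture: each variant alone has a weak
marginal effect, while the compound genotype carries the signal.

This package screens for such effects by **collapsing** every pair of nearby
SNPs into a single pseudo-marker and association-testing the pseudo-markers
genome-wide. The compound signal concentrated in one synthetic marker can be
dramatically stronger than either marginal signal.

## The collapsing model

Genotypes are 2-bit PLINK codes: 0 = homozygote of the minor allele (A1),
1 = missing, 2 = heterozygote, 3 = homozygote of the major allele. A
*collapsing matrix* $M$ maps a pair of codes to one pseudo-genotype code:

$$C(g_1, g_2) = M_{g_1, g_2}.$$

The default (recessive) matrix encodes the CH hypothesis: a sample is a
**carrier** (pseudo-code 0) when either SNP is homozygous minor or both are
heterozygous (the double heterozygote, assumed in trans); everything else that
is fully observed is a non-carrier (pseudo-code 3). A hom-minor genotype
dominates a missing partner; other cells with a missing member are missing.
An additive alternative grades the het + hom-major cells as an intermediate
pseudo-dose, which is useful when more than two interacting variants are
suspected. Users may supply any 4x4 matrix over the codes.

```{r}
collapsing_matrix("recessive-default")
```

Because bed files pack four genotypes per byte, collapsing is performed
byte-against-byte through a precomputed 256x256 lookup table
(`build_byte_table()`); the table is built once per run and every collapsed
byte is then a single array indexing operation. In the SNP-major layout the
two packed rows of a pair are sample-aligned byte for byte, so no bit
re-alignment is needed; pad bits of a ragged final byte are re-zeroed after
lookup so written filesets stay canonical.

## Genome shifting

Testing all pairs within a window of rank distance $k$ is organised as $k$
whole-genome passes: pass $i$ collapses every variant with the variant $i$
positions downstream on the same chromosome (`shift_genome()`), yielding a
shifted pseudo-genotype dataset that is itself a valid PLINK fileset. The
union of passes $1..k$ is exactly the sliding-window enumeration
(`window_pairs()`), which the test suite asserts as a multiset identity on
random datasets. Pairs never span chromosomes — a cross-chromosome "pair" has
no compound-heterozygous reading — and the trailing $i$ variants of each
chromosome are dropped rather than padded with missing values.

## Association scans

Scans are native regressions, not delegations to an external program: ordinary
least squares for quantitative traits and maximum-likelihood logistic
regression for binary traits, each marker regressed on its additive dose
(A1-allele count; pseudo-doses 0/2 under the default matrix) plus covariates
and an intercept, reported with the two-sided Wald statistic. Missing handling
is per-marker listwise deletion. Degenerate markers — constant dose after
deletion, too few observations, separation or non-convergence in the logistic
case (tolerance 1e-8, 25 iterations) — are reported as NA rows with a reason,
never with a fabricated p-value, and row alignment across shifted scans is
preserved. Wald p-values are invariant to affine rescaling of the dose, so the
choice of 0/2 versus 0/1 coding cannot alter scan results.

The OLS path is vectorised with a Frisch–Waugh–Lovell pass: phenotype and
doses are residualised against the covariate block once and all
complete-dose markers are fitted simultaneously; markers with their own
missingness fall back to an exact per-marker fit. Both routes are checked
against closed-form $(X^\top X)^{-1} X^\top y$ and hand-rolled IRLS oracles to
1e-6 in the test suite.

## The pipeline and the report

`run_gcdh()` chains: single-SNP scan, optional marginal p-value filter, $k$
shifts, $k$ pseudo-marker scans, and a merged pair report. Each pair record
keeps the pair identity (ids, positions, shift), the pair statistics, the
carrier frequency of the collapsed marker, and both members' single-SNP
p-values.

Reports are queryable by genomic region (`query_region()`: any pair with
either member in the region, ordered by p with deterministic (bp1, bp2)
tie-breaks) and by rank (`top_pairs()`). The on-disk backend stores the tables
as parquet files and pushes region predicates down into the file scan, so
queries never load the whole store; the in-memory backend holds plain data
frames. Completeness is accounted on every run: reported records plus
degenerate records equal the window enumeration of the scanned variant set,
and the count of filter-removed variants is kept in the metadata. When a
filter is active, rank distance is measured **on the filtered set** — this
changes pair composition and is the documented behaviour, matching shifting a
filtered fileset.

The marginal filter deserves caution, which `extract_region()` +
regional re-analysis addresses: a true CH partner can be marginally
non-significant, so an aggressive filter can remove it from the genome-wide
scan while a regional run on the unfiltered extract still finds it. The test
suite constructs exactly this scenario.

## Significance calibration

Two thresholds are offered. The analytic rule `bonferroni_threshold(k)` =
$5\times10^{-8}/k$ extends the conventional genome-wide level to $k$ shifted
genomes and is conservative. The empirical route (`run_type_i()`) permutes the
phenotype $N$ times (covariates travel with their phenotype row, preserving
the phenotype–covariate joint distribution while severing all
genotype–phenotype links), records the global minimum pair p-value of each
permuted analysis, and takes the lower empirical $\alpha$-quantile (order
statistic $\lceil \alpha N \rceil$) as the genome-wide threshold. A second,
independent permutation batch reports the achieved type-I rate. $N$ defaults
to 100 with a warning below 20; at $N = 100$ the quantile has resolution 0.01,
which is adequate for $\alpha = 0.05$ but not for much smaller targets.

Since the shifted pseudo-genotypes do not depend on the phenotype, the shifts
are computed once and only the scans are repeated per permutation; the test
suite verifies this equals a literal full re-run per permutation. With a
p-value filter configured the filter itself depends on the permuted phenotype,
so the full pipeline is re-run each time.

## Synthetic genotypes

The power protocols and the test suite draw genotypes from two generators.

**Independent HWE pairs** (`simulate_hwe_pair()`): per-sample minor-allele
counts are Binomial(2, MAF) independently per SNP — Hardy–Weinberg proportions
with zero LD. Under the default matrix the carrier probability of such a pair
at shared MAF $p$ is $1 - q^2(q^2 + 4pq)$, $q = 1-p$, which the suite checks
against a 3x3 enumeration oracle and empirical frequencies.

**LD-structured regions** (`simulate_region()`): a block-copying haplotype
simulator. Sites fall into blocks of exponential length (mean 5 kb); within a
block each of the $2n$ haplotypes copies one of 8 founder haplotypes, founders
being drawn Bernoulli at a site frequency from a rare-skewed Beta(0.8, 8)
spectrum truncated to [0.0015, 0.5] and chosen with random weights so that
some founders are common and some rare; a 1% per-site mutation rate adds
continuous frequency variation. Founder choices are independent across blocks.
This produces strong within-block LD, no cross-block LD, and mean r² decaying
with distance — the properties the protocols actually use (tunable r²
screening and MAF strata) — and is deliberately *not* a coalescent model: it
reproduces neither realistic allele-frequency spectra, nor recombination
hotspots, nor the long-range LD of real exome data. Defaults (block length,
founder count, mutation rate, spectrum, 2 variants/kb density) were fixed once
when the generator was written; passing power tests therefore demonstrate the
method's behaviour under this stylised LD, not under any particular cohort's
LD.

## Power protocols

**Pair protocol** (`pair_power()`): per replicate, draw an independent HWE
pair at the target MAF, collapse, simulate $y = \beta x + \varepsilon$,
$\varepsilon \sim N(0,1)$, with $x$ the **0/1 carrier indicator** of the
collapsed genotype, then fit three regressions (SNP a, SNP b, collapsed) and
score each against the significance thresholds. The carrier-indicator coding
is a deliberate design choice: scan p-values are coding-invariant, but the
simulation's effect size scale is not, and the 0/1 coding is the one under
which the protocol's published operating characteristics are internally
consistent (a 0/2 coding would double every noncentrality and saturate power
at moderate effect sizes). Replicates that draw no carrier are counted as
non-significant for the collapsed model and tallied.

**Region protocol** (`region_power()`): per loop, draw a region (width uniform
in 10–50 kb, 2 variants/kb, $n = 1037$ samples by default), select a causal
pair with both MAFs in the target stratum and $r^2 < 0.01$ (discarding and
redrawing the region when none exists), simulate an associated phenotype from
the collapsed carrier indicator and an independent null phenotype, and run
single-SNP and GCDH scans (window 50) with the causal sites typed, plus
associated-trait scans with them removed. Each loop yields six regional
minimum p-values. The 5% lower quantiles of the null minima give empirical
thresholds $T_s$ and $T_g$; each power is the fraction of the matching
associated minima below **its own method's** threshold (scoring GCDH against
the single-SNP threshold is also computable from the returned minima, but
cross-scoring mixes two different multiplicity burdens and is not the
default). The untyped scenario is a re-scan of the reduced region, so rank
distances are measured on what a study without those sites would actually
scan.

Problem sizes in the test suite are chosen to keep the default run fast while
leaving Monte-Carlo error well inside the asserted bands: 500 replicates per
pair-protocol combination (binomial SE ≤ 2.2 points), 200 loops per
region-protocol combination, 100 + 100 permutations for the type-I check on a
200-variant, 500-sample null fixture.

## Numerical and design choices

* **Quantile definition**: all empirical thresholds use the lower order
  statistic $\lceil \alpha N \rceil$, so a null batch scored against its own
  threshold rejects at most $\alpha$ by construction.
* **Tie-breaks**: report orderings are (p, bp1, bp2) ascending, making "top
  pair" claims reproducible.
* **Exact fits**: a zero residual sum of squares reports the smallest positive
  double rather than p = 0.
* **Degenerate inputs**: empty shifted sets warn and return empty datasets;
  an empty post-filter set is an error; all-missing variants carry NA
  frequencies; regions with no eligible causal pair signal a redraw.
* **A1 orientation**: A1 is taken as minor by file convention and never
  re-estimated; `read_bed(check_a1_freq = TRUE)` warns when the data
  contradict the convention.
* **Determinism**: every stochastic entry point takes a seed; the pipeline
  itself is deterministic, and two runs with the same configuration produce
  identical reports.
* **Store backend**: the report store is a single-directory parquet layout
  with predicate pushdown; relative to an embedded SQL database this keeps the
  deliverable dependency-light while preserving the property that motivates a
  store at all — region queries without loading the full table.

## Limitations

* Only pairwise collapsing: higher-order compound effects are visible, if at
  all, through the additive matrix, not modelled directly.
* Windows are rank-distance windows, not base-pair windows; the effective
  physical span depends on marker density.
* No mixed models: relatedness and population structure must be handled by
  covariates (e.g. principal components).
* Hard-call genotypes only; imputed dosages must be hard-called upstream.
* The synthetic LD model is stylised (see above): power estimates under it
  characterise the method, not any specific cohort, and the single-SNP and
  untyped-scenario columns are the most sensitive to that stylisation because
  they depend entirely on proxy LD structure.
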