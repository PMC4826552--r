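# gcdh

Genome-wide screening for **generalized compound heterozygosity** (GCH):
association testing of collapsed SNP-pair pseudo-genotypes over PLINK
bed/bim/fam filesets.

Classical compound heterozygosity is two different recessive variants at one
locus, one per parental chromosome, jointly knocking out function. Its relaxed
form — variants that are not necessarily rare, coding or deleterious — is
invisible to single-marker GWAS: each variant's marginal effect is weak while
the *compound* genotype carries the signal. This package makes the compound
genotype directly testable.

## Who this is for

Statistical geneticists running GWAS on quantitative or binary traits who want
to scan for CH-like two-SNP effects, calibrate genome-wide significance for
that scan, and estimate its statistical power under explicit simulation
protocols.

## The method

A 4×4 **collapsing matrix** `M` maps a pair of 2-bit PLINK genotype codes
(0 = hom minor, 1 = missing, 2 = het, 3 = hom major) to one pseudo-genotype:

    C(g1, g2) = M[g1, g2]

The default recessive matrix marks a sample as a *carrier* when either SNP is
homozygous minor or both are heterozygous. Collapsing runs directly on packed
bed bytes via a precomputed 256×256 byte table, and a window of rank distance
`k` is covered by `k` **genome shifts**: pass `i` collapses every SNP with the
SNP `i` positions downstream (provably identical to the sliding-window
enumeration). Pseudo-markers are scanned with native OLS / logistic Wald
tests (covariates supported), merged into a region-queryable report,
and significance is calibrated either analytically (`5e-8 / k`) or by
phenotype permutation (the lower α-quantile of per-permutation global minimum
p-values).

## Worked example

Plant a compound-heterozygous pair (MAF 0.05 each, phenotype
`y = 1·carrier + N(0,1)`) among 100 background SNPs for 2000 samples, then
scan with window 3:

```r
library(gcdh)
set.seed(42)
n <- 2000
geno <- make_fixture(m = 100, n = n, out_prefix = file.path(tempdir(), "demo"),
                     seed = 42, maf_range = c(0.03, 0.3))
pair <- simulate_hwe_pair(0.05, 0.05, n)
geno$bed[, 50] <- pack_genotypes(pair$g1)
geno$bed[, 51] <- pack_genotypes(pair$g2)
write_bed(geno, file.path(tempdir(), "demo"))

dataset <- read_bed(file.path(tempdir(), "demo"))
x <- carrier_indicator(collapse_codes(pair$g1, pair$g2))
pheno <- data.frame(fid = dataset$samples$fid, iid = dataset$samples$iid,
                    y = simulate_phenotype(x, beta = 1))

report <- run_gcdh(dataset, pheno, gcdh_config(window_size = 3))
report
top_pairs(report, 3)[c("snp1", "snp2", "shift", "pair_carrier_freq",
                       "beta", "p", "p_snp1", "p_snp2")]
```

```
gcdh_report [memory]: 294 pair records (0 degenerate) over 100 variants, window 3
     snp1     snp2 shift pair_carrier_freq    beta        p p_snp1 p_snp2
 rs000050 rs000051     1            0.0110  0.4100 0.000111 0.3353  0.738
 rs000061 rs000063     2            0.2265 -0.0692 0.008886 0.0164  0.580
 rs000087 rs000088     1            0.0265 -0.1763 0.010574 0.2396  0.412
```

The planted pair tops the report: the collapsed marker (22 carriers,
frequency 0.011) reaches p = 1.1e-4 while its members' single-SNP p-values are
0.34 and 0.74 — the compound signal neither marginal scan sees. The best
single-SNP p anywhere in this dataset is 0.0145. With a real effect and
cohort-scale data the same contrast separates by orders of magnitude;
`contrast_manhattan()` overlays the two sets of p-values with their
respective significance lines, and `run_type_i()` replaces the analytic
`bonferroni_threshold(k)` (here 1.67e-8) with a permutation threshold.

A shell entry point with `run`, `region`, `query`, `type1` and `power-pair`
subcommands is installed at `inst/cli/gcdh.R` (see `?gcdh_cli`).

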