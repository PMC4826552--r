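Package: gcdh
Title: Generalized Compound Double Heterozygosity Scans for PLINK Genotype Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide screening for generalized compound heterozygosity:
    pairwise genotype collapsing of PLINK binary filesets via a genome-shifting
    algorithm, native linear and logistic association scans over the collapsed
    pseudo-genotypes, a queryable on-disk pair report, permutation-based
    genome-wide significance calibration, and simulation protocols for
    estimating the statistical power of the collapsed-pair test against
    conventional single-SNP association scans. Includes a synthetic genotype
    generator (Hardy-Weinberg pairs, LD-structured haplotype regions) used by
    the power protocols and the test suite.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    rlang,
    stats,
    utils,
    ggplot2,
    arrow,
    dplyr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
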