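test_that("a window-2 run reports exactly the enumerated pairs", {
  d <- rand_dataset(5, 30, missing_rate = 0, seed = 1)
  ph <- rand_pheno(d, seed = 2)
  rep <- run_gcdh(d, ph, gcdh_config(window_size = 2))
  expect_identical(rep$meta$n_pairs_reported, 7L)
  expect_identical(rep$meta$n_pairs_enumerated, 7L)
  expect_identical(nrow(rep$pairs), 7L)
  expect_true(all(rep$pairs$bp1 < rep$pairs$bp2))
})

test_that("p-value filter retains exactly the sub-threshold markers", {
  d <- rand_dataset(100, 120, missing_rate = 0, seed = 3)
  ph <- rand_pheno(d, seed = 4)
  sc <- linear_scan(d, ph)
  expect_error(apply_pvalue_filter(sc, d, 0), "\\(0, 1\\]")
  expect_error(apply_pvalue_filter(sc, d, 1.5), "\\(0, 1\\]")

  # threshold 1.0 is the identity subset
  expect_identical(apply_pvalue_filter(sc, d, 1)$m, d$m)

  # retained count equals the scan oracle's count
  n_pass <- sum(!is.na(sc$p) & sc$p < 0.03)
  filt <- apply_pvalue_filter(sc, d, 0.03)
  expect_identical(filt$m, n_pass)
  expect_identical(filt$variants$id, sc$id[!is.na(sc$p) & sc$p < 0.03])
})

test_that("a planted compound-heterozygous pair is the top pair of the scan", {
  set.seed(5)
  n <- 2000
  d <- rand_dataset(40, n, missing_rate = 0, seed = 5)
  # plant the causal pair at adjacent ranks 20/21 with MAF 0.05
  pair <- simulate_hwe_pair(0.05, 0.05, n)
  d$bed[, 20] <- pack_genotypes(pair$g1)
  d$bed[, 21] <- pack_genotypes(pair$g2)
  x <- carrier_indicator(collapse_codes(pair$g1, pair$g2))
  ph <- rand_pheno(d)
  ph$y <- simulate_phenotype(x, beta = 1)
  rep <- run_gcdh(d, ph, gcdh_config(window_size = 3))
  top <- top_pairs(rep, 1)
  expect_identical(top$snp1, d$variants$id[20])
  expect_identical(top$snp2, d$variants$id[21])
  expect_lt(top$p, 1e-6)
})

test_that("an aggressive marginal filter can drop a true pair the unfiltered run finds", {
  set.seed(6)
  n <- 2000
  d <- rand_dataset(150, n, missing_rate = 0, seed = 6)
  pair <- simulate_hwe_pair(0.05, 0.05, n)
  d$bed[, 15] <- pack_genotypes(pair$g1)
  d$bed[, 16] <- pack_genotypes(pair$g2)
  x <- carrier_indicator(collapse_codes(pair$g1, pair$g2))
  ph <- rand_pheno(d)
  ph$y <- simulate_phenotype(x, beta = 0.9)

  unfiltered <- run_gcdh(d, ph, gcdh_config(window_size = 1))
  top <- top_pairs(unfiltered, 1)
  causal_id <- paste0(d$variants$id[15], "/", d$variants$id[16])
  expect_identical(paste0(top$snp1, "/", top$snp2), causal_id)

  # both members are marginally non-significant at 0.03 on this draw, so the
  # filtered run cannot contain the causal pair
  marg <- report_single(unfiltered)
  expect_true(all(marg$p[c(15, 16)] > 0.03))
  filtered <- run_gcdh(d, ph, gcdh_config(window_size = 1, pvalue_filter = 0.03))
  ids <- paste0(filtered$pairs$snp1, "/", filtered$pairs$snp2)
  expect_false(causal_id %in% ids)

  # filter monotonicity: the unfiltered minimum p is never larger
  expect_lte(min(unfiltered$pairs$p, na.rm = TRUE),
             min(c(filtered$pairs$p, Inf), na.rm = TRUE))
})

test_that("with causal variants removed, the scan still lands in the causal region", {
  set.seed(7)
  n <- 1500
  # chromosome 1: unlinked background; chromosome 2: LD region with the signal
  bg <- rand_dataset(25, n, missing_rate = 0, seed = 7)
  reg <- simulate_region(40000, 0.002, n = n, chr = "2")
  cp <- select_causal_pair(reg, c(0.05, 0.15), max_r2 = 0.05)
  expect_false(is.null(cp))
  G <- genotype_matrix(reg)
  x <- carrier_indicator(collapse_codes(G[cp$i, ], G[cp$j, ]))
  y <- simulate_phenotype(x, beta = 2)

  reg$samples <- bg$samples
  combined <- bed_dataset(rbind(bg$variants, reg$variants), bg$samples,
                          cbind(bg$bed, reg$bed))
  ph <- data.frame(fid = bg$samples$fid, iid = bg$samples$iid, y = y)

  typed <- run_gcdh(combined, ph, gcdh_config(window_size = 4))
  top_typed <- top_pairs(typed, 1)
  expect_identical(top_typed$chromosome, "2")

  causal_ids <- reg$variants$id[c(cp$i, cp$j)]
  untyped_ds <- gcdh:::.subset_variants(combined,
                                        !combined$variants$id %in% causal_ids)
  untyped <- run_gcdh(untyped_ds, ph, gcdh_config(window_size = 4))
  top_un <- top_pairs(untyped, 1)
  expect_identical(top_un$chromosome, "2")
  expect_lt(abs(top_un$bp1 - reg$variants$bp[cp$i]), 40000)
  # proxies carry less information than the causal pair itself
  expect_gt(top_un$p, top_typed$p)
})

test_that("region queries equal a full linear scan of the records", {
  d <- rand_dataset(c(10, 8), 40, missing_rate = 0.05, seed = 8)
  ph <- rand_pheno(d, seed = 9)
  for (dir in list(NULL, tempfile())) {
    rep <- run_gcdh(d, ph, gcdh_config(window_size = 3, output_dir = dir))
    # oracle: materialise everything and filter in base R
    full <- top_pairs(rep, n = 1e6)
    lo <- sort(d$variants$bp[d$variants$chr == "chr1"])[3]
    hi <- sort(d$variants$bp[d$variants$chr == "chr1"])[7]
    want <- full[full$chromosome == "chr1" &
                   ((full$bp1 >= lo & full$bp1 <= hi) |
                      (full$bp2 >= lo & full$bp2 <= hi)), ]
    want <- want[order(want$p, want$bp1, want$bp2, na.last = TRUE), ]
    got <- query_region(rep, "chr1", lo, hi)
    expect_equal(got$snp1, want$snp1)
    expect_equal(got$snp2, want$snp2)
    expect_equal(got$p, want$p)

    # whole-chromosome region returns every pair of that chromosome
    all1 <- query_region(rep, "chr1", 0, 2e6)
    expect_identical(nrow(all1), sum(full$chromosome == "chr1"))

    # degenerate region equal to one pair's left bp still includes it
    bp <- full$bp1[1]
    hit <- query_region(rep, full$chromosome[1], bp, bp)
    expect_true(any(hit$bp1 == bp | hit$bp2 == bp))
  }
})

test_that("region extraction preserves genotype bytes exactly", {
  d <- rand_dataset(c(12, 6), 15, missing_rate = 0.1, seed = 10)
  v <- d$variants[d$variants$chr == "chr1", ]
  one <- extract_region(d, "chr1", v$bp[4], v$bp[4], flank = 0)
  expect_identical(one$m, 1L)
  expect_identical(one$variants$id, v$id[4])

  sub <- extract_region(d, "chr1", v$bp[3], v$bp[9], flank = 0)
  keep <- which(d$variants$chr == "chr1" &
                  d$variants$bp >= v$bp[3] & d$variants$bp <= v$bp[9])
  expect_identical(sub$bed, d$bed[, keep, drop = FALSE])
  expect_identical(genotype_matrix(sub), genotype_matrix(d)[keep, ])

  expect_warning(empty <- extract_region(d, "chr2", 1, 2, flank = 0),
                 "no variants")
  expect_identical(empty$m, 0L)
})

test_that("variance explained sums per-item R-squared percentages", {
  set.seed(11)
  y <- rnorm(50)
  expect_equal(variance_explained(2 * y + 3, y)$r2_percent, 100)
  dd <- cbind(a = y + rnorm(50), b = rnorm(50), c = rep(1, 50))
  expect_warning(ve <- variance_explained(y, dd), "degenerate")
  expect_true(is.na(ve$r2_percent[3]))
  expect_equal(r2_total(ve), sum(ve$r2_percent[1:2]))
  expect_equal(attr(ve, "total"), r2_total(ve))
})

test_that("pair completeness accounting holds on every run", {
  for (seed in 1:4) {
    d <- rand_dataset(c(15, 9), 25, missing_rate = 0.25, seed = seed)
    ph <- rand_pheno(d, seed = seed + 50)
    filt <- if (seed %% 2 == 0) 0.8 else NULL
    rep <- run_gcdh(d, ph, gcdh_config(window_size = 4, pvalue_filter = filt))
    expect_identical(rep$meta$n_pairs_reported, rep$meta$n_pairs_enumerated)
    expect_identical(rep$meta$n_pairs_degenerate, sum(is.na(rep$pairs$p)))
    if (is.null(filt)) {
      expect_identical(rep$meta$n_pairs_enumerated, nrow(window_pairs(d, 4)))
      expect_identical(rep$meta$n_filtered_out, 0L)
    } else {
      expect_identical(rep$meta$n_variants_scanned + rep$meta$n_filtered_out,
                       d$m)
    }
  }
})

test_that("identical configurations give identical reports, in memory and on disk", {
  d <- rand_dataset(12, 20, missing_rate = 0.1, seed = 12)
  ph <- rand_pheno(d, seed = 13)
  cfg <- gcdh_config(window_size = 2, seed = 42)
  r1 <- run_gcdh(d, ph, cfg)
  r2 <- run_gcdh(d, ph, cfg)
  expect_identical(r1$pairs, r2$pairs)
  expect_identical(r1$single, r2$single)

  dir <- tempfile()
  rd <- run_gcdh(d, ph, gcdh_config(window_size = 2, seed = 42,
                                    output_dir = dir))
  reopened <- open_gcdh_report(dir)
  expect_equal(top_pairs(reopened, 100)$p, top_pairs(r1, 100)$p)
  expect_identical(reopened$meta$n_pairs_reported, r1$meta$n_pairs_reported)

  # tab-delimited export round-trips the record count
  exp_dir <- tempfile()
  export_report(r1, exp_dir)
  tsv <- read.delim(file.path(exp_dir, "pairs.tsv"))
  expect_identical(nrow(tsv), nrow(r1$pairs))
})
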