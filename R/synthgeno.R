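# Synthetic genotype generation: independent Hardy-Weinberg pairs, LD-structured
# haplotype regions (block-copying simulator) and on-disk PLINK fixtures. These
# supply the genotype pools for the power protocols and the test suite.

.counts_to_codes <- function(minor_counts) {
  # 2 minor alleles -> code 0 (hom minor), 1 -> 2 (het), 0 -> 3 (hom major)
  c(3L, 2L, 0L)[minor_counts + 1L]
}

#' Simulate an independent Hardy-Weinberg SNP pair
#'
#' Draws per-sample minor-allele counts as independent Binomial(2, maf) for
#' each SNP, so the pair is in HWE with zero LD by construction.
#'
#' @param maf1,maf2 minor allele frequencies in (0, 0.5].
#' @param n sample count.
#' @param seed optional seed.
#' @return list with integer code vectors \code{g1}, \code{g2}.
#' @export
simulate_hwe_pair <- function(maf1, maf2 = maf1, n, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  stopifnot(maf1 > 0, maf1 <= 0.5, maf2 > 0, maf2 <= 0.5, n >= 1)
  list(
    g1 = .counts_to_codes(stats::rbinom(n, 2L, maf1)),
    g2 = .counts_to_codes(stats::rbinom(n, 2L, maf2))
  )
}

#' Linkage-disequilibrium model for the region simulator
#'
#' A block-copying haplotype model: sites are partitioned into blocks whose
#' lengths are exponential with mean \code{block_mean_bp}; within a block each
#' haplotype copies one of \code{n_founders} founder haplotypes (chosen with
#' random Dirichlet-like weights, so some founders are common and some rare),
#' and per-site mutation flips alleles at rate \code{mutation_rate}. Founder
#' choices are independent across blocks (free recombination between blocks),
#' so LD is strong within a block and absent across blocks, and mean r-squared
#' decreases with bp distance.
#'
#' @param block_mean_bp mean block length in bp.
#' @param n_founders founder haplotypes per block.
#' @param mutation_rate per-site allele flip probability.
#' @return an \code{ld_model} list.
#' @export
ld_model <- function(block_mean_bp = 5000, n_founders = 8L,
                     mutation_rate = 0.01) {
  stopifnot(block_mean_bp > 0, n_founders >= 2, mutation_rate >= 0,
            mutation_rate < 0.5)
  structure(list(block_mean_bp = block_mean_bp,
                 n_founders = as.integer(n_founders),
                 mutation_rate = mutation_rate), class = "ld_model")
}

# Default site allele-frequency spectrum: skewed towards rare variants,
# truncated to [0.0015, 0.5] (the range the regional power strata live in).
.default_maf_spectrum <- function(m) {
  pmin(pmax(stats::rbeta(m, 0.8, 8), 0.0015), 0.5)
}

#' Simulate an LD-structured genotype region
#'
#' Generates \code{2n} haplotypes over approximately \code{width_bp * density}
#' sites under the block-copying model of [ld_model()], then forms diploid
#' genotypes site by site (code 0 = two minor alleles, 2 = one, 3 = none). The
#' haplotype panel is attached as attribute \code{"haplotypes"} (a 2n x m 0/1
#' matrix, minor allele = 1) for LD screening of candidate causal pairs.
#'
#' @param width_bp region width in bp.
#' @param density expected variant density per bp (default 0.002 = 2 per kb).
#' @param ld an [ld_model()].
#' @param maf_spectrum function of one argument m returning m target site
#'   frequencies; defaults to a rare-skewed Beta(0.8, 8) truncated to
#'   \code{[0.0015, 0.5]}.
#' @param n sample count.
#' @param seed optional seed.
#' @param chr chromosome label for the variant table.
#' @return a [bed_dataset()] with attributes \code{haplotypes}.
#' @export
simulate_region <- function(width_bp, density = 0.002, ld = ld_model(),
                            maf_spectrum = NULL, n, seed = NULL, chr = "1") {
  if (!is.null(seed)) set.seed(as.integer(seed))
  stopifnot(width_bp > 0, density > 0, n >= 1)
  if (is.null(maf_spectrum)) maf_spectrum <- .default_maf_spectrum

  m <- stats::rpois(1L, width_bp * density)
  if (m < 2L) stop("region of width ", width_bp, " bp at density ", density,
                   "/bp yielded fewer than 2 variants; widen the region")
  positions <- sort(sample.int(as.integer(width_bp), m))

  # block boundaries from exponential lengths
  breaks <- 0
  while (utils::tail(breaks, 1L) < width_bp) {
    breaks <- c(breaks, utils::tail(breaks, 1L) +
                  stats::rexp(1L, rate = 1 / ld$block_mean_bp))
  }
  block <- findInterval(positions, breaks, rightmost.closed = TRUE)

  nh <- 2L * n
  H <- matrix(0L, nrow = nh, ncol = m)
  pfreq <- maf_spectrum(m)
  for (b in unique(block)) {
    sites <- which(block == b)
    nf <- ld$n_founders
    founders <- matrix(
      stats::rbinom(nf * length(sites), 1L, rep(pfreq[sites], each = nf)),
      nrow = nf
    )
    w <- stats::rexp(nf)
    choice <- sample.int(nf, nh, replace = TRUE, prob = w / sum(w))
    Hb <- founders[choice, , drop = FALSE]
    if (ld$mutation_rate > 0) {
      flips <- matrix(stats::rbinom(length(Hb), 1L, ld$mutation_rate),
                      nrow = nh)
      Hb <- bitwXor(Hb, flips)
    }
    H[, sites] <- Hb
  }

  counts <- H[seq(1L, nh, by = 2L), , drop = FALSE] +
    H[seq(2L, nh, by = 2L), , drop = FALSE]
  G <- matrix(.counts_to_codes(as.integer(counts)), nrow = n)

  variants <- data.frame(
    chr = chr, id = paste0("v", chr, "_", positions), cm = 0, bp = positions,
    a1 = "A", a2 = "B", stringsAsFactors = FALSE
  )
  samples <- data.frame(
    fid = paste0("F", seq_len(n)), iid = paste0("I", seq_len(n)),
    pid = "0", mid = "0", sex = 0L, phenotype = NA_real_,
    stringsAsFactors = FALSE
  )
  x <- bed_dataset(variants, samples, t(G))
  attr(x, "haplotypes") <- H
  x
}

#' Squared allelic correlation between two sites
#'
#' @param hap 2N x m 0/1 haplotype matrix (as attached by [simulate_region()]).
#' @param i,j site indices.
#' @return r-squared of the haplotype alleles (0 when either site is
#'   monomorphic).
#' @export
haplotype_r2 <- function(hap, i, j) {
  a <- hap[, i]; b <- hap[, j]
  if (stats::var(a) == 0 || stats::var(b) == 0) return(0)
  stats::cor(a, b)^2
}

#' Select a low-LD causal pair within a MAF stratum
#'
#' Scans a simulated region for a pair of sites whose sample MAFs both fall in
#' \code{(stratum[1], stratum[2]]} and whose genotype-dose r-squared is below
#' \code{max_r2}. Candidate pairs are tried in random order; if none qualifies
#' the function returns NULL, signalling the caller to discard the region and
#' draw a new one.
#'
#' @param region a [simulate_region()] result.
#' @param maf_stratum length-2 numeric, lower-exclusive / upper-inclusive MAF
#'   bounds.
#' @param max_r2 LD ceiling for the pair (default 0.01).
#' @param max_candidates cap on the number of candidate pairs examined.
#' @return list with \code{i}, \code{j} (variant indices), \code{r2} and
#'   \code{mafs}, or NULL if no eligible pair exists.
#' @export
select_causal_pair <- function(region, maf_stratum, max_r2 = 0.01,
                               max_candidates = 200L) {
  stopifnot(length(maf_stratum) == 2, maf_stratum[1] < maf_stratum[2])
  st <- allele_stats(region)
  eligible <- which(!is.na(st$maf) &
                      st$maf > maf_stratum[1] & st$maf <= maf_stratum[2])
  if (length(eligible) < 2L) return(NULL)
  cand <- utils::combn(eligible, 2L)
  cand <- cand[, sample.int(ncol(cand)), drop = FALSE]
  if (ncol(cand) > max_candidates) cand <- cand[, seq_len(max_candidates), drop = FALSE]
  D <- dose_matrix(region)
  for (c in seq_len(ncol(cand))) {
    i <- cand[1L, c]; j <- cand[2L, c]
    di <- D[, i]; dj <- D[, j]
    if (stats::var(di) < 1e-12 || stats::var(dj) < 1e-12) next
    r2 <- stats::cor(di, dj)^2
    if (r2 < max_r2) {
      return(list(i = i, j = j, r2 = r2, mafs = st$maf[c(i, j)]))
    }
  }
  NULL
}

#' Write a random HWE PLINK fixture to disk
#'
#' Generates m independent HWE variants (MAF uniform in \code{maf_range}) for n
#' samples, optionally injects missing calls, and writes a valid bed/bim/fam
#' fileset. Deterministic for a given seed.
#'
#' @param m,n variant and sample counts.
#' @param out_prefix output fileset prefix.
#' @param seed optional seed.
#' @param missing_rate per-call probability of a missing genotype.
#' @param maf_range range the per-variant MAFs are drawn from.
#' @param chr chromosome label.
#' @return the generated [bed_dataset()], invisibly.
#' @export
make_fixture <- function(m, n, out_prefix, seed = NULL, missing_rate = 0,
                         maf_range = c(0.05, 0.5), chr = "1") {
  if (!is.null(seed)) set.seed(as.integer(seed))
  stopifnot(m >= 1, n >= 1, missing_rate >= 0, missing_rate < 1)
  mafs <- stats::runif(m, maf_range[1], maf_range[2])
  G <- matrix(0L, nrow = m, ncol = n)
  for (j in seq_len(m)) {
    G[j, ] <- .counts_to_codes(stats::rbinom(n, 2L, mafs[j]))
  }
  if (missing_rate > 0) {
    G[matrix(stats::rbinom(m * n, 1L, missing_rate) == 1L, nrow = m)] <- 1L
  }
  positions <- sort(sample.int(m * 1000L, m))
  variants <- data.frame(
    chr = chr, id = sprintf("rs%06d", seq_len(m)), cm = 0, bp = positions,
    a1 = "A", a2 = "B", stringsAsFactors = FALSE
  )
  samples <- data.frame(
    fid = paste0("F", seq_len(n)), iid = paste0("I", seq_len(n)),
    pid = "0", mid = "0", sex = rep_len(c(1L, 2L), n),
    phenotype = NA_real_, stringsAsFactors = FALSE
  )
  x <- bed_dataset(variants, samples, G)
  write_bed(x, out_prefix)
  invisible(x)
}
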