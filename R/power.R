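# Power-simulation protocols: the microarray SNP-pair protocol (independent
# HWE pairs, phenotype from the collapsed carrier indicator) and the
# exome-region protocol (LD-structured regions, empirical null thresholds from
# regional minimum p-values).

#' Carrier indicator of collapsed pseudo-genotypes
#'
#' 1 when the collapsed pseudo-genotype carries the compound signal (pseudo
#' dose > 0), 0 otherwise, NA when the pseudo-genotype is missing. Under the
#' recessive-default matrix this is exactly the 0/1 carrier status; under the
#' additive matrix heterozygous pseudo-genotypes also count as carriers.
#'
#' @param codes integer vector of collapsed pseudo-genotype codes.
#' @return integer 0/1 vector (NA for missing).
#' @export
carrier_indicator <- function(codes) {
  d <- dose_map()[as.integer(codes) + 1L]
  as.integer(d > 0)
}

#' Simulate a quantitative phenotype from a carrier indicator
#'
#' \code{y = beta * x + e} with standard normal noise \code{e}. \code{x} is the
#' 0/1 carrier indicator of the collapsed causal genotype; scan p-values are
#' invariant to the dose coding, so the coding only matters for the effect-size
#' scale of the simulation.
#'
#' @param x numeric (0/1) carrier vector.
#' @param beta effect size in phenotype standard deviations per carrier.
#' @param seed optional seed.
#' @return numeric phenotype vector.
#' @export
simulate_phenotype <- function(x, beta, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  beta * x + stats::rnorm(length(x))
}

#' Pair-protocol power estimation
#'
#' Per replicate, draws an independent HWE SNP pair at the given MAF, collapses
#' it, simulates \code{y = beta * carrier + N(0, 1)}, and fits three
#' regressions: phenotype on SNP a, on SNP b, and on the collapsed
#' pseudo-genotype. Power per model and per significance threshold is the
#' fraction of replicates with p below the threshold. Replicates whose
#' collapsed marker is degenerate (no carriers drawn) count as non-significant
#' for the collapsed model and are tallied in attribute
#' \code{n_zero_carrier}.
#'
#' @param n sample size.
#' @param beta effect size.
#' @param maf minor allele frequency of both pair members.
#' @param thresholds significance thresholds to score against.
#' @param reps number of replicate pairs.
#' @param matrix a [collapsing_matrix()].
#' @param seed optional seed.
#' @return data.frame with one row per threshold: \code{threshold,
#'   power_snp_a, power_snp_b, power_gcdh}; attributes carry the settings and
#'   the raw p-value matrix (\code{"pvalues"}).
#' @export
pair_power <- function(n, beta, maf, thresholds = c(5e-2, 5e-8, 5e-11),
                       reps = 500L, matrix = collapsing_matrix(),
                       seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  stopifnot(n >= 10, reps >= 1, maf > 0, maf <= 0.5)
  matrix <- collapsing_matrix(matrix)
  dm <- dose_map()

  P <- matrix(NA_real_, nrow = reps, ncol = 3L,
              dimnames = list(NULL, c("snp_a", "snp_b", "gcdh")))
  n_zero <- 0L
  for (r in seq_len(reps)) {
    pair <- simulate_hwe_pair(maf, maf, n)
    cc <- collapse_codes(pair$g1, pair$g2, matrix)
    x <- carrier_indicator(cc)
    if (sum(x, na.rm = TRUE) == 0L) n_zero <- n_zero + 1L
    y <- simulate_phenotype(x, beta)
    D <- cbind(dm[pair$g1 + 1L], dm[pair$g2 + 1L], dm[cc + 1L])
    P[r, ] <- .ols_scan(D, y)$p
  }

  pw <- function(col, thr) mean(!is.na(P[, col]) & P[, col] < thr)
  out <- data.frame(
    threshold = thresholds,
    power_snp_a = vapply(thresholds, function(t) pw("snp_a", t), numeric(1)),
    power_snp_b = vapply(thresholds, function(t) pw("snp_b", t), numeric(1)),
    power_gcdh = vapply(thresholds, function(t) pw("gcdh", t), numeric(1))
  )
  attr(out, "settings") <- list(n = n, beta = beta, maf = maf, reps = reps)
  attr(out, "n_zero_carrier") <- n_zero
  attr(out, "pvalues") <- P
  class(out) <- c("pair_power", "data.frame")
  out
}

# Regional minimum pair p-value over shifts 1..k for one or more phenotypes
# (columns of Y), reusing the genome-shifting path. Returns a vector of minima
# aligned to the phenotype columns.
.gcdh_region_min_p <- function(dataset, Y, k, matrix, byte_table) {
  mins <- rep(Inf, ncol(Y))
  for (i in seq_len(min(k, dataset$m - 1L))) {
    sd <- shift_genome(dataset, i, matrix, byte_table = byte_table)
    if (sd$m == 0L) break
    D <- dose_matrix(sd)
    for (c in seq_len(ncol(Y))) {
      p <- .ols_scan(D, Y[, c])$p
      if (any(!is.na(p))) mins[c] <- min(mins[c], p, na.rm = TRUE)
    }
  }
  mins
}

#' Exome-region protocol power estimation
#'
#' Per loop: draw an LD-structured region (width uniform in \code{width_kb},
#' density \code{density} variants/kb, [simulate_region()]); select a causal
#' pair with both MAFs in \code{maf_stratum} and pairwise r-squared below
#' \code{max_r2} (the region is discarded and redrawn if none exists); simulate
#' an associated phenotype from the collapsed carrier indicator and an
#' independent standard-normal null phenotype; run single-SNP and GCDH scans
#' (window \code{window}) with the causal sites typed, and the associated-trait
#' scans again with the two causal sites removed; record the six regional
#' minimum p-values. After all loops the 5\% (i.e. \code{alpha}) lower
#' quantiles of the null minima give the empirical thresholds \code{T_s}
#' (single-SNP) and \code{T_g} (GCDH), and each power is the fraction of the
#' matching associated-scan minima below its method's threshold.
#'
#' @param beta effect size of the collapsed carrier genotype.
#' @param maf_stratum length-2 MAF bounds (lower-exclusive, upper-inclusive)
#'   for both causal SNPs.
#' @param loops number of simulation loops.
#' @param n sample size.
#' @param window GCDH window size (maximum rank distance).
#' @param alpha target regional type-I rate defining the null quantile.
#' @param width_kb region width range in kb.
#' @param density variant density per kb.
#' @param max_r2 LD ceiling for the causal pair.
#' @param ld an [ld_model()].
#' @param matrix a [collapsing_matrix()].
#' @param seed optional seed.
#' @param max_redraws maximum region redraws per loop before the loop is
#'   skipped with a warning.
#' @return a \code{region_power} list: \code{thresholds} (\code{T_s},
#'   \code{T_g}), \code{power} (data.frame with single/GCDH x typed/untyped),
#'   \code{minima} (the six raw minima vectors) and \code{settings}.
#' @export
region_power <- function(beta, maf_stratum, loops = 500L, n = 1037L,
                         window = 50L, alpha = 0.05, width_kb = c(10, 50),
                         density = 2, max_r2 = 0.01, ld = ld_model(),
                         matrix = collapsing_matrix(), seed = NULL,
                         max_redraws = 50L) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  stopifnot(loops >= 1, n >= 10, window >= 1)
  matrix <- collapsing_matrix(matrix)
  bt <- build_byte_table(matrix)

  p_s_d <- p_g_d <- p_s <- p_g <- p_s_n <- p_g_n <- rep(NA_real_, loops)
  skipped <- 0L

  for (l in seq_len(loops)) {
    cp <- NULL
    for (try in seq_len(max_redraws)) {
      width <- stats::runif(1, width_kb[1], width_kb[2]) * 1000
      reg <- tryCatch(
        simulate_region(width, density / 1000, ld, NULL, n),
        error = function(e) NULL
      )
      if (is.null(reg) || reg$m < 3L) next
      cp <- select_causal_pair(reg, maf_stratum, max_r2)
      if (!is.null(cp)) break
    }
    if (is.null(cp)) { skipped <- skipped + 1L; next }

    G <- genotype_matrix(reg)
    cc <- collapse_codes(G[cp$i, ], G[cp$j, ], matrix)
    x <- carrier_indicator(cc)
    y_assoc <- simulate_phenotype(x, beta)
    y_null <- stats::rnorm(n)

    D_typed <- dose_matrix(reg)
    s_assoc <- .ols_scan(D_typed, y_assoc)$p
    s_null <- .ols_scan(D_typed, y_null)$p
    p_s[l] <- suppressWarnings(min(s_assoc, na.rm = TRUE))
    p_s_d[l] <- suppressWarnings(min(s_null, na.rm = TRUE))

    g_mins <- .gcdh_region_min_p(reg, cbind(y_assoc, y_null), window,
                                 matrix, bt)
    p_g[l] <- g_mins[1L]
    p_g_d[l] <- g_mins[2L]

    reg_un <- .subset_variants(reg, setdiff(seq_len(reg$m), c(cp$i, cp$j)))
    p_s_n[l] <- suppressWarnings(
      min(.ols_scan(dose_matrix(reg_un), y_assoc)$p, na.rm = TRUE))
    p_g_n[l] <- .gcdh_region_min_p(reg_un, cbind(y_assoc), window, matrix, bt)
  }
  if (skipped > 0L) {
    warning(skipped, " loop(s) skipped: no eligible causal pair in stratum (",
            maf_stratum[1], ", ", maf_stratum[2], "] after ", max_redraws,
            " redraws")
  }
  done <- !is.na(p_s)
  if (!any(done)) stop("no loop produced a scan; stratum too restrictive")

  lower_q <- function(v) sort(v)[max(1L, ceiling(alpha * length(v)))]
  T_s <- lower_q(p_s_d[done])
  T_g <- lower_q(p_g_d[done])

  power <- data.frame(
    method = c("single_snp", "gcdh", "single_snp", "gcdh"),
    causal = c("typed", "typed", "untyped", "untyped"),
    power = c(mean(p_s[done] < T_s), mean(p_g[done] < T_g),
              mean(p_s_n[done] < T_s), mean(p_g_n[done] < T_g))
  )
  structure(list(
    thresholds = c(T_s = T_s, T_g = T_g),
    power = power,
    minima = list(p_s_d = p_s_d[done], p_g_d = p_g_d[done], p_s = p_s[done],
                  p_g = p_g[done], p_s_n = p_s_n[done], p_g_n = p_g_n[done]),
    settings = list(beta = beta, maf_stratum = maf_stratum,
                    loops = sum(done), n = n, window = window, alpha = alpha,
                    width_kb = width_kb, density = density, max_r2 = max_r2,
                    skipped = skipped)
  ), class = "region_power")
}

#' @export
print.region_power <- function(x, ...) {
  s <- x$settings
  cat(sprintf(
    "region_power: beta %.3g, MAF stratum (%g, %g], %d loops, n %d, window %d\n",
    s$beta, s$maf_stratum[1], s$maf_stratum[2], s$loops, s$n, s$window))
  cat(sprintf("  null thresholds: T_s %.3g, T_g %.3g\n",
              x$thresholds["T_s"], x$thresholds["T_g"]))
  print(x$power, row.names = FALSE)
  invisible(x)
}

#' Theoretical carrier probability of an independent HWE pair
#'
#' Under the recessive-default matrix, a sample is a carrier when either SNP is
#' homozygous minor or both are heterozygous; for two independent HWE SNPs at
#' the same MAF p this probability is \code{1 - q^2 (q^2 + 4 p q)} with
#' \code{q = 1 - p}.
#'
#' @param maf shared minor allele frequency.
#' @return carrier probability.
#' @export
carrier_probability <- function(maf) {
  q <- 1 - maf
  1 - q^2 * (q^2 + 4 * maf * q)
}
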