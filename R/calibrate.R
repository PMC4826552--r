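# Genome-wide significance calibration: the analytic window-corrected
# threshold and the permutation procedure over global minimum p-values.

#' Window-corrected analytic significance threshold
#'
#' The conventional genome-wide level divided by the window size k, a
#' Bonferroni-style correction for scanning k shifted pseudo-genomes. This is
#' conservative; the permutation threshold from [run_type_i()] is usually less
#' stringent.
#'
#' @param k window size (k >= 1).
#' @param base per-genome significance level (default 5e-8).
#' @return \code{base / k}.
#' @export
bonferroni_threshold <- function(k, base = 5e-8) {
  k <- as.numeric(k)
  if (any(is.na(k) | k < 1)) stop("k must be >= 1")
  base / k
}

#' Permute a phenotype table across samples
#'
#' Permutes the phenotype rows across samples while keeping covariates attached
#' to their phenotype value: the joint (phenotype, covariate) rows travel
#' together, preserving the phenotype-covariate relationship while breaking all
#' genotype-phenotype links (the null hypothesis of no genotype effect). The
#' multiset of values is unchanged.
#'
#' @param pheno a phenotype data.frame with \code{fid}/\code{iid} key columns
#'   (all other columns are permuted jointly), or a plain numeric vector.
#' @param seed optional integer seed; the same seed always yields the same
#'   permutation (R's default Mersenne-Twister generator).
#' @return the permuted phenotype, same shape as the input.
#' @export
permute_phenotype <- function(pheno, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (is.numeric(pheno)) {
    return(pheno[sample.int(length(pheno))])
  }
  stopifnot(is.data.frame(pheno))
  value_cols <- setdiff(names(pheno), c("fid", "iid"))
  perm <- sample.int(nrow(pheno))
  pheno[value_cols] <- pheno[perm, value_cols, drop = FALSE]
  pheno
}

#' Permutation-based type-I error calibration
#'
#' Runs the GCDH analysis on \code{n_perm} phenotype permutations, collecting
#' the global minimum pair p-value of each run; the empirical lower
#' alpha-quantile of these minima (order statistic \code{ceiling(alpha *
#' n_perm)}) is the genome-wide significance threshold controlling the
#' family-wise type-I error at alpha. A second, independent batch of
#' permutations is then scored against the threshold to report the achieved
#' (validation) type-I rate.
#'
#' Because the shifted pseudo-genotypes do not depend on the phenotype, the k
#' genome shifts are computed once and each permutation re-runs only the
#' association scans; the per-permutation minima are identical to running the
#' full pipeline on each permuted phenotype. When a marginal p-value filter is
#' configured the filter would itself depend on the permuted phenotype, so the
#' full pipeline is re-run per permutation instead (much slower).
#'
#' @param dataset a [bed_dataset()].
#' @param pheno phenotype vector or table (see [linear_scan()]).
#' @param config a [gcdh_config()]; \code{output_dir} is ignored here.
#' @param n_perm number of permutations per batch (a warning is issued below
#'   20; at 100 permutations the alpha-quantile has resolution 1/100).
#' @param alpha target family-wise type-I error rate.
#' @param seed integer seed for the permutation stream.
#' @return a \code{calibration_result}: list with \code{alpha},
#'   \code{n_permutations}, \code{minima} (calibration batch),
#'   \code{threshold}, \code{minima_validation} and \code{empirical_type_i}.
#' @export
run_type_i <- function(dataset, pheno, config, n_perm = 100, alpha = 0.05,
                       seed = NULL) {
  stopifnot(inherits(config, "gcdh_config"))
  n_perm <- as.integer(n_perm)
  if (n_perm < 1L) stop("n_perm must be >= 1")
  if (n_perm < 20L) {
    warning("n_perm = ", n_perm, " gives a very coarse quantile; >= 20 ",
            "(ideally >= 100) permutations are recommended")
  }
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  if (!is.null(seed)) set.seed(as.integer(seed))

  use_fast <- is.null(config$pvalue_filter)

  if (use_fast) {
    jp <- .join_pheno(dataset, pheno, config$pheno_name, config$covariate_names)
    scan_min <- .make_min_p_scanner(dataset, config)
    draw_min <- function() {
      perm <- sample.int(dataset$n)
      scan_min(jp$y[perm],
               if (is.null(jp$covars)) NULL else jp$covars[perm, , drop = FALSE])
    }
  } else {
    draw_min <- function() {
      ph <- permute_phenotype(pheno)
      cfg <- config
      cfg$output_dir <- NULL
      rep <- run_gcdh(dataset, ph, cfg)
      min(rep$pairs$p, na.rm = TRUE)
    }
  }

  minima <- vapply(seq_len(n_perm), function(b) draw_min(), numeric(1))
  threshold <- sort(minima)[ceiling(alpha * n_perm)]
  minima2 <- vapply(seq_len(n_perm), function(b) draw_min(), numeric(1))

  structure(list(
    alpha = alpha,
    n_permutations = n_perm,
    minima = minima,
    threshold = threshold,
    minima_validation = minima2,
    empirical_type_i = mean(minima2 < threshold)
  ), class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(
    "calibration_result: threshold %.3g (alpha %.3g, %d permutations); validation type-I %.3g\n",
    x$threshold, x$alpha, x$n_permutations, x$empirical_type_i))
  invisible(x)
}

# Precompute the pair dose matrix for all shifts 1..k once; the returned
# closure scans a (permuted) phenotype and returns the global minimum pair p.
.make_min_p_scanner <- function(dataset, config) {
  bt <- build_byte_table(config$matrix)
  blocks <- list()
  for (i in seq_len(config$window_size)) {
    sd <- withCallingHandlers(
      shift_genome(dataset, i, config$matrix, byte_table = bt),
      warning = function(w) invokeRestart("muffleWarning"))
    if (sd$m > 0L) blocks[[length(blocks) + 1L]] <- dose_matrix(sd)
  }
  if (!length(blocks)) stop("window produces no pairs on this dataset")
  D <- do.call(cbind, blocks)
  if (config$trait_type != "quantitative") {
    return(function(y, covars) min(.logit_scan(D, y, covars)$p, na.rm = TRUE))
  }
  function(y, covars) min(.ols_scan(D, y, covars)$p, na.rm = TRUE)
}
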