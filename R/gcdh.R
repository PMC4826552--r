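# The GCDH pipeline: optional marginal p-value filter, k genome shifts, scans,
# and a queryable pair report, plus regional re-analysis and variance-explained
# accounting.

#' GCDH run configuration
#'
#' @param window_size maximum rank distance k between paired SNPs (k >= 1).
#' @param pvalue_filter optional marginal filter: only variants whose
#'   single-marker p is strictly below this threshold enter the pairwise scan.
#'   Rank distance is then measured on the filtered set. Use with caution: a
#'   true compound-heterozygous partner can be marginally non-significant.
#' @param trait_type \code{"quantitative"} (linear scan) or \code{"binary"}
#'   (logistic scan).
#' @param matrix a [collapsing_matrix()] (name, matrix or file path).
#' @param covariate_names covariate columns of the phenotype table.
#' @param pheno_name phenotype column name (see [linear_scan()]).
#' @param seed integer recorded in the report metadata (the pipeline itself is
#'   deterministic; the seed matters for callers that randomise inputs).
#' @param output_dir when set, the report is materialised on disk under this
#'   directory (parquet tables + dcf metadata) and queries stream from disk;
#'   when NULL the report is kept in memory.
#' @return a \code{gcdh_config} list.
#' @export
gcdh_config <- function(window_size,
                        pvalue_filter = NULL,
                        trait_type = c("quantitative", "binary"),
                        matrix = collapsing_matrix(),
                        covariate_names = NULL,
                        pheno_name = NULL,
                        seed = NULL,
                        output_dir = NULL) {
  window_size <- as.integer(window_size)
  if (is.na(window_size) || window_size < 1L) stop("window_size must be >= 1")
  if (!is.null(pvalue_filter)) {
    if (!is.numeric(pvalue_filter) || pvalue_filter <= 0 || pvalue_filter > 1) {
      stop("pvalue_filter must lie in (0, 1]")
    }
  }
  structure(list(
    window_size = window_size,
    pvalue_filter = pvalue_filter,
    trait_type = match.arg(trait_type),
    matrix = collapsing_matrix(matrix),
    covariate_names = covariate_names,
    pheno_name = pheno_name,
    seed = seed,
    output_dir = output_dir
  ), class = "gcdh_config")
}

#' Filter variants by marginal association p-value
#'
#' Retains exactly the variants whose single-marker p-value is strictly below
#' the threshold, preserving order. Subsequent genome shifts pair only retained
#' variants, so rank distance is measured on the filtered set.
#'
#' @param single_scan scan result aligned row-by-row to \code{dataset}.
#' @param dataset the scanned [bed_dataset()].
#' @param threshold p-value threshold in (0, 1].
#' @return the filtered [bed_dataset()].
#' @export
apply_pvalue_filter <- function(single_scan, dataset, threshold) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    stop("threshold must lie in (0, 1]")
  }
  if (nrow(single_scan) != dataset$m) {
    stop("scan result (", nrow(single_scan), " rows) is not aligned to the dataset (",
         dataset$m, " variants)")
  }
  # threshold 1 is the identity subset (p-values lie in (0, 1], so nothing can
  # be "more significant than 1" exclusively); otherwise strictly p < threshold,
  # dropping markers with no computable p.
  keep <- if (threshold == 1) rep(TRUE, nrow(single_scan))
          else !is.na(single_scan$p) & single_scan$p < threshold
  .subset_variants(dataset, keep)
}

.scan_fun <- function(trait_type) {
  switch(trait_type, quantitative = linear_scan, binary = logistic_scan)
}

#' Run the full GCDH pipeline
#'
#' Performs the single-SNP scan, optionally filters variants by marginal
#' p-value, then for each shift \code{i = 1..k} collapses the genome with
#' [shift_genome()] and scans the pseudo-genotypes, merging everything into a
#' queryable report. Each pair record carries the pair statistics, the carrier
#' frequency of the collapsed pseudo-marker and the single-SNP p-values of both
#' members.
#'
#' @param dataset a [bed_dataset()].
#' @param pheno phenotype vector or table (see [linear_scan()]).
#' @param config a [gcdh_config()].
#' @return a \code{gcdh_report}; see [query_region()], [top_pairs()].
#' @export
run_gcdh <- function(dataset, pheno, config) {
  stopifnot(inherits(config, "gcdh_config"))
  scan <- .scan_fun(config$trait_type)

  single <- scan(dataset, pheno, pheno_name = config$pheno_name,
                 covariate_names = config$covariate_names)

  scanned <- dataset
  n_filtered_out <- 0L
  if (!is.null(config$pvalue_filter)) {
    scanned <- apply_pvalue_filter(single, dataset, config$pvalue_filter)
    n_filtered_out <- dataset$m - scanned$m
    if (scanned$m < 2L) {
      stop("fewer than 2 variants pass the p-value filter (",
           config$pvalue_filter, "); nothing to pair")
    }
  }

  bt <- build_byte_table(config$matrix)
  enumerated <- nrow(window_pairs(scanned, config$window_size))
  p_by_id <- stats::setNames(single$p, single$id)

  pair_list <- vector("list", config$window_size)
  for (i in seq_len(config$window_size)) {
    sd <- withCallingHandlers(
      shift_genome(scanned, i, config$matrix, byte_table = bt),
      warning = function(w) invokeRestart("muffleWarning")
    )
    if (sd$m == 0L) next
    res <- scan(sd, pheno, pheno_name = config$pheno_name,
                covariate_names = config$covariate_names)
    pair_list[[i]] <- data.frame(
      snp1 = res$snp1, snp2 = res$snp2,
      chromosome = res$chr, bp1 = res$bp1, bp2 = res$bp2,
      shift = res$shift,
      n_used = res$n_used,
      pair_carrier_freq = res$pair_carrier_freq,
      beta = res$beta, se = res$se, stat = res$stat, p = res$p,
      p_snp1 = unname(p_by_id[res$snp1]),
      p_snp2 = unname(p_by_id[res$snp2]),
      note = res$note,
      stringsAsFactors = FALSE
    )
  }
  pairs <- do.call(rbind, pair_list[!vapply(pair_list, is.null, logical(1))])
  if (is.null(pairs)) pairs <- .empty_pairs_table()

  meta <- list(
    window_size = config$window_size,
    trait_type = config$trait_type,
    matrix_name = attr(config$matrix, "name"),
    pvalue_filter = if (is.null(config$pvalue_filter)) NA_real_ else config$pvalue_filter,
    seed = if (is.null(config$seed)) NA_integer_ else as.integer(config$seed),
    n_variants_input = dataset$m,
    n_variants_scanned = scanned$m,
    n_filtered_out = n_filtered_out,
    n_samples = dataset$n,
    n_pairs_enumerated = enumerated,
    n_pairs_reported = nrow(pairs),
    n_pairs_degenerate = sum(is.na(pairs$p))
  )

  gcdh_report(single = single, pairs = pairs, meta = meta,
              output_dir = config$output_dir)
}

.empty_pairs_table <- function() {
  data.frame(snp1 = character(0), snp2 = character(0),
             chromosome = character(0), bp1 = integer(0), bp2 = integer(0),
             shift = integer(0), n_used = integer(0),
             pair_carrier_freq = numeric(0),
             beta = numeric(0), se = numeric(0), stat = numeric(0),
             p = numeric(0), p_snp1 = numeric(0), p_snp2 = numeric(0),
             note = character(0), stringsAsFactors = FALSE)
}

#' Construct or persist a GCDH report
#'
#' With \code{output_dir = NULL} the report is an in-memory object; otherwise
#' the single-SNP and pair tables are written as parquet files plus a dcf
#' metadata file, and region queries stream from disk with predicate pushdown
#' rather than loading the whole store.
#'
#' @param single single-SNP scan table.
#' @param pairs pair record table.
#' @param meta named list of run metadata.
#' @param output_dir optional directory for the on-disk backend.
#' @return a \code{gcdh_report}.
#' @export
gcdh_report <- function(single, pairs, meta, output_dir = NULL) {
  if (is.null(output_dir)) {
    return(structure(list(backend = "memory", single = single, pairs = pairs,
                          meta = meta), class = "gcdh_report"))
  }
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  arrow::write_parquet(single, file.path(output_dir, "single_snp.parquet"))
  arrow::write_parquet(pairs, file.path(output_dir, "pairs.parquet"))
  write.dcf(data.frame(lapply(meta, as.character), stringsAsFactors = FALSE),
            file.path(output_dir, "meta.dcf"))
  structure(list(backend = "disk", dir = output_dir, meta = meta),
            class = "gcdh_report")
}

#' Open a GCDH report from disk
#'
#' @param dir directory written by [run_gcdh()] with an \code{output_dir}.
#' @return a \code{gcdh_report} with the disk backend.
#' @export
open_gcdh_report <- function(dir) {
  meta_path <- file.path(dir, "meta.dcf")
  if (!file.exists(meta_path)) stop("no GCDH report found in ", dir)
  raw <- as.list(as.data.frame(read.dcf(meta_path), stringsAsFactors = FALSE))
  num <- c("pvalue_filter")
  int <- c("window_size", "seed", "n_variants_input", "n_variants_scanned",
           "n_filtered_out", "n_samples", "n_pairs_enumerated",
           "n_pairs_reported", "n_pairs_degenerate")
  meta <- raw
  for (f in intersect(num, names(meta))) meta[[f]] <- as.numeric(meta[[f]])
  for (f in intersect(int, names(meta))) meta[[f]] <- as.integer(meta[[f]])
  structure(list(backend = "disk", dir = dir, meta = meta),
            class = "gcdh_report")
}

#' @export
print.gcdh_report <- function(x, ...) {
  cat(sprintf("gcdh_report [%s]: %d pair records (%d degenerate) over %d variants, window %d\n",
              x$backend, x$meta$n_pairs_reported, x$meta$n_pairs_degenerate,
              x$meta$n_variants_scanned, x$meta$window_size))
  invisible(x)
}

.report_pairs_query <- function(report, predicate = NULL) {
  if (report$backend == "memory") {
    out <- report$pairs
    if (!is.null(predicate)) out <- out[predicate(out), , drop = FALSE]
    return(out)
  }
  ds <- arrow::open_dataset(file.path(report$dir, "pairs.parquet"))
  if (is.null(predicate)) return(as.data.frame(dplyr::collect(ds)))
  as.data.frame(dplyr::collect(predicate(ds)))
}

.order_pairs <- function(x) {
  x[order(x$p, x$bp1, x$bp2, na.last = TRUE), , drop = FALSE]
}

#' Query pair records by genomic region
#'
#' Returns every pair with either member inside the (1-based, inclusive)
#' region, ordered by ascending p with ties broken by (bp1, bp2). For on-disk
#' reports the filter is pushed down to the parquet scan so the store is never
#' loaded whole.
#'
#' @param report a \code{gcdh_report}.
#' @param chr chromosome label.
#' @param start,end region bounds in bp, \code{start <= end}.
#' @param limit optional maximum number of records.
#' @return data.frame of pair records.
#' @export
query_region <- function(report, chr, start, end, limit = NULL) {
  stopifnot(inherits(report, "gcdh_report"))
  if (start > end) stop("region start must be <= end")
  chr <- as.character(chr)
  out <- if (report$backend == "memory") {
    .report_pairs_query(report, function(x) {
      x$chromosome == chr &
        ((x$bp1 >= start & x$bp1 <= end) | (x$bp2 >= start & x$bp2 <= end))
    })
  } else {
    .report_pairs_query(report, function(ds) {
      dplyr::filter(ds, .data$chromosome == chr &
                      ((.data$bp1 >= start & .data$bp1 <= end) |
                         (.data$bp2 >= start & .data$bp2 <= end)))
    })
  }
  out <- .order_pairs(out)
  rownames(out) <- NULL
  if (!is.null(limit)) out <- utils::head(out, limit)
  out
}

#' Top pair records by p-value
#'
#' @param report a \code{gcdh_report}.
#' @param n number of records.
#' @param p_max optional p-value ceiling applied before ranking.
#' @return data.frame of pair records, ordered by p (ties by bp1, bp2).
#' @export
top_pairs <- function(report, n = 10, p_max = NULL) {
  stopifnot(inherits(report, "gcdh_report"))
  out <- if (is.null(p_max)) {
    .report_pairs_query(report)
  } else if (report$backend == "memory") {
    .report_pairs_query(report, function(x) !is.na(x$p) & x$p <= p_max)
  } else {
    .report_pairs_query(report, function(ds) {
      dplyr::filter(ds, !is.na(.data$p) & .data$p <= p_max)
    })
  }
  out <- .order_pairs(out)
  rownames(out) <- NULL
  utils::head(out, n)
}

#' Single-SNP scan table of a report
#'
#' @param report a \code{gcdh_report}.
#' @return the single-marker scan results.
#' @export
report_single <- function(report) {
  stopifnot(inherits(report, "gcdh_report"))
  if (report$backend == "memory") return(report$single)
  as.data.frame(dplyr::collect(
    arrow::open_dataset(file.path(report$dir, "single_snp.parquet"))
  ))
}

#' Export a report as tab-delimited text
#'
#' @param report a \code{gcdh_report}.
#' @param dir output directory; \code{single_snp.tsv} and \code{pairs.tsv} are
#'   written there.
#' @return the directory, invisibly.
#' @export
export_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(report_single(report), file.path(dir, "single_snp.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(.report_pairs_query(report), file.path(dir, "pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Extract a genomic region from a dataset
#'
#' Keeps the variants whose position lies in \code{[start - flank, end +
#' flank]} on the given chromosome; regional GCDH is then [run_gcdh()] on the
#' extract. Genotype bytes are carried over unchanged.
#'
#' @param dataset a [bed_dataset()].
#' @param chr chromosome label.
#' @param start,end region bounds in bp (1-based, inclusive).
#' @param flank symmetric flank in bp added to both sides.
#' @return the extracted [bed_dataset()] (possibly empty, with a warning).
#' @export
extract_region <- function(dataset, chr, start, end, flank = 0) {
  stopifnot(inherits(dataset, "bed_dataset"))
  if (start > end) stop("region start must be <= end")
  lo <- start - flank
  hi <- end + flank
  keep <- dataset$variants$chr == as.character(chr) &
    dataset$variants$bp >= lo & dataset$variants$bp <= hi
  if (!any(keep)) {
    warning("no variants in ", chr, ":", lo, "-", hi, "; empty dataset")
  }
  .subset_variants(dataset, keep)
}

#' Phenotypic variance explained by markers or pairs
#'
#' Per item, the squared correlation between the quantitative phenotype and the
#' item's dose vector, as a percentage; the total is the sum of the per-item
#' percentages (degenerate doses are NA and excluded from the total with a
#' warning).
#'
#' @param y quantitative phenotype vector.
#' @param doses numeric matrix (items in columns), list of vectors, or a single
#'   vector.
#' @return data.frame with \code{item} and \code{r2_percent}; the total is
#'   available via [r2_total()] or \code{attr(, "total")}.
#' @export
variance_explained <- function(y, doses) {
  if (is.list(doses) && !is.data.frame(doses)) doses <- do.call(cbind, doses)
  if (is.vector(doses)) doses <- matrix(doses, ncol = 1)
  doses <- as.matrix(doses)
  if (nrow(doses) != length(y)) stop("dose vectors must match the phenotype length")
  items <- colnames(doses)
  if (is.null(items)) items <- paste0("item", seq_len(ncol(doses)))
  r2 <- vapply(seq_len(ncol(doses)), function(j) {
    d <- doses[, j]
    ok <- !is.na(d) & !is.na(y)
    if (sum(ok) < 3 || stats::var(d[ok]) < 1e-12) return(NA_real_)
    100 * stats::cor(y[ok], d[ok])^2
  }, numeric(1))
  if (anyNA(r2)) {
    warning(sum(is.na(r2)), " degenerate dose vector(s) excluded from the total")
  }
  out <- data.frame(item = items, r2_percent = r2, stringsAsFactors = FALSE)
  attr(out, "total") <- r2_total(r2)
  out
}

#' Total variance explained
#'
#' Sums per-item R-squared percentages, excluding NA items. This is the
#' totalling rule used in variance-explained tables (the total of per-pair or
#' per-SNP percentages, not the R-squared of a joint model).
#'
#' @param r2 numeric vector of per-item percentages, or a
#'   [variance_explained()] result.
#' @return the total percentage.
#' @export
r2_total <- function(r2) {
  if (is.data.frame(r2)) r2 <- r2$r2_percent
  sum(r2, na.rm = TRUE)
}
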