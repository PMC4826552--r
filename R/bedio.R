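# PLINK bed/bim/fam reading, writing and the packed 2-bit genotype codec.
#
# Genotype codes follow the PLINK binary convention:
#   0 (00) homozygote of allele A1 (minor by file convention)
#   1 (01) missing
#   2 (10) heterozygote
#   3 (11) homozygote of allele A2 (major)
# Within a byte the first sample occupies the least-significant bit pair.

BED_MAGIC1 <- as.raw(0x6c)
BED_MAGIC2 <- as.raw(0x1b)
BED_MODE_SNP_MAJOR <- as.raw(0x01)

# 256 x 4 table: row b+1 holds the four 2-bit codes packed in byte b,
# least-significant pair first.
.decode_table <- local({
  b <- 0:255
  m <- cbind(
    bitwAnd(b, 3L),
    bitwAnd(bitwShiftR(b, 2L), 3L),
    bitwAnd(bitwShiftR(b, 4L), 3L),
    bitwAnd(bitwShiftR(b, 6L), 3L)
  )
  storage.mode(m) <- "integer"
  m
})

#' Pack genotype codes into PLINK bed bytes
#'
#' Packs a vector of 2-bit genotype codes (values 0--3) into raw bytes, four
#' codes per byte, first sample in the least-significant bit pair. Pad bits in
#' the final byte are zero.
#'
#' @param codes integer vector of genotype codes in \code{0:3}.
#' @return raw vector of length \code{ceiling(length(codes)/4)}.
#' @seealso [unpack_genotypes()]
#' @export
pack_genotypes <- function(codes) {
  codes <- as.integer(codes)
  if (anyNA(codes) || any(codes < 0L | codes > 3L)) {
    stop("genotype codes must be integers in 0..3 (1 encodes missing)")
  }
  n <- length(codes)
  nbytes <- ceiling(n / 4)
  padded <- c(codes, integer(nbytes * 4L - n))
  q <- matrix(padded, nrow = 4L)
  as.raw(q[1L, ] + 4L * q[2L, ] + 16L * q[3L, ] + 64L * q[4L, ])
}

#' Unpack PLINK bed bytes into genotype codes
#'
#' @param bytes raw vector holding at least \code{ceiling(n/4)} bytes.
#' @param n number of samples (codes) to extract.
#' @return integer vector of \code{n} genotype codes.
#' @export
unpack_genotypes <- function(bytes, n) {
  if (length(bytes) * 4L < n) {
    stop("byte vector too short: ", length(bytes), " bytes cannot hold ", n, " genotypes")
  }
  codes <- t(.decode_table[as.integer(bytes) + 1L, , drop = FALSE])
  as.integer(codes)[seq_len(n)]
}

.bytes_per_variant <- function(n) as.integer(ceiling(n / 4))

.pad_mask <- function(n) {
  r <- n %% 4L
  if (r == 0L) as.raw(0xff) else as.raw(bitwShiftL(1L, 2L * r) - 1L)
}

#' Construct a bed dataset
#'
#' In-memory representation of a PLINK binary fileset: a variant table (bim
#' fields), a sample table (fam fields) and the SNP-major packed genotype
#' matrix. Genotypes are kept packed (one raw column of
#' \code{ceiling(n/4)} bytes per variant); use [genotype_matrix()] to decode.
#'
#' @param variants data.frame with columns \code{chr, id, cm, bp, a1, a2};
#'   within each chromosome rows must be sorted by ascending \code{bp} and ids
#'   must be unique across the fileset.
#' @param samples data.frame with columns \code{fid, iid, pid, mid, sex,
#'   phenotype}; \code{(fid, iid)} pairs must be unique.
#' @param genotypes either an \code{m x n} integer matrix of genotype codes
#'   (variants in rows) or a raw matrix of packed bytes with
#'   \code{ceiling(n/4)} rows and \code{m} columns.
#' @return an object of class \code{bed_dataset}.
#' @export
bed_dataset <- function(variants, samples, genotypes) {
  variants <- .as_variant_table(variants)
  samples <- .as_sample_table(samples)
  m <- nrow(variants)
  n <- nrow(samples)
  if (is.raw(genotypes)) {
    bed <- matrix(genotypes, nrow = .bytes_per_variant(n), ncol = m)
  } else if (is.matrix(genotypes) && !is.raw(genotypes)) {
    if (nrow(genotypes) != m || ncol(genotypes) != n) {
      stop("genotype matrix must be m x n = ", m, " x ", n)
    }
    bed <- matrix(as.raw(0), nrow = .bytes_per_variant(n), ncol = m)
    for (j in seq_len(m)) bed[, j] <- pack_genotypes(genotypes[j, ])
  } else {
    stop("genotypes must be an integer code matrix or a raw byte matrix")
  }
  if (nrow(bed) != .bytes_per_variant(n) || ncol(bed) != m) {
    stop("packed genotypes have wrong shape: expected ",
         .bytes_per_variant(n), " x ", m)
  }
  # force pad bits to zero so written files are canonical
  if (n %% 4L != 0L && nrow(bed) > 0L && m > 0L) {
    bed[nrow(bed), ] <- bed[nrow(bed), ] & .pad_mask(n)
  }
  x <- structure(
    list(variants = variants, samples = samples, bed = bed, n = n, m = m),
    class = "bed_dataset"
  )
  .validate_bed_dataset(x)
  x
}

.as_variant_table <- function(v) {
  need <- c("chr", "id", "cm", "bp", "a1", "a2")
  if (!all(need %in% names(v))) {
    stop("variant table must have columns: ", paste(need, collapse = ", "))
  }
  v <- as.data.frame(v)[, need]
  v$chr <- as.character(v$chr)
  v$id <- as.character(v$id)
  v$cm <- as.numeric(v$cm)
  v$bp <- as.integer(v$bp)
  rownames(v) <- NULL
  v
}

.as_sample_table <- function(s) {
  need <- c("fid", "iid", "pid", "mid", "sex", "phenotype")
  if (!all(need %in% names(s))) {
    stop("sample table must have columns: ", paste(need, collapse = ", "))
  }
  s <- as.data.frame(s)[, need]
  s$fid <- as.character(s$fid)
  s$iid <- as.character(s$iid)
  rownames(s) <- NULL
  s
}

.validate_bed_dataset <- function(x) {
  v <- x$variants
  if (anyDuplicated(v$id)) {
    stop("variant ids are not unique (first duplicate: ",
         v$id[anyDuplicated(v$id)], ")")
  }
  if (anyDuplicated(paste(x$samples$fid, x$samples$iid, sep = "\r"))) {
    stop("(fid, iid) sample keys are not unique")
  }
  if (nrow(v) > 1L) {
    unsorted <- tapply(v$bp, factor(v$chr, levels = unique(v$chr)),
                       function(bp) is.unsorted(bp))
    if (any(unlist(unsorted))) {
      stop("variants must be sorted by ascending position within chromosome (",
           paste(names(which(unlist(unsorted))), collapse = ", "), ")")
    }
  }
  invisible(x)
}

#' @export
print.bed_dataset <- function(x, ...) {
  cat(sprintf("bed_dataset: %d variants x %d samples (%d chromosome(s))\n",
              x$m, x$n, length(unique(x$variants$chr))))
  invisible(x)
}

#' Decode the full genotype matrix of a bed dataset
#'
#' @param dataset a [bed_dataset()].
#' @return \code{m x n} integer matrix of genotype codes (variants in rows).
#' @export
genotype_matrix <- function(dataset) {
  m <- dataset$m
  n <- dataset$n
  if (m == 0L || n == 0L) return(matrix(integer(0), nrow = m, ncol = n))
  codes <- t(.decode_table[as.integer(dataset$bed) + 1L, , drop = FALSE])
  dim(codes) <- c(4L * nrow(dataset$bed), m)
  t(codes[seq_len(n), , drop = FALSE])
}

#' Read a PLINK binary fileset
#'
#' Reads the bed/bim/fam triplet identified by a path prefix. Only SNP-major
#' bed files (mode byte 0x01) are supported. Fileset consistency (bed size vs
#' bim/fam line counts) is verified before decoding.
#'
#' @param prefix path prefix; \code{.bed/.bim/.fam} are appended unless the
#'   individual paths are overridden.
#' @param bed,bim,fam optional explicit file paths.
#' @param check_a1_freq when TRUE, warn if any variant's observed A1 allele
#'   frequency exceeds 0.5 (A1 is assumed minor by file convention; it is never
#'   re-estimated).
#' @return a [bed_dataset()].
#' @export
read_bed <- function(prefix,
                     bed = paste0(prefix, ".bed"),
                     bim = paste0(prefix, ".bim"),
                     fam = paste0(prefix, ".fam"),
                     check_a1_freq = FALSE) {
  variants <- utils::read.table(
    bim, header = FALSE,
    col.names = c("chr", "id", "cm", "bp", "a1", "a2"),
    colClasses = c("character", "character", "numeric", "integer",
                   "character", "character")
  )
  samples <- utils::read.table(
    fam, header = FALSE,
    col.names = c("fid", "iid", "pid", "mid", "sex", "phenotype"),
    colClasses = c("character", "character", "character", "character",
                   "integer", "numeric")
  )
  samples$phenotype[samples$phenotype == -9] <- NA_real_

  raw <- readBin(bed, what = "raw", n = file.size(bed))
  if (length(raw) < 3L) stop("bed file too short to contain a header: ", bed)
  if (raw[1L] != BED_MAGIC1 || raw[2L] != BED_MAGIC2) {
    bad <- if (raw[1L] != BED_MAGIC1) 1L else 2L
    stop(sprintf(
      "not a PLINK bed file: header byte %d is 0x%02X (expected 0x%02X)",
      bad, as.integer(raw[bad]), as.integer(c(BED_MAGIC1, BED_MAGIC2)[bad])
    ))
  }
  if (raw[3L] != BED_MODE_SNP_MAJOR) {
    stop(sprintf(
      "unsupported bed mode byte 0x%02X at position 3; only SNP-major (0x01) is supported",
      as.integer(raw[3L])
    ))
  }
  m <- nrow(variants)
  n <- nrow(samples)
  expected <- 3L + .bytes_per_variant(n) * m
  if (length(raw) != expected) {
    stop(sprintf(
      "bed size inconsistent with bim/fam: expected %d bytes (3 + ceil(%d/4) * %d), found %d",
      expected, n, m, length(raw)
    ))
  }
  body <- if (m > 0L) raw[-(1:3)] else raw(0)
  x <- bed_dataset(variants, samples,
                   matrix(body, nrow = .bytes_per_variant(n), ncol = m))
  if (check_a1_freq && m > 0L) {
    st <- allele_stats(x)
    high <- which(!is.na(st$freq_a1) & st$freq_a1 > 0.5)
    if (length(high)) {
      warning(length(high), " variant(s) have observed A1 frequency > 0.5 ",
              "(A1 is assumed to be the minor allele); e.g. ",
              paste(utils::head(st$id[high], 3), collapse = ", "))
    }
  }
  x
}

#' Write a PLINK binary fileset
#'
#' Emits bed (magic bytes, SNP-major mode byte, packed genotype rows), bim and
#' fam files that re-read bit-exactly. Missing phenotypes are written as -9.
#'
#' @param dataset a [bed_dataset()].
#' @param prefix output path prefix.
#' @return the prefix, invisibly.
#' @export
write_bed <- function(dataset, prefix) {
  stopifnot(inherits(dataset, "bed_dataset"))
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(c(BED_MAGIC1, BED_MAGIC2, BED_MODE_SNP_MAJOR), con)
  if (dataset$m > 0L) writeBin(as.vector(dataset$bed), con)

  utils::write.table(dataset$variants, paste0(prefix, ".bim"),
                     quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  fam <- dataset$samples
  fam$phenotype[is.na(fam$phenotype)] <- -9
  utils::write.table(fam, paste0(prefix, ".fam"),
                     quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read a phenotype/covariate table
#'
#' Whitespace-delimited text with a header line; the first two columns must be
#' the family and individual ids (FID, IID). A value of -9 in any numeric
#' column is treated as missing.
#'
#' @param path file path.
#' @return data.frame whose first two columns are named \code{fid}, \code{iid}.
#' @export
read_pheno <- function(path) {
  ph <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(ph) < 3L) stop("phenotype file needs FID, IID and at least one value column")
  names(ph)[1:2] <- c("fid", "iid")
  ph$fid <- as.character(ph$fid)
  ph$iid <- as.character(ph$iid)
  for (j in seq(3L, ncol(ph))) {
    if (is.numeric(ph[[j]])) ph[[j]][ph[[j]] == -9] <- NA
  }
  ph
}

# Subset a dataset to the variants in `idx` (logical or integer), preserving
# order. Shared by the p-value filter and region extraction.
.subset_variants <- function(dataset, idx) {
  if (is.logical(idx)) idx <- which(idx)
  out <- dataset
  out$variants <- dataset$variants[idx, , drop = FALSE]
  rownames(out$variants) <- NULL
  out$bed <- dataset$bed[, idx, drop = FALSE]
  out$m <- length(idx)
  class(out) <- "bed_dataset"
  out["pairs"] <- NULL
  out$shift <- NULL
  out
}
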