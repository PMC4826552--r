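# Genotype collapsing: the collapsing matrix, its byte-pair lookup table and
# the genome-shifting algorithm that produces shifted pseudo-genotype datasets.

# Default (recessive) model: a carrier pseudo-genotype (code 0, i.e. the
# "homozygote" of the pseudo-marker) arises from a homozygote-minor at either
# SNP or from the double heterozygote. Rows index the first genotype code,
# columns the second.
.MATRIX_RECESSIVE <- matrix(as.integer(c(
  0, 0, 0, 0,
  0, 1, 1, 1,
  0, 1, 0, 3,
  0, 1, 3, 3
)), nrow = 4, byrow = TRUE)

# Additive alternative: the double heterozygote and the het+hom-major cells
# grade the pseudo-genotype over 0/2/3 (doses 2/1/0).
.MATRIX_ADDITIVE <- matrix(as.integer(c(
  0, 0, 0, 0,
  0, 1, 1, 1,
  0, 1, 0, 2,
  0, 1, 2, 3
)), nrow = 4, byrow = TRUE)

#' Collapsing matrices
#'
#' A collapsing matrix is a 4x4 map \code{M} from a pair of 2-bit genotype
#' codes to one pseudo-genotype code: the collapsing function is
#' \code{C(g1, g2) = M[g1, g2]} (0-based codes). Two named models are built in:
#' \describe{
#'   \item{\code{"recessive-default"}}{carrier (pseudo-code 0) when either SNP
#'     is homozygous for the minor allele or both are heterozygous; output
#'     pseudo-genotypes are 0, 3 or missing.}
#'   \item{\code{"additive-alternative"}}{as above, but the het + hom-major
#'     cells collapse to the intermediate pseudo-code 2 (dose 1), giving an
#'     additive 0/1/2 pseudo-dose.}
#' }
#' A custom matrix may be given as a 4x4 array of codes in \code{0:3}, or as a
#' path to a whitespace-delimited text file of 4 lines x 4 integers.
#'
#' @param model model name, 4x4 numeric matrix, or file path.
#' @return an integer 4x4 matrix of class \code{collapsing_matrix} with a
#'   \code{name} attribute.
#' @export
collapsing_matrix <- function(model = "recessive-default") {
  if (inherits(model, "collapsing_matrix")) return(model)
  if (is.character(model) && length(model) == 1L && file.exists(model)) {
    m <- as.matrix(utils::read.table(model, header = FALSE))
    return(collapsing_matrix(unname(m)))
  }
  if (is.character(model)) {
    m <- switch(model,
      "recessive-default" = , "recessive" = , "default" = .MATRIX_RECESSIVE,
      "additive-alternative" = , "additive" = , "alternative" = .MATRIX_ADDITIVE,
      stop("unknown collapsing model '", model,
           "'; use \"recessive-default\", \"additive-alternative\", a 4x4 matrix or a file path")
    )
    name <- if (identical(m, .MATRIX_RECESSIVE)) "recessive-default" else "additive-alternative"
  } else {
    if (!is.matrix(model) || any(dim(model) != 4L)) {
      stop("a custom collapsing matrix must be 4x4")
    }
    m <- model
    storage.mode(m) <- "integer"
    bad <- which(is.na(m) | m < 0L | m > 3L)
    if (length(bad)) {
      rc <- arrayInd(bad[1L], dim(m))
      stop(sprintf(
        "collapsing matrix entries must be codes in 0..3; cell [%d, %d] is %s",
        rc[1L], rc[2L], as.character(model[bad[1L]])
      ))
    }
    name <- "custom"
  }
  dimnames(m) <- list(g1 = 0:3, g2 = 0:3)
  structure(m, class = "collapsing_matrix", name = name)
}

#' @export
print.collapsing_matrix <- function(x, ...) {
  cat("collapsing_matrix:", attr(x, "name"), "\n")
  print(unclass(x))
  invisible(x)
}

#' Collapse a pair of genotype codes
#'
#' Vectorised lookup \code{M[g1, g2]}. Symmetry in \code{g1}/\code{g2} is a
#' property of the matrix (both built-in matrices are symmetric), not of the
#' operation.
#'
#' @param g1,g2 integer vectors of genotype codes in \code{0:3}.
#' @param matrix a [collapsing_matrix()].
#' @return integer vector of pseudo-genotype codes.
#' @export
collapse_codes <- function(g1, g2, matrix = collapsing_matrix()) {
  matrix <- collapsing_matrix(matrix)
  g1 <- as.integer(g1); g2 <- as.integer(g2)
  if (any(g1 < 0L | g1 > 3L | g2 < 0L | g2 > 3L, na.rm = TRUE)) {
    stop("genotype codes must be in 0..3")
  }
  as.integer(unclass(matrix)[cbind(g1 + 1L, g2 + 1L)])
}

#' Build the byte-pair collapsing lookup table
#'
#' Precomputes the collapsed packed byte for every pair of input bytes, so that
#' whole-genome collapsing reduces to indexing a 256x256 array: for all bytes
#' \code{a}, \code{b} and in-byte positions \code{j},
#' \code{unpack(table[a, b])[j] == M[unpack(a)[j], unpack(b)[j]]}.
#'
#' @param matrix a [collapsing_matrix()].
#' @return a 256x256 raw matrix of class \code{byte_lookup}; element
#'   \code{[a + 1, b + 1]} is the collapsed byte for input bytes \code{a, b}.
#' @export
build_byte_table <- function(matrix = collapsing_matrix()) {
  matrix <- collapsing_matrix(matrix)
  M <- unclass(matrix)
  ia <- rep(1:256, times = 256)
  ib <- rep(1:256, each = 256)
  out <- matrix(0L, nrow = 65536L, ncol = 4L)
  for (pos in 1:4) {
    out[, pos] <- M[cbind(.decode_table[ia, pos] + 1L,
                          .decode_table[ib, pos] + 1L)]
  }
  tab <- as.raw(out[, 1L] + 4L * out[, 2L] + 16L * out[, 3L] + 64L * out[, 4L])
  dim(tab) <- c(256L, 256L)
  structure(tab, class = "byte_lookup", name = attr(matrix, "name"))
}

#' Enumerate within-window SNP pairs
#'
#' Returns every ordered pair of variant indices \code{(j, j + i)} with rank
#' distance \code{1 <= i <= k} on the same chromosome. This is the sliding
#' window enumeration that genome shifting reproduces shift by shift; it is
#' used for report completeness accounting and as the test oracle for
#' [shift_genome()].
#'
#' @param dataset a [bed_dataset()].
#' @param k window size (maximum rank distance), \code{k >= 1}.
#' @return data.frame with columns \code{left_index, right_index, shift}.
#' @export
window_pairs <- function(dataset, k) {
  stopifnot(inherits(dataset, "bed_dataset"), k >= 1)
  k <- as.integer(k)
  chr <- factor(dataset$variants$chr, levels = unique(dataset$variants$chr))
  out <- lapply(split(seq_len(dataset$m), chr), function(ix) {
    mc <- length(ix)
    res <- lapply(seq_len(min(k, mc - 1L)), function(i) {
      data.frame(left_index = ix[seq_len(mc - i)],
                 right_index = ix[seq_len(mc - i) + i],
                 shift = i)
    })
    do.call(rbind, res)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(left_index = integer(0), right_index = integer(0),
                      shift = integer(0))
  }
  rownames(out) <- NULL
  out[order(out$shift, out$left_index), , drop = FALSE]
}

#' Shift the genome and collapse SNP pairs
#'
#' Collapses every variant with the variant \code{shift} positions downstream
#' on the same chromosome, producing a dataset of pseudo-genotypes. Collapsing
#' operates directly on the packed byte rows via the byte lookup table; because
#' the bed layout is SNP-major, the two rows of a pair are packed sample by
#' sample in identical order and bytes align one to one. Pad bits of a ragged
#' final byte are re-zeroed after lookup. The trailing \code{shift} variants of
#' each chromosome produce no pseudo-variant; pairs never span chromosomes.
#'
#' @param dataset a [bed_dataset()], sorted by position within chromosome.
#' @param shift positive rank distance between pair members.
#' @param matrix a [collapsing_matrix()].
#' @param byte_table optional precomputed [build_byte_table()] for the same
#'   matrix (built once per run when scanning many shifts).
#' @return a \code{shifted_dataset} (a [bed_dataset()] of pseudo-variants with
#'   id \code{"leftID/rightID"}, position of the left member and synthetic
#'   alleles P/A) carrying a \code{pairs} table with the pair identities and a
#'   \code{shift} field.
#' @export
shift_genome <- function(dataset, shift, matrix = collapsing_matrix(),
                         byte_table = NULL) {
  stopifnot(inherits(dataset, "bed_dataset"))
  shift <- as.integer(shift)
  if (is.na(shift) || shift < 1L) stop("shift must be a positive integer")
  matrix <- collapsing_matrix(matrix)
  if (is.null(byte_table)) byte_table <- build_byte_table(matrix)

  v <- dataset$variants
  chr <- factor(v$chr, levels = unique(v$chr))
  left <- unlist(lapply(split(seq_len(dataset$m), chr), function(ix) {
    mc <- length(ix)
    if (mc > shift) ix[seq_len(mc - shift)] else integer(0)
  }), use.names = FALSE)

  if (length(left) == 0L) {
    warning("shift ", shift, " is >= the variant count of every chromosome; ",
            "empty shifted dataset")
  }
  right <- left + shift

  A <- dataset$bed[, left, drop = FALSE]
  B <- dataset$bed[, right, drop = FALSE]
  out <- byte_table[cbind(as.integer(A) + 1L, as.integer(B) + 1L)]
  dim(out) <- dim(A)
  if (dataset$n %% 4L != 0L && nrow(out) > 0L && ncol(out) > 0L) {
    out[nrow(out), ] <- out[nrow(out), ] & .pad_mask(dataset$n)
  }

  pseudo <- data.frame(
    chr = v$chr[left],
    id = if (length(left)) paste0(v$id[left], "/", v$id[right]) else character(0),
    cm = rep(0, length(left)),
    bp = v$bp[left],
    a1 = rep("P", length(left)),
    a2 = rep("A", length(left)),
    stringsAsFactors = FALSE
  )
  x <- bed_dataset(pseudo, dataset$samples, out)
  x$pairs <- data.frame(
    left_index = left, right_index = right,
    snp1 = v$id[left], snp2 = v$id[right],
    chr = v$chr[left], bp1 = v$bp[left], bp2 = v$bp[right],
    shift = rep(shift, length(left)),
    stringsAsFactors = FALSE
  )
  x$shift <- shift
  class(x) <- c("shifted_dataset", "bed_dataset")
  x
}

#' @export
print.shifted_dataset <- function(x, ...) {
  cat(sprintf("shifted_dataset (shift %d): %d pseudo-variants x %d samples\n",
              x$shift, x$m, x$n))
  invisible(x)
}
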