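# Contrast Manhattan plot: pair-level p-values overlaid on single-SNP
# p-values with separate genome-wide significance lines.

#' Contrast Manhattan plot
#'
#' Plots single-SNP results as conventional Manhattan points (alternating
#' shades by chromosome) and overlays the GCDH pair p-values (triangles,
#' plotted at the left member's position by default, or at the pair midpoint).
#' Two horizontal lines mark the single-SNP genome-wide threshold and the GCDH
#' threshold (either supplied directly, e.g. from [run_type_i()], or derived
#' analytically as \code{5e-8 / k} via [bonferroni_threshold()]).
#'
#' @param single single-SNP scan table (columns \code{chr, bp, p}).
#' @param pairs pair record table (columns \code{chromosome, bp1, bp2, p}),
#'   e.g. from [top_pairs()] or [query_region()]; may be NULL to plot singles
#'   only.
#' @param single_threshold single-SNP genome-wide significance level.
#' @param gcdh_threshold GCDH significance level; defaults to
#'   \code{bonferroni_threshold(k)} when \code{k} is given.
#' @param k window size used for the analytic GCDH threshold.
#' @param pair_position \code{"left"} plots a pair at its left member's bp,
#'   \code{"midpoint"} at the average of the two positions.
#' @param file optional output path (.png/.pdf/.svg); written via
#'   \code{ggplot2::ggsave}.
#' @param width,height device size in inches when \code{file} is given.
#' @return the ggplot object, invisibly when written to file.
#' @export
contrast_manhattan <- function(single, pairs = NULL,
                               single_threshold = 5e-8,
                               gcdh_threshold = NULL, k = NULL,
                               pair_position = c("left", "midpoint"),
                               file = NULL, width = 9, height = 4.5) {
  pair_position <- match.arg(pair_position)
  if (is.null(gcdh_threshold)) {
    gcdh_threshold <- if (!is.null(k)) bonferroni_threshold(k) else single_threshold
  }
  stopifnot(single_threshold > 0, gcdh_threshold > 0)

  sp <- data.frame(chr = as.character(single$chr), bp = single$bp,
                   p = single$p, stringsAsFactors = FALSE)
  pp <- NULL
  if (!is.null(pairs) && nrow(pairs)) {
    bp <- if (pair_position == "left") pairs$bp1 else (pairs$bp1 + pairs$bp2) / 2
    pp <- data.frame(chr = as.character(pairs$chromosome), bp = bp,
                     p = pairs$p, stringsAsFactors = FALSE)
  }
  sp <- sp[!is.na(sp$p), , drop = FALSE]
  if (!is.null(pp)) pp <- pp[!is.na(pp$p), , drop = FALSE]
  if (nrow(sp) == 0L && (is.null(pp) || nrow(pp) == 0L)) {
    stop("nothing to plot: all p-values are NA")
  }

  # genome coordinate: chromosomes laid end to end with a small gap
  chrs <- unique(c(sp$chr, if (!is.null(pp)) pp$chr))
  span <- vapply(chrs, function(cc) {
    max(c(sp$bp[sp$chr == cc], if (!is.null(pp)) pp$bp[pp$chr == cc], 1))
  }, numeric(1))
  gap <- 0.02 * sum(span)
  offset <- stats::setNames(cumsum(c(0, utils::head(span + gap, -1))), chrs)
  centers <- offset + span / 2

  clip <- function(p) pmax(p, 1e-300)
  sp$x <- offset[sp$chr] + sp$bp
  sp$logp <- -log10(clip(sp$p))
  sp$shade <- factor(match(sp$chr, chrs) %% 2L)
  if (!is.null(pp)) {
    pp$x <- offset[pp$chr] + pp$bp
    pp$logp <- -log10(clip(pp$p))
  }

  g <- ggplot2::ggplot() +
    ggplot2::geom_point(
      data = sp,
      ggplot2::aes(x = .data$x, y = .data$logp, colour = .data$shade),
      size = 0.7, show.legend = FALSE
    ) +
    ggplot2::scale_colour_manual(values = c(`0` = "grey35", `1` = "grey60"))
  if (!is.null(pp) && nrow(pp)) {
    g <- g + ggplot2::geom_point(
      data = pp,
      ggplot2::aes(x = .data$x, y = .data$logp),
      colour = "#1f78b4", shape = 17, size = 1.3
    )
  }
  g <- g +
    ggplot2::geom_hline(yintercept = -log10(single_threshold),
                        colour = "red", linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(gcdh_threshold),
                        colour = "blue", linetype = "dashed") +
    ggplot2::scale_x_continuous(breaks = centers, labels = chrs,
                                expand = ggplot2::expansion(mult = 0.01)) +
    ggplot2::labs(x = "chromosome", y = expression(-log[10](italic(p)))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(panel.grid.major.x = ggplot2::element_blank(),
                   panel.grid.minor.x = ggplot2::element_blank())

  if (!is.null(file)) {
    ggplot2::ggsave(file, g, width = width, height = height)
    return(invisible(g))
  }
  g
}
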