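#' Nx / NGx curve of an assembly
#'
#' Contigs are sorted in descending length; `Nx` is the length of the contig
#' at which the cumulative length first reaches x% of the assembly total
#' (or of an independent genome-size estimate, for the NGx variant). The
#' result is a step function, non-increasing in x.
#'
#' When `genome_size` exceeds the assembly total, NGx is undefined (`NA`)
#' for x beyond the covered fraction.
#'
#' @param contigs A [contig_set()].
#' @param genome_size Optional genome size in bp; when given the curve is
#'   NGx rather than Nx.
#' @return An object of class `nx_curve`: a list with the step table
#'   (`x_from`, `x_to`, `nx_bp`), the target size and a logical `is_ng`.
#'   Evaluate it at arbitrary x with [nx_at()].
#' @export
nx_curve <- function(contigs, genome_size = NULL) {
  if (nrow(contigs) < 1L) stop("need at least one contig")
  if (!is.null(genome_size) && genome_size <= 0) stop("genome_size must be > 0")
  ord <- order(-contigs$length, contigs$name)
  len <- contigs$length[ord]
  total <- sum(len)
  target <- if (is.null(genome_size)) total else genome_size
  cum <- cumsum(len)
  x_to <- pmin(100 * cum / target, 100)
  x_from <- c(0, utils::head(x_to, -1))
  keep <- x_to > x_from
  steps <- data.frame(x_from = x_from[keep], x_to = x_to[keep],
                      nx_bp = len[keep])
  structure(list(steps = steps, target_bp = target,
                 is_ng = !is.null(genome_size),
                 covered_x = 100 * total / target),
            class = "nx_curve")
}

#' Evaluate an Nx/NGx curve at one or more x values
#'
#' @param curve An [nx_curve()].
#' @param x Percentages in (0, 100].
#' @return Nx (bp) at each x; `NA` where NGx is undefined because the
#'   assembly does not cover x% of the genome size.
#' @export
nx_at <- function(curve, x) {
  stopifnot(all(x > 0 & x <= 100))
  vapply(x, function(xx) {
    if (xx > curve$covered_x + 1e-9) return(NA_real_)
    i <- which(curve$steps$x_from < xx & xx <= curve$steps$x_to + 1e-9)[1]
    curve$steps$nx_bp[i]
  }, numeric(1))
}

#' Contiguity statistics of an assembly
#'
#' Computes total size, contig count, largest contig, N50 and L50 (and NG50
#' when a genome size is supplied), the auN statistic, and the fraction of
#' assembled bases in contigs of at least `large_threshold` bp.
#'
#' auN is the area under the Nx curve, \eqn{auN = \sum_i L_i (L_i / \sum_j
#' L_j)}: the expected contig length of a random assembled base. Unlike
#' N50 it responds to every break in the assembly, which makes it a fairer
#' statistic for comparing versions of the same assembly.
#'
#' @param contigs A [contig_set()].
#' @param genome_size Optional independent genome-size estimate (bp) for
#'   NG50.
#' @param large_threshold Contig length (bp) defining "large" contigs for
#'   the fraction statistic (default 10 kb).
#' @return An object of class `ContiguityStats` (list).
#' @export
contiguity_stats <- function(contigs, genome_size = NULL,
                             large_threshold = 10000) {
  if (nrow(contigs) < 1L) stop("need at least one contig")
  len <- contigs$length
  total <- sum(len)
  curve <- nx_curve(contigs)
  n50 <- nx_at(curve, 50)
  l50 <- which(cumsum(sort(len, decreasing = TRUE)) >= total / 2)[1]
  ng50 <- if (is.null(genome_size)) NA_real_ else {
    nx_at(nx_curve(contigs, genome_size), 50)
  }
  structure(list(
    assembly_id = attr(contigs, "assembly_id"),
    total_bp = total,
    n_contigs = nrow(contigs),
    largest_bp = max(len),
    N50_bp = n50,
    L50 = l50,
    NG50_bp = ng50,
    auN_bp = sum(len * (len / total)),
    fraction_bp_in_large_contigs = sum(len[len >= large_threshold]) / total,
    large_threshold_bp = large_threshold
  ), class = "ContiguityStats")
}

#' @export
print.ContiguityStats <- function(x, ...) {
  cat(sprintf("Assembly %s: %d contigs, %.0f bp\n", x$assembly_id,
              x$n_contigs, x$total_bp))
  cat(sprintf("  N50 %.0f bp (L50 %d), largest %.0f bp, auN %.1f bp\n",
              x$N50_bp, x$L50, x$largest_bp, x$auN_bp))
  if (!is.na(x$NG50_bp)) cat(sprintf("  NG50 %.0f bp\n", x$NG50_bp))
  cat(sprintf("  %.2f%% of bases in contigs >= %.0f bp\n",
              100 * x$fraction_bp_in_large_contigs, x$large_threshold_bp))
  invisible(x)
}
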