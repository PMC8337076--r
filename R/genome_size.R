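#' Mean read depth over single-copy marker regions
#'
#' Averages per-position read depth over the intervals of complete
#' single-copy markers. Single-copy markers behave like unique k-mers: the
#' depth of coverage over them reflects the true sequencing depth of the
#' genome, which is what coverage-based genome-size estimation needs.
#' Duplicated and fragmented markers are excluded. Overlapping marker
#' intervals are merged first so each position counts once.
#'
#' @param track A [depth_track()].
#' @param markers A [marker_table()]; only `complete_single` rows with
#'   coordinates are used.
#' @param zero_fill When `TRUE` (default), positions inside marker intervals
#'   that are absent from the track count as depth 0 (depth files typically
#'   omit zero rows); when `FALSE` they are excluded from the mean.
#' @return A list with `mean_depth` and `n_positions`.
#' @export
mean_depth_over_markers <- function(track, markers, zero_fill = TRUE) {
  use <- markers[markers$status == "complete_single" & !is.na(markers$start), ,
                 drop = FALSE]
  if (nrow(use) == 0L) stop("no usable complete_single marker intervals")
  iv <- iv_merge(iv_frame(contig = use$contig, start = use$start, end = use$end))
  inside <- iv_contains_points(iv, track$contig, track$pos)
  depth_sum <- sum(track$depth[inside])
  n_pos <- if (zero_fill) iv_total_bp(iv) else sum(inside)
  if (n_pos == 0L) stop("no usable positions in marker intervals")
  mean_depth <- depth_sum / n_pos
  if (mean_depth == 0) stop("mean depth over markers is zero")
  list(mean_depth = mean_depth, n_positions = n_pos)
}

#' Coverage-based genome-size estimate
#'
#' Genome size is estimated as total read bases divided by the mean depth
#' of coverage over single-copy marker regions, adjusted for any fraction
#' of the assembly removed as contaminant:
#' \deqn{G = B (1 - r) / d}
#' with B the total bases in the read set, d the mean depth and r the
#' proportion of the assembly removed.
#'
#' @param total_read_bases Total bases in the (long) read set.
#' @param mean_depth Mean depth over single-copy markers, e.g. from
#'   [mean_depth_over_markers()].
#' @param removed_fraction Proportion of the assembly removed as
#'   contaminant, in [0, 1); default 0.
#' @param n_positions_used Optional record of how many marker positions the
#'   depth estimate used.
#' @return An object of class `GenomeSizeEstimate` (list) with field
#'   `genome_size_bp` and the inputs.
#' @export
estimate_genome_size <- function(total_read_bases, mean_depth,
                                 removed_fraction = 0,
                                 n_positions_used = NA_integer_) {
  if (mean_depth <= 0) stop("mean_depth must be > 0")
  if (removed_fraction < 0 || removed_fraction >= 1) {
    stop("removed_fraction must be in [0, 1)")
  }
  structure(list(
    total_read_bases = total_read_bases,
    mean_depth = mean_depth,
    removed_fraction = removed_fraction,
    n_positions_used = n_positions_used,
    genome_size_bp = total_read_bases * (1 - removed_fraction) / mean_depth
  ), class = "GenomeSizeEstimate")
}

#' @export
print.GenomeSizeEstimate <- function(x, ...) {
  cat(sprintf("Genome size estimate: %.3g bp (%.3g read bases / depth %.2f",
              x$genome_size_bp, x$total_read_bases, x$mean_depth))
  if (x$removed_fraction > 0) {
    cat(sprintf(", %.1f%% removed", 100 * x$removed_fraction))
  }
  cat(")\n")
  invisible(x)
}
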