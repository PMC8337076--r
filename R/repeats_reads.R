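#' Repeat-content summary of an assembly
#'
#' Per-class masked bp (within-class intervals merged before summing), the
#' total repetitive bp as the union across all classes, and the
#' non-repetitive remainder. Fractions are relative to total assembly size.
#' Classes may overlap each other, so the per-class fractions can sum to
#' more than the union fraction.
#'
#' @param records Repeat records (contig, start, end, repeat_name,
#'   repeat_class), e.g. from [read_repeatmasker_out()].
#' @param contigs A [contig_set()].
#' @return An object of class `RepeatSummary` (list): `assembly_bp`,
#'   `by_class` (data frame class/bp/fraction), `repetitive_bp`,
#'   `non_repetitive_bp`, `repetitive_fraction`.
#' @export
repeat_summary <- function(records, contigs) {
  unknown <- setdiff(unique(records$contig), contigs$name)
  if (length(unknown) > 0L) stop("repeat record on unknown contig: ", unknown[1])
  assembly_bp <- sum(contigs$length)
  if (nrow(records) == 0L) {
    return(structure(list(
      assembly_bp = assembly_bp,
      by_class = data.frame(class = character(), bp = numeric(),
                            fraction = numeric(), stringsAsFactors = FALSE),
      repetitive_bp = 0, non_repetitive_bp = assembly_bp,
      repetitive_fraction = 0), class = "RepeatSummary"))
  }
  classes <- sort(unique(records$repeat_class))
  by_class <- do.call(rbind, lapply(classes, function(cl) {
    r <- records[records$repeat_class == cl, , drop = FALSE]
    bp <- iv_total_bp(iv_frame(contig = r$contig, start = r$start, end = r$end))
    data.frame(class = cl, bp = bp, fraction = bp / assembly_bp,
               stringsAsFactors = FALSE)
  }))
  union_bp <- iv_total_bp(iv_frame(contig = records$contig,
                                   start = records$start, end = records$end))
  structure(list(
    assembly_bp = assembly_bp,
    by_class = by_class,
    repetitive_bp = union_bp,
    non_repetitive_bp = assembly_bp - union_bp,
    repetitive_fraction = union_bp / assembly_bp
  ), class = "RepeatSummary")
}

#' Read-set statistics
#'
#' Read N50 (same cumulative rule as contig N50) and, for each length
#' threshold, the fraction of total bases contained in reads longer than
#' the threshold (strict `>` by default, matching the usual "bases in reads
#' longer than L" phrasing).
#'
#' @param lengths Numeric vector of read lengths (bp); at least one read.
#' @param thresholds Length thresholds in bp (default 25 kb, 50 kb,
#'   100 kb).
#' @param strict Use strict `>` for "longer than" (default `TRUE`).
#' @return An object of class `ReadSetStats` (list): `n_reads`, `total_bp`,
#'   `read_N50_bp`, `fraction_bp_longer` (named by threshold).
#' @export
read_stats <- function(lengths, thresholds = c(25000, 50000, 100000),
                       strict = TRUE) {
  if (length(lengths) == 0L) stop("empty read set")
  total <- sum(lengths)
  srt <- sort(lengths, decreasing = TRUE)
  n50 <- srt[which(cumsum(srt) >= total / 2)[1]]
  frac <- vapply(thresholds, function(L) {
    keep <- if (strict) lengths > L else lengths >= L
    sum(lengths[keep]) / total
  }, numeric(1))
  names(frac) <- format(thresholds, scientific = FALSE, trim = TRUE)
  structure(list(n_reads = length(lengths), total_bp = total,
                 read_N50_bp = n50, fraction_bp_longer = frac),
            class = "ReadSetStats")
}

#' Seeded downsampling of a read set to a target depth
#'
#' Reads are taken in a seeded uniform random permutation until the
#' cumulative length first reaches `target_depth * genome_size`. Because
#' the permutation is uniform, selection is length-unbiased: the marginal
#' inclusion probability of a read does not depend on its length, so the
#' downsampled set preserves the read-length distribution (and hence read
#' N50) of the full set.
#'
#' @param ids Read identifiers (parallel to `lengths`).
#' @param lengths Read lengths in bp.
#' @param target_depth Target depth of coverage.
#' @param genome_size Genome size in bp.
#' @param seed RNG seed.
#' @return A list: `ids` (selected, in selection order), `achieved_bp`,
#'   `achieved_depth`.
#' @export
downsample <- function(ids, lengths, target_depth, genome_size, seed) {
  stopifnot(length(ids) == length(lengths))
  target_bp <- target_depth * genome_size
  if (sum(lengths) < target_bp) {
    stop(sprintf("insufficient data: max achievable depth %.2f",
                 sum(lengths) / genome_size))
  }
  perm <- with_seed(seed, sample.int(length(ids)))
  cum <- cumsum(lengths[perm])
  k <- which(cum >= target_bp)[1]
  sel <- perm[seq_len(k)]
  list(ids = ids[sel], achieved_bp = cum[k],
       achieved_depth = cum[k] / genome_size)
}
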