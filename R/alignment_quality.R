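#' Derive genomic element classes from gene/exon/repeat annotations
#'
#' Introns are the within-gene complement of exons; intergenic regions are
#' the complement of genic regions, so exon/intron/intergenic partition each
#' contig exactly. Repeats are kept as a parallel overlay class, since they
#' overlap genes. All interval sets are merged and sorted, 0-based
#' half-open.
#'
#' @param genes,exons,repeats Data frames (contig, start, end); `repeats`
#'   may be `NULL`. Exons must fall inside genes after merging.
#' @param contig_lengths Named numeric vector of contig lengths.
#' @return An object of class `ElementAnnotation`: a list with `classes`
#'   (named list of interval frames: exon, intron, intergenic, and repeat
#'   when given) and `contig_lengths`.
#' @export
derive_elements <- function(genes, exons, repeats = NULL, contig_lengths) {
  g <- iv_merge(iv_frame(contig = genes$contig, start = genes$start,
                         end = genes$end))
  e <- iv_merge(iv_frame(contig = exons$contig, start = exons$start,
                         end = exons$end))
  stray <- iv_setdiff(e, g)
  if (nrow(stray) > 0L) {
    stop("exon intervals outside any gene: ",
         paste(sprintf("%s:%.0f-%.0f", stray$contig, stray$start,
                       stray$end)[seq_len(min(5, nrow(stray)))],
               collapse = ", "))
  }
  classes <- list(
    exon = e,
    intron = iv_setdiff(g, e),
    intergenic = iv_complement(g, contig_lengths)
  )
  if (!is.null(repeats) && nrow(repeats) > 0L) {
    classes$repeat_ <- iv_merge(iv_frame(contig = repeats$contig,
                                         start = repeats$start,
                                         end = repeats$end))
  } else if (!is.null(repeats)) {
    classes$repeat_ <- iv_frame()
  }
  structure(list(classes = classes, contig_lengths = contig_lengths),
            class = "ElementAnnotation")
}

# Chop a merged interval frame at multiples of `window_bp`; adds a
# `window_start` column.
chop_windows <- function(iv, window_bp) {
  if (nrow(iv) == 0L) {
    return(cbind(iv_frame(), data.frame(window_start = numeric())))
  }
  pieces <- lapply(seq_len(nrow(iv)), function(i) {
    s <- iv$start[i]; e <- iv$end[i]
    cuts <- seq(floor(s / window_bp), floor((e - 1) / window_bp)) * window_bp
    data.frame(contig = iv$contig[i],
               start = pmax(s, cuts),
               end = pmin(e, cuts + window_bp),
               window_start = cuts, stringsAsFactors = FALSE)
  })
  do.call(rbind, pieces)
}

#' Windowed reference-based QV by element class and error type
#'
#' Differences between a query assembly and a reference (SNVs, insertions,
#' deletions in reference coordinates) are binned into non-overlapping
#' windows (default 100 kb) and, when an element annotation is supplied,
#' intersected with each element class. Within each window and class the
#' denominator is the aligned reference bp falling in that window and
#' class; the per-type numerators are substituted bp, inserted bp (an
#' insertion contributes its full length at its anchor coordinate) and
#' deleted bp (prorated across windows/classes by reference overlap). Each
#' QV is \eqn{-10\log_{10}(\mathrm{error\ bp}/\mathrm{aligned\ bp})}, with
#' zero errors reported at the cap. Windows with zero aligned bp in a class
#' are omitted.
#'
#' @param diffs Difference records (as from [parse_cs_diffs()] /
#'   [read_paf_diffs()]).
#' @param aligned Data frame (contig, start, end) of aligned reference
#'   intervals.
#' @param elements Optional [derive_elements()] annotation; when given,
#'   per-class rows are emitted in addition to the `whole` rows.
#' @param window_bp Window size in bp (default 100000).
#' @param cap QV reported for zero errors (default 60).
#' @return Data frame with one row per (class, contig, window): columns
#'   `class`, `contig`, `window_start`, `aligned_bp`, `snv_bp`, `ins_bp`,
#'   `del_bp`, `qv_total`, `qv_snv`, `qv_ins`, `qv_del`.
#' @export
window_qv <- function(diffs, aligned, elements = NULL, window_bp = 100000,
                      cap = 60) {
  if (window_bp <= 0) stop("window_bp must be > 0")
  aligned <- iv_merge(iv_frame(contig = aligned$contig, start = aligned$start,
                               end = aligned$end))
  class_ivs <- list(whole = aligned)
  if (!is.null(elements)) {
    for (cl in names(elements$classes)) {
      class_ivs[[cl]] <- iv_intersect(aligned, elements$classes[[cl]])
    }
  }
  out <- list()
  for (cl in names(class_ivs)) {
    region <- class_ivs[[cl]]
    pieces <- chop_windows(region, window_bp)
    if (nrow(pieces) == 0L) next
    key <- paste(pieces$contig, pieces$window_start)
    den <- tapply(pieces$end - pieces$start, key, sum)
    tab <- data.frame(contig = tapply(pieces$contig, key, `[`, 1L),
                      window_start = as.numeric(tapply(pieces$window_start, key, `[`, 1L)),
                      aligned_bp = as.numeric(den),
                      snv_bp = 0, ins_bp = 0, del_bp = 0,
                      stringsAsFactors = FALSE)
    rownames(tab) <- names(den)

    add <- function(tab, contig, win, col, amount) {
      k <- paste(contig, win)
      ok <- k %in% rownames(tab)
      agg <- tapply(amount[ok], k[ok], sum)
      tab[names(agg), col] <- tab[names(agg), col] + as.numeric(agg)
      tab
    }
    if (nrow(diffs) > 0L) {
      pts <- diffs[diffs$kind %in% c("snv", "ins"), , drop = FALSE]
      if (nrow(pts) > 0L) {
        inside <- iv_contains_points(region, pts$contig, pts$ref_start)
        pts <- pts[inside, , drop = FALSE]
        win <- floor(pts$ref_start / window_bp) * window_bp
        sn <- pts$kind == "snv"
        if (any(sn)) tab <- add(tab, pts$contig[sn], win[sn], "snv_bp",
                                pts$length[sn])
        if (any(!sn)) tab <- add(tab, pts$contig[!sn], win[!sn], "ins_bp",
                                 pts$length[!sn])
      }
      dels <- diffs[diffs$kind == "del", , drop = FALSE]
      if (nrow(dels) > 0L) {
        for (ct in unique(dels$contig)) {
          p <- pieces[pieces$contig == ct, , drop = FALSE]
          d <- dels[dels$contig == ct, , drop = FALSE]
          if (nrow(p) == 0L) next
          hits <- IRanges::findOverlaps(
            IRanges::IRanges(d$ref_start + 1L, d$ref_start + d$length),
            IRanges::IRanges(p$start + 1L, p$end))
          if (length(hits) == 0L) next
          qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
          ov <- pmin(d$ref_start[qi] + d$length[qi], p$end[si]) -
            pmax(d$ref_start[qi], p$start[si])
          tab <- add(tab, rep(ct, length(si)), p$window_start[si], "del_bp", ov)
        }
      }
    }
    err <- tab$snv_bp + tab$ins_bp + tab$del_bp
    tab$qv_total <- mapply(phred_qv, err, tab$aligned_bp, cap)
    tab$qv_snv <- mapply(phred_qv, tab$snv_bp, tab$aligned_bp, cap)
    tab$qv_ins <- mapply(phred_qv, tab$ins_bp, tab$aligned_bp, cap)
    tab$qv_del <- mapply(phred_qv, tab$del_bp, tab$aligned_bp, cap)
    tab <- cbind(class = cl, tab, stringsAsFactors = FALSE)
    out[[cl]] <- tab
  }
  res <- do.call(rbind, out)
  res <- res[order(res$class, res$contig, res$window_start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Aggregate windowed QV values
#'
#' Reports the pooled mean QV (Phred transform of total error bp over total
#' aligned bp), the median of the per-window QVs, and the QV value such
#' that `percentile` percent of windows fall below it (the "bottom
#' percentile" accuracy cutoff). Because errors cluster into few windows,
#' the median typically exceeds the pooled mean.
#'
#' @param windows Rows of a [window_qv()] table (usually one class).
#' @param percentile Lower percentile for the cutoff (default 10).
#' @param cap QV used for zero pooled errors (default 60).
#' @return A list: `n_windows`, `qv_pooled`, `qv_median`, `qv_percentile`,
#'   `percentile`.
#' @export
aggregate_qv <- function(windows, percentile = 10, cap = 60) {
  if (is.null(windows) || nrow(windows) == 0L) stop("no windows to aggregate")
  err <- sum(windows$snv_bp + windows$ins_bp + windows$del_bp)
  list(
    n_windows = nrow(windows),
    qv_pooled = phred_qv(err, sum(windows$aligned_bp), cap),
    qv_median = stats::median(windows$qv_total),
    qv_percentile = as.numeric(stats::quantile(windows$qv_total,
                                               percentile / 100, type = 1)),
    percentile = percentile
  )
}

#' Coding-indel impact summary
#'
#' Counts insertions and deletions whose reference anchor (insertions) or
#' reference span (deletions) intersects the coding intervals of queried
#' genes, and summarizes their size spectrum: how many genes carry at least
#' one indel, inserted/deleted bp totals, small (< `small_cutoff`) and
#' large (>= `large_cutoff`) counts per kind, and the share of all
#' differing bp contributed by large insertions.
#'
#' @param diffs Difference records; only `ins`/`del` rows are used.
#' @param coding Data frame (gene, contig, start, end) of coding intervals,
#'   0-based half-open; genes with no indel still count toward
#'   `n_genes_queried`.
#' @param small_cutoff Indels shorter than this are "small" (default 50 bp).
#' @param large_cutoff Insertions at least this long are "large"
#'   (default 100 bp).
#' @return An object of class `IndelImpactSummary` (list).
#' @export
indel_impact <- function(diffs, coding, small_cutoff = 50,
                         large_cutoff = 100) {
  genes <- unique(coding$gene)
  if (length(genes) == 0L) stop("no genes queried")
  ind <- diffs[diffs$kind %in% c("ins", "del"), , drop = FALSE]
  hit_genes <- character(0)
  keep <- logical(nrow(ind))
  if (nrow(ind) > 0L) {
    span_end <- ifelse(ind$kind == "del", ind$ref_start + ind$length,
                       ind$ref_start + 1)
    for (ct in unique(ind$contig)) {
      ci <- coding[coding$contig == ct, , drop = FALSE]
      di <- which(ind$contig == ct)
      if (nrow(ci) == 0L) next
      hits <- IRanges::findOverlaps(
        IRanges::IRanges(ind$ref_start[di] + 1L, span_end[di]),
        IRanges::IRanges(ci$start + 1L, ci$end))
      keep[di[unique(S4Vectors::queryHits(hits))]] <- TRUE
      hit_genes <- union(hit_genes, ci$gene[S4Vectors::subjectHits(hits)])
    }
  }
  ind <- ind[keep, , drop = FALSE]
  ins <- ind[ind$kind == "ins", , drop = FALSE]
  del <- ind[ind$kind == "del", , drop = FALSE]
  inserted_bp <- sum(ins$length); deleted_bp <- sum(del$length)
  large_ins_bp <- sum(ins$length[ins$length >= large_cutoff])
  total_diff_bp <- inserted_bp + deleted_bp
  structure(list(
    n_genes_queried = length(genes),
    n_genes_with_indel = length(hit_genes),
    pct_genes_with_indel = 100 * length(hit_genes) / length(genes),
    n_insertions = nrow(ins), n_deletions = nrow(del),
    inserted_bp = inserted_bp, deleted_bp = deleted_bp,
    n_small_insertions = sum(ins$length < small_cutoff),
    n_small_deletions = sum(del$length < small_cutoff),
    n_large_insertions = sum(ins$length >= large_cutoff),
    n_large_deletions = sum(del$length >= large_cutoff),
    pct_diff_bp_from_large_insertions =
      if (total_diff_bp > 0) 100 * large_ins_bp / total_diff_bp else 0
  ), class = "IndelImpactSummary")
}

#' @export
print.IndelImpactSummary <- function(x, ...) {
  cat(sprintf("%d insertions and %d deletions in %d of %d (%.2f%%) queried genes\n",
              x$n_insertions, x$n_deletions, x$n_genes_with_indel,
              x$n_genes_queried, x$pct_genes_with_indel))
  cat(sprintf("  %.0f inserted bp, %.0f deleted bp; large insertions carry %.1f%% of differing bp\n",
              x$inserted_bp, x$deleted_bp, x$pct_diff_bp_from_large_insertions))
  invisible(x)
}
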