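#' Summarize a BUSCO marker table
#'
#' Collapses per-placement rows to per-marker statuses and reports the
#' standard completeness breakdown: complete (C = single S + duplicated D),
#' fragmented (F) and missing (M) counts and percentages, plus the
#' duplication rate D / n_searched. A marker with two or more placements
#' counts once, as duplicated.
#'
#' @param table A [marker_table()].
#' @return An object of class `BuscoSummary` (list) with fields
#'   `n_searched`, `n_complete`, `n_single`, `n_duplicated`, `n_fragmented`,
#'   `n_missing`, matching `pct_*` percentages, and `duplication_rate_pct`.
#' @export
busco_summary <- function(table) {
  if (nrow(table) == 0L) stop("empty marker table")
  per_marker <- vapply(split(table$status, table$marker_id), function(st) {
    if (length(st) >= 2L || any(st == "duplicated")) "duplicated" else st[1]
  }, character(1))
  n <- length(per_marker)
  cnt <- function(s) sum(per_marker == s)
  s <- cnt("complete_single"); d <- cnt("duplicated")
  f <- cnt("fragmented"); m <- cnt("missing")
  structure(list(
    assembly_id = attr(table, "assembly_id"),
    n_searched = n,
    n_complete = s + d, n_single = s, n_duplicated = d,
    n_fragmented = f, n_missing = m,
    pct_complete = 100 * (s + d) / n,
    pct_single = 100 * s / n,
    pct_duplicated = 100 * d / n,
    pct_fragmented = 100 * f / n,
    pct_missing = 100 * m / n,
    duplication_rate_pct = 100 * d / n
  ), class = "BuscoSummary")
}

#' @export
print.BuscoSummary <- function(x, ...) {
  cat(sprintf("BUSCO summary (%s): C:%.1f%%[S:%.1f%%,D:%.1f%%],F:%.1f%%,M:%.1f%%,n:%d\n",
              x$assembly_id, x$pct_complete, x$pct_single, x$pct_duplicated,
              x$pct_fragmented, x$pct_missing, x$n_searched))
  invisible(x)
}

#' Haplotig-purging decision rule
#'
#' Returns `TRUE` when the BUSCO duplication rate strictly exceeds the
#' threshold (default 1%), i.e. when haplotig identification and removal
#' is warranted on the draft assembly. A rate exactly at the threshold does
#' not trigger purging.
#'
#' @param summary A [busco_summary()] result, or a bare numeric duplication
#'   rate in percent.
#' @param threshold_pct Duplication-rate threshold in percent (default 1).
#' @return Logical.
#' @export
purge_decision <- function(summary, threshold_pct = 1.0) {
  if (threshold_pct < 0) stop("threshold must be non-negative")
  rate <- if (inherits(summary, "BuscoSummary")) summary$duplication_rate_pct
          else as.numeric(summary)
  rate > threshold_pct
}
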