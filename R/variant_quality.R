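#' Variant-filter thresholds
#'
#' Defaults follow the standard consensus-quality workflow for long-read
#' variant calls: minimum read depth 10, minimum site quality 30 and (when
#' the caller reports it) minimum genotype quality 30. All comparisons are
#' inclusive (`>=`).
#'
#' @param min_depth Minimum read depth (default 10).
#' @param min_site_quality Minimum site QUAL (default 30).
#' @param min_genotype_quality Minimum GQ (default 30); applied only when a
#'   record carries a GQ.
#' @return A list of class `FilterThresholds`.
#' @export
filter_thresholds <- function(min_depth = 10, min_site_quality = 30,
                              min_genotype_quality = 30) {
  if (any(c(min_depth, min_site_quality, min_genotype_quality) < 0,
          na.rm = TRUE)) {
    stop("thresholds must be non-negative")
  }
  structure(list(min_depth = min_depth,
                 min_site_quality = min_site_quality,
                 min_genotype_quality = min_genotype_quality),
            class = "FilterThresholds")
}

#' Filter variant calls and count callable sites
#'
#' A variant row passes when its depth and site quality meet the thresholds
#' and its genotype quality, if present, does too (a variant with no
#' recorded depth or quality fails: it cannot be shown to be callable). A
#' banded invariant interval passes when each of its optional fields
#' (minimum depth, quality) that is present meets the corresponding
#' threshold; banded gVCF blocks often omit QUAL, and only the fields
#' actually present are required.
#'
#' The number of callable sites is the sum of the lengths of the passing
#' invariant intervals plus the number of distinct sites carrying a passing
#' variant. Overlapping callable intervals are normalized (merged) with a
#' warning. An optional exclusion interval set (e.g. repeat annotations)
#' removes both variants and callable positions before counting.
#'
#' @param variants Variant-record data frame as from
#'   [read_vcf_with_bands()].
#' @param callable_intervals Callable-interval data frame (contig, start,
#'   end, min_depth, quality), 0-based half-open.
#' @param thresholds A [filter_thresholds()].
#' @param exclude Optional data frame (contig, start, end) of regions to
#'   mask out (e.g. repeats).
#' @return A list with `variants` (kept rows), `callable` (passing, merged
#'   intervals) and `n_callable_sites`.
#' @export
filter_calls <- function(variants, callable_intervals,
                         thresholds = filter_thresholds(), exclude = NULL) {
  th <- thresholds
  v_pass <- !is.na(variants$depth) & variants$depth >= th$min_depth &
    !is.na(variants$site_quality) &
    variants$site_quality >= th$min_site_quality &
    (is.na(variants$genotype_quality) |
       is.null(th$min_genotype_quality) |
       variants$genotype_quality >= th$min_genotype_quality)
  kept <- variants[v_pass, , drop = FALSE]

  ci <- callable_intervals
  band_md <- if (is.null(ci$min_depth)) rep(NA_real_, nrow(ci)) else ci$min_depth
  band_q <- if (is.null(ci$quality)) rep(NA_real_, nrow(ci)) else ci$quality
  b_pass <- (is.na(band_md) | band_md >= th$min_depth) &
    (is.na(band_q) | band_q >= th$min_site_quality)
  bands <- ci[b_pass, c("contig", "start", "end"), drop = FALSE]
  if (nrow(bands) > 0L) {
    merged <- iv_merge(bands)
    if (iv_total_bp(bands) != sum(bands$end - bands$start)) {
      warning("overlapping callable intervals normalized by merging")
    }
    bands <- merged
  }

  if (!is.null(exclude) && nrow(exclude) > 0L) {
    ex <- iv_merge(iv_frame(contig = exclude$contig, start = exclude$start,
                            end = exclude$end))
    if (nrow(bands) > 0L) bands <- iv_setdiff(bands, ex)
    if (nrow(kept) > 0L) {
      kept <- kept[!iv_contains_points(ex, kept$contig, kept$pos), ,
                   drop = FALSE]
    }
  }

  n_var_sites <- if (nrow(kept) == 0L) 0L else {
    nrow(unique(kept[, c("contig", "pos")]))
  }
  n_callable <- iv_total_bp(bands) + n_var_sites
  list(variants = kept, callable = bands, n_callable_sites = n_callable)
}

#' Per-site heterozygosity and variant counts
#'
#' Heterozygosity is the number of heterozygous SNPs divided by the number
#' of callable sites; indels and homozygous variants are counted but do not
#' enter the numerator.
#'
#' @param variants Kept variant rows (after [filter_calls()]).
#' @param n_callable_sites Callable-site count from the same filtering.
#' @return An object of class `DiversityStats` (list): per-kind/genotype
#'   counts, `n_callable_sites`, `het_per_site` and `het_pct`.
#' @export
heterozygosity <- function(variants, n_callable_sites) {
  if (n_callable_sites <= 0) stop("n_callable_sites must be > 0")
  cnt <- function(k, g) sum(variants$kind == k & variants$genotype == g)
  h <- cnt("snp", "het")
  structure(list(
    n_het_snps = h,
    n_hom_snps = cnt("snp", "hom_alt"),
    n_het_indels = cnt("indel", "het"),
    n_hom_indels = cnt("indel", "hom_alt"),
    n_callable_sites = n_callable_sites,
    het_per_site = h / n_callable_sites,
    het_pct = 100 * h / n_callable_sites
  ), class = "DiversityStats")
}

# Shared Phred transform: p = 0 reports the cap.
phred_qv <- function(n_errors, n_sites, cap = 60) {
  p <- n_errors / n_sites
  if (p > 0) -10 * log10(p) else cap
}

#' Variant-based consensus quality (QV)
#'
#' Treats every site carrying at least one non-reference variant (SNP or
#' indel, heterozygous or homozygous) as an error in the consensus; the
#' error rate is that count divided by the number of callable sites, and
#' QV is the Phred transform \eqn{-10 \log_{10}(P_{error})}. With zero
#' errors the QV is reported at the cap (default 60).
#'
#' @param variants Kept variant rows (after [filter_calls()]).
#' @param n_callable_sites Callable-site count from the same filtering.
#' @param cap QV reported when no errors are observed (default 60).
#' @return An object of class `QVEstimate` (list): `n_error_sites`,
#'   `n_callable_sites`, `p_error`, `qv`, `cap`, `capped`.
#' @export
variant_qv <- function(variants, n_callable_sites, cap = 60) {
  if (n_callable_sites <= 0) stop("n_callable_sites must be > 0")
  n_err <- if (nrow(variants) == 0L) 0L else {
    nrow(unique(variants[, c("contig", "pos")]))
  }
  p <- n_err / n_callable_sites
  structure(list(
    n_error_sites = n_err,
    n_callable_sites = n_callable_sites,
    p_error = p,
    qv = phred_qv(n_err, n_callable_sites, cap),
    cap = cap,
    capped = p == 0
  ), class = "QVEstimate")
}

#' @export
print.QVEstimate <- function(x, ...) {
  cat(sprintf("QV %.2f%s (%d error sites / %.0f callable)\n", x$qv,
              if (x$capped) " (capped)" else "", x$n_error_sites,
              x$n_callable_sites))
  invisible(x)
}

#' @export
print.DiversityStats <- function(x, ...) {
  cat(sprintf("Heterozygosity %.3g per site (%.4g%%): %d het SNPs / %.0f callable sites\n",
              x$het_per_site, x$het_pct, x$n_het_snps, x$n_callable_sites))
  cat(sprintf("  hom SNPs %d, het indels %d, hom indels %d\n",
              x$n_hom_snps, x$n_het_indels, x$n_hom_indels))
  invisible(x)
}
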