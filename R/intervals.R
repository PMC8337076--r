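# Internal interval arithmetic on 0-based half-open intervals.
#
# Every public data structure in this package stores genomic intervals as
# data frames with columns (contig, start, end), 0-based half-open, the
# convention of BED and PAF. IRanges is 1-based closed; the conversion
# (start + 1, end) happens only inside these helpers so that the rest of
# the package never touches 1-based arithmetic.

iv_frame <- function(contig = character(), start = integer(), end = integer(), ...) {
  df <- data.frame(contig = as.character(contig),
                   start = as.numeric(start), end = as.numeric(end),
                   ..., stringsAsFactors = FALSE)
  bad <- df$end <= df$start
  if (any(bad)) {
    stop("invalid interval (end <= start): ", df$contig[bad][1], ":",
         df$start[bad][1], "-", df$end[bad][1])
  }
  df
}

.iv_to_ir <- function(df) {
  IRanges::IRanges(start = df$start + 1L, end = df$end)
}

.ir_to_iv <- function(ir, contig) {
  if (length(ir) == 0L) return(iv_frame())
  iv_frame(contig = contig, start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}

.iv_by_contig <- function(df) split(df, df$contig)

# Merge overlapping/adjacent intervals per contig; result sorted.
iv_merge <- function(df) {
  if (nrow(df) == 0L) return(iv_frame())
  pieces <- lapply(.iv_by_contig(df), function(d) {
    .ir_to_iv(IRanges::reduce(.iv_to_ir(d)), d$contig[1])
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out[order(out$contig, out$start), , drop = FALSE]
}

.iv_binop <- function(a, b, f) {
  contigs <- union(unique(a$contig), unique(b$contig))
  pieces <- lapply(contigs, function(ct) {
    ra <- .iv_to_ir(a[a$contig == ct, , drop = FALSE])
    rb <- .iv_to_ir(b[b$contig == ct, , drop = FALSE])
    .ir_to_iv(f(IRanges::reduce(ra), IRanges::reduce(rb)), ct)
  })
  out <- do.call(rbind, c(pieces, list(iv_frame())))
  rownames(out) <- NULL
  out[order(out$contig, out$start), , drop = FALSE]
}

iv_intersect <- function(a, b) .iv_binop(a, b, IRanges::intersect)

iv_setdiff <- function(a, b) .iv_binop(a, b, IRanges::setdiff)

iv_total_bp <- function(df) {
  if (nrow(df) == 0L) return(0)
  sum(iv_merge(df)$end - iv_merge(df)$start)
}

# Complement of `df` within contigs of the given lengths (named vector).
iv_complement <- function(df, contig_lengths) {
  whole <- iv_frame(contig = names(contig_lengths), start = 0,
                    end = as.numeric(contig_lengths))
  iv_setdiff(whole, df)
}

# For each point (contig, pos) return TRUE if it lies inside the merged
# interval set.
iv_contains_points <- function(df, contig, pos) {
  if (length(contig) == 0L) return(logical(0))
  m <- iv_merge(df)
  out <- logical(length(contig))
  for (ct in unique(contig)) {
    sel <- contig == ct
    d <- m[m$contig == ct, , drop = FALSE]
    if (nrow(d) == 0L) { out[sel] <- FALSE; next }
    hit <- IRanges::overlapsAny(
      IRanges::IRanges(start = pos[sel] + 1L, width = 1L), .iv_to_ir(d))
    out[sel] <- hit
  }
  out
}

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's
# RNG state afterwards. All stochastic operations in the package go through
# this so that results are pure functions of their arguments.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-seed derivation: master seed plus a small component
# index, kept inside 32-bit integer range.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1000 + k) %% .Machine$integer.max)
}
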