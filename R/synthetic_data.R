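#' Specification for simulated multi-species marker genomes
#'
#' Describes the structure the marker-adjacency analyses assume: a fixed
#' number of chromosome arms whose marker (gene) content is conserved
#' across species while marker order is shuffled within arms by
#' inversions, with optional rare cross-arm translocations, and each
#' species' genome fragmented into contigs.
#'
#' @param n_species Number of species (assemblies) to simulate.
#' @param n_arms Number of chromosome arms.
#' @param markers_per_arm Markers per arm (>= 2).
#' @param inversions_per_species Number of within-arm block reversals
#'   applied to each species.
#' @param translocation_rate Probability per species of one cross-arm
#'   marker move (default 0).
#' @param contig_markers_mean Mean number of markers per contig for the
#'   geometric fragmentation process (>= 1).
#' @param seed Master RNG seed.
#' @return A list of class `MarkerGenomeSpec`.
#' @export
marker_genome_spec <- function(n_species, n_arms, markers_per_arm,
                               inversions_per_species = 0,
                               translocation_rate = 0,
                               contig_markers_mean = 10, seed = 1) {
  if (markers_per_arm < 2) stop("markers_per_arm must be >= 2")
  if (contig_markers_mean < 1) stop("contig_markers_mean must be >= 1")
  if (translocation_rate < 0 || translocation_rate > 1) {
    stop("translocation_rate must be a probability")
  }
  structure(list(n_species = n_species, n_arms = n_arms,
                 markers_per_arm = markers_per_arm,
                 inversions_per_species = inversions_per_species,
                 translocation_rate = translocation_rate,
                 contig_markers_mean = contig_markers_mean, seed = seed),
            class = "MarkerGenomeSpec")
}

#' Simulate marker tables for a set of species
#'
#' Each species starts from the shared ancestral marker order per arm,
#' receives `inversions_per_species` random block reversals (block
#' endpoints uniform over within-arm pairs, so blocks have length >= 2),
#' optionally one cross-arm marker move with probability
#' `translocation_rate`, and is then fragmented into contigs whose marker
#' counts are 1 + Geometric, with the stated mean. Contigs never span arms
#' when the translocation rate is 0. All markers are emitted as complete
#' single-copy with synthetic coordinates.
#'
#' Per-species RNG streams are derived deterministically from the master
#' seed (seed * 1000 + species index, mod 2^31), so any species' table is
#' reproducible in isolation.
#'
#' @param spec A [marker_genome_spec()].
#' @return A list: `tables` (list of [marker_table()], one per species) and
#'   `truth` (list with `arm_of_marker`, a named integer vector, and the
#'   spec).
#' @export
sim_marker_assemblies <- function(spec) {
  n_markers <- spec$n_arms * spec$markers_per_arm
  marker_ids <- sprintf("%dat7147", seq_len(n_markers))
  arm_of_marker <- rep(seq_len(spec$n_arms), each = spec$markers_per_arm)
  names(arm_of_marker) <- marker_ids
  ancestral <- split(seq_len(n_markers), arm_of_marker)

  tables <- lapply(seq_len(spec$n_species), function(sp) {
    with_seed(derive_seed(spec$seed, sp), {
      arms <- ancestral
      for (k in seq_len(spec$inversions_per_species)) {
        a <- sample.int(spec$n_arms, 1)
        m <- length(arms[[a]])
        st <- sort(sample.int(m, 2))
        arms[[a]][st[1]:st[2]] <- rev(arms[[a]][st[1]:st[2]])
      }
      if (spec$translocation_rate > 0 &&
          stats::runif(1) < spec$translocation_rate && spec$n_arms > 1) {
        src <- sample.int(spec$n_arms, 1)
        if (length(arms[[src]]) > 2) {
          i <- sample.int(length(arms[[src]]), 1)
          mk <- arms[[src]][i]
          arms[[src]] <- arms[[src]][-i]
          dst <- sample(setdiff(seq_len(spec$n_arms), src), 1)
          j <- sample.int(length(arms[[dst]]) + 1L, 1)
          arms[[dst]] <- append(arms[[dst]], mk, after = j - 1L)
        }
      }
      rows <- list(); contig_no <- 0L
      for (a in seq_len(spec$n_arms)) {
        ord <- arms[[a]]
        i <- 1L
        while (i <= length(ord)) {
          size <- 1L + stats::rgeom(1, 1 / spec$contig_markers_mean)
          size <- min(size, length(ord) - i + 1L)
          contig_no <- contig_no + 1L
          idx <- ord[i:(i + size - 1L)]
          rows[[length(rows) + 1L]] <- data.frame(
            marker_id = marker_ids[idx],
            contig = sprintf("s%03d_c%04d", sp, contig_no),
            start = (seq_along(idx) - 1) * 5000,
            end = (seq_along(idx) - 1) * 5000 + 2000,
            strand = sample(c("+", "-"), length(idx), replace = TRUE),
            stringsAsFactors = FALSE)
          i <- i + size
        }
      }
      df <- do.call(rbind, rows)
      marker_table(df$marker_id, "complete_single", df$contig, df$start,
                   df$end, df$strand,
                   assembly_id = sprintf("species%03d", sp))
    })
  })
  list(tables = tables,
       truth = list(arm_of_marker = arm_of_marker, spec = spec))
}

#' Simulate filtered variant calls over a callable region
#'
#' Each of `n_callable` sites on one contig is independently a
#' heterozygous SNP with probability `het_rate` and a homozygous-alternate
#' SNP with probability `hom_rate`. Emitted variant records carry DP 30,
#' QUAL 50, GQ 50, so all pass the default filters; a
#' `contamination_fraction` > 0 adds that fraction of sites as
#' sub-threshold records (DP 5, QUAL 10, GQ 10) which default filtering
#' must remove. Invariant sites are emitted as banded callable intervals
#' (min_depth 30, quality 50).
#'
#' @param n_callable Number of sites simulated.
#' @param het_rate,hom_rate Per-site probabilities.
#' @param seed RNG seed.
#' @param contamination_fraction Fraction of sites emitted as sub-threshold
#'   variant records (default 0).
#' @param contig Contig name (default "chr1").
#' @return A list: `variants`, `callable` (both in the
#'   [read_vcf_with_bands()] schemas) and `truth` (rates, expected callable
#'   count after default filtering).
#' @export
sim_variant_calls <- function(n_callable, het_rate, hom_rate, seed,
                              contamination_fraction = 0, contig = "chr1") {
  stopifnot(het_rate >= 0, hom_rate >= 0, het_rate + hom_rate <= 1)
  with_seed(seed, {
    n_het <- stats::rbinom(1, n_callable, het_rate)
    n_hom <- stats::rbinom(1, n_callable, hom_rate)
    n_bad <- round(contamination_fraction * n_callable)
    n_var <- n_het + n_hom + n_bad
    pos <- if (n_var > 0) sort(sample.int(n_callable, n_var)) - 1 else numeric(0)
    lab <- rep(c("het", "hom", "bad"),
               times = c(n_het, n_hom, n_bad))[sample.int(max(n_var, 1))[seq_len(n_var)]]
    variants <- data.frame(
      contig = rep(contig, n_var), pos = pos,
      kind = rep("snp", n_var),
      genotype = ifelse(lab == "hom", "hom_alt", "het"),
      site_quality = ifelse(lab == "bad", 10, 50),
      depth = ifelse(lab == "bad", 5, 30),
      genotype_quality = ifelse(lab == "bad", 10, 50),
      stringsAsFactors = FALSE)
    # invariant-site bands: maximal runs between variant positions
    bounds <- c(-1, pos, n_callable)
    starts <- utils::head(bounds, -1) + 1
    ends <- utils::tail(bounds, -1)
    keep <- ends > starts
    callable <- data.frame(contig = contig, start = starts[keep],
                           end = ends[keep], min_depth = 30, quality = 50,
                           stringsAsFactors = FALSE)
    list(variants = variants, callable = callable,
         truth = list(het_rate = het_rate, hom_rate = hom_rate,
                      n_sites = n_callable,
                      n_het = n_het, n_hom = n_hom,
                      n_callable_expected = n_callable - n_bad))
  })
}

# Indel length mixture: 90% uniform on 1-3 bp, 10% geometric tail.
.sim_indel_lengths <- function(n, p_small = 0.9, tail_p = 0.3) {
  small <- stats::runif(n) < p_small
  len <- integer(n)
  len[small] <- sample(1:3, sum(small), replace = TRUE)
  len[!small] <- 4L + stats::rgeom(sum(!small), tail_p)
  len
}

#' Simulate reference-alignment differences with an element annotation
#'
#' Builds one reference contig partitioned into exon, intron and
#' intergenic segments (segments of `segment_bp`, shuffled, achieving the
#' requested bp per class), plus optional repeat intervals overlaid on
#' intergenic sequence, then places SNV/insertion/deletion differences as
#' a Poisson process per class at the stated per-bp rates. Indel lengths
#' follow a 90% 1-3 bp / 10% geometric-tail mixture.
#'
#' @param element_bp Named numeric: bp of `exon`, `intron`, `intergenic`.
#' @param error_rates Named list per class, each a list with per-bp rates
#'   `snv`, `ins`, `del` (missing entries = 0).
#' @param seed RNG seed.
#' @param repeat_fraction Fraction of intergenic bp overlaid as repeat
#'   (default 0).
#' @param segment_bp Segment granularity of the partition (default 10 kb).
#' @param contig Contig name.
#' @return A list: `diffs`, `aligned` (whole-contig interval), `elements`
#'   (a [derive_elements()] annotation), `genes`/`exons`/`repeats` interval
#'   frames, and `truth` (rates and realized class bp).
#' @export
sim_alignment_diffs <- function(element_bp, error_rates, seed,
                                repeat_fraction = 0, segment_bp = 10000,
                                contig = "chrS") {
  stopifnot(all(names(element_bp) %in% c("exon", "intron", "intergenic")))
  with_seed(seed, {
    segs <- list()
    for (cl in names(element_bp)) {
      bp <- element_bp[[cl]]
      if (bp <= 0) next
      n_full <- floor(bp / segment_bp)
      lens <- c(rep(segment_bp, n_full),
                if (bp - n_full * segment_bp > 0) bp - n_full * segment_bp)
      segs[[cl]] <- lens
    }
    seg_class <- rep(names(segs), times = vapply(segs, length, integer(1)))
    seg_len <- unlist(segs, use.names = FALSE)
    ord <- sample.int(length(seg_len))
    seg_class <- seg_class[ord]; seg_len <- seg_len[ord]
    seg_end <- cumsum(seg_len); seg_start <- seg_end - seg_len
    contig_len <- sum(seg_len)
    class_iv <- lapply(c("exon", "intron", "intergenic"), function(cl) {
      sel <- seg_class == cl
      if (!any(sel)) return(iv_frame())
      iv_merge(iv_frame(contig = contig, start = seg_start[sel],
                        end = seg_end[sel]))
    })
    names(class_iv) <- c("exon", "intron", "intergenic")
    genes <- iv_merge(rbind(class_iv$exon, class_iv$intron))
    repeats <- iv_frame()
    if (repeat_fraction > 0 && nrow(class_iv$intergenic) > 0L) {
      ig <- class_iv$intergenic
      rep_rows <- lapply(seq_len(nrow(ig)), function(i) {
        w <- (ig$end[i] - ig$start[i]) * repeat_fraction
        if (w < 1) return(NULL)
        data.frame(contig = contig, start = ig$start[i],
                   end = ig$start[i] + floor(w), stringsAsFactors = FALSE)
      })
      repeats <- do.call(rbind, c(rep_rows, list(iv_frame())))
    }

    place <- function(cl, kind, rate) {
      iv <- class_iv[[cl]]
      bp <- sum(iv$end - iv$start)
      if (bp == 0 || rate <= 0) return(NULL)
      n <- stats::rpois(1, rate * bp)
      if (n == 0) return(NULL)
      off <- sort(sample.int(bp, n, replace = FALSE)) - 1
      cum <- cumsum(iv$end - iv$start)
      i <- findInterval(off, c(0, utils::head(cum, -1) + 0), rightmost.closed = FALSE)
      gpos <- iv$start[i] + (off - c(0, utils::head(cum, -1))[i])
      len <- if (kind == "snv") rep(1L, n) else .sim_indel_lengths(n)
      data.frame(contig = contig, ref_start = gpos, kind = kind,
                 length = as.numeric(len),
                 ref_allele = ifelse(kind == "snv", "a", NA),
                 alt_allele = ifelse(kind == "snv", "t", NA),
                 stringsAsFactors = FALSE)
    }
    diffs <- list()
    for (cl in names(error_rates)) {
      for (kind in c("snv", "ins", "del")) {
        r <- error_rates[[cl]][[kind]]
        if (!is.null(r)) diffs[[paste(cl, kind)]] <- place(cl, kind, r)
      }
    }
    diffs <- do.call(rbind, c(diffs, list(.empty_diffs())))
    diffs <- diffs[order(diffs$contig, diffs$ref_start), , drop = FALSE]
    rownames(diffs) <- NULL
    contig_lengths <- stats::setNames(contig_len, contig)
    elements <- derive_elements(genes, class_iv$exon,
                                repeats = if (nrow(repeats)) repeats else NULL,
                                contig_lengths)
    list(diffs = diffs,
         aligned = iv_frame(contig = contig, start = 0, end = contig_len),
         elements = elements, genes = genes, exons = class_iv$exon,
         repeats = repeats,
         truth = list(error_rates = error_rates,
                      class_bp = vapply(class_iv, function(v)
                        sum(v$end - v$start), numeric(1)),
                      contig_len = contig_len))
  })
}

#' Simulate a long-read length set and a depth track
#'
#' Read lengths are lognormal with the log-scale mean chosen so the
#' length-weighted median (read N50) matches the target; after drawing,
#' lengths are rescaled by target/realized-N50, guaranteeing the realized
#' read N50 is within 10% of target. Reads are accumulated until total
#' bases first reach `genome_size * mean_depth`. The depth track covers
#' `track_bp` positions of one contig, with per-position depth either
#' Poisson(`mean_depth`) or exactly `mean_depth` (exact-uniform mode).
#'
#' @param genome_size True genome size (bp).
#' @param mean_depth Target mean depth of coverage.
#' @param length_N50_target Target read N50 (bp).
#' @param seed RNG seed.
#' @param depth_mode `"poisson"` (default) or `"exact"`.
#' @param track_bp Positions in the depth track (default
#'   `min(genome_size, 2e5)`).
#' @param sdlog Lognormal shape parameter (default 0.55, a typical
#'   long-read spread).
#' @return A list: `read_lengths`, `depth` (a [depth_track()]) and `truth`
#'   (genome size, depth, N50 target, total bases).
#' @export
sim_reads_and_depth <- function(genome_size, mean_depth, length_N50_target,
                                seed, depth_mode = c("poisson", "exact"),
                                track_bp = min(genome_size, 200000),
                                sdlog = 0.55) {
  depth_mode <- match.arg(depth_mode)
  with_seed(seed, {
    target_bp <- genome_size * mean_depth
    meanlog <- log(length_N50_target) - sdlog^2
    mean_len <- exp(meanlog + sdlog^2 / 2)
    n_draw <- max(100L, ceiling(1.3 * target_bp / mean_len))
    pool <- stats::rlnorm(n_draw, meanlog, sdlog)
    pool <- pool * (length_N50_target / read_stats(pool)$read_N50_bp)
    pool <- pmax(1, round(pool))
    while (sum(pool) < target_bp) {
      extra <- stats::rlnorm(n_draw, meanlog, sdlog)
      pool <- c(pool, pmax(1, round(extra)))
    }
    k <- which(cumsum(pool) >= target_bp)[1]
    lengths <- pool[seq_len(k)]
    depth_vals <- if (depth_mode == "exact") rep(round(mean_depth), track_bp)
                  else stats::rpois(track_bp, mean_depth)
    track <- depth_track(rep("chr1", track_bp), seq_len(track_bp) - 1,
                         depth_vals)
    list(read_lengths = lengths, depth = track,
         truth = list(genome_size = genome_size, mean_depth = mean_depth,
                      length_N50_target = length_N50_target,
                      total_bases = sum(lengths)))
  })
}

#' Simulate a repeat annotation with target class proportions
#'
#' Tiles each contig into `tile_bp` tiles and assigns a seeded random
#' subset of tiles to each repeat class so the realized per-class
#' proportion is within one tile of the target (well under 1% at default
#' granularity). Adjacent same-class tiles are merged into single records;
#' classes never overlap.
#'
#' @param contig_lengths Named numeric vector of contig lengths (bp).
#' @param class_proportions Named numeric vector of target fractions per
#'   repeat class; must sum to <= 1.
#' @param seed RNG seed.
#' @param tile_bp Tile granularity (default 1000).
#' @return A data frame of repeat records (contig, start, end, repeat_name,
#'   repeat_class).
#' @export
sim_repeat_annotation <- function(contig_lengths, class_proportions, seed,
                                  tile_bp = 1000) {
  if (sum(class_proportions) > 1 + 1e-9) stop("proportions must sum to <= 1")
  with_seed(seed, {
    out <- list()
    for (ct in names(contig_lengths)) {
      len <- contig_lengths[[ct]]
      n_tiles <- floor(len / tile_bp)
      targets <- round(class_proportions * len / tile_bp)
      if (sum(targets) > n_tiles) stop("proportions exceed contig capacity")
      if (sum(targets) == 0) next
      tiles <- sample.int(n_tiles, sum(targets))
      cls <- rep(names(class_proportions), times = targets)
      for (cl in unique(cls)) {
        t_cl <- sort(tiles[cls == cl])
        if (length(t_cl) == 0L) next
        brk <- c(0, which(diff(t_cl) > 1), length(t_cl))
        for (j in seq_len(length(brk) - 1L)) {
          run <- t_cl[(brk[j] + 1L):brk[j + 1L]]
          out[[length(out) + 1L]] <- data.frame(
            contig = ct, start = (run[1] - 1) * tile_bp,
            end = run[length(run)] * tile_bp,
            repeat_name = paste0(cl, "_sim"), repeat_class = cl,
            stringsAsFactors = FALSE)
        }
      }
    }
    df <- do.call(rbind, c(out, list(
      data.frame(contig = character(), start = numeric(), end = numeric(),
                 repeat_name = character(), repeat_class = character(),
                 stringsAsFactors = FALSE))))
    rownames(df) <- NULL
    df[order(df$contig, df$start), , drop = FALSE]
  })
}
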