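#' Construct a contig set
#'
#' A `ContigSet` holds the named contig lengths (optionally the sequences)
#' of one assembly. It is the input of every contiguity statistic, where the
#' contig lengths play the role of the `L_i` in the auN definition.
#'
#' @param name Character vector of contig names (unique within an assembly).
#' @param length Numeric vector of contig lengths in bp (all >= 1).
#' @param sequence Optional character vector of sequences; when present,
#'   `nchar(sequence)` must equal `length`.
#' @param assembly_id Identifier for the assembly.
#' @return An object of class `ContigSet`: a data frame with columns
#'   `name`, `length` (and `sequence` when kept) plus an `assembly_id`
#'   attribute.
#' @export
contig_set <- function(name, length, sequence = NULL, assembly_id = "assembly") {
  name <- as.character(name)
  if (length(name) == 0L) stop("a ContigSet needs at least one contig")
  dup <- name[duplicated(name)]
  if (length(dup) > 0L) stop("duplicate contig name: ", dup[1])
  length <- as.numeric(length)
  if (any(length < 1)) stop("contig lengths must be >= 1")
  df <- data.frame(name = name, length = length, stringsAsFactors = FALSE)
  if (!is.null(sequence)) {
    if (any(nchar(sequence) != length)) {
      stop("sequence length disagrees with declared contig length")
    }
    df$sequence <- as.character(sequence)
  }
  attr(df, "assembly_id") <- assembly_id
  class(df) <- c("ContigSet", "data.frame")
  df
}

#' Read contig names and lengths from a FASTA file
#'
#' Headers are tokenized at the first whitespace; records appear in file
#' order. Characters outside the IUPAC nucleotide alphabet are tolerated
#' with a warning reporting their count.
#'
#' @param path Path to a FASTA file.
#' @param keep_sequences Keep the sequences themselves (default `FALSE`,
#'   lengths only).
#' @param assembly_id Assembly identifier; defaults to the file name without
#'   extension.
#' @return A [contig_set()].
#' @export
read_fasta_lengths <- function(path, keep_sequences = FALSE,
                               assembly_id = tools::file_path_sans_ext(basename(path))) {
  if (!file.exists(path)) stop("no such file: ", path)
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA file: ", path)
  nm <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1L)
  dup <- nm[duplicated(nm)]
  if (length(dup) > 0L) stop("duplicate contig name: ", dup[1])
  txt <- as.character(seqs)
  n_bad <- sum(vapply(txt, function(s) {
    nchar(gsub("[ACGTUMRWSYKVHDBNacgtumrwsykvhdbn-]", "", s))
  }, integer(1)))
  if (n_bad > 0L) {
    warning(n_bad, " non-IUPAC character(s) in ", path)
  }
  contig_set(nm, nchar(txt),
             sequence = if (keep_sequences) unname(txt) else NULL,
             assembly_id = assembly_id)
}

#' Write a contig set with sequences to FASTA
#'
#' @param contigs A [contig_set()] carrying sequences.
#' @param path Output path.
#' @export
write_fasta <- function(contigs, path) {
  if (is.null(contigs$sequence)) stop("ContigSet carries no sequences")
  x <- Biostrings::BStringSet(contigs$sequence)
  names(x) <- contigs$name
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

.marker_statuses <- c("complete_single", "duplicated", "fragmented", "missing")

#' Construct a marker table
#'
#' A `MarkerTable` holds the per-assembly single-copy ortholog (BUSCO)
#' annotations: one row per placement, with 0-based half-open coordinates.
#' A `missing` marker has no location; a `duplicated` marker has one row per
#' placement.
#'
#' @param marker_id,status,contig,start,end,strand Column vectors; `status`
#'   one of `complete_single`, `duplicated`, `fragmented`, `missing`.
#' @param assembly_id Identifier for the assembly the table describes.
#' @return An object of class `MarkerTable` (data frame).
#' @export
marker_table <- function(marker_id, status, contig = NA_character_,
                         start = NA_real_, end = NA_real_,
                         strand = NA_character_, assembly_id = "assembly") {
  status <- as.character(status)
  bad <- setdiff(unique(status), .marker_statuses)
  if (length(bad) > 0L) stop("unknown marker status: ", bad[1])
  df <- data.frame(marker_id = as.character(marker_id), status = status,
                   contig = as.character(contig), start = as.numeric(start),
                   end = as.numeric(end), strand = as.character(strand),
                   stringsAsFactors = FALSE)
  miss <- df$status == "missing"
  if (any(miss & !is.na(df$contig))) stop("missing marker must have no contig")
  if (any(!miss & is.na(df$contig))) stop("placed marker must name a contig")
  located <- !is.na(df$start) & !is.na(df$end)
  if (any(located & df$end <= df$start)) {
    i <- which(located & df$end <= df$start)[1]
    stop("marker interval has end <= start: ", df$marker_id[i])
  }
  attr(df, "assembly_id") <- assembly_id
  class(df) <- c("MarkerTable", "data.frame")
  df
}

#' Read a BUSCO v4 full-table TSV
#'
#' Lines starting with `#` are comments. Statuses are mapped to the internal
#' vocabulary (`Complete` -> `complete_single`, `Duplicated`, `Fragmented`,
#' `Missing`); 1-based inclusive coordinates become 0-based half-open.
#' Duplicated markers yield one row per placement.
#'
#' @param path Path to a `full_table.tsv`.
#' @param assembly_id Assembly identifier; defaults to the file name.
#' @return A [marker_table()].
#' @export
read_busco_table <- function(path,
                             assembly_id = tools::file_path_sans_ext(basename(path))) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  status_map <- c(Complete = "complete_single", Duplicated = "duplicated",
                  Fragmented = "fragmented", Missing = "missing")
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 2L) stop("malformed BUSCO row at line ", i)
    st <- status_map[f[2]]
    if (is.na(st)) stop("unknown status token: ", f[2])
    if (st == "missing" || length(f) < 5L || !nzchar(f[3])) {
      return(data.frame(marker_id = f[1], status = unname(st),
                        contig = NA_character_, start = NA_real_,
                        end = NA_real_, strand = NA_character_,
                        stringsAsFactors = FALSE))
    }
    s1 <- as.numeric(f[4]); e1 <- as.numeric(f[5])
    s0 <- s1 - 1; e0 <- e1
    if (e0 <= s0) stop("marker interval has end <= start: ", f[1])
    data.frame(marker_id = f[1], status = unname(st), contig = f[3],
               start = s0, end = e0,
               strand = if (length(f) >= 6L && f[6] %in% c("+", "-")) f[6] else NA_character_,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  marker_table(df$marker_id, df$status, df$contig, df$start, df$end,
               df$strand, assembly_id = assembly_id)
}

#' Write a marker table in BUSCO full-table layout
#'
#' Internal 0-based half-open coordinates are converted back to the 1-based
#' inclusive file convention; [read_busco_table()] round-trips the result.
#'
#' @param table A [marker_table()].
#' @param path Output path.
#' @export
write_busco_table <- function(table, path) {
  status_map <- c(complete_single = "Complete", duplicated = "Duplicated",
                  fragmented = "Fragmented", missing = "Missing")
  lines <- c("# Busco id\tStatus\tSequence\tGene Start\tGene End\tStrand")
  for (i in seq_len(nrow(table))) {
    r <- table[i, ]
    if (r$status == "missing") {
      lines <- c(lines, paste(r$marker_id, status_map[r$status], sep = "\t"))
    } else {
      lines <- c(lines, paste(r$marker_id, status_map[r$status], r$contig,
                              format(r$start + 1, scientific = FALSE),
                              format(r$end, scientific = FALSE),
                              ifelse(is.na(r$strand), "+", r$strand),
                              sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a VCF, separating variant rows from banded invariant blocks
#'
#' Consumes VCF 4.x including banded gVCF records: a record carrying
#' `INFO/END` (and typically a symbolic non-ref ALT) at 1-based `POS` with
#' `END = e` describes the invariant block `[POS-1, e)` in 0-based half-open
#' coordinates. Non-banded reference-call rows (genotype `0/0` with no real
#' ALT) become length-1 intervals. Variant rows are classified `snp` vs
#' `indel` (indel if any called ALT differs in length from REF) and `het`
#' vs `hom_alt` (het if the two called alleles differ). `DP`/`GQ`/`MIN_DP`
#' are taken from the first sample's FORMAT fields.
#'
#' @param path Path to an uncompressed VCF/gVCF.
#' @return A list with `variants` (data frame: contig, pos (0-based), kind,
#'   genotype, site_quality, depth, genotype_quality) and `callable`
#'   (data frame: contig, start, end, min_depth, quality).
#' @export
read_vcf_with_bands <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  variants <- list(); bands <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 8L) stop("malformed VCF row at line ", i)
    contig <- f[1]; pos1 <- as.numeric(f[2]); ref <- f[4]; alt <- f[5]
    qual <- suppressWarnings(as.numeric(f[6]))
    info <- f[8]
    fmt <- if (length(f) >= 10L) strsplit(f[9], ":", fixed = TRUE)[[1]] else character(0)
    smp <- if (length(f) >= 10L) strsplit(f[10], ":", fixed = TRUE)[[1]] else character(0)
    fval <- function(key) {
      j <- match(key, fmt)
      if (is.na(j) || j > length(smp) || smp[j] == ".") NA_real_
      else suppressWarnings(as.numeric(smp[j]))
    }
    end_m <- regmatches(info, regexpr("(?:^|;)END=([0-9]+)", info))
    has_end <- length(end_m) == 1L
    alts <- strsplit(alt, ",", fixed = TRUE)[[1]]
    real_alts <- alts[!alts %in% c(".", "<NON_REF>", "<*>")]
    gt <- {
      j <- match("GT", fmt)
      if (is.na(j) || j > length(smp)) NA_character_ else smp[j]
    }
    alleles <- if (is.na(gt)) integer(0) else {
      a <- strsplit(gt, "[/|]")[[1]]
      suppressWarnings(as.integer(a[a != "."]))
    }
    is_variant_call <- length(real_alts) > 0L && any(alleles > 0L, na.rm = TRUE)

    if (has_end) {
      e <- as.numeric(sub(".*END=", "", end_m))
      if (e < pos1) stop("END < POS at line ", i)
      bands[[length(bands) + 1L]] <- data.frame(
        contig = contig, start = pos1 - 1, end = e,
        min_depth = { md <- fval("MIN_DP"); if (is.na(md)) fval("DP") else md },
        quality = qual, stringsAsFactors = FALSE)
    } else if (!is_variant_call) {
      bands[[length(bands) + 1L]] <- data.frame(
        contig = contig, start = pos1 - 1, end = pos1,
        min_depth = fval("DP"), quality = qual, stringsAsFactors = FALSE)
    } else {
      kind <- if (any(nchar(real_alts) != nchar(ref))) "indel" else "snp"
      genotype <- if (length(alleles) >= 2L && length(unique(alleles)) > 1L)
        "het" else "hom_alt"
      variants[[length(variants) + 1L]] <- data.frame(
        contig = contig, pos = pos1 - 1, kind = kind, genotype = genotype,
        site_quality = qual, depth = fval("DP"),
        genotype_quality = fval("GQ"), stringsAsFactors = FALSE)
    }
  }
  empty_var <- data.frame(contig = character(), pos = numeric(),
                          kind = character(), genotype = character(),
                          site_quality = numeric(), depth = numeric(),
                          genotype_quality = numeric(), stringsAsFactors = FALSE)
  empty_band <- data.frame(contig = character(), start = numeric(),
                           end = numeric(), min_depth = numeric(),
                           quality = numeric(), stringsAsFactors = FALSE)
  list(variants = if (length(variants)) do.call(rbind, variants) else empty_var,
       callable = if (length(bands)) do.call(rbind, bands) else empty_band)
}

.empty_diffs <- function() {
  data.frame(contig = character(), ref_start = numeric(), kind = character(),
             length = numeric(), ref_allele = character(),
             alt_allele = character(), stringsAsFactors = FALSE)
}

#' Parse a minimap2 cs difference string into unit difference records
#'
#' Accepts the short form (`:` match length, `*xy` substitution, `+seq`
#' insertion, `-seq` deletion) and the long form (`=SEQ` match). The
#' reference cursor advances over matches, substitutions and deletions;
#' insertions are anchored at the current reference coordinate and consume
#' no reference bp. Runs of substitutions are split into unit SNV records.
#'
#' @param contig Reference contig name.
#' @param ref_start 0-based reference coordinate where the alignment starts.
#' @param cs The cs tag payload (without the `cs:Z:` prefix).
#' @return A data frame of difference records (contig, ref_start, kind in
#'   snv/ins/del, length, ref_allele, alt_allele) sorted by `ref_start`,
#'   with attribute `ref_span` giving the reference bp consumed.
#' @export
parse_cs_diffs <- function(contig, ref_start, cs) {
  stopifnot(length(cs) == 1L)
  pat <- "(:[0-9]+)|(=[A-Za-z]+)|(\\*[A-Za-z][A-Za-z])|(\\+[A-Za-z]+)|(-[A-Za-z]+)"
  m <- gregexpr(pat, cs)[[1]]
  toks <- regmatches(cs, gregexpr(pat, cs))[[1]]
  # Detect malformed input: tokens must tile the string with no gaps.
  cursor_txt <- 1L
  for (j in seq_along(toks)) {
    if (m[j] != cursor_txt) stop("malformed cs string at byte offset ", cursor_txt)
    cursor_txt <- cursor_txt + attr(m, "match.length")[j]
  }
  if (cursor_txt != nchar(cs) + 1L) {
    stop("malformed cs string at byte offset ", cursor_txt)
  }
  out <- list(); pos <- ref_start
  for (tok in toks) {
    op <- substr(tok, 1L, 1L)
    body <- substr(tok, 2L, nchar(tok))
    if (op == ":") {
      pos <- pos + as.numeric(body)
    } else if (op == "=") {
      pos <- pos + nchar(body)
    } else if (op == "*") {
      out[[length(out) + 1L]] <- data.frame(
        contig = contig, ref_start = pos, kind = "snv", length = 1,
        ref_allele = substr(body, 1L, 1L), alt_allele = substr(body, 2L, 2L),
        stringsAsFactors = FALSE)
      pos <- pos + 1
    } else if (op == "+") {
      out[[length(out) + 1L]] <- data.frame(
        contig = contig, ref_start = pos, kind = "ins", length = nchar(body),
        ref_allele = NA_character_, alt_allele = body, stringsAsFactors = FALSE)
    } else { # deletion
      out[[length(out) + 1L]] <- data.frame(
        contig = contig, ref_start = pos, kind = "del", length = nchar(body),
        ref_allele = body, alt_allele = NA_character_, stringsAsFactors = FALSE)
      pos <- pos + nchar(body)
    }
  }
  df <- if (length(out)) do.call(rbind, out) else .empty_diffs()
  df <- df[order(df$ref_start), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "ref_span") <- pos - ref_start
  df
}

#' Read alignment differences from a PAF file carrying cs tags
#'
#' Each PAF line contributes the differences of one alignment, in reference
#' (target) coordinates, via [parse_cs_diffs()]. Lines without a cs tag are
#' an error. Also returns the aligned target intervals.
#'
#' @param path Path to a PAF file with `cs:Z:` tags.
#' @return A list with `diffs` (difference records across all alignments)
#'   and `aligned` (data frame contig/start/end of target spans).
#' @export
read_paf_diffs <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  diffs <- list(); aligned <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 12L) stop("malformed PAF row at line ", i)
    tname <- f[6]; tstart <- as.numeric(f[8]); tend <- as.numeric(f[9])
    cs <- grep("^cs:Z:", f[-(1:12)], value = TRUE)
    if (length(cs) == 0L) stop("PAF row without cs tag at line ", i)
    d <- parse_cs_diffs(tname, tstart, sub("^cs:Z:", "", cs[1]))
    diffs[[i]] <- d
    aligned[[i]] <- data.frame(contig = tname, start = tstart, end = tend,
                               stringsAsFactors = FALSE)
  }
  d <- if (length(diffs)) do.call(rbind, diffs) else .empty_diffs()
  rownames(d) <- NULL
  list(diffs = d,
       aligned = if (length(aligned)) do.call(rbind, aligned)
                 else iv_frame())
}

#' Write / read difference records as TSV
#'
#' Plain-text round-trip of the internal difference-record table (0-based
#' reference coordinates).
#'
#' @param diffs A difference-record data frame.
#' @param path File path.
#' @export
write_diffs_tsv <- function(diffs, path) {
  utils::write.table(diffs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_diffs_tsv
#' @export
read_diffs_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "numeric", "character",
                                         "numeric", "character", "character"),
                          stringsAsFactors = FALSE)
  df
}

#' Read a RepeatMasker .out annotation table
#'
#' Standard layout: header lines (skipped), then whitespace-separated
#' columns. Query begin/end (1-based inclusive) are converted to 0-based
#' half-open; the repeat class/family string is split at `/` keeping the
#' class part.
#'
#' @param path Path to a RepeatMasker `.out` file.
#' @return Data frame of repeat records: contig, start, end, repeat_name,
#'   repeat_class.
#' @export
read_repeatmasker_out <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    f <- strsplit(ln, "\\s+")[[1]]
    # header lines start with a non-numeric token (SW score column otherwise)
    if (is.na(suppressWarnings(as.numeric(f[1])))) next
    if (length(f) < 15L) stop("too few columns at line ", i)
    cls <- strsplit(f[11], "/", fixed = TRUE)[[1]][1]
    s1 <- as.numeric(f[6]); e1 <- as.numeric(f[7])
    out[[length(out) + 1L]] <- data.frame(
      contig = f[5], start = s1 - 1, end = e1, repeat_name = f[10],
      repeat_class = cls, stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(contig = character(), start = numeric(),
                      end = numeric(), repeat_name = character(),
                      repeat_class = character(), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' Read a per-position depth TSV (contig, 1-based position, depth)
#'
#' The samtools-depth layout. Positions are converted to 0-based and sorted
#' per contig; absent positions are treated as depth 0 only when queried
#' downstream with zero-fill enabled.
#'
#' @param path Path to the TSV.
#' @return A `DepthTrack`: data frame (contig, pos (0-based), depth), sorted.
#' @export
read_depth_tsv <- function(path) {
  if (file.size(path) == 0L) {
    return(depth_track(character(), numeric(), numeric()))
  }
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("contig", "pos", "depth"),
                          colClasses = c("character", "numeric", "numeric"),
                          stringsAsFactors = FALSE)
  depth_track(df$contig, df$pos - 1, df$depth)
}

#' Construct a depth track
#'
#' @param contig,pos,depth Vectors: contig name, 0-based position,
#'   non-negative integer depth. Sorted on construction; duplicate positions
#'   within a contig are an error.
#' @return An object of class `DepthTrack` (data frame).
#' @export
depth_track <- function(contig, pos, depth) {
  if (any(depth < 0)) stop("negative depth")
  df <- data.frame(contig = as.character(contig), pos = as.numeric(pos),
                   depth = as.numeric(depth), stringsAsFactors = FALSE)
  df <- df[order(df$contig, df$pos), , drop = FALSE]
  if (anyDuplicated(df[, c("contig", "pos")])) {
    stop("duplicate position in depth track")
  }
  rownames(df) <- NULL
  class(df) <- c("DepthTrack", "data.frame")
  df
}

#' Write variant records and callable intervals as a banded gVCF
#'
#' Inverse of [read_vcf_with_bands()] for synthetic data: variant rows are
#' written as single-sample VCF records (SNP as A>T, indel as AT>A /
#' A>AT), callable intervals as banded reference blocks with `INFO/END`
#' and `MIN_DP`. Reading the file back reproduces the variant positions,
#' kinds, genotypes, qualities and the intervals.
#'
#' @param variants Variant-record data frame (see [read_vcf_with_bands()]).
#' @param callable Callable-interval data frame.
#' @param path Output path.
#' @param sample Sample name in the header.
#' @export
write_vcf_with_bands <- function(variants, callable, path,
                                 sample = "sample1") {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End of block\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
           "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
           "##FORMAT=<ID=MIN_DP,Number=1,Type=Integer,Description=\"Min depth in block\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", sample, sep = "\t"))
  fnum <- function(x) ifelse(is.na(x), ".", format(x, scientific = FALSE, trim = TRUE))
  rows <- character(0)
  if (nrow(variants) > 0L) {
    ref <- ifelse(variants$kind == "indel", "AT", "A")
    alt <- ifelse(variants$kind == "indel", "A", "T")
    gt <- ifelse(variants$genotype == "het", "0/1", "1/1")
    rows <- c(rows, paste(variants$contig,
                          format(variants$pos + 1, scientific = FALSE, trim = TRUE), ".",
                          ref, alt, fnum(variants$site_quality), "PASS", ".",
                          "GT:DP:GQ",
                          paste(gt, fnum(variants$depth),
                                fnum(variants$genotype_quality), sep = ":"),
                          sep = "\t"))
  }
  if (nrow(callable) > 0L) {
    rows <- c(rows, paste(callable$contig,
                          format(callable$start + 1, scientific = FALSE, trim = TRUE), ".",
                          "A", "<NON_REF>", fnum(callable$quality), "PASS",
                          paste0("END=", format(callable$end, scientific = FALSE, trim = TRUE)),
                          "GT:MIN_DP",
                          paste("0/0", fnum(callable$min_depth), sep = ":"),
                          sep = "\t"))
  }
  key <- c(if (nrow(variants) > 0L) paste(variants$contig, variants$pos),
           if (nrow(callable) > 0L) paste(callable$contig, callable$start))
  ord <- order(sub(" .*", "", key), as.numeric(sub(".* ", "", key)))
  writeLines(c(hdr, rows[ord]), path)
  invisible(path)
}

#' Write repeat records in RepeatMasker .out layout
#'
#' Inverse of [read_repeatmasker_out()]: standard header lines followed by
#' 15 whitespace-separated columns, query coordinates 1-based inclusive.
#'
#' @param records Repeat-record data frame.
#' @param path Output path.
#' @export
write_repeatmasker_out <- function(records, path) {
  hdr <- c("   SW   perc perc perc  query     position in query    matching  repeat        position in repeat",
           "score   div. del. ins.  sequence  begin end   (left)   repeat    class/family  begin end (left) ID",
           "")
  rows <- if (nrow(records) > 0L) {
    sprintf("%5d %5.1f %4.1f %4.1f  %s %d %d (%d) + %s %s %d %d (%d) %d",
            1000L, 1.0, 0.1, 0.1, records$contig,
            records$start + 1, records$end, 0L,
            records$repeat_name, records$repeat_class,
            1L, records$end - records$start, 0L, seq_len(nrow(records)))
  } else character(0)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Write a depth track as a samtools-depth style TSV
#'
#' Inverse of [read_depth_tsv()]: contig, 1-based position, depth.
#'
#' @param track A [depth_track()].
#' @param path Output path.
#' @export
write_depth_tsv <- function(track, path) {
  utils::write.table(
    data.frame(track$contig, format(track$pos + 1, scientific = FALSE, trim = TRUE),
               track$depth),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
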