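# Independent brute-force oracles, kept deliberately naive.

# Nx by direct cumulative scan over descending lengths.
brute_nx <- function(lengths, x, target = sum(lengths)) {
  srt <- sort(lengths, decreasing = TRUE)
  cum <- 0
  for (L in srt) {
    cum <- cum + L
    if (cum >= x / 100 * target) return(L)
  }
  NA_real_
}

# auN as the step integral of the brute-force Nx curve over x in (0, 100].
brute_auN <- function(lengths) {
  srt <- sort(lengths, decreasing = TRUE)
  total <- sum(srt)
  x_hi <- 100 * cumsum(srt) / total
  x_lo <- c(0, x_hi[-length(x_hi)])
  sum(srt * (x_hi - x_lo)) / 100
}

random_contig_set <- function(max_contigs = 20) {
  n <- sample.int(max_contigs, 1)
  contig_set(paste0("c", seq_len(n)), sample.int(10000, n, replace = TRUE))
}

# A toy banded gVCF with two passing variants and one passing 100-site band,
# plus records that the default filters must drop.
write_toy_vcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
    "chr1\t101\t.\tA\t<NON_REF>\t50\tPASS\tEND=200\tGT:MIN_DP\t0/0:15",
    "chr1\t250\t.\tA\tT\t50\tPASS\t.\tGT:DP:GQ\t0/1:30:40",
    "chr1\t300\t.\tAT\tA\t60\tPASS\t.\tGT:DP:GQ\t1/1:25:50",
    "chr1\t400\t.\tA\tT\t50\tPASS\t.\tGT:DP:GQ\t0/1:9:40",
    "chr1\t501\t.\tA\t<NON_REF>\t50\tPASS\tEND=600\tGT:MIN_DP\t0/0:5"
  ), path)
}
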