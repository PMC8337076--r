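iv <- function(start, end, contig = "c1") {
  data.frame(contig = rep(contig, length.out = length(start)), start = start,
             end = end, stringsAsFactors = FALSE)
}

test_that("element derivation: introns and intergenic by set arithmetic", {
  ann <- derive_elements(genes = iv(10, 60), exons = iv(c(10, 40), c(20, 60)),
                         contig_lengths = c(c1 = 100))
  expect_equal(ann$classes$intron[, c("start", "end")],
               data.frame(start = 20, end = 40))
  expect_equal(ann$classes$intergenic$start, c(0, 60))
  expect_equal(ann$classes$intergenic$end, c(10, 100))

  # no genes -> whole contig intergenic
  ann2 <- derive_elements(genes = iv(numeric(0), numeric(0)),
                          exons = iv(numeric(0), numeric(0)),
                          contig_lengths = c(c1 = 100))
  expect_equal(ann2$classes$intergenic[, c("start", "end")],
               data.frame(start = 0, end = 100))
  # exons == genes -> no introns
  ann3 <- derive_elements(genes = iv(10, 60), exons = iv(10, 60),
                          contig_lengths = c(c1 = 100))
  expect_equal(nrow(ann3$classes$intron), 0)
})

test_that("exons outside genes are rejected with offenders listed", {
  expect_error(derive_elements(genes = iv(10, 60), exons = iv(70, 80),
                               contig_lengths = c(c1 = 100)),
               "c1:70-80")
})

test_that("genic and intergenic regions partition every contig exactly", {
  set.seed(31)
  for (rep in 1:10) {
    len <- sample(5000:20000, 1)
    gs <- sort(sample.int(len - 100, 6))
    genes <- iv(gs[c(1, 3, 5)], gs[c(2, 4, 6)])
    exons <- iv(gs[c(1, 3, 5)], pmin(gs[c(2, 4, 6)], gs[c(1, 3, 5)] + 50))
    ann <- derive_elements(genes, exons, contig_lengths = c(c1 = len))
    covered <- sum(vapply(ann$classes[c("exon", "intron", "intergenic")],
                          function(v) sum(v$end - v$start), numeric(1)))
    expect_equal(covered, len)
    # pairwise disjoint
    for (p in list(c("exon", "intron"), c("exon", "intergenic"),
                   c("intron", "intergenic"))) {
      inter <- asmqc:::iv_intersect(ann$classes[[p[1]]], ann$classes[[p[2]]])
      expect_equal(nrow(inter), 0)
    }
  }
})

test_that("window QV: Phred arithmetic, cap, boundary-spanning deletions", {
  diffs <- do.call(rbind, lapply(0:9, function(i)
    parse_cs_diffs("c1", i * 1000, "*at")))
  w <- window_qv(diffs, iv(0, 1e5), window_bp = 1e5)
  expect_equal(nrow(w), 1)
  expect_equal(w$qv_total, 40)  # 10 snv / 1e5
  expect_equal(w$qv_snv, 40)
  expect_equal(w$qv_ins, 60)

  w0 <- window_qv(diffs[0, ], iv(0, 1e5), window_bp = 1e5)
  expect_equal(w0$qv_total, 60)

  # 2-bp deletion spanning a window boundary: 1 bp in each window
  del <- data.frame(contig = "c1", ref_start = 99999, kind = "del",
                    length = 2, ref_allele = "ca", alt_allele = NA,
                    stringsAsFactors = FALSE)
  wd <- window_qv(del, iv(0, 2e5), window_bp = 1e5)
  expect_equal(wd$del_bp, c(1, 1))
  expect_error(window_qv(del, iv(0, 2e5), window_bp = 0), "window_bp")
})

test_that("insertions contribute full length at their anchor; denominators are aligned bp", {
  ins <- data.frame(contig = "c1", ref_start = 50, kind = "ins", length = 500,
                    ref_allele = NA, alt_allele = NA, stringsAsFactors = FALSE)
  w <- window_qv(ins, iv(0, 1000), window_bp = 1000)
  expect_equal(w$ins_bp, 500)
  expect_equal(w$aligned_bp, 1000)
  # unaligned reference carries no denominator: second window absent
  w2 <- window_qv(ins, iv(0, 800), window_bp = 500)
  expect_equal(w2$aligned_bp, c(500, 300))
})

test_that("per-class windows partition whole-window error counts", {
  sim <- sim_alignment_diffs(
    element_bp = c(exon = 2e5, intron = 2e5, intergenic = 2e5),
    error_rates = list(exon = list(snv = 1e-4, ins = 5e-5, del = 5e-5),
                       intron = list(snv = 5e-4, ins = 1e-4, del = 1e-4),
                       intergenic = list(snv = 1e-3, ins = 2e-4, del = 2e-4)),
    seed = 17)
  w <- window_qv(sim$diffs, sim$aligned, sim$elements, window_bp = 1e5)
  whole <- w[w$class == "whole", ]
  parts <- w[w$class %in% c("exon", "intron", "intergenic"), ]
  for (col in c("aligned_bp", "snv_bp", "ins_bp", "del_bp")) {
    by_win <- tapply(parts[[col]], parts$window_start, sum)
    expect_equal(as.numeric(by_win[as.character(whole$window_start)]),
                 whole[[col]])
  }
})

test_that("window tables are independent of difference-record order", {
  sim <- sim_alignment_diffs(element_bp = c(exon = 1e5, intergenic = 1e5),
                             error_rates = list(exon = list(snv = 1e-3),
                                                intergenic = list(del = 5e-4)),
                             seed = 23)
  w1 <- window_qv(sim$diffs, sim$aligned, sim$elements)
  shuffled <- sim$diffs[rev(seq_len(nrow(sim$diffs))), ]
  w2 <- window_qv(shuffled, sim$aligned, sim$elements)
  expect_equal(w2, w1)
})

test_that("aggregate QV: identical windows, bounds, clustered-error example", {
  w <- window_qv(data.frame(contig = "c1", ref_start = 1, kind = "snv",
                            length = 1, ref_allele = "a", alt_allele = "t",
                            stringsAsFactors = FALSE),
                 iv(0, 1e5), window_bp = 1e5)
  agg <- aggregate_qv(w)
  expect_equal(agg$qv_pooled, agg$qv_median)
  expect_equal(agg$qv_pooled, agg$qv_percentile)

  # 10 windows, 9 clean and 1 with 100 errors on 1e5 bp each:
  # median stays at the cap while the pooled mean is 40
  snvs <- do.call(rbind, lapply(0:99, function(i)
    data.frame(contig = "c1", ref_start = 9e5 + i * 10, kind = "snv",
               length = 1, ref_allele = "a", alt_allele = "t",
               stringsAsFactors = FALSE)))
  w10 <- window_qv(snvs, iv(0, 1e6), window_bp = 1e5)
  expect_equal(nrow(w10), 10)
  agg10 <- aggregate_qv(w10)
  expect_equal(agg10$qv_median, 60)
  expect_equal(agg10$qv_pooled, 40)
  expect_gt(agg10$qv_median, agg10$qv_pooled)
  expect_gte(max(w10$qv_total), agg10$qv_pooled)
  expect_lte(min(w10$qv_total), agg10$qv_pooled)
  expect_error(aggregate_qv(w10[0, ]), "no windows")
})

test_that("indel impact: direct arithmetic and gene hit accounting", {
  coding <- data.frame(gene = c("g1", "g2", "g3"), contig = "c1",
                       start = c(0, 1000, 2000), end = c(500, 1500, 2500),
                       stringsAsFactors = FALSE)
  diffs <- data.frame(
    contig = "c1", ref_start = c(10, 1100, 2100, 1200),
    kind = c("ins", "ins", "ins", "del"),
    length = c(3, 120, 4410, 2),
    ref_allele = NA, alt_allele = NA, stringsAsFactors = FALSE)
  s <- indel_impact(diffs, coding)
  expect_equal(s$n_insertions, 3)
  expect_equal(s$n_deletions, 1)
  expect_equal(s$inserted_bp, 4533)
  expect_equal(s$deleted_bp, 2)
  expect_equal(s$pct_diff_bp_from_large_insertions, 100 * 4530 / 4535)
  expect_equal(s$n_genes_with_indel, 3)
  expect_equal(s$n_small_insertions, 1)
  expect_equal(s$n_large_insertions, 2)

  s0 <- indel_impact(diffs[0, ], coding)
  expect_equal(s0$n_genes_with_indel, 0)
  expect_equal(s0$pct_genes_with_indel, 0)

  # an indel outside all coding intervals is not counted
  outside <- data.frame(contig = "c1", ref_start = 600, kind = "ins",
                        length = 10, ref_allele = NA, alt_allele = NA,
                        stringsAsFactors = FALSE)
  expect_equal(indel_impact(outside, coding)$n_insertions, 0)
  expect_error(indel_impact(diffs, coding[0, ]), "no genes")
})
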