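variant_row <- function(pos = 0, kind = "snp", genotype = "het", qual = 50,
                        dp = 30, gq = 40, contig = "chr1") {
  data.frame(contig = contig, pos = pos, kind = kind, genotype = genotype,
             site_quality = qual, depth = dp, genotype_quality = gq,
             stringsAsFactors = FALSE)
}

band_row <- function(start, end, min_depth = 30, quality = 50, contig = "chr1") {
  data.frame(contig = contig, start = start, end = end,
             min_depth = min_depth, quality = quality, stringsAsFactors = FALSE)
}

test_that("filters drop sub-threshold records and keep inclusive boundaries", {
  v <- rbind(variant_row(10, dp = 9, qual = 50),       # depth below minimum
             variant_row(20, dp = 10, qual = 30, gq = 30),  # all at boundary
             variant_row(30, qual = 29),                # quality below
             variant_row(40, gq = NA))                  # GQ absent: kept
  out <- filter_calls(v, band_row(100, 200))
  expect_equal(out$variants$pos, c(20, 40))
  expect_equal(out$n_callable_sites, 100 + 2)
})

test_that("callable-site arithmetic sums passing bands and variant sites", {
  v <- rbind(variant_row(10), variant_row(20))
  b <- rbind(band_row(100, 200),              # 100 passing sites
             band_row(300, 400, min_depth = 5))  # fails depth
  out <- filter_calls(v, b)
  expect_equal(out$n_callable_sites, 102)
  # bands missing optional fields pass on the fields they do have
  b2 <- band_row(500, 600, min_depth = NA, quality = NA)
  expect_equal(filter_calls(v[0, ], b2)$n_callable_sites, 100)
})

test_that("overlapping callable intervals are merged with a warning", {
  b <- rbind(band_row(0, 100), band_row(50, 150))
  expect_warning(out <- filter_calls(variant_row(10)[0, ], b), "normalized")
  expect_equal(out$n_callable_sites, 150)
})

test_that("filtering is idempotent", {
  sim <- sim_variant_calls(20000, 0.01, 0.005, seed = 5,
                           contamination_fraction = 0.01)
  f1 <- filter_calls(sim$variants, sim$callable)
  f2 <- filter_calls(f1$variants, f1$callable)
  expect_equal(f2$variants, f1$variants)
  expect_equal(f2$n_callable_sites, f1$n_callable_sites)
})

test_that("all-passing simulated records survive filtering untouched", {
  sim <- sim_variant_calls(50000, 0.002, 0.001, seed = 8)
  out <- filter_calls(sim$variants, sim$callable)
  expect_equal(nrow(out$variants), nrow(sim$variants))
  expect_equal(out$n_callable_sites, sim$truth$n_callable_expected)
})

test_that("repeat exclusion removes variants and callable bp before counting", {
  v <- rbind(variant_row(10), variant_row(150))
  b <- band_row(100, 200)
  excl <- data.frame(contig = "chr1", start = 140, end = 160)
  out <- filter_calls(v, b, exclude = excl)
  expect_equal(out$variants$pos, 10)
  expect_equal(out$n_callable_sites, (100 - 20) + 1)
})

test_that("heterozygosity: worked ratios and SNP-only numerator", {
  v <- rbind(variant_row(1, "snp", "het"), variant_row(2, "snp", "hom_alt"),
             variant_row(3, "indel", "het"))
  d <- heterozygosity(v, 1000)
  expect_equal(d$n_het_snps, 1)
  expect_equal(d$n_hom_snps, 1)
  expect_equal(d$n_het_indels, 1)
  expect_equal(d$het_per_site, 1e-3)
  expect_equal(d$het_pct, 0.1)

  expect_equal(heterozygosity(v[0, ], 100)$het_per_site, 0)
  expect_equal(heterozygosity(do.call(rbind, lapply(1:42, variant_row)),
                              1.2e6)$het_per_site, 3.5e-5)
  expect_error(heterozygosity(v, 0), "callable")
})

test_that("heterozygosity recovers the simulated rate within binomial error", {
  n <- 1e6; h <- 1e-3
  sim <- sim_variant_calls(n, h, 0, seed = 13)
  out <- filter_calls(sim$variants, sim$callable)
  est <- heterozygosity(out$variants, out$n_callable_sites)$het_per_site
  expect_lt(abs(est - h), 4 * sqrt(h * n) / n)
})

test_that("variant QV follows the Phred identity and the zero-error cap", {
  v1 <- variant_row(1)
  expect_equal(variant_qv(v1, 1000)$qv, 30)          # p = 1e-3
  v5 <- do.call(rbind, lapply(1:5, variant_row))
  expect_equal(variant_qv(v5, 1e6)$qv, -10 * log10(5e-6), tolerance = 1e-12)
  z <- variant_qv(v1[0, ], 1e6)
  expect_equal(z$qv, 60)
  expect_true(z$capped)
  for (k in 1:6) {
    n <- 10^(6 - k)
    vk <- data.frame(contig = "chr1", pos = seq_len(n) - 1, kind = "snp",
                     genotype = "het", site_quality = 50, depth = 30,
                     genotype_quality = 40, stringsAsFactors = FALSE)
    expect_equal(variant_qv(vk, 1e6)$qv, 10 * k)
  }
})

test_that("QV is monotone in errors and callable sites; multi-record sites count once", {
  v <- do.call(rbind, lapply(1:10, variant_row))
  q1 <- variant_qv(v, 1e5)$qv
  q2 <- variant_qv(rbind(v, variant_row(99)), 1e5)$qv
  expect_lt(q2, q1)
  q3 <- variant_qv(v, 2e5)$qv
  expect_gt(q3, q1)
  # same site twice (snp + indel records) counts once
  dup <- rbind(variant_row(5, "snp"), variant_row(5, "indel"))
  expect_equal(variant_qv(dup, 1000)$n_error_sites, 1)
})
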