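chain_table <- function(markers, assembly_id, contig = "c1") {
  marker_table(markers, "complete_single", contig,
               (seq_along(markers) - 1) * 100, (seq_along(markers) - 1) * 100 + 50,
               assembly_id = assembly_id)
}

test_that("edge weights count immediate-neighbor co-occurrence", {
  t3 <- lapply(1:3, function(i) chain_table(c("A", "B", "C"), paste0("a", i)))
  g <- build_adjacency(t3)
  m <- adjacency_matrix(g)
  expect_equal(m["A", "B"], 3)
  expect_equal(m["B", "C"], 3)
  expect_equal(m["A", "C"], 0)

  g4 <- build_adjacency(c(t3, list(chain_table(c("A", "C", "B"), "a4"))))
  m4 <- adjacency_matrix(g4)
  expect_equal(m4["A", "B"], 3)
  expect_equal(m4["B", "C"], 4)
  expect_equal(m4["A", "C"], 1)
  expect_equal(m4, t(m4))
})

test_that("single-marker contigs and non-single statuses contribute no edges", {
  tb <- marker_table(c("A", "B", "C", "D"),
                     c("complete_single", "complete_single", "duplicated",
                       "fragmented"),
                     c("c1", "c2", "c1", "c1"), c(0, 0, 100, 200),
                     c(50, 50, 150, 250))
  g <- build_adjacency(list(tb))
  expect_equal(nrow(g$edges), 0)
})

test_that("a marker placed twice as complete_single is a status inconsistency", {
  tb <- marker_table(c("A", "A"), "complete_single", c("c1", "c2"),
                     c(0, 0), c(50, 50))
  expect_error(build_adjacency(list(tb)), "twice as complete_single")
})

test_that("chains of three or more markers add no transitive pairs; alternate mode drops them", {
  tb <- chain_table(c("A", "B", "C", "D"), "a1")
  g <- build_adjacency(list(tb))
  expect_equal(sum(g$edges$weight), 3)  # A-B, B-C, C-D only
  expect_equal(adjacency_matrix(g)["A", "C"], 0)
  g_drop <- build_adjacency(list(tb), mode = "drop_chains_ge3")
  expect_equal(nrow(g_drop$edges), 0)
  two <- chain_table(c("A", "B"), "a2")
  expect_equal(sum(build_adjacency(list(two), mode = "drop_chains_ge3")$edges$weight), 1)
})

test_that("total edge mass equals sum over contigs of (markers - 1)", {
  sim <- sim_marker_assemblies(marker_genome_spec(6, 3, 25, 3,
                                                  contig_markers_mean = 4,
                                                  seed = 41))
  g <- build_adjacency(sim$tables)
  expected <- sum(vapply(sim$tables, function(tb) {
    per_contig <- table(tb$contig)
    sum(pmax(per_contig - 1, 0))
  }, numeric(1)))
  expect_equal(sum(g$edges$weight), expected)
})

test_that("adding an assembly never decreases an edge weight", {
  sim <- sim_marker_assemblies(marker_genome_spec(5, 2, 15, 2, seed = 43))
  g4 <- build_adjacency(sim$tables[1:4])
  g5 <- build_adjacency(sim$tables)
  m4 <- adjacency_matrix(g4); m5 <- adjacency_matrix(g5)
  common <- intersect(rownames(m4), rownames(m5))
  expect_true(all(m5[common, common] >= m4[common, common]))
})

test_that("arms stay disconnected without translocation and cluster per arm", {
  sim <- sim_marker_assemblies(marker_genome_spec(
    n_species = 10, n_arms = 6, markers_per_arm = 30,
    inversions_per_species = 5, translocation_rate = 0,
    contig_markers_mean = 8, seed = 47))
  g <- build_adjacency(sim$tables)
  arm <- sim$truth$arm_of_marker
  expect_true(all(arm[g$edges$a] == arm[g$edges$b]))
  cl <- components(g)
  expect_equal(cl$n_clusters, 6)
  # cluster labels follow connectivity, and min_weight above the max weight
  # isolates every node
  expect_error(components(g, min_weight = 0), "min_weight")
  iso <- components(g, min_weight = max(g$edges$weight) + 1)
  expect_equal(iso$n_clusters, length(g$observed))
})

test_that("marker universe supplies nodes never observed", {
  g <- build_adjacency(list(chain_table(c("A", "B"), "a1")),
                       marker_universe = c("A", "B", "Z"))
  expect_true("Z" %in% g$nodes)
  expect_false("Z" %in% g$observed)
  expect_equal(dim(adjacency_matrix(g)), c(3, 3))
})

test_that("layout pulls connected nodes together, deterministically", {
  g <- build_adjacency(list(chain_table(c("A", "B"), "a1")))
  p <- layout_params(iterations = 200, seed = 3)
  init <- asmqc:::with_seed(3, matrix(stats::runif(4, -1, 1) * sqrt(2), ncol = 2))
  xy <- fa2_layout(g, p)
  expect_lt(stats::dist(xy)[1], stats::dist(init)[1] + 1e-9)
  expect_identical(fa2_layout(g, p), xy)
})

test_that("layout separates arm clusters (intra < inter distances)", {
  sim <- sim_marker_assemblies(marker_genome_spec(
    n_species = 8, n_arms = 3, markers_per_arm = 12,
    inversions_per_species = 3, contig_markers_mean = 6, seed = 53))
  g <- build_adjacency(sim$tables)
  xy <- fa2_layout(g, layout_params(iterations = 400, seed = 7))
  arm <- sim$truth$arm_of_marker[rownames(xy)]
  d <- as.matrix(stats::dist(xy))
  same <- outer(arm, arm, "==") & upper.tri(d)
  diff_arm <- outer(arm, arm, "!=") & upper.tri(d)
  expect_lt(mean(d[same]), mean(d[diff_arm]))
})

test_that("edge list writer produces the documented three-column TSV", {
  g <- build_adjacency(list(chain_table(c("A", "B", "C"), "a1")))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_adjacency_edges(g, f)
  tab <- utils::read.table(f, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  expect_equal(names(tab), c("marker_a", "marker_b", "weight"))
  expect_equal(sum(tab$weight), 2)
})
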