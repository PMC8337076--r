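#' Build the marker-adjacency (synteny) graph across assemblies
#'
#' Represents each assembly as a set of paths through its single-copy
#' orthologous markers: within each contig, complete single-copy markers
#' are ordered by start coordinate and every pair of immediate neighbors
#' contributes 1 to the weight of the corresponding undirected edge. The
#' resulting weighted graph has an edge weight equal to the number of
#' assemblies in which the two markers are direct neighbors; chromosome
#' arms with conserved gene content but shuffled gene order show up as
#' dense clusters.
#'
#' Only immediate neighbors form edges; chains of three or more markers on
#' a contig contribute no transitive (long-range) pairs. The alternate
#' reading — discarding entire contigs that carry three or more markers —
#' is available as `mode = "drop_chains_ge3"`.
#'
#' @param tables List of [marker_table()]s, one per assembly.
#' @param marker_universe Optional character vector of all marker ids to
#'   use as the node set (e.g. the full ortholog database); defaults to the
#'   union of observed markers.
#' @param mode `"immediate_pairs"` (default) or `"drop_chains_ge3"`.
#' @return An object of class `AdjacencyGraph`: list with `nodes`,
#'   `observed`, `edges` (data frame `a`, `b`, `weight`, with `a < b`) and
#'   `n_assemblies`.
#' @export
build_adjacency <- function(tables, marker_universe = NULL,
                            mode = c("immediate_pairs", "drop_chains_ge3")) {
  mode <- match.arg(mode)
  if (length(tables) == 0L) stop("need at least one marker table")
  pair_count <- new.env(hash = TRUE, parent = emptyenv())
  observed <- character(0)
  for (tb in tables) {
    sc <- tb[tb$status == "complete_single" & !is.na(tb$contig), , drop = FALSE]
    dup <- sc$marker_id[duplicated(sc$marker_id)]
    if (length(dup) > 0L) {
      stop("marker appears twice as complete_single in one assembly: ", dup[1])
    }
    observed <- union(observed, sc$marker_id)
    for (ct in unique(sc$contig)) {
      d <- sc[sc$contig == ct, , drop = FALSE]
      d <- d[order(d$start, d$end, d$marker_id), , drop = FALSE]
      if (nrow(d) < 2L) next
      if (mode == "drop_chains_ge3" && nrow(d) >= 3L) next
      for (i in seq_len(nrow(d) - 1L)) {
        ab <- sort(c(d$marker_id[i], d$marker_id[i + 1L]))
        key <- paste(ab[1], ab[2], sep = "\r")
        pair_count[[key]] <- (if (is.null(pair_count[[key]])) 0L
                              else pair_count[[key]]) + 1L
      }
    }
  }
  keys <- ls(pair_count)
  edges <- if (length(keys) > 0L) {
    ab <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
    data.frame(a = ab[, 1], b = ab[, 2],
               weight = vapply(keys, function(k) pair_count[[k]], integer(1)),
               stringsAsFactors = FALSE, row.names = NULL)
  } else {
    data.frame(a = character(), b = character(), weight = integer(),
               stringsAsFactors = FALSE)
  }
  edges <- edges[order(edges$a, edges$b), , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- if (is.null(marker_universe)) sort(observed)
           else sort(unique(as.character(marker_universe)))
  structure(list(nodes = nodes, observed = sort(observed), edges = edges,
                 n_assemblies = length(tables)),
            class = "AdjacencyGraph")
}

.graph_to_igraph <- function(graph, min_weight = 1) {
  e <- graph$edges[graph$edges$weight >= min_weight, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    e, directed = FALSE,
    vertices = data.frame(name = graph$observed, stringsAsFactors = FALSE))
  g
}

#' Connected components of the adjacency graph
#'
#' Clusters observed markers by connectivity in the subgraph of edges with
#' weight at least `min_weight`. With conserved arm content and no
#' between-arm rearrangement, each chromosome arm forms one component.
#' Isolated observed markers are singleton clusters. Cluster labels are
#' deterministic: the smallest member marker id.
#'
#' @param graph An [build_adjacency()] result.
#' @param min_weight Minimum edge weight to keep (default 1).
#' @return An object of class `ClusterAssignment`: list with `assignment`
#'   (data frame `marker_id`, `cluster`) and `n_clusters`.
#' @export
components <- function(graph, min_weight = 1) {
  if (min_weight < 1) stop("min_weight must be >= 1")
  g <- .graph_to_igraph(graph, min_weight)
  comp <- igraph::components(g)
  memb <- comp$membership
  label_of <- vapply(split(names(memb), memb),
                     function(v) min(v), character(1))
  assignment <- data.frame(marker_id = names(memb),
                           cluster = unname(label_of[as.character(memb)]),
                           stringsAsFactors = FALSE, row.names = NULL)
  assignment <- assignment[order(assignment$marker_id), , drop = FALSE]
  rownames(assignment) <- NULL
  structure(list(assignment = assignment, n_clusters = comp$no),
            class = "ClusterAssignment")
}

#' Layout parameters for the force-directed graph layout
#'
#' @param tolerance Speed tolerance (default 1).
#' @param gravity Gravity strength toward the origin (default 1).
#' @param iterations Number of iterations (default 3000).
#' @param seed RNG seed for the initial placement.
#' @return A list of class `LayoutParams`.
#' @export
layout_params <- function(tolerance = 1, gravity = 1, iterations = 3000,
                          seed = 1) {
  if (iterations < 1) stop("iterations must be >= 1")
  structure(list(tolerance = tolerance, gravity = gravity,
                 iterations = iterations, seed = seed),
            class = "LayoutParams")
}

#' ForceAtlas2-style force-directed layout of the adjacency graph
#'
#' A faithful-in-spirit implementation of the ForceAtlas2 force model:
#' linear attraction along edges scaled by edge weight, repulsion between
#' every node pair proportional to (degree+1)(degree+1)/distance, and a
#' gravity force pulling nodes toward the origin scaled by (degree+1).
#' Displacements use the ForceAtlas2 adaptive local speed with the global
#' speed controlled by the tolerance parameter. No Barnes-Hut
#' approximation is used; intended for graphs of up to a few thousand
#' nodes.
#'
#' @param graph An [build_adjacency()] result.
#' @param params A [layout_params()].
#' @return Matrix with one row per observed marker (rownames = marker ids)
#'   and columns `x`, `y`. Deterministic under the seed.
#' @export
fa2_layout <- function(graph, params = layout_params()) {
  nodes <- graph$observed
  n <- length(nodes)
  if (n < 1L) stop("graph has no observed nodes")
  e <- graph$edges
  ia <- match(e$a, nodes); ib <- match(e$b, nodes)
  deg <- tabulate(c(ia, ib), nbins = n)
  mass <- deg + 1
  pos <- with_seed(params$seed,
                   matrix(stats::runif(2 * n, -1, 1) * sqrt(n), ncol = 2))
  if (n == 1L) {
    rownames(pos) <- nodes; colnames(pos) <- c("x", "y"); return(pos)
  }
  k_r <- 1; speed <- 1; speed_eff <- 1
  old_force <- matrix(0, n, 2)
  for (it in seq_len(params$iterations)) {
    dx <- outer(pos[, 1], pos[, 1], "-")
    dy <- outer(pos[, 2], pos[, 2], "-")
    d2 <- dx * dx + dy * dy
    d <- sqrt(d2); d[d < 1e-9] <- 1e-9
    # repulsion: k_r * m_i * m_j / d, directed away
    coef <- k_r * outer(mass, mass) / d2
    diag(coef) <- 0
    fx <- rowSums(coef * dx)
    fy <- rowSums(coef * dy)
    # attraction along edges: weight * distance, i.e. force = w * (vec)
    if (nrow(e) > 0L) {
      ax <- pos[ia, 1] - pos[ib, 1]
      ay <- pos[ia, 2] - pos[ib, 2]
      w <- e$weight
      fx <- fx - unname(tapply(c(w * ax, -w * ax), c(ia, ib), sum)[as.character(seq_len(n))])
      fy <- fy - unname(tapply(c(w * ay, -w * ay), c(ia, ib), sum)[as.character(seq_len(n))])
      fx[is.na(fx)] <- 0; fy[is.na(fy)] <- 0
    }
    # gravity toward origin
    dist0 <- sqrt(rowSums(pos^2)); dist0[dist0 < 1e-9] <- 1e-9
    fx <- fx - params$gravity * mass * pos[, 1] / dist0
    fy <- fy - params$gravity * mass * pos[, 2] / dist0
    force <- cbind(fx, fy)
    # adaptive speed (swing vs traction), as in ForceAtlas2
    swing <- sqrt(rowSums((force - old_force)^2))
    traction <- sqrt(rowSums((force + old_force)^2)) / 2
    total_swing <- sum(mass * swing); total_traction <- sum(traction)
    if (total_swing > 0) {
      target <- params$tolerance * total_traction / total_swing
      speed <- speed + min(target - speed, 0.5 * speed)
    }
    fmag <- sqrt(rowSums(force^2)); fmag[fmag < 1e-9] <- 1e-9
    local_speed <- speed / (1 + speed * sqrt(swing))
    step <- pmin(local_speed * fmag, 10) / fmag
    pos <- pos + force * step
    old_force <- force
  }
  rownames(pos) <- nodes; colnames(pos) <- c("x", "y")
  pos
}

#' Write adjacency edges or the full symmetric matrix
#'
#' `write_adjacency_edges` writes a three-column TSV (marker_a, marker_b,
#' weight). `adjacency_matrix` returns the dense symmetric matrix over the
#' node universe (marker-sorted), the form in which the graph is usually
#' deposited.
#'
#' @param graph An [build_adjacency()] result.
#' @param path Output TSV path.
#' @export
write_adjacency_edges <- function(graph, path) {
  utils::write.table(graph$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE,
                     col.names = c("marker_a", "marker_b", "weight"))
  invisible(path)
}

#' @rdname write_adjacency_edges
#' @export
adjacency_matrix <- function(graph) {
  n <- length(graph$nodes)
  m <- matrix(0L, n, n, dimnames = list(graph$nodes, graph$nodes))
  if (nrow(graph$edges) > 0L) {
    i <- match(graph$edges$a, graph$nodes)
    j <- match(graph$edges$b, graph$nodes)
    m[cbind(i, j)] <- graph$edges$weight
    m[cbind(j, i)] <- graph$edges$weight
  }
  m
}
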