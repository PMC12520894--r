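# Dense-module (molecular-complex) detection: seed-and-expand clustering
# driven by k-core-weighted vertices, plus the module retention filter
# applied before downstream driver analysis.

graph_density_simple <- function(g) {
  n <- igraph::vcount(g)
  if (n < 2) return(0)
  2 * igraph::ecount(g) / (n * (n - 1))
}

#' MCODE vertex weighting
#'
#' Weights each node by the core-clustering coefficient: take the closed
#' neighborhood (the node, its neighbors and all induced edges), find its
#' highest k-core, and set `weight = k_max * density` of that core. Isolated
#' nodes weigh 0.
#'
#' @param net Simple undirected igraph object.
#' @return Named numeric vector of weights.
#' @export
mcode_vertex_weights <- function(net) {
  w <- numeric(igraph::vcount(net))
  names(w) <- igraph::V(net)$name
  adj <- igraph::adjacent_vertices(net, igraph::V(net))
  for (i in seq_along(w)) {
    nb <- adj[[i]]
    if (length(nb) == 0) next
    sub <- igraph::induced_subgraph(net, c(i, as.integer(nb)))
    core <- igraph::coreness(sub)
    k_max <- max(core)
    core_sub <- igraph::induced_subgraph(sub, which(core >= k_max))
    if (igraph::vcount(core_sub) < 2) next
    w[i] <- k_max * graph_density_simple(core_sub)
  }
  w
}

# Iteratively strip nodes with within-complex degree < 2.
haircut_nodes <- function(net, members) {
  repeat {
    sub <- igraph::induced_subgraph(net, members)
    low <- igraph::degree(sub) < 2
    if (!any(low) || sum(!low) == 0) {
      if (any(low)) members <- members[!low]
      return(members)
    }
    members <- members[!low]
  }
}

module_cluster <- function(net, members, seed_name) {
  sub <- igraph::induced_subgraph(net, members)
  nodes <- sort(igraph::V(sub)$name)
  list(
    node_set = nodes,
    seed_node = seed_name,
    mcode_score = graph_density_simple(sub) * length(nodes),
    kcore_max = max(igraph::coreness(sub)),
    avg_within_degree = mean(igraph::degree(sub))
  )
}

#' Find dense complexes by seeded expansion
#'
#' Processes nodes as seeds in order of decreasing vertex weight (ties
#' broken lexicographically by symbol). From each unvisited seed, a
#' breadth-first expansion adds unvisited neighbors whose weight is at least
#' `seed_weight * (1 - vwp)`. An optional haircut then iteratively removes
#' nodes with fewer than two connections inside the complex. Complexes with
#' fewer than two nodes are discarded; every node belongs to at most one
#' complex.
#'
#' @param net Simple undirected igraph object.
#' @param weights Optional precomputed [mcode_vertex_weights()].
#' @param vwp Vertex weight percentage in `[0, 1)` controlling expansion
#'   (default 0.2).
#' @param haircut Remove degree-<2 members iteratively (default TRUE).
#' @return List of module clusters, each a list with `node_set`,
#'   `seed_node`, `mcode_score` (density x size), `kcore_max`,
#'   `avg_within_degree`; ordered by decreasing score.
#' @export
mcode_find_complexes <- function(net, weights = NULL, vwp = 0.2,
                                 haircut = TRUE) {
  if (vwp < 0 || vwp >= 1) stop("`vwp` must lie in [0, 1)")
  if (is.null(weights)) weights <- mcode_vertex_weights(net)
  vnames <- igraph::V(net)$name
  weights <- weights[vnames]
  adj <- igraph::adjacent_vertices(net, igraph::V(net))
  seed_order <- order(-weights, vnames)
  visited <- logical(length(vnames))
  clusters <- list()
  for (s in seed_order) {
    if (visited[s] || weights[s] <= 0) next
    thr <- weights[s] * (1 - vwp)
    members <- s
    visited[s] <- TRUE
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (u in as.integer(adj[[v]])) {
        if (!visited[u] && weights[u] >= thr) {
          visited[u] <- TRUE
          members <- c(members, u)
          queue <- c(queue, u)
        }
      }
    }
    if (haircut) members <- haircut_nodes(net, members)
    if (length(members) >= 2)
      clusters[[length(clusters) + 1L]] <-
        module_cluster(net, members, vnames[s])
  }
  clusters[order(-vapply(clusters, `[[`, numeric(1), "mcode_score"),
                 vapply(clusters, `[[`, character(1), "seed_node"))]
}

#' Retain modules that pass the k-core and degree gates
#'
#' Keeps complexes whose module subgraph has a k-core number strictly
#' greater than `kcore_min_exclusive` and a within-module degree statistic
#' strictly greater than `degree_min_exclusive`. The degree statistic is the
#' mean within-module degree by default; `min` (every node) and `seed`
#' (seed node only) are available alternatives.
#'
#' @param clusters List of module clusters from [mcode_find_complexes()].
#' @param kcore_min_exclusive Retain if `kcore_max >` this (default 5).
#' @param degree_min_exclusive Retain if degree statistic `>` this
#'   (default 5).
#' @param degree_stat One of "mean", "min", "seed".
#' @param net igraph object; required for `degree_stat` other than "mean".
#' @return Filtered list, ordered by decreasing `mcode_score`.
#' @export
filter_modules <- function(clusters, kcore_min_exclusive = 5,
                           degree_min_exclusive = 5,
                           degree_stat = c("mean", "min", "seed"),
                           net = NULL) {
  degree_stat <- match.arg(degree_stat)
  stat <- vapply(clusters, function(cl) {
    switch(degree_stat,
      mean = cl$avg_within_degree,
      min = ,
      seed = {
        if (is.null(net))
          stop("`net` is required for degree_stat = \"", degree_stat, "\"")
        sub <- igraph::induced_subgraph(net, cl$node_set)
        d <- igraph::degree(sub)
        if (degree_stat == "min") min(d) else
          unname(d[igraph::V(sub)$name == cl$seed_node])
      })
  }, numeric(1))
  keep <- vapply(clusters, `[[`, numeric(1), "kcore_max") >
    kcore_min_exclusive & stat > degree_min_exclusive
  out <- clusters[keep]
  out[order(-vapply(out, `[[`, numeric(1), "mcode_score"))]
}
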