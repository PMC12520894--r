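# Twelve node-centrality coefficients and the top-10 / >=5-of-12 consensus
# hub rule. Degree, betweenness and the local clustering coefficient come
# from igraph; the remaining coefficients (stress, radiality, harmonic
# closeness, eccentricity score, MNC, DMNC, MCC, BottleNeck, EPC) follow
# the hub-screening definitions used by network-biology hub panels and are
# implemented here directly.

centrality_metrics <- c("Degree", "Closeness", "Betweenness", "Stress",
                        "Eccentricity", "Radiality", "ClusteringCoefficient",
                        "MCC", "MNC", "DMNC", "EPC", "BottleNeck")

# Number of shortest paths between every ordered pair, by BFS layering.
shortest_path_counts <- function(net, d) {
  n <- nrow(d)
  A <- igraph::as_adjacency_matrix(net, sparse = TRUE)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    ds <- d[s, ]
    sig <- numeric(n)
    sig[s] <- 1
    maxd <- max(c(0, ds[is.finite(ds)]))
    l <- 1
    while (l <= maxd) {
      at <- which(ds == l)
      prev <- which(ds == l - 1)
      if (length(at) == 0) break
      sig[at] <- as.numeric(A[at, prev, drop = FALSE] %*% sig[prev])
      l <- l + 1
    }
    sigma[s, ] <- sig
  }
  sigma
}

# Stress of v: number of shortest paths (over all unordered pairs s,t with
# s != v != t) passing through v.
stress_centrality <- function(d, sigma) {
  n <- nrow(d)
  vapply(seq_len(n), function(v) {
    idx <- which(is.finite(d[, v]) & seq_len(n) != v)
    if (length(idx) < 2) return(0)
    dsub <- d[idx, idx, drop = FALSE]
    cond <- outer(d[idx, v], d[v, idx], "+") == dsub
    m <- outer(sigma[idx, v], sigma[v, idx]) * cond
    diag(m) <- 0
    sum(m) / 2
  }, numeric(1))
}

# Maximum neighborhood component (MNC) and its density-modulated form
# (DMNC = E/V^1.7 of the largest connected component of the open
# neighborhood subgraph).
mnc_dmnc <- function(net) {
  vnames <- igraph::V(net)$name
  adj <- igraph::adjacent_vertices(net, igraph::V(net))
  mnc <- numeric(length(vnames))
  dmnc <- numeric(length(vnames))
  for (i in seq_along(vnames)) {
    nb <- as.integer(adj[[i]])
    if (length(nb) == 0) next
    sub <- igraph::induced_subgraph(net, nb)
    comps <- igraph::components(sub)
    best_size <- max(comps$csize)
    cand <- which(comps$csize == best_size)
    best_edges <- -1
    for (cm in cand) {
      csub <- igraph::induced_subgraph(sub, which(comps$membership == cm))
      if (igraph::ecount(csub) > best_edges) best_edges <- igraph::ecount(csub)
    }
    mnc[i] <- best_size
    dmnc[i] <- best_edges / best_size^1.7
  }
  list(mnc = mnc, dmnc = dmnc)
}

# Maximal clique centrality: sum over the maximal cliques (size >= 2)
# containing v of (|clique| - 1)!.  When v's neighborhood holds no edges
# its maximal cliques are exactly its edges, so MCC(v) = degree(v);
# isolated nodes score 0.
mcc_centrality <- function(net) {
  scores <- numeric(igraph::vcount(net))
  cliques <- igraph::max_cliques(net, min = 2)
  for (cl in cliques) {
    idx <- as.integer(cl)
    scores[idx] <- scores[idx] + factorial(length(idx) - 1)
  }
  scores
}

# BottleNeck: over the BFS shortest-path tree rooted at each source, v
# collects one point when its subtree holds more than a quarter of the
# tree's nodes. Parent choice (among equally near candidates) is the
# lexicographically smallest symbol, making the trees deterministic.
bottleneck_centrality <- function(net, d) {
  n <- nrow(d)
  vnames <- igraph::V(net)$name
  name_rank <- rank(vnames, ties.method = "first")
  adj <- igraph::adjacent_vertices(net, igraph::V(net))
  adj_sorted <- lapply(adj, function(nb) {
    nb <- as.integer(nb)
    nb[order(name_rank[nb])]
  })
  score <- numeric(n)
  for (s in seq_len(n)) {
    ds <- d[s, ]
    comp <- which(is.finite(ds))
    n_tree <- length(comp)
    if (n_tree == 1) {
      score[s] <- score[s] + 1  # root subtree is the whole (trivial) tree
      next
    }
    parent <- integer(n)
    for (w in comp) {
      if (w == s) next
      nb <- adj_sorted[[w]]
      parent[w] <- nb[which(ds[nb] == ds[w] - 1)[1]]
    }
    size <- integer(n)
    size[comp] <- 1L
    for (w in comp[order(-ds[comp])]) {
      if (w == s) next
      size[parent[w]] <- size[parent[w]] + size[w]
    }
    score[comp] <- score[comp] + (size[comp] > n_tree / 4)
  }
  score
}

# Edge percolated component: mean, over random edge-retention realizations,
# of the number of other nodes still reachable from v.
epc_centrality <- function(net, realizations, retention, seed) {
  n <- igraph::vcount(net)
  m <- igraph::ecount(net)
  if (m == 0) return(numeric(n))
  withr::with_seed(seed, {
    total <- numeric(n)
    for (r in seq_len(realizations)) {
      keep <- which(stats::runif(m) < retention)
      sub <- igraph::subgraph_from_edges(net, keep, delete.vertices = FALSE)
      comps <- igraph::components(sub)
      total <- total + comps$csize[comps$membership] - 1
    }
    total / realizations
  })
}

#' Compute twelve node-centrality coefficients
#'
#' Returns, for every node: Degree; Closeness (harmonic form, the sum of
#' reciprocal distances to reachable nodes, so disconnected graphs are
#' well defined); Betweenness; Stress (number of shortest paths through the
#' node); Eccentricity score (reciprocal of the node's eccentricity within
#' its component, so higher = more central; the raw eccentricity is also
#' returned); Radiality; local ClusteringCoefficient; MCC (maximal clique
#' centrality); MNC (maximum neighborhood component size); DMNC (density of
#' the maximum neighborhood component, E/V^1.7); EPC (edge percolated
#' component, averaged over seeded random edge-retention realizations); and
#' BottleNeck (shortest-path-tree subtree dominance). Isolated nodes score
#' 0 on all path-based coefficients.
#'
#' @param net Simple undirected igraph object with named vertices.
#' @param epc_realizations Number of EPC percolation realizations.
#' @param epc_retention Independent edge-retention probability for EPC.
#' @param seed RNG seed for the EPC realizations (recorded in the output).
#' @return data.frame with column `node`, one column per coefficient and
#'   `Eccentricity_raw`; attributes `seed`, `epc_realizations`,
#'   `epc_retention`.
#' @export
compute_centralities <- function(net, epc_realizations = 1000,
                                 epc_retention = 0.5, seed = 1) {
  n <- igraph::vcount(net)
  if (n < 1) stop("network needs at least one node")
  vnames <- igraph::V(net)$name
  d <- igraph::distances(net)
  fin <- is.finite(d) & d > 0

  degree <- as.numeric(igraph::degree(net))
  closeness <- rowSums(ifelse(fin, 1 / d, 0))
  betweenness <- as.numeric(igraph::betweenness(net, directed = FALSE))
  sigma <- shortest_path_counts(net, d)
  stress <- stress_centrality(d, sigma)

  ecc_raw <- apply(d, 1, function(r) {
    r <- r[is.finite(r)]
    if (length(r) <= 1) 0 else max(r)
  })
  ecc_score <- ifelse(ecc_raw > 0, 1 / ecc_raw, 0)

  comps <- igraph::components(net)
  radiality <- numeric(n)
  for (cm in seq_len(comps$no)) {
    members <- which(comps$membership == cm)
    sz <- length(members)
    if (sz < 2) next
    dsub <- d[members, members, drop = FALSE]
    diam <- max(dsub)
    radiality[members] <- (rowSums(diam + 1 - dsub) - (diam + 1)) / (sz - 1)
  }

  clustering <- igraph::transitivity(net, type = "local", isolates = "zero")
  nd <- mnc_dmnc(net)
  mcc <- mcc_centrality(net)
  epc <- epc_centrality(net, epc_realizations, epc_retention, seed)
  bottleneck <- bottleneck_centrality(net, d)

  out <- data.frame(
    node = vnames,
    Degree = degree, Closeness = closeness, Betweenness = betweenness,
    Stress = stress, Eccentricity = ecc_score, Radiality = radiality,
    ClusteringCoefficient = clustering, MCC = mcc, MNC = nd$mnc,
    DMNC = nd$dmnc, EPC = epc, BottleNeck = bottleneck,
    Eccentricity_raw = ecc_raw,
    stringsAsFactors = FALSE
  )
  attr(out, "seed") <- seed
  attr(out, "epc_realizations") <- epc_realizations
  attr(out, "epc_retention") <- epc_retention
  rownames(out) <- NULL
  out
}

#' Top-k node sets per centrality coefficient
#'
#' Ranks nodes by decreasing score for each coefficient and returns the set
#' of nodes with competition rank <= k. Ties at the boundary are all
#' included, so a set may exceed k members; with all scores equal the set
#' is the whole node set.
#'
#' @param table Centrality table from [compute_centralities()].
#' @param k Rank cutoff (default 10).
#' @return Named list of character vectors, one per coefficient.
#' @export
top_k_sets <- function(table, k = 10) {
  if (nrow(table) <= k)
    message("network has <= k nodes; every top-k set is the full node set")
  sets <- lapply(centrality_metrics, function(metric) {
    r <- rank(-table[[metric]], ties.method = "min")
    sort(table$node[r <= k])
  })
  names(sets) <- centrality_metrics
  sets
}

#' Consensus hub calling
#'
#' Counts, per node, the number of per-coefficient top-k sets it belongs
#' to; nodes appearing in at least `min_metrics` of the twelve sets are
#' called hubs.
#'
#' @param top_sets Named list from [top_k_sets()] (all twelve coefficients).
#' @param min_metrics Minimum number of memberships (default 5).
#' @return data.frame with `node`, `n_top_memberships`, one logical column
#'   per coefficient and `is_hub`; sorted by decreasing membership count,
#'   then node.
#' @export
call_hubs <- function(top_sets, min_metrics = 5) {
  if (!all(centrality_metrics %in% names(top_sets)))
    stop("`top_sets` must contain all twelve coefficient sets")
  nodes <- sort(unique(unlist(top_sets, use.names = FALSE)))
  memb <- vapply(centrality_metrics,
                 function(metric) nodes %in% top_sets[[metric]],
                 logical(length(nodes)))
  if (length(nodes) == 1) memb <- matrix(memb, nrow = 1,
                                         dimnames = list(NULL, centrality_metrics))
  counts <- rowSums(memb)
  out <- data.frame(node = nodes, n_top_memberships = as.integer(counts),
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(memb))
  out$is_hub <- counts >= min_metrics
  out <- out[order(-out$n_top_memberships, out$node), , drop = FALSE]
  rownames(out) <- NULL
  out
}
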