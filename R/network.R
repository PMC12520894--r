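#' Build the DEG interaction network
#'
#' Induces the subgraph of a user-supplied interactome on the DEG symbols:
#' the node set is the full set of DEG symbols (isolated DEGs are kept as
#' singleton nodes so they count towards connected components), the edge set
#' is every interactome edge with both endpoints among the DEGs. The graph
#' is simple and undirected; self-loops and duplicate edges are collapsed,
#' and edges touching symbols outside the DEG set are dropped (their count
#' is reported in a message). Node attributes `log2fc` and `direction` are
#' carried over from the DEG table.
#'
#' @param degs data.frame of DEG records with `symbol`, `log2fc`,
#'   `direction` columns (typically the `kept` table of
#'   [filter_annotated()]).
#' @param interactome Two-column matrix/data.frame of interacting symbol
#'   pairs, or the result of [read_sif()].
#' @return An `igraph` object.
#' @export
build_network <- function(degs, interactome) {
  if (!is.data.frame(degs) || nrow(degs) == 0)
    stop("`degs` must be a non-empty data.frame of DEG records")
  edges <- as.matrix(interactome[, 1:2])
  mode(edges) <- "character"
  symbols <- unique(degs$symbol)
  inside <- edges[, 1] %in% symbols & edges[, 2] %in% symbols
  n_drop <- sum(!inside)
  if (n_drop > 0)
    message(n_drop, " interactome edge(s) with endpoints outside the DEG ",
            "set dropped")
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges[inside, 1], to = edges[inside, 2],
               stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = symbols, stringsAsFactors = FALSE)
  )
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  first <- degs[!duplicated(degs$symbol), , drop = FALSE]
  ord <- match(igraph::V(g)$name, first$symbol)
  igraph::V(g)$log2fc <- first$log2fc[ord]
  igraph::V(g)$direction <- first$direction[ord]
  g
}

#' Topology report of a gene network
#'
#' Computes the standard whole-network statistics: node and edge counts,
#' average number of neighbors (mean degree), network diameter and
#' characteristic path length (both over the largest connected component, so
#' they stay finite on disconnected graphs), clustering coefficient, number
#' of connected components, and the power-law fit of the degree
#' distribution. The clustering coefficient is reported two ways: averaged
#' over nodes of degree >= 2 (`clustering_coefficient`) and averaged over
#' all nodes with degree < 2 scored as 0 (`clustering_coefficient_all`).
#'
#' @param net igraph object.
#' @return list of named statistics.
#' @export
topology_report <- function(net) {
  n <- igraph::vcount(net)
  if (n < 1) stop("network needs at least one node")
  comps <- igraph::components(net)
  big <- igraph::induced_subgraph(
    net, which(comps$membership == which.max(comps$csize)))
  deg <- igraph::degree(net)
  loc <- igraph::transitivity(net, type = "local", isolates = "zero")
  eligible <- deg >= 2
  fit <- if (sum(deg >= 1) >= 10) scale_free_fit(net) else
    list(gamma = NA_real_, r2 = NA_real_)
  list(
    n_nodes = n,
    n_edges = igraph::ecount(net),
    avg_neighbors = mean(deg),
    diameter = if (igraph::vcount(big) > 1)
      igraph::diameter(big, unconnected = FALSE) else 0,
    char_path_length = if (igraph::vcount(big) > 1)
      igraph::mean_distance(big) else 0,
    clustering_coefficient = if (any(eligible)) mean(loc[eligible]) else 0,
    clustering_coefficient_all = mean(loc),
    n_connected_components = comps$no,
    powerlaw_gamma = fit$gamma,
    powerlaw_r2 = fit$r2
  )
}

#' Scale-free check of the degree distribution
#'
#' Fits a least-squares line to `log10 P(k)` versus `log10 k` over the
#' observed (nonzero-count) degrees `k >= 1` and reports the power-law
#' exponent `gamma = -slope` and the fit's R-squared. The network is flagged
#' scale-free when R-squared >= `r2_min` and gamma lies in `gamma_range`.
#' Degree distributions with fewer than three distinct degree values cannot
#' support the regression and are flagged not fittable.
#'
#' @param net igraph object with at least 10 nodes of degree >= 1.
#' @param r2_min Minimum R-squared (default 0.8).
#' @param gamma_range Admissible exponent range (default `c(1, 4)`).
#' @return list with `gamma`, `r2`, `is_scale_free`, `reason`.
#' @export
scale_free_fit <- function(net, r2_min = 0.8, gamma_range = c(1, 4)) {
  deg <- igraph::degree(net)
  deg <- deg[deg >= 1]
  if (length(deg) < 10)
    stop("scale-free fit needs >= 10 nodes with degree >= 1")
  tab <- table(deg)
  k <- as.numeric(names(tab))
  pk <- as.numeric(tab) / length(deg)
  if (length(k) < 3)
    return(list(gamma = NA_real_, r2 = NA_real_, is_scale_free = FALSE,
                reason = "degenerate degree distribution (<3 distinct degrees)"))
  fit <- stats::lm(log10(pk) ~ log10(k))
  r2 <- summary(fit)$r.squared
  gamma <- -unname(stats::coef(fit)[2])
  ok <- is.finite(r2) && r2 >= r2_min &&
    gamma >= gamma_range[1] && gamma <= gamma_range[2]
  list(gamma = gamma, r2 = r2, is_scale_free = ok,
       reason = if (ok) "ok" else "fit below threshold or gamma out of range")
}
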