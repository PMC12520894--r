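# Independent brute-force oracles used to cross-check the package's graph
# statistics. Everything here works on a plain named adjacency matrix and
# deliberately avoids the code paths (and the igraph routines) used by the
# implementation: distances by naive BFS, shortest paths by exhaustive
# simple-path enumeration, cliques by subset enumeration, k-cores by
# peeling.

rand_adj <- function(n, p) {
  a <- matrix(0L, n, n, dimnames = list(LETTERS[1:n], LETTERS[1:n]))
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (stats::runif(1) < p) a[i, j] <- a[j, i] <- 1L
  a
}

adj_to_graph <- function(a) {
  igraph::graph_from_adjacency_matrix(a, mode = "undirected")
}

o_bfs_dist <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0
    frontier <- s
    lev <- 0
    while (length(frontier) > 0) {
      lev <- lev + 1
      nxt <- unique(unlist(lapply(frontier, function(v) which(a[v, ] == 1))))
      nxt <- nxt[!is.finite(d[s, nxt])]
      d[s, nxt] <- lev
      frontier <- nxt
    }
  }
  d
}

# All simple paths from s to t, as lists of vertex indices.
o_simple_paths <- function(a, s, t) {
  out <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == t) {
      out[[length(out) + 1L]] <<- path
      return()
    }
    for (u in which(a[v, ] == 1)) if (!u %in% path) walk(c(path, u))
  }
  walk(s)
  out
}

# Betweenness and stress from exhaustive shortest-path enumeration.
o_betweenness_stress <- function(a) {
  n <- nrow(a)
  d <- o_bfs_dist(a)
  bet <- numeric(n)
  str <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    if (!is.finite(d[s, t])) next
    paths <- Filter(function(p) length(p) - 1 == d[s, t],
                    o_simple_paths(a, s, t))
    for (v in setdiff(seq_len(n), c(s, t))) {
      through <- sum(vapply(paths, function(p) v %in% p, logical(1)))
      bet[v] <- bet[v] + through / length(paths)
      str[v] <- str[v] + through
    }
  }
  list(betweenness = bet, stress = str)
}

o_components <- function(a) {
  n <- nrow(a)
  comp <- rep(0L, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0) next
    cur <- cur + 1L
    frontier <- s
    comp[s] <- cur
    while (length(frontier) > 0) {
      nxt <- unique(unlist(lapply(frontier, function(v) which(a[v, ] == 1))))
      nxt <- nxt[comp[nxt] == 0]
      comp[nxt] <- cur
      frontier <- nxt
    }
  }
  comp
}

o_closeness <- function(a) {
  d <- o_bfs_dist(a)
  vapply(seq_len(nrow(a)), function(v) {
    x <- d[v, -v]
    sum(1 / x[is.finite(x) & x > 0])
  }, numeric(1))
}

o_eccentricity_score <- function(a) {
  d <- o_bfs_dist(a)
  vapply(seq_len(nrow(a)), function(v) {
    x <- d[v, ][is.finite(d[v, ])]
    if (length(x) <= 1) 0 else 1 / max(x)
  }, numeric(1))
}

o_radiality <- function(a) {
  d <- o_bfs_dist(a)
  comp <- o_components(a)
  n <- nrow(a)
  vapply(seq_len(n), function(v) {
    members <- which(comp == comp[v])
    if (length(members) < 2) return(0)
    diam <- max(d[members, members])
    sum(diam + 1 - d[v, setdiff(members, v)]) / (length(members) - 1)
  }, numeric(1))
}

o_mnc_dmnc <- function(a) {
  n <- nrow(a)
  mnc <- numeric(n)
  dmnc <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(a[v, ] == 1)
    if (length(nb) == 0) next
    sub <- a[nb, nb, drop = FALSE]
    comp <- o_components(sub)
    sizes <- tabulate(comp)
    best <- max(sizes)
    edges <- max(vapply(which(sizes == best), function(cm) {
      m <- sub[comp == cm, comp == cm, drop = FALSE]
      sum(m) / 2
    }, numeric(1)))
    mnc[v] <- best
    dmnc[v] <- edges / best^1.7
  }
  list(mnc = mnc, dmnc = dmnc)
}

# Maximal cliques by subset enumeration (n <= ~12).
o_maximal_cliques <- function(a) {
  n <- nrow(a)
  is_clique <- function(set) {
    if (length(set) < 2) return(FALSE)
    all(a[set, set][upper.tri(diag(length(set)))] == 1)
  }
  cliques <- list()
  for (mask in seq_len(2^n - 1)) {
    set <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(set) < 2 || !is_clique(set)) next
    extendable <- any(vapply(setdiff(seq_len(n), set),
                             function(u) all(a[u, set] == 1), logical(1)))
    if (!extendable) cliques[[length(cliques) + 1L]] <- set
  }
  cliques
}

o_mcc <- function(a) {
  scores <- numeric(nrow(a))
  for (cl in o_maximal_cliques(a))
    scores[cl] <- scores[cl] + factorial(length(cl) - 1)
  scores
}

# Largest k with a nonempty k-core, by peeling.
o_max_kcore <- function(a) {
  n <- nrow(a)
  best <- 0
  for (k in seq_len(n)) {
    keep <- rep(TRUE, n)
    repeat {
      deg <- rowSums(a[keep, keep, drop = FALSE])
      low <- deg < k
      if (!any(low) || !any(keep)) break
      keep[which(keep)[low]] <- FALSE
      if (!any(keep)) break
    }
    if (any(keep)) best <- k else break
  }
  best
}

# Benjamini-Hochberg step-up rejection set.
o_bh_reject <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  ok <- which(ps <= seq_len(m) * alpha / m)
  if (length(ok) == 0) return(logical(m))
  p <= ps[max(ok)]
}

# Small named graph from an edge string like "A-B,B-C".
edge_graph <- function(spec, isolated = character(0)) {
  pairs <- do.call(rbind, strsplit(strsplit(spec, ",")[[1]], "-"))
  igraph::graph_from_data_frame(
    data.frame(from = pairs[, 1], to = pairs[, 2]),
    directed = FALSE,
    vertices = data.frame(name = union(as.vector(pairs), isolated)))
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

best_jaccard <- function(truth_set, clusters) {
  if (length(clusters) == 0) return(0)
  max(vapply(clusters, function(m) jaccard(m$node_set, truth_set),
             numeric(1)))
}

# BottleNeck oracle: per source, rebuild the deterministic BFS tree
# (lexicographic parent) and count subtree sizes by walking every node's
# parent chain up to the root.
o_bottleneck <- function(a) {
  n <- nrow(a)
  d <- o_bfs_dist(a)
  score <- numeric(n)
  for (s in seq_len(n)) {
    comp <- which(is.finite(d[s, ]))
    parent <- rep(NA_integer_, n)
    for (w in comp) {
      if (w == s) next
      cand <- which(a[w, ] == 1 & d[s, ] == d[s, w] - 1)
      parent[w] <- cand[order(rownames(a)[cand])][1]
    }
    size <- numeric(n)
    for (w in comp) {
      v <- w
      repeat {
        size[v] <- size[v] + 1
        if (v == s) break
        v <- parent[v]
      }
    }
    score[comp] <- score[comp] + (size[comp] > length(comp) / 4)
  }
  score
}

o_local_clustering <- function(a) {
  vapply(seq_len(nrow(a)), function(v) {
    nb <- which(a[v, ] == 1)
    if (length(nb) < 2) return(0)
    sum(a[nb, nb]) / 2 / choose(length(nb), 2)
  }, numeric(1))
}
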