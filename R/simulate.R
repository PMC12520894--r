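# Seeded synthetic-data generator: grouped expression matrices with planted
# differential expression, scale-free interactomes with planted dense
# modules and high-centrality hubs, and bundled study fixtures with ground
# truth, so every downstream stage is testable without external data.

#' Simulation configuration
#'
#' Collects every knob of the generator with defaults emulating the study
#' conditions: ~22,141 transcripts profiled in 3 biological replicates per
#' group, ~6% of genes differentially expressed, planted linear fold
#' changes drawn lognormal (median 2.8, shape 0.5) and resampled until they
#' clear the 2-fold gate -- so most planted DEGs pass the fold-change
#' threshold but only a tail reaches outlier magnitude -- per-observation
#' Gaussian noise of 0.25 log2 units, a preferential-attachment interactome
#' over the full gene panel with planted near-clique modules, ten planted
#' hubs each wired to a random 20% of all nodes, and 18 planted extreme
#' outlier DEGs with |log2FC| of at least 4.
#'
#' @param n_genes Number of genes/transcripts.
#' @param groups Named integer vector: replicate count per group label (at
#'   least two groups, at least two replicates each). Planted effects are
#'   applied to the last group relative to the others.
#' @param deg_fraction Fraction of genes planted as DEGs.
#' @param effect_meanlog,effect_sdlog Lognormal parameters of the planted
#'   linear fold change (resampled until linear FC >= 2).
#' @param down_fraction Probability a planted DEG is downregulated.
#' @param noise_sd Per-observation Gaussian noise, log2 units.
#' @param network_size Interactome node count (default: `n_genes`).
#' @param attachment_m Edges added per node in preferential-attachment
#'   growth (>= 1).
#' @param planted_modules List of `c(size, within_density)` pairs.
#' @param planted_hubs Number of planted high-centrality hubs.
#' @param hub_attach_fraction Fraction of all nodes each hub is wired to.
#' @param planted_outliers Number of planted extreme-fold-change DEGs.
#' @param outlier_floor Minimum |log2FC| of planted outliers.
#' @param uncharacterized_fraction Fraction of genes flagged as
#'   uncharacterized / lncRNA / not protein-annotated in the annotation
#'   table.
#' @param seed RNG seed fixing every downstream draw.
#' @return Validated list of class `ccdr_sim_config`.
#' @export
simulation_config <- function(n_genes = 22141,
                              groups = c(GV_startpoint = 3, MII_endpoint = 3),
                              deg_fraction = 0.06,
                              effect_meanlog = log(2.8),
                              effect_sdlog = 0.5,
                              down_fraction = 0.54,
                              noise_sd = 0.25,
                              network_size = NULL,
                              attachment_m = 3,
                              planted_modules = list(c(15, 0.9), c(13, 0.9),
                                                     c(12, 0.9), c(11, 0.9),
                                                     c(10, 0.9), c(9, 0.9),
                                                     c(8, 0.9), c(8, 0.9)),
                              planted_hubs = 10,
                              hub_attach_fraction = 0.2,
                              planted_outliers = 18,
                              outlier_floor = 4,
                              uncharacterized_fraction = 0.16,
                              seed = 1) {
  if (is.null(network_size)) network_size <- n_genes
  cfg <- list(n_genes = as.integer(n_genes), groups = groups,
              deg_fraction = deg_fraction, effect_meanlog = effect_meanlog,
              effect_sdlog = effect_sdlog, down_fraction = down_fraction,
              noise_sd = noise_sd, network_size = as.integer(network_size),
              attachment_m = as.integer(attachment_m),
              planted_modules = planted_modules,
              planted_hubs = as.integer(planted_hubs),
              hub_attach_fraction = hub_attach_fraction,
              planted_outliers = as.integer(planted_outliers),
              outlier_floor = outlier_floor,
              uncharacterized_fraction = uncharacterized_fraction,
              seed = as.integer(seed))
  stopifnot(cfg$n_genes > 0, cfg$network_size > 0, cfg$attachment_m >= 1,
            cfg$deg_fraction >= 0, cfg$deg_fraction <= 1,
            cfg$noise_sd >= 0, cfg$down_fraction >= 0,
            cfg$down_fraction <= 1, cfg$planted_hubs >= 0,
            cfg$planted_outliers >= 0, cfg$outlier_floor >= 0,
            cfg$uncharacterized_fraction >= 0,
            cfg$uncharacterized_fraction < 1)
  if (length(cfg$groups) < 2) stop("need at least two groups")
  if (any(cfg$groups < 2))
    stop("every group needs >= 2 replicates (variance undefined otherwise)")
  if (round(cfg$deg_fraction * cfg$n_genes) < cfg$planted_outliers)
    stop("cannot plant more outliers than DEGs")
  if (cfg$network_size <= cfg$attachment_m)
    stop("network_size must exceed attachment_m")
  for (pm in cfg$planted_modules) {
    if (pm[2] > 1) stop("module within-density cannot exceed 1")
    if (pm[1] > cfg$network_size)
      stop("planted module larger than the network")
  }
  class(cfg) <- "ccdr_sim_config"
  cfg
}

gene_ids <- function(n) sprintf("G%06d", seq_len(n))

#' Simulate a grouped expression matrix with known DEG truth
#'
#' Baseline log2 intensities are Gaussian per gene; planted DEGs receive a
#' group-mean offset in the last group equal to their planted signed log2
#' fold change (drawn from the configured effect distribution, always at
#' least 1 log2 unit, i.e. linear FC >= 2); planted outlier DEGs receive
#' |log2FC| of at least `outlier_floor`. Observation noise is i.i.d.
#' Gaussian, so with `noise_sd = 0` the empirical group-mean difference of
#' every planted DEG equals its planted value exactly.
#'
#' @param config A [simulation_config()].
#' @return list with `expression` (a [expression_set()]) and `truth`
#'   (`true_deg_ids`, `true_directions`, `true_outlier_ids`,
#'   `planted_log2fc`).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "ccdr_sim_config"))
  withr::with_seed(config$seed, {
    ids <- gene_ids(config$n_genes)
    reps <- config$groups
    grp <- rep(names(reps), times = reps)
    sample_ids <- paste0(grp, "_r", unlist(lapply(reps, seq_len)))
    n_deg <- round(config$deg_fraction * config$n_genes)
    deg_idx <- sort(sample.int(config$n_genes, n_deg))
    out_idx <- if (config$planted_outliers > 0)
      sort(sample(deg_idx, config$planted_outliers)) else integer(0)

    effect <- numeric(config$n_genes)
    if (n_deg > 0) {
      mag <- numeric(n_deg)
      todo <- seq_len(n_deg)
      while (length(todo) > 0) {
        draw <- stats::rlnorm(length(todo), config$effect_meanlog,
                              config$effect_sdlog)
        ok <- draw >= 2
        mag[todo[ok]] <- log2(draw[ok])
        todo <- todo[!ok]
      }
      sign <- ifelse(stats::runif(n_deg) < config$down_fraction, -1, 1)
      effect[deg_idx] <- sign * mag
      if (length(out_idx) > 0)
        effect[out_idx] <- sign[match(out_idx, deg_idx)] *
          (config$outlier_floor + stats::rexp(length(out_idx), rate = 2))
    }

    baseline <- stats::rnorm(config$n_genes, mean = 7, sd = 1.5)
    values <- matrix(baseline, nrow = config$n_genes, ncol = length(grp))
    last_group <- names(reps)[length(reps)]
    values[, grp == last_group] <- values[, grp == last_group] + effect
    if (config$noise_sd > 0)
      values <- values + matrix(stats::rnorm(length(values), 0,
                                             config$noise_sd),
                                nrow = config$n_genes)
    dimnames(values) <- list(ids, sample_ids)
    groups <- stats::setNames(grp, sample_ids)
    truth <- list(
      true_deg_ids = ids[deg_idx],
      true_directions = stats::setNames(
        ifelse(effect[deg_idx] >= 0, "up", "down"), ids[deg_idx]),
      true_outlier_ids = ids[out_idx],
      planted_log2fc = stats::setNames(effect, ids)
    )
    list(expression = expression_set(values, groups), truth = truth)
  })
}

# Raise the within-density of the induced subgraph on `nodes` to `density`
# by adding uniformly chosen missing pairs.
raise_module_density <- function(g, nodes, density) {
  s <- length(nodes)
  pairs <- utils::combn(nodes, 2)
  eid <- igraph::get_edge_ids(g, as.vector(pairs))
  missing <- which(eid == 0)
  target <- ceiling(density * s * (s - 1) / 2)
  need <- target - (ncol(pairs) - length(missing))
  if (need > 0) {
    pick <- if (need >= length(missing)) missing else
      sample(missing, need)
    g <- igraph::add_edges(g, as.vector(pairs[, pick, drop = FALSE]))
  }
  g
}

#' Simulate a scale-free interactome with planted structure
#'
#' Grows a preferential-attachment backbone, then plants dense modules
#' (raising the within-density of chosen node subsets to the requested
#' level; backbone edges joining two distinct planted modules are removed,
#' so the planted communities are separated by construction) and
#' high-centrality hubs (each wired to a random fraction of all nodes).
#' Node labels are gene symbols consistent with [simulate_expression()]
#' output.
#'
#' @param config A [simulation_config()].
#' @param symbols Optional vector of `network_size` node symbols (default:
#'   the first `network_size` generated gene ids).
#' @param structure_symbols Optional pool of symbols on which modules and
#'   hubs are planted (must be a subset of `symbols`); by default the full
#'   node set.
#' @return list with `graph` (igraph), `edges` (two-column data.frame) and
#'   `truth` (`true_module_nodesets`, `true_hub_ids`).
#' @export
simulate_interactome <- function(config, symbols = NULL,
                                 structure_symbols = NULL) {
  stopifnot(inherits(config, "ccdr_sim_config"))
  n <- config$network_size
  if (is.null(symbols)) symbols <- gene_ids(config$n_genes)[seq_len(n)]
  if (length(symbols) != n || anyDuplicated(symbols))
    stop("`symbols` must supply network_size unique labels")
  if (is.null(structure_symbols)) structure_symbols <- symbols
  if (!all(structure_symbols %in% symbols))
    stop("`structure_symbols` must be nodes of the network")
  sizes <- vapply(config$planted_modules, `[`, numeric(1), 1)
  n_struct <- sum(sizes) + config$planted_hubs
  if (n_struct > length(structure_symbols))
    stop("not enough structure symbols to host planted modules and hubs")
  withr::with_seed(config$seed + 1L, {
    g <- igraph::sample_pa(n, m = config$attachment_m, directed = FALSE)
    g <- igraph::simplify(g)
    igraph::V(g)$name <- symbols
    pool <- sample(match(structure_symbols, symbols))
    module_sets <- list()
    module_nodes <- list()
    used <- 0
    for (pm in config$planted_modules) {
      nodes <- pool[(used + 1):(used + pm[1])]
      used <- used + pm[1]
      g <- raise_module_density(g, nodes, pm[2])
      module_nodes[[length(module_nodes) + 1L]] <- nodes
      module_sets[[length(module_sets) + 1L]] <- sort(symbols[nodes])
    }
    # planted modules are separated communities: backbone edges that
    # happen to join two distinct planted modules are removed so the
    # planted partition stays identifiable
    if (length(module_nodes) >= 2) {
      for (i in 2:length(module_nodes)) for (j in seq_len(i - 1)) {
        cross <- as.matrix(expand.grid(module_nodes[[i]],
                                       module_nodes[[j]]))
        eid <- igraph::get_edge_ids(g, as.vector(t(cross)))
        if (any(eid > 0)) g <- igraph::delete_edges(g, eid[eid > 0])
      }
    }
    hub_nodes <- if (config$planted_hubs > 0)
      pool[(used + 1):(used + config$planted_hubs)] else integer(0)
    n_wire <- floor(config$hub_attach_fraction * n)
    for (h in hub_nodes) {
      targets <- sample(setdiff(seq_len(n), h), n_wire)
      g <- igraph::add_edges(g, as.vector(rbind(h, targets)))
    }
    g <- igraph::simplify(g)
    el <- igraph::as_edgelist(g)
    list(graph = g,
         edges = data.frame(from = el[, 1], to = el[, 2],
                            stringsAsFactors = FALSE),
         truth = list(true_module_nodesets = module_sets,
                      true_hub_ids = sort(symbols[hub_nodes])))
  })
}

#' Generate a complete study fixture with ground truth
#'
#' Bundles an expression matrix, an annotation table and an interactome
#' whose planted structure is placed on genes that survive both the DEG
#' gates and the annotation filter, so the full pipeline can be scored
#' against known truth. A configurable fraction of genes is flagged as
#' uncharacterized (empty symbol), lncRNA, or lacking protein annotation;
#' planted modules, hubs and outliers are never flagged.
#'
#' @param config A [simulation_config()].
#' @return list with `expression`, `annotation`, `interactome` (list with
#'   `graph`, `edges`), `truth` (union of expression and network truth plus
#'   `removed_gene_ids`) and `config`.
#' @export
make_fixture_study <- function(config) {
  stopifnot(inherits(config, "ccdr_sim_config"))
  expr <- simulate_expression(config)
  ids <- rownames(expr$expression$values)
  truth <- expr$truth

  ann <- withr::with_seed(config$seed + 2L, {
    n_flag <- round(config$uncharacterized_fraction * config$n_genes)
    protected <- match(truth$true_outlier_ids, ids)
    flaggable <- setdiff(seq_along(ids), protected)
    flag <- sort(sample(flaggable, min(n_flag, length(flaggable))))
    cls <- sample(c("uncharacterized", "lncRNA", "no_protein"),
                  length(flag), replace = TRUE,
                  prob = c(0.5, 0.25, 0.25))
    ann <- data.frame(gene_id = ids, symbol = ids,
                      biotype = "protein_coding",
                      protein_annotated = TRUE, stringsAsFactors = FALSE)
    ann$symbol[flag[cls == "uncharacterized"]] <- ""
    ann$biotype[flag[cls == "lncRNA"]] <- "lncRNA"
    ann$biotype[flag[cls == "no_protein"]] <- "other"
    ann$protein_annotated[flag] <- FALSE
    ann
  })
  removed <- ann$gene_id[ann$symbol == "" | ann$biotype == "lncRNA" |
                           !ann$protein_annotated]
  kept_degs <- setdiff(truth$true_deg_ids, removed)

  n <- config$network_size
  symbols <- if (n >= length(ids)) ids[seq_len(n)] else
    withr::with_seed(config$seed + 3L, {
      extra <- setdiff(ids, kept_degs)
      need <- n - min(length(kept_degs), n)
      c(utils::head(kept_degs, n), sample(extra, max(0, need)))[seq_len(n)]
    })
  net <- simulate_interactome(config, symbols = symbols,
                              structure_symbols = intersect(kept_degs,
                                                            symbols))
  truth <- c(truth, net$truth)
  truth$removed_gene_ids <- removed
  list(expression = expr$expression, annotation = ann,
       interactome = net[c("graph", "edges")], truth = truth,
       config = config)
}
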