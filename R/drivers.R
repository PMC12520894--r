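# Highly modulated (outlier) DEG detection, shared/distinctive driver
# partitioning across pairwise comparisons, first-neighbor context, and the
# individual-gene fallback for comparisons with too few DEGs to support
# network analysis.

# Studentized deviation test of a single value against the Gaussian fitted
# to a reference sample of size m: t = (x - mean) / (sd * sqrt(1 + 1/m))
# with m - 1 degrees of freedom, two-sided.  The sqrt(1 + 1/m) term
# accounts for the estimated mean; the reference never contains the tested
# value, so multiple extreme values cannot mask one another.
deviation_p_value <- function(x, ref) {
  m <- length(ref)
  if (m < 3) return(NA_real_)
  s <- stats::sd(ref)
  if (s == 0) return(if (x == ref[1]) 1 else 0)
  t_stat <- abs(x - mean(ref)) / (s * sqrt(1 + 1 / m))
  2 * stats::pt(t_stat, df = m - 1, lower.tail = FALSE)
}

detect_outliers_subset <- function(x, alpha, fence_mult, rule) {
  n <- length(x)
  q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  fence_low <- q[1] - fence_mult * iqr
  fence_high <- q[2] + fence_mult * iqr
  outside <- x < fence_low | x > fence_high
  inliers <- x[!outside]
  deviation_p <- vapply(seq_len(n), function(i) {
    ref <- if (outside[i]) inliers else inliers[-match(x[i], inliers)]
    deviation_p_value(x[i], ref)
  }, numeric(1))
  deviates <- !is.na(deviation_p) & deviation_p < alpha
  is_outlier <- switch(rule,
    both = outside & deviates,
    fence = outside,
    deviation = deviates)
  data.frame(fence_low = fence_low, fence_high = fence_high,
             outside_fence = outside, deviation_p = deviation_p,
             is_outlier = is_outlier)
}

#' Detect highly modulated (outlier) DEGs
#'
#' Flags DEGs whose log2 fold change is an outlier of the comparison's fold
#' change distribution, by a two-stage rule: (i) the value falls outside
#' the interquartile-range fences `Q1 - fence_mult*IQR` /
#' `Q3 + fence_mult*IQR` (quartiles by the linear-interpolation, type-7,
#' convention); and (ii) a Grubbs-type studentized deviation test finds the
#' value to deviate significantly (`p < alpha`) from the Gaussian fitted to
#' the non-outlier (fence-inlier) values. Because the reference Gaussian
#' excludes every fence candidate, several simultaneous extremes cannot
#' mask one another. By default the test is run separately within up- and
#' downregulated DEGs (`split = "direction"`), since a fold-change
#' distribution pooled across directions is bimodal and its pooled fences
#' mask one-sided extremes; `split = "signed"` runs it once on the pooled
#' signed values.
#'
#' @param degs data.frame of DEG records (rows are assumed to already be
#'   DEGs); needs a `log2fc` column and `symbol` or `gene_id`.
#' @param alpha Significance gate for the deviation test (default 0.05).
#' @param fence_mult IQR fence multiplier (default 1.5).
#' @param split "direction" (default) or "signed".
#' @param rule "both" (fence AND deviation, default), "fence", or
#'   "deviation" -- the latter two apply a single criterion.
#' @return data.frame with `gene`, `log2fc`, `fence_low`, `fence_high`,
#'   `outside_fence`, `deviation_p`, `is_outlier` (input order preserved);
#'   attributes record the quartile type, split and rule.
#' @export
detect_outliers <- function(degs, alpha = 0.05, fence_mult = 1.5,
                            split = c("direction", "signed"),
                            rule = c("both", "fence", "deviation")) {
  split <- match.arg(split)
  rule <- match.arg(rule)
  if (nrow(degs) < 5)
    stop("fewer than 5 DEGs: quartiles are not meaningful; use ",
         "endpoint_marker_path() for small comparisons")
  gene <- if (!is.null(degs$symbol)) degs$symbol else degs$gene_id
  x <- degs$log2fc
  groups <- if (split == "direction")
    ifelse(x >= 0, "up", "down") else rep("all", length(x))
  out <- data.frame(gene = gene, log2fc = x, fence_low = NA_real_,
                    fence_high = NA_real_, outside_fence = FALSE,
                    deviation_p = NA_real_, is_outlier = FALSE,
                    stringsAsFactors = FALSE)
  for (grp in unique(groups)) {
    idx <- which(groups == grp)
    res <- detect_outliers_subset(x[idx], alpha, fence_mult, rule)
    out[idx, c("fence_low", "fence_high", "outside_fence", "deviation_p",
               "is_outlier")] <- res
  }
  attr(out, "quartile_type") <- 7
  attr(out, "split") <- split
  attr(out, "rule") <- rule
  out
}

#' Partition labeled gene sets into Venn regions
#'
#' Enumerates every nonempty region of the Venn diagram of 2-4 labeled
#' sets: for each combination of labels, the members belonging to exactly
#' those sets. Region names join the member labels with `"&"`.
#'
#' @param sets Named list of 2-4 character vectors.
#' @return list with `labels` and `regions` (named list of member vectors;
#'   empty regions omitted). Regions are disjoint and their union is the
#'   union of the inputs.
#' @export
venn_partition <- function(sets) {
  if (!is.list(sets) || length(sets) < 2 || length(sets) > 4)
    stop("`sets` must be a named list of 2-4 sets")
  if (is.null(names(sets)) || anyDuplicated(names(sets)) ||
      any(names(sets) == ""))
    stop("`sets` needs unique non-empty names")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  labels <- names(sets)
  members <- sort(unique(unlist(sets, use.names = FALSE)))
  if (length(members) == 0)
    return(list(labels = labels, regions = list()))
  memb <- vapply(sets, function(s) members %in% s, logical(length(members)))
  if (length(members) == 1)
    memb <- matrix(memb, nrow = 1, dimnames = list(NULL, labels))
  key <- apply(memb, 1, function(r) paste(labels[r], collapse = "&"))
  regions <- split(members, key)
  # order regions: singles first in label order, then larger intersections
  ord <- order(vapply(names(regions),
                      function(k) length(strsplit(k, "&", fixed = TRUE)[[1]]),
                      numeric(1)), names(regions))
  list(labels = labels, regions = regions[ord])
}

venn_exclusive <- function(partition, label) {
  r <- partition$regions[[label]]
  if (is.null(r)) character(0) else r
}

venn_shared_with <- function(partition, label) {
  keys <- names(partition$regions)
  hit <- vapply(keys, function(k) {
    parts <- strsplit(k, "&", fixed = TRUE)[[1]]
    label %in% parts && length(parts) > 1
  }, logical(1))
  sort(unique(unlist(partition$regions[hit], use.names = FALSE)))
}

#' Assemble the cross-comparison driver panel
#'
#' Partitions per-comparison outlier and hub sets into distinctive
#' (exclusive to one comparison) and shared (appearing in more than one)
#' drivers, and reports the panel size: the number of distinct genes in the
#' union of all distinctive outliers and distinctive hubs.
#'
#' @param outliers_by_comparison Named list (one element per comparison) of
#'   outlier gene vectors.
#' @param hubs_by_comparison Named list with the same names, of hub gene
#'   vectors.
#' @return list with `comparisons` (per comparison: `distinctive_outliers`,
#'   `distinctive_hubs`, `shared_outliers`, `shared_hubs`), the two Venn
#'   partitions, and `panel_size`.
#' @export
assemble_driver_panel <- function(outliers_by_comparison,
                                  hubs_by_comparison) {
  if (!identical(sort(names(outliers_by_comparison)),
                 sort(names(hubs_by_comparison))))
    stop("outlier and hub lists must cover the same comparisons")
  vo <- venn_partition(outliers_by_comparison)
  vh <- venn_partition(hubs_by_comparison)
  labels <- names(outliers_by_comparison)
  comparisons <- lapply(labels, function(lb) {
    list(distinctive_outliers = venn_exclusive(vo, lb),
         distinctive_hubs = venn_exclusive(vh, lb),
         shared_outliers = venn_shared_with(vo, lb),
         shared_hubs = venn_shared_with(vh, lb))
  })
  names(comparisons) <- labels
  distinct_all <- unique(unlist(lapply(comparisons, function(cc)
    c(cc$distinctive_outliers, cc$distinctive_hubs)), use.names = FALSE))
  list(comparisons = comparisons, outlier_venn = vo, hub_venn = vh,
       panel_size = length(distinct_all))
}

#' First-neighbor context of a driver gene
#'
#' @param net igraph network whose vertices carry `direction` and `log2fc`
#'   attributes (see [build_network()]).
#' @param driver Gene symbol; must be a node of `net`.
#' @return list with `driver`, `neighbors` (data.frame of `gene`,
#'   `direction`, `log2fc`, sorted by gene) and `n_neighbors`. Drivers
#'   without interaction partners return an empty table.
#' @export
neighbor_context <- function(net, driver) {
  vnames <- igraph::V(net)$name
  if (!driver %in% vnames) stop("driver '", driver, "' is not in the network")
  nb <- as.integer(igraph::neighbors(net, driver))
  dir_attr <- igraph::V(net)$direction
  fc_attr <- igraph::V(net)$log2fc
  tab <- data.frame(
    gene = vnames[nb],
    direction = if (is.null(dir_attr))
      rep(NA_character_, length(nb)) else dir_attr[nb],
    log2fc = if (is.null(fc_attr)) rep(NA_real_, length(nb)) else
      fc_attr[nb],
    stringsAsFactors = FALSE
  )
  tab <- tab[order(tab$gene), , drop = FALSE]
  rownames(tab) <- NULL
  list(driver = driver, neighbors = tab, n_neighbors = nrow(tab))
}

#' Individual-gene fallback for small comparisons
#'
#' Comparisons yielding too few DEGs cannot support network construction,
#' module detection or driver filtering. Below `min_for_network` DEGs this
#' path applies the annotation filter and emits a per-gene marker table
#' ranked by fold-change magnitude; otherwise it signals that the full
#' network path applies.
#'
#' @param degs data.frame of DEG records (all genes; only `is_deg` rows are
#'   used).
#' @param ann Annotation table (see [filter_annotated()]).
#' @param min_for_network DEG count below which the fallback applies
#'   (default 20).
#' @return list with `path` ("endpoint" or "full") and `n_deg`; for the
#'   endpoint path also `markers` (gene_id, symbol, log2fc, signed_fc,
#'   direction, p_adj, sorted by decreasing |log2fc|) and `removed`.
#' @export
endpoint_marker_path <- function(degs, ann, min_for_network = 20) {
  d <- degs[degs$is_deg, , drop = FALSE]
  if (nrow(d) >= min_for_network)
    return(list(path = "full", n_deg = nrow(d)))
  fa <- filter_annotated(d, ann)
  markers <- fa$kept[order(-abs(fa$kept$log2fc)),
                     c("gene_id", "symbol", "log2fc", "signed_fc",
                       "direction", "p_adj"), drop = FALSE]
  rownames(markers) <- NULL
  list(path = "endpoint", n_deg = nrow(d), markers = markers,
       removed = fa$removed)
}
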