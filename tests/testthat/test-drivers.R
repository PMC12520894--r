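# Outlier detection, Venn partitioning, driver-panel assembly, neighbor
# context and the small-DEG endpoint fallback.

fc_degs <- function(log2fc, symbols = NULL) {
  if (is.null(symbols)) symbols <- sprintf("g%03d", seq_along(log2fc))
  data.frame(gene_id = symbols, symbol = symbols, log2fc = log2fc,
             signed_fc = signed_fold_change(log2fc),
             p_raw = 0.01, p_adj = 0.04,
             direction = ifelse(log2fc >= 0, "up", "down"),
             is_deg = TRUE, stringsAsFactors = FALSE)
}

test_that("a single extreme value is the only flagged outlier", {
  oc <- detect_outliers(fc_degs(c(1.1, 1.2, -1.1, 1.3, -1.2, 5.3)))
  expect_equal(oc$gene[oc$is_outlier], "g006")
  expect_true(oc$outside_fence[6])
  expect_lt(oc$deviation_p[6], 0.05)
})

test_that("degenerate fold-change vectors produce no outliers", {
  oc <- detect_outliers(fc_degs(rep(1.5, 8)))
  expect_false(any(oc$is_outlier))
  expect_error(detect_outliers(fc_degs(c(1, 2, 3))), "fewer than 5")
})

test_that("flags are invariant to positive scaling (default split)", {
  set.seed(3)
  x <- c(runif(30, 1, 2), -runif(30, 1, 2), 6.5, -7.1)
  base <- detect_outliers(fc_degs(x))$is_outlier
  scaled <- detect_outliers(fc_degs(2.5 * x))$is_outlier
  expect_identical(scaled, base)
})

test_that("flags are affine-invariant under the pooled signed split", {
  set.seed(4)
  x <- c(rnorm(40, 0, 0.8), 6.2, -5.9)
  base <- detect_outliers(fc_degs(x), split = "signed")$is_outlier
  shifted <- detect_outliers(fc_degs(1.7 * x + 3), split = "signed")$is_outlier
  expect_identical(shifted, base)
})

test_that("single-criterion rules relax the conjunction", {
  x <- c(runif(20, 1, 1.5), -runif(20, 1, 1.5), 4.5)
  both <- detect_outliers(fc_degs(x), rule = "both")
  fence <- detect_outliers(fc_degs(x), rule = "fence")
  expect_true(all(both$is_outlier ==
                    (both$outside_fence & both$deviation_p < 0.05)))
  expect_identical(fence$is_outlier, fence$outside_fence)
})

test_that("planted extremes are recovered with near-zero false positives", {
  hits <- 0; fps <- 0; planted <- 0
  for (s in 1:50) {
    set.seed(s)
    n_body <- 995
    body <- sample(c(-1, 1), n_body, TRUE) * runif(n_body, 1, 1.5)
    n_out <- 5
    out <- sample(c(-1, 1), n_out, TRUE) * (4 + runif(n_out))
    oc <- detect_outliers(fc_degs(c(body, out)))
    flagged <- which(oc$is_outlier)
    hits <- hits + sum(flagged > n_body)
    fps <- fps + sum(flagged <= n_body)
    planted <- planted + n_out
  }
  expect_equal(hits, planted)      # sensitivity 1.0
  expect_lte(fps / 50, 1)          # <= 1 false positive per 1,000 genes
})

test_that("venn regions partition the union", {
  vp <- venn_partition(list(S1 = c("A", "B", "C"), S2 = c("B", "C", "D")))
  expect_setequal(vp$regions[["S1&S2"]], c("B", "C"))
  expect_equal(vp$regions[["S1"]], "A")
  expect_equal(vp$regions[["S2"]], "D")

  same <- venn_partition(list(a = c("X", "Y"), b = c("X", "Y")))
  expect_length(same$regions, 1)
  expect_setequal(same$regions[["a&b"]], c("X", "Y"))

  set.seed(13)
  for (i in 1:50) {
    k <- sample(2:4, 1)
    sets <- lapply(1:k, function(j) sample(letters, sample(0:12, 1)))
    names(sets) <- paste0("s", 1:k)
    vp <- venn_partition(sets)
    all_members <- unlist(vp$regions, use.names = FALSE)
    expect_false(anyDuplicated(all_members) > 0)
    expect_setequal(all_members, unique(unlist(sets)))
  }
  expect_error(venn_partition(list(a = "x")), "2-4")
})

test_that("shared and distinctive hub partition matches the worked case", {
  vp <- venn_partition(list(
    network1 = c("KIF11", "CDC6", "CDCA8", "CCNA2", "PLK1"),
    network2 = c("CASP3", "CDCA8", "CCNA2", "PLK1")))
  expect_setequal(vp$regions[["network1&network2"]],
                  c("CDCA8", "CCNA2", "PLK1"))
  expect_setequal(vp$regions[["network1"]], c("KIF11", "CDC6"))
  expect_equal(vp$regions[["network2"]], "CASP3")
})

test_that("driver panel counts distinctive genes once across categories", {
  panel <- assemble_driver_panel(
    outliers_by_comparison = list(
      n1 = c("EFHD1", "HS6ST2", "SLC35G1", "SHARED1"),
      n2 = c("HBA1", "SLC39A8", "ERO1A", "TKDP5", "CALCRL", "ELOVL6",
             "SHARED1")),
    hubs_by_comparison = list(
      n1 = c("KIF11", "CDC6", "CDCA8", "CCNA2", "PLK1"),
      n2 = c("CASP3", "CDCA8", "CCNA2", "PLK1")))
  expect_equal(panel$panel_size, 12)
  expect_setequal(panel$comparisons$n1$distinctive_hubs,
                  c("KIF11", "CDC6"))
  expect_setequal(panel$comparisons$n1$shared_hubs,
                  c("CDCA8", "CCNA2", "PLK1"))
  expect_equal(panel$comparisons$n2$distinctive_hubs, "CASP3")
  expect_equal(panel$comparisons$n1$shared_outliers, "SHARED1")

  empty <- assemble_driver_panel(list(a = character(0), b = character(0)),
                                 list(a = character(0), b = character(0)))
  expect_equal(empty$panel_size, 0)

  dup <- assemble_driver_panel(list(a = "X", b = character(0)),
                               list(a = "X", b = character(0)))
  expect_equal(dup$panel_size, 1)  # same gene in both categories

  # order-invariance of inputs
  p1 <- assemble_driver_panel(list(a = c("u", "v"), b = "w"),
                              list(a = "h1", b = "h2"))
  p2 <- assemble_driver_panel(list(a = c("v", "u"), b = "w"),
                              list(a = "h1", b = "h2"))
  expect_equal(p1$panel_size, p2$panel_size)
  expect_setequal(p1$comparisons$a$distinctive_outliers,
                  p2$comparisons$a$distinctive_outliers)
})

test_that("neighbor context returns the exact adjacency", {
  g <- edge_graph("H-A,H-B,H-C,A-B", isolated = "LONER")
  igraph::V(g)$direction <- "down"
  igraph::V(g)$log2fc <- -2
  ctx <- neighbor_context(g, "H")
  expect_equal(ctx$neighbors$gene, c("A", "B", "C"))
  expect_equal(ctx$n_neighbors, 3)
  lone <- neighbor_context(g, "LONER")
  expect_equal(lone$n_neighbors, 0)
  expect_error(neighbor_context(g, "MISSING"), "not in the network")

  set.seed(19)
  a <- rand_adj(10, 0.3)
  gg <- adj_to_graph(a)
  for (v in rownames(a))
    expect_setequal(neighbor_context(gg, v)$neighbors$gene,
                    rownames(a)[a[v, ] == 1])
})

test_that("the endpoint fallback emits a ranked marker table", {
  log2fc <- c(2.1, rep(-seq(1.2, 3, length.out = 12)))
  degs <- fc_degs(log2fc, symbols = c("SEMA3A", sprintf("DN%02d", 1:12)))
  ann <- data.frame(gene_id = degs$gene_id, symbol = degs$gene_id,
                    biotype = "protein_coding", protein_annotated = TRUE,
                    stringsAsFactors = FALSE)
  ann$symbol[c(5, 11)] <- ""  # two uncharacterized transcripts
  res <- endpoint_marker_path(degs, ann)
  expect_equal(res$path, "endpoint")
  expect_equal(nrow(res$markers), 11)
  expect_equal(sum(res$markers$direction == "up"), 1)
  expect_equal(sum(res$markers$direction == "down"), 10)
  expect_true(all(diff(abs(res$markers$log2fc)) <= 0))
  expect_equal(res$markers$symbol[1], "DN12")  # strongest fold change first

  big <- fc_degs(rep(c(1.5, -1.5), 250))
  expect_equal(endpoint_marker_path(big, ann)$path, "full")

  none <- degs[degs$log2fc > 99, ]
  res0 <- endpoint_marker_path(none, ann)
  expect_equal(nrow(res0$markers), 0)
})
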