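# Differential-expression calling, annotation filtering and summary
# bookkeeping.

two_group_es <- function(values_a, values_b, genes = NULL) {
  va <- as.matrix(values_a)
  vb <- as.matrix(values_b)
  values <- cbind(va, vb)
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(nrow(values)))
  rownames(values) <- genes
  colnames(values) <- c(paste0("a", seq_len(ncol(va))),
                        paste0("b", seq_len(ncol(vb))))
  expression_set(values, setNames(rep(c("A", "B"), c(ncol(va), ncol(vb))),
                                  colnames(values)))
}

test_that("expression_set enforces its invariants", {
  v <- matrix(rnorm(12), 3, 4,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  g <- setNames(c("A", "A", "B", "B"), colnames(v))
  expect_s3_class(expression_set(v, g), "ccdr_expression")
  expect_error(expression_set(v, setNames(rep("A", 4), colnames(v))),
               "two groups")
  expect_error(expression_set(v, setNames(c("A", "B", "B", "B"),
                                          colnames(v))), "replicate")
  v2 <- v; v2[1, 1] <- NA
  expect_error(expression_set(v2, g), "missing")
})

test_that("null and forced genes follow the fold-change conventions", {
  es <- two_group_es(matrix(c(5, 5, 5,   # null gene
                              7, 7, 7),  # +2 log2 units, zero variance
                            2, 3, byrow = TRUE),
                     matrix(c(5, 5, 5,
                              5, 5, 5), 2, 3, byrow = TRUE))
  degs <- suppressMessages(call_degs(es, "A", "B"))
  expect_equal(degs$signed_fc[1], 1)  # boundary convention, never in (-1,1)
  expect_false(degs$is_deg[1])
  expect_equal(degs$log2fc[2], 2)
  expect_equal(degs$signed_fc[2], 4)
  expect_equal(degs$direction[2], "up")
  expect_equal(degs$p_raw[2], 0)  # zero within-group variance, nonzero delta
  expect_true(degs$is_deg[2])
})

test_that("an all-identical matrix yields no DEGs and no error", {
  es <- two_group_es(matrix(3, 4, 3), matrix(3, 4, 3))
  degs <- call_degs(es, "A", "B")
  expect_false(any(degs$is_deg))
  expect_true(all(degs$p_raw == 1))
})

test_that("swapping groups negates log2fc and preserves p-values", {
  set.seed(42)
  es <- two_group_es(matrix(rnorm(30, 6), 10, 3),
                     matrix(rnorm(30, 6.5), 10, 3))
  ab <- call_degs(es, "A", "B")
  ba <- call_degs(es, "B", "A")
  expect_equal(ba$log2fc, -ab$log2fc)
  expect_equal(ba$p_raw, ab$p_raw)
  expect_equal(ba$p_adj, ab$p_adj)
})

test_that("permuting samples within a group changes nothing", {
  set.seed(7)
  v <- matrix(rnorm(36, 7), 6, 6,
              dimnames = list(paste0("g", 1:6), paste0("s", 1:6)))
  g <- setNames(rep(c("A", "B"), each = 3), colnames(v))
  perm <- c(3, 1, 2, 4, 6, 5)
  d1 <- call_degs(expression_set(v, g), "A", "B")
  d2 <- call_degs(expression_set(v[, perm], g[perm]), "A", "B")
  expect_equal(d1, d2)
})

test_that("raising the fold-change threshold never adds a DEG", {
  set.seed(11)
  es <- two_group_es(matrix(rnorm(60, 6, 1), 20, 3),
                     matrix(rnorm(60, 7, 1), 20, 3))
  loose <- call_degs(es, "A", "B", fc_threshold = 2)
  strict <- call_degs(es, "A", "B", fc_threshold = 3)
  expect_true(all(which(strict$is_deg) %in% which(loose$is_deg)))
})

test_that("BH gating matches the brute-force step-up procedure", {
  set.seed(101)
  for (i in 1:1000) {
    m <- sample(3:40, 1)
    p <- round(runif(m)^sample(1:3, 1), 3)  # ties on purpose
    alpha <- runif(1, 0.01, 0.2)
    expect_identical(unname(p.adjust(p, "BH") < alpha), o_bh_reject(p, alpha))
  }
})

test_that("synthetic recovery meets sensitivity and FDP bounds", {
  cfg <- simulation_config(n_genes = 1000, noise_sd = 0.25,
                           deg_fraction = 0.06, seed = 7,
                           planted_modules = list(), planted_hubs = 0,
                           planted_outliers = 10)
  sim <- simulate_expression(cfg)
  degs <- call_degs(sim$expression, "MII_endpoint", "GV_startpoint")
  called <- degs$gene_id[degs$is_deg]
  truth <- sim$truth$true_deg_ids
  sens <- length(intersect(called, truth)) / length(truth)
  fdp <- length(setdiff(called, truth)) / max(1, length(called))
  expect_gte(sens, 0.9)
  expect_lte(fdp, 0.1)
})

make_ann <- function(gene_id, symbol = gene_id, biotype = "protein_coding",
                     protein_annotated = TRUE) {
  data.frame(gene_id = gene_id, symbol = symbol, biotype = biotype,
             protein_annotated = protein_annotated, stringsAsFactors = FALSE)
}

fake_degs <- function(n, log2fc = 1.5) {
  ids <- sprintf("d%04d", seq_len(n))
  data.frame(gene_id = ids, symbol = ids,
             log2fc = rep_len(log2fc, n),
             signed_fc = signed_fold_change(rep_len(log2fc, n)),
             p_raw = 0.01, p_adj = 0.04,
             direction = ifelse(rep_len(log2fc, n) >= 0, "up", "down"),
             is_deg = TRUE, stringsAsFactors = FALSE)
}

test_that("annotation filter removes the three exclusion classes", {
  degs <- fake_degs(1386)
  ann <- make_ann(degs$gene_id)
  ann$symbol[1:100] <- ""                 # uncharacterized
  ann$biotype[101:180] <- "lncRNA"        # long non-coding
  ann$protein_annotated[181:242] <- FALSE # no protein annotation
  fa <- filter_annotated(degs, ann)
  expect_equal(nrow(fa$removed), 242)
  expect_equal(nrow(fa$kept), 1144)
  expect_equal(round_half_up(100 * nrow(fa$removed) / nrow(degs), 1), 17.5)
  expect_equal(c(fa$kept$gene_id, fa$removed$gene_id)[order(
    c(which(!degs$gene_id %in% fa$removed$gene_id),
      which(degs$gene_id %in% fa$removed$gene_id)))], degs$gene_id)
})

test_that("fully annotated input passes through untouched", {
  degs <- fake_degs(25)
  fa <- filter_annotated(degs, make_ann(degs$gene_id))
  expect_equal(nrow(fa$removed), 0)
  expect_equal(fa$kept$gene_id, degs$gene_id)
})

test_that("two uncharacterized transcripts of thirteen leave eleven", {
  degs <- fake_degs(13)
  ann <- make_ann(degs$gene_id)
  ann$symbol[c(4, 9)] <- ""
  fa <- filter_annotated(degs, ann)
  expect_equal(nrow(fa$kept), 11)
})

test_that("missing annotation ids are treated as uncharacterized", {
  degs <- fake_degs(5)
  ann <- make_ann(degs$gene_id[1:3])
  expect_message(fa <- filter_annotated(degs, ann), "absent")
  expect_equal(nrow(fa$removed), 2)
})

test_that("summary percentages follow half-up rounding per policy", {
  degs <- fake_degs(1386)
  degs$log2fc[1:742] <- -1.5
  degs$direction[1:742] <- "down"
  s <- summarize_deg_table(22141, degs, decimals_pct = 0)
  expect_equal(s$pct_down, 54)
  expect_equal(s$n_up, 644)
  s1 <- summarize_deg_table(22141, degs, decimals_pct = 1)
  expect_equal(s1$pct_deg, 6.3)
  expect_equal(s1$pct_unchanged, 93.7)

  d3 <- fake_degs(13)
  d3$log2fc[1:11] <- -2
  d3$direction[1:11] <- "down"
  s3 <- summarize_deg_table(22141, d3, decimals_pct = 1)
  expect_equal(s3$pct_down, 84.6)
  expect_equal(s3$pct_up, 15.4)
})

test_that("degenerate summaries behave at the boundaries", {
  degs <- fake_degs(10)
  s <- summarize_deg_table(10, degs, decimals_pct = 0)
  expect_equal(s$pct_deg, 100)
  expect_equal(s$pct_down, 0)
  none <- degs[degs$log2fc > 99, ]
  s0 <- summarize_deg_table(10, none)
  expect_true(is.na(s0$pct_up) && is.na(s0$pct_down))
  expect_error(summarize_deg_table(5, degs), "more DEGs")
})
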