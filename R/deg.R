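#' Construct a grouped expression set
#'
#' Bundles a genes x samples matrix of log2 intensities with a sample-to-group
#' assignment and validates the invariants every downstream stage relies on:
#' no missing values, unique gene identifiers, at least two groups and at
#' least two samples per group (otherwise within-group variance, and hence
#' the ANOVA, is undefined).
#'
#' @param values Numeric matrix, rows = genes (rownames required),
#'   columns = samples (colnames required), entries = log2 intensities.
#' @param groups Named character vector mapping sample id to group label;
#'   names must match `colnames(values)`.
#' @return An object of class `ccdr_expression`: a list with elements
#'   `values` and `groups`.
#' @export
expression_set <- function(values, groups) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("`values` needs unique rownames (gene ids)")
  if (is.null(colnames(values)))
    stop("`values` needs colnames (sample ids)")
  if (anyNA(values))
    stop("expression matrix contains missing values")
  groups <- groups[colnames(values)]
  if (anyNA(groups))
    stop("every sample needs a group label")
  tab <- table(groups)
  if (length(tab) < 2)
    stop("need at least two groups")
  if (any(tab < 2))
    stop("need at least two samples (replicates) per group; groups with one ",
         "replicate have undefined variance")
  structure(list(values = values, groups = as.character(groups)),
            class = "ccdr_expression")
}

#' @export
print.ccdr_expression <- function(x, ...) {
  cat("ccdr_expression:", nrow(x$values), "genes x", ncol(x$values),
      "samples;", length(unique(x$groups)), "groups (",
      paste(sprintf("%s=%d", names(table(x$groups)), table(x$groups)),
            collapse = ", "), ")\n")
  invisible(x)
}

# Vectorised one-way ANOVA over the rows of a matrix.  Equivalent to the
# pooled-variance two-sample t-test when exactly two groups are present,
# but written for k >= 2 groups.  Degenerate rows: zero within-group sum of
# squares with a real between-group difference gives p = 0 (the difference
# is infinitely many residual sds away); rows with no between-group signal
# give p = 1.
row_anova_p <- function(values, fac) {
  fac <- droplevels(as.factor(fac))
  k <- nlevels(fac)
  n <- length(fac)
  if (k < 2) stop("ANOVA needs at least two groups")
  if (any(tabulate(fac) < 2)) stop("every group needs >= 2 replicates")
  grand <- rowMeans(values)
  ssb <- numeric(nrow(values))
  ssw <- numeric(nrow(values))
  for (lv in levels(fac)) {
    idx <- which(fac == lv)
    m_g <- rowMeans(values[, idx, drop = FALSE])
    ssb <- ssb + length(idx) * (m_g - grand)^2
    ssw <- ssw + rowSums((values[, idx, drop = FALSE] - m_g)^2)
  }
  eps <- 1e-12
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  p <- stats::pf(f, k - 1, n - k, lower.tail = FALSE)
  degen <- ssw <= eps & ssb > eps
  if (any(degen)) {
    message(sum(degen), " gene(s) with zero within-group variance and a ",
            "nonzero group difference; p set to 0")
    p[degen] <- 0
  }
  p[ssb <= eps] <- 1
  p
}

#' Signed linear fold change
#'
#' Converts log2 fold changes to the array-analysis signed convention:
#' `2^|log2fc|` carrying the sign of the change, so values never fall in
#' (-1, 1) and a null gene sits at +1.
#'
#' @param log2fc Numeric vector of log2 fold changes.
#' @return Numeric vector of signed linear fold changes.
#' @export
signed_fold_change <- function(log2fc) {
  ifelse(log2fc >= 0, 2^log2fc, -(2^(-log2fc)))
}

#' Call differentially expressed genes between two groups
#'
#' Per gene, the effect is `log2fc = mean(group_a) - mean(group_b)` and the
#' p-value comes from a one-way ANOVA across the two groups (identical to a
#' pooled-variance t-test for the two-group case). P-values are
#' Benjamini-Hochberg adjusted over all genes and both raw and adjusted
#' values are reported. A gene is a DEG when its signed linear fold change
#' exceeds `fc_threshold` in magnitude *and* its p-value is below `alpha`;
#' the gate uses the raw ANOVA p by default (the classical array DEG
#' criterion, which at three replicates per group retains usable power),
#' with `use_adjusted = TRUE` switching to the BH-adjusted p.
#'
#' @param es `ccdr_expression` object from [expression_set()].
#' @param group_a,group_b Group labels; fold change is a minus b.
#' @param fc_threshold Linear fold-change gate (strict, `> fc_threshold`).
#' @param alpha Significance gate (strict, `< alpha`).
#' @param use_adjusted Gate on BH-adjusted p-values instead of raw p
#'   (default `FALSE`).
#' @param annotation Optional annotation table (see [filter_annotated()]);
#'   used only to attach symbols. Genes without a match keep their id.
#' @return data.frame with one row per gene: `gene_id`, `symbol`, `log2fc`,
#'   `signed_fc`, `p_raw`, `p_adj`, `direction` ("up"/"down"), `is_deg`.
#' @export
call_degs <- function(es, group_a, group_b, fc_threshold = 2, alpha = 0.05,
                      use_adjusted = FALSE, annotation = NULL) {
  stopifnot(inherits(es, "ccdr_expression"))
  if (fc_threshold <= 0) stop("`fc_threshold` must be positive")
  keep <- es$groups %in% c(group_a, group_b)
  if (!any(es$groups == group_a) || !any(es$groups == group_b))
    stop("both groups must be present in the expression set")
  values <- es$values[, keep, drop = FALSE]
  fac <- es$groups[keep]
  log2fc <- rowMeans(values[, fac == group_a, drop = FALSE]) -
    rowMeans(values[, fac == group_b, drop = FALSE])
  p_raw <- row_anova_p(values, fac)
  p_adj <- stats::p.adjust(p_raw, method = "BH")
  signed_fc <- signed_fold_change(log2fc)
  p_gate <- if (use_adjusted) p_adj else p_raw
  out <- data.frame(
    gene_id   = rownames(values),
    symbol    = rownames(values),
    log2fc    = unname(log2fc),
    signed_fc = unname(signed_fc),
    p_raw     = unname(p_raw),
    p_adj     = unname(p_adj),
    direction = ifelse(log2fc >= 0, "up", "down"),
    is_deg    = unname(abs(signed_fc) > fc_threshold & p_gate < alpha),
    stringsAsFactors = FALSE
  )
  if (!is.null(annotation)) {
    m <- match(out$gene_id, annotation$gene_id)
    hit <- !is.na(m) & !is.na(annotation$symbol[m]) & annotation$symbol[m] != ""
    out$symbol[hit] <- annotation$symbol[m[hit]]
  }
  rownames(out) <- NULL
  out
}

#' Remove genes without usable protein annotation
#'
#' Drops DEG records whose gene is uncharacterized (empty symbol), a long
#' non-coding RNA, or lacks a protein annotation -- the pruning applied
#' before any network construction. Genes absent from the annotation table
#' are treated as uncharacterized (and counted in a message).
#'
#' @param degs data.frame of DEG records (from [call_degs()]).
#' @param ann Annotation data.frame with columns `gene_id`, `symbol`,
#'   `biotype` (one of "protein_coding", "lncRNA", "other") and
#'   `protein_annotated` (logical).
#' @return list with `kept` and `removed` data.frames (input order
#'   preserved; `kept` rows carry the annotation symbol).
#' @export
filter_annotated <- function(degs, ann) {
  stopifnot(is.data.frame(degs), is.data.frame(ann))
  if (anyDuplicated(ann$gene_id)) stop("annotation gene_id must be unique")
  m <- match(degs$gene_id, ann$gene_id)
  missing <- is.na(m)
  if (any(missing))
    message(sum(missing), " DEG id(s) absent from the annotation table; ",
            "treated as uncharacterized")
  symbol <- ifelse(missing, "", as.character(ann$symbol[m]))
  symbol[is.na(symbol)] <- ""
  biotype <- ifelse(missing, "other", as.character(ann$biotype[m]))
  prot <- ifelse(missing, FALSE, ann$protein_annotated[m])
  drop <- symbol == "" | biotype == "lncRNA" | !prot
  kept <- degs[!drop, , drop = FALSE]
  kept$symbol <- symbol[!drop]
  list(kept = kept, removed = degs[drop, , drop = FALSE])
}

#' Half-up decimal rounding
#'
#' Rounds halves away from zero (base `round()` rounds half to even),
#' matching how percentages are conventionally printed in result tables.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Summarize a DEG table as counts and percentages
#'
#' Produces the count/percentage bookkeeping of a per-comparison DEG table:
#' how many genes passed the filter criteria, how many were up- or
#' downregulated, and the corresponding percentages. `pct_deg` and
#' `pct_unchanged` are percentages of `total_genes`; `pct_up` and `pct_down`
#' are percentages of the DEG count. Percentages are rounded half-up to
#' `decimals_pct` decimals.
#'
#' @param total_genes Number of transcripts interrogated.
#' @param degs data.frame of DEG records; only rows with `is_deg` count.
#' @param decimals_pct Decimals used for the percentage fields (0-2).
#' @return list with `total_genes`, `n_deg`, `n_up`, `n_down`, `pct_deg`,
#'   `pct_unchanged`, `pct_up`, `pct_down`, `rounding`. With zero DEGs the
#'   up/down percentages are `NA` (undefined), not 0.
#' @export
summarize_deg_table <- function(total_genes, degs, decimals_pct = 1) {
  stopifnot(decimals_pct %in% 0:2)
  d <- degs[degs$is_deg, , drop = FALSE]
  n_deg <- nrow(d)
  if (n_deg > total_genes) stop("more DEGs than total genes")
  n_up <- sum(d$direction == "up")
  n_down <- n_deg - n_up
  pc <- function(num, den) {
    if (den == 0) return(NA_real_)
    round_half_up(100 * num / den, decimals_pct)
  }
  list(
    total_genes = total_genes,
    n_deg = n_deg, n_up = n_up, n_down = n_down,
    pct_deg = pc(n_deg, total_genes),
    pct_unchanged = pc(total_genes - n_deg, total_genes),
    pct_up = if (n_deg == 0) NA_real_ else pc(n_up, n_deg),
    pct_down = if (n_deg == 0) NA_real_ else pc(n_down, n_deg),
    rounding = decimals_pct
  )
}
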