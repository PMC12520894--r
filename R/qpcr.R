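#' Construct a qPCR plate
#'
#' Bundles long-format Ct records with the reference-gene list and the
#' calibrator group. Technical replicates (repeated Ct rows for the same
#' sample/gene) are averaged. Every sample must carry a Ct for every
#' reference gene.
#'
#' @param records data.frame with columns `sample`, `group`, `gene`, `ct`.
#' @param reference_genes Character vector of reference genes (default
#'   GAPDH and YWHAZ).
#' @param calibrator_group Group label used as the calibrator.
#' @return Object of class `ccdr_qpcr_plate`.
#' @export
qpcr_plate <- function(records, reference_genes = c("GAPDH", "YWHAZ"),
                       calibrator_group) {
  stopifnot(all(c("sample", "group", "gene", "ct") %in% names(records)))
  if (anyNA(records$ct)) stop("Ct values must not be missing")
  agg <- stats::aggregate(ct ~ sample + group + gene, data = records,
                          FUN = mean)
  if (!calibrator_group %in% agg$group)
    stop("calibrator group '", calibrator_group, "' has no samples")
  for (s in unique(agg$sample)) {
    have <- agg$gene[agg$sample == s]
    miss <- setdiff(reference_genes, have)
    if (length(miss) > 0)
      stop("sample '", s, "' lacks reference gene Ct: ",
           paste(miss, collapse = ", "))
  }
  structure(list(records = agg, reference_genes = reference_genes,
                 calibrator_group = calibrator_group),
            class = "ccdr_qpcr_plate")
}

#' Relative quantification by the delta-delta-Ct method
#'
#' Per sample, `dCt = Ct_target - mean(Ct of the reference genes)` (the
#' arithmetic mean of reference Cts, i.e. the geometric mean of reference
#' quantities); `ddCt = dCt - mean(dCt of the calibrator group)`; and
#' `RQ = 2^(-ddCt)`, assuming an amplification efficiency of 2 with no
#' efficiency correction. Group means and standard deviations of RQ are
#' reported alongside the per-sample values.
#'
#' @param plate A [qpcr_plate()].
#' @param target Target gene measured on every sample.
#' @return list with `per_sample` (sample, group, delta_ct, ddct, rq) and
#'   `per_group` (group, mean_rq, sd_rq, n).
#' @export
relative_quantification <- function(plate, target) {
  stopifnot(inherits(plate, "ccdr_qpcr_plate"))
  rec <- plate$records
  samples <- unique(rec$sample)
  tgt <- rec[rec$gene == target, ]
  if (!all(samples %in% tgt$sample))
    stop("target '", target, "' is not measured in every sample")
  ref_ct <- vapply(samples, function(s) {
    mean(rec$ct[rec$sample == s & rec$gene %in% plate$reference_genes])
  }, numeric(1))
  m <- match(samples, tgt$sample)
  per_sample <- data.frame(
    sample = samples,
    group = tgt$group[m],
    delta_ct = tgt$ct[m] - ref_ct,
    stringsAsFactors = FALSE
  )
  cal <- per_sample$group == plate$calibrator_group
  per_sample$ddct <- per_sample$delta_ct - mean(per_sample$delta_ct[cal])
  per_sample$rq <- 2^(-per_sample$ddct)
  per_group <- do.call(rbind, lapply(split(per_sample, per_sample$group),
    function(df) data.frame(group = df$group[1], mean_rq = mean(df$rq),
                            sd_rq = stats::sd(df$rq), n = nrow(df),
                            stringsAsFactors = FALSE)))
  rownames(per_group) <- NULL
  list(per_sample = per_sample, per_group = per_group)
}
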