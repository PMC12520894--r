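# Plain-text interchange: TSV expression matrices and group maps, TSV
# annotation and DEG tables, SIF / two-column edge lists, JSON reports.

#' Read an expression matrix and group map from TSV
#'
#' @param matrix_path TSV with a `gene_id` first column and one column per
#'   sample (log2 intensities).
#' @param groups_path Two-column TSV (`sample`, `group`), no header
#'   required if the columns are in that order with a header line.
#' @return A [expression_set()].
#' @export
read_expression_tsv <- function(matrix_path, groups_path) {
  tab <- utils::read.delim(matrix_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  values <- as.matrix(tab[, -1, drop = FALSE])
  rownames(values) <- tab[[1]]
  gmap <- utils::read.delim(groups_path, stringsAsFactors = FALSE)
  expression_set(values, stats::setNames(gmap[[2]], gmap[[1]]))
}

#' Write an expression matrix and group map as TSV
#' @param es A [expression_set()].
#' @param matrix_path,groups_path Output paths.
#' @export
write_expression_tsv <- function(es, matrix_path, groups_path) {
  tab <- data.frame(gene_id = rownames(es$values), es$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  gmap <- data.frame(sample = colnames(es$values), group = es$groups)
  utils::write.table(gmap, groups_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(NULL)
}

#' Read / write a gene annotation table (TSV)
#'
#' Columns: `gene_id`, `symbol`, `biotype`, `protein_annotated`.
#' @param path File path.
#' @return data.frame.
#' @export
read_annotation_tsv <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = character(0))
  ann$protein_annotated <- as.logical(ann$protein_annotated)
  ann
}

#' @rdname read_annotation_tsv
#' @param ann Annotation data.frame.
#' @export
write_annotation_tsv <- function(ann, path) {
  utils::write.table(ann, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(NULL)
}

#' Read an interaction edge list (SIF or two-column TSV)
#'
#' SIF lines are `A <type> B` (only binary interactions are supported);
#' two-column files are taken as symbol pairs directly. Comment of the
#' interaction type is ignored.
#'
#' @param path File path.
#' @return data.frame with columns `from`, `to`.
#' @export
read_interactome <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  first <- toks[[1]]
  has_header <- length(first) == 2 &&
    any(tolower(first) %in% c("from", "to", "source", "target"))
  if (has_header) toks <- toks[-1]
  pairs <- lapply(toks, function(tk) {
    if (length(tk) == 3) tk[c(1, 3)]
    else if (length(tk) == 2) tk
    else stop("cannot parse edge line with ", length(tk), " fields")
  })
  el <- do.call(rbind, pairs)
  data.frame(from = el[, 1], to = el[, 2], stringsAsFactors = FALSE)
}

#' Write a network as SIF
#' @param net igraph object or two-column edge data.frame.
#' @param path Output path.
#' @param type Interaction type token (default "pp").
#' @export
write_sif <- function(net, path, type = "pp") {
  el <- if (inherits(net, "igraph")) igraph::as_edgelist(net) else
    as.matrix(net[, 1:2])
  writeLines(paste(el[, 1], type, el[, 2]), path)
  invisible(NULL)
}

#' Write a DEG table as TSV
#' @param degs DEG data.frame from [call_degs()].
#' @param path Output path.
#' @export
write_deg_tsv <- function(degs, path) {
  utils::write.table(degs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(NULL)
}

#' Write an R structure as JSON
#'
#' Thin wrapper with the package's conventions: scalars unboxed, full
#' numeric precision, pretty-printed.
#' @param x Object.
#' @param path Output path.
#' @export
write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(NULL)
}
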