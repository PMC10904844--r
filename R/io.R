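# Plain-text I/O conventions shared by all stages: tab-separated tables
# with header rows, gene ids in the first column of expression matrices.

#' Write an expression cohort to TSV
#'
#' Writes `<cohort_id>_expression.tsv` (gene column + one column per
#' sample) and `<cohort_id>_metadata.tsv` (`sample_id`, `group`).
#'
#' @param cohort An `"expression_cohort"`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the two file paths.
#' @export
write_cohort_tsv <- function(cohort, dir) {
  stopifnot(inherits(cohort, "expression_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  expr_path <- file.path(dir, paste0(cohort$cohort_id, "_expression.tsv"))
  meta_path <- file.path(dir, paste0(cohort$cohort_id, "_metadata.tsv"))
  df <- data.frame(gene = rownames(cohort$values), cohort$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, expr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(sample_id = colnames(cohort$values),
                                group = cohort$group),
                     meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(expression = expr_path, metadata = meta_path))
}

#' Read an expression cohort from TSV
#'
#' @param expr_path Expression TSV (gene ids in the first column).
#' @param meta_path Metadata TSV with columns `sample_id` and `group`.
#' @param cohort_id Cohort identifier (default: file name stem).
#' @return An `"expression_cohort"`.
#' @export
read_cohort_tsv <- function(expr_path, meta_path,
                            cohort_id = sub("_expression\\.tsv$", "",
                                            basename(expr_path))) {
  expr <- utils::read.delim(expr_path, check.names = FALSE,
                            stringsAsFactors = FALSE)
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  values <- as.matrix(expr[, -1, drop = FALSE])
  rownames(values) <- expr[[1]]
  group <- meta$group[match(colnames(values), meta$sample_id)]
  expression_cohort(cohort_id, values, group)
}

#' Write / read a survival cohort TSV
#'
#' Columns: `id`, `time_months`, `event`, `expression`.
#'
#' @param cohort A `"survival_cohort"`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_survival_tsv <- function(cohort, path) {
  stopifnot(inherits(cohort, "survival_cohort"))
  utils::write.table(data.frame(id = cohort$id, time_months = cohort$time,
                                event = cohort$event,
                                expression = cohort$expression),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_survival_tsv
#' @export
read_survival_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  survival_cohort(df$id, df$time_months, df$event, df$expression)
}

#' Write / read a plate-trace TSV
#'
#' Long format with columns `assay`, `well`, `phase`, `timepoint`, `OCR`,
#' `ECAR`.
#'
#' @param traces List of trace data frames from [simulate_plate_traces()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_trace_tsv <- function(traces, path) {
  utils::write.table(do.call(rbind, traces), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_tsv
#' @export
read_trace_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  split(df, df$assay)
}

#' Write a per-cohort differential-expression TSV
#'
#' Columns: `gene`, `log2fc`, `p_value`, `passes_gate`.
#'
#' @param table A `"diffexp_table"`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_diffexp_tsv <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write the consensus table and its status summary
#'
#' Writes the per-gene consensus TSV (gene, per-cohort direction, n_up,
#' n_down, status) and a JSON summary of counts per status.
#'
#' @param consensus A `"consensus_call"`.
#' @param tsv_path,json_path Output file paths.
#' @return Invisibly, the two paths.
#' @export
write_consensus <- function(consensus, tsv_path, json_path) {
  stopifnot(inherits(consensus, "consensus_call"))
  utils::write.table(as.data.frame(consensus), tsv_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  counts <- as.list(table(factor(consensus$status,
                                 levels = c("consistent_up",
                                            "consistent_down",
                                            "not_consistent"))))
  jsonlite::write_json(c(list(n_genes = nrow(consensus),
                              min_datasets = attr(consensus, "min_datasets"),
                              n_datasets = attr(consensus, "n_datasets")),
                         counts),
                       json_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(tsv = tsv_path, json = json_path))
}

#' Write / read a gene-set text file (one id per line)
#'
#' @param genes Character vector of gene ids.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_gene_set <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}

#' @rdname write_gene_set
#' @export
read_gene_set <- function(path) {
  x <- unique(trimws(readLines(path)))
  x[nzchar(x)]
}
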