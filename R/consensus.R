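# Cross-cohort consensus calling of tumor-altered metabolic genes:
# metabolic restriction, per-cohort adaptive |log2FC| cutoff, direction
# classification, and the exclusive >= min_datasets vote.

#' Restrict a gated DE table to a metabolic gene set
#'
#' Keeps exactly the gate-passing genes whose id belongs to the
#' metabolism-annotated gene list (in the original study, a published list
#' of 2752 metabolism-annotated genes), preserving row order. An empty
#' intersection yields an empty table (valid; a message is emitted).
#'
#' @param table A gated `"diffexp_table"` (see [apply_de_gate()]).
#' @param genes Character vector of metabolic gene ids.
#' @return The filtered `"diffexp_table"`.
#' @export
restrict_to_metabolic <- function(table, genes) {
  stopifnot(inherits(table, "diffexp_table"))
  genes <- unique(as.character(genes))
  if (length(genes) == 0) stop("metabolic gene set is empty")
  if (all(is.na(table$passes_gate))) {
    stop("apply_de_gate() must be run before metabolic restriction")
  }
  keep <- table$passes_gate & table$gene %in% genes
  out <- table[keep, , drop = FALSE]
  if (nrow(out) == 0) {
    message(sprintf("cohort '%s': no gated genes in the metabolic set",
                    attr(table, "cohort_id") %||% "?"))
  }
  rownames(out) <- NULL
  out
}

#' Per-cohort adaptive fold-change cutoff
#'
#' The cutoff is the mean absolute log2 fold change of the cohort's
#' gate-passing genes. It is applied symmetrically (at +cutoff for
#' up-regulation, -cutoff for down-regulation) and serves to exclude
#' metabolic gene probes with very small expression changes. By default the
#' average is taken over all gate-passing genes of the cohort (before
#' metabolic restriction); pass an already-restricted table to compute it
#' after restriction instead.
#'
#' @param table A gated `"diffexp_table"`.
#' @return Positive scalar cutoff in log2 units.
#' @export
adaptive_cutoff <- function(table) {
  stopifnot(inherits(table, "diffexp_table"))
  if (all(is.na(table$passes_gate))) {
    stop("apply_de_gate() must be run before computing the adaptive cutoff")
  }
  fc <- table$log2fc[table$passes_gate]
  if (length(fc) == 0) {
    stop(sprintf("no DEGs; cutoff undefined for cohort '%s'",
                 attr(table, "cohort_id") %||% "?"))
  }
  mean(abs(fc))
}

#' Classify gene direction against a cutoff
#'
#' A gene is `up` when its log2 fold change is at or above `+cutoff`,
#' `down` when at or below `-cutoff`, and `ns` otherwise (boundaries
#' inclusive).
#'
#' @param table A `"diffexp_table"` (typically gated and restricted).
#' @param cutoff Positive log2 cutoff, usually from [adaptive_cutoff()].
#' @return Character vector of directions, one per row, named by gene.
#' @export
classify_direction <- function(table, cutoff) {
  stopifnot(inherits(table, "diffexp_table"), is.numeric(cutoff),
            length(cutoff) == 1L)
  if (!is.finite(cutoff) || cutoff <= 0) stop("cutoff must be positive")
  dir <- ifelse(table$log2fc >= cutoff, "up",
                ifelse(table$log2fc <= -cutoff, "down", "ns"))
  stats::setNames(dir, table$gene)
}

#' Cross-cohort consensus vote
#'
#' A gene is called consistently altered when it falls exclusively in the
#' up-regulated (or exclusively in the down-regulated) category in at least
#' `min_datasets` of the `n_datasets` cohorts: a single cohort calling the
#' opposite direction voids the consensus. A gene absent from a cohort's
#' classified table counts as `ns` in that cohort, keeping `n_datasets`
#' fixed at the design value.
#'
#' @param calls Named list (one element per cohort) of direction vectors as
#'   returned by [classify_direction()].
#' @param n_datasets Number of cohorts in the design (default 10).
#' @param min_datasets Minimum number of same-direction cohorts (default 8).
#' @return A `"consensus_call"` data frame: `gene`, one direction column per
#'   cohort, `n_up`, `n_down`, `status` in `consistent_up`,
#'   `consistent_down`, `not_consistent`.
#' @export
consensus_vote <- function(calls, n_datasets = 10, min_datasets = 8) {
  if (!is.list(calls) || length(calls) == 0) stop("'calls' must be a non-empty list")
  if (min_datasets > n_datasets) {
    stop("min_datasets cannot exceed n_datasets")
  }
  if (length(calls) > n_datasets) {
    stop(sprintf("%d cohorts supplied but n_datasets = %d",
                 length(calls), n_datasets))
  }
  if (is.null(names(calls)) || any(names(calls) == "")) {
    names(calls) <- paste0("cohort_", seq_along(calls))
  }
  genes <- sort(unique(unlist(lapply(calls, names))))
  dir_mat <- matrix("ns", length(genes), length(calls),
                    dimnames = list(genes, names(calls)))
  for (j in seq_along(calls)) {
    v <- calls[[j]]
    v <- v[v %in% c("up", "down")]
    dir_mat[names(v), j] <- unname(v)
  }
  n_up <- rowSums(dir_mat == "up")
  n_down <- rowSums(dir_mat == "down")
  status <- rep("not_consistent", length(genes))
  status[n_up >= min_datasets & n_down == 0] <- "consistent_up"
  status[n_down >= min_datasets & n_up == 0] <- "consistent_down"
  out <- data.frame(gene = genes, dir_mat, n_up = n_up, n_down = n_down,
                    status = status, row.names = NULL,
                    check.names = FALSE, stringsAsFactors = FALSE)
  attr(out, "n_datasets") <- n_datasets
  attr(out, "min_datasets") <- min_datasets
  class(out) <- c("consensus_call", "data.frame")
  out
}

#' @export
print.consensus_call <- function(x, ...) {
  tab <- table(factor(x$status, levels = c("consistent_up",
                                           "consistent_down",
                                           "not_consistent")))
  cat(sprintf("Consensus calls over %d genes (>= %d of %d cohorts, exclusive direction)\n",
              nrow(x), attr(x, "min_datasets"), attr(x, "n_datasets")))
  cat(sprintf("  consistent_up: %d, consistent_down: %d, not_consistent: %d\n",
              tab[1], tab[2], tab[3]))
  invisible(x)
}

#' Full cross-cohort metabolic consensus procedure
#'
#' Convenience wrapper chaining the per-cohort steps: DE gate, adaptive
#' cutoff (computed on all gate-passing genes by default, or after
#' metabolic restriction with `cutoff_after_restriction = TRUE`), metabolic
#' restriction, direction classification, and the cross-cohort vote.
#'
#' @param tables Named list of per-cohort `"diffexp_table"` objects (raw;
#'   the gate is applied here).
#' @param metabolic_genes Character vector of metabolism-annotated gene ids.
#' @param p_max,lfc_min,absolute Gate parameters, see [apply_de_gate()].
#' @param n_datasets,min_datasets Vote parameters, see [consensus_vote()].
#' @param cutoff_after_restriction Compute the adaptive cutoff on the
#'   metabolic subset instead of all gate-passing genes.
#' @return A `"consensus_call"` table with per-cohort cutoffs in
#'   `attr(, "cutoffs")`.
#' @export
metabolic_consensus <- function(tables, metabolic_genes,
                                p_max = 0.001, lfc_min = 1.5, absolute = TRUE,
                                n_datasets = length(tables), min_datasets = 8,
                                cutoff_after_restriction = FALSE) {
  stopifnot(is.list(tables), length(tables) > 0)
  if (is.null(names(tables)) || any(names(tables) == "")) {
    names(tables) <- paste0("cohort_", seq_along(tables))
  }
  calls <- list()
  cutoffs <- numeric(0)
  for (nm in names(tables)) {
    gated <- apply_de_gate(tables[[nm]], p_max = p_max, lfc_min = lfc_min,
                           absolute = absolute)
    restricted <- restrict_to_metabolic(gated, metabolic_genes)
    cut_tab <- if (cutoff_after_restriction) restricted else gated
    cutoffs[nm] <- adaptive_cutoff(cut_tab)
    calls[[nm]] <- classify_direction(restricted, cutoffs[nm])
  }
  out <- consensus_vote(calls, n_datasets = n_datasets,
                        min_datasets = min_datasets)
  attr(out, "cutoffs") <- cutoffs
  out
}
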