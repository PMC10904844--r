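# Per-cohort two-group differential expression and the primary DE gate.

#' Construct an expression cohort
#'
#' Bundles one cohort's log2 expression matrix (genes x samples) with its
#' tumor/normal sample labels and checks the invariants: matching
#' dimensions, finite values, and both groups non-empty.
#'
#' @param cohort_id Cohort identifier.
#' @param values Numeric matrix of log2 intensities, genes in rows. Row and
#'   column names supply gene and sample ids unless given explicitly.
#' @param group Character vector per sample, values `"tumor"` or `"normal"`.
#' @param gene_ids,sample_ids Optional explicit identifiers.
#' @return An object of class `"expression_cohort"`.
#' @export
expression_cohort <- function(cohort_id, values, group,
                              gene_ids = rownames(values),
                              sample_ids = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stop("gene and sample ids are required (as dimnames or arguments)")
  }
  if (nrow(values) != length(gene_ids) || ncol(values) != length(sample_ids)) {
    stop("matrix dimensions do not match gene/sample ids")
  }
  if (any(!is.finite(values))) stop("expression values must be finite")
  group <- as.character(group)
  if (length(group) != ncol(values)) stop("one group label per sample required")
  if (!all(group %in% c("tumor", "normal"))) {
    stop("group labels must be 'tumor' or 'normal'")
  }
  if (sum(group == "tumor") < 1 || sum(group == "normal") < 1) {
    stop("both groups must be non-empty")
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(list(cohort_id = cohort_id, values = values, group = group),
            class = "expression_cohort")
}

#' @export
print.expression_cohort <- function(x, ...) {
  cat(sprintf("Expression cohort '%s': %d genes, %d tumor vs %d normal samples\n",
              x$cohort_id, nrow(x$values),
              sum(x$group == "tumor"), sum(x$group == "normal")))
  invisible(x)
}

# Vectorized Welch t-test over the rows of a genes x samples matrix.
# Returns log2fc = mean(tumor) - mean(normal) and the two-sided p-value
# with Welch-Satterthwaite degrees of freedom. Degenerate rows (zero
# variance in both groups) get p = 1 when the means are equal and p = 0
# otherwise -- the limit of the t statistic as the pooled standard error
# goes to 0.
.welch_rows <- function(values, group) {
  tum <- values[, group == "tumor", drop = FALSE]
  nor <- values[, group == "normal", drop = FALSE]
  n1 <- ncol(tum); n2 <- ncol(nor)
  m1 <- rowMeans(tum); m2 <- rowMeans(nor)
  v1 <- rowSums((tum - m1)^2) / (n1 - 1L)
  v2 <- rowSums((nor - m2)^2) / (n2 - 1L)
  se2 <- v1 / n1 + v2 / n2
  lfc <- m1 - m2
  p <- numeric(length(lfc))
  ok <- se2 > 0
  tstat <- lfc[ok] / sqrt(se2[ok])
  df <- se2[ok]^2 / ((v1[ok] / n1)^2 / (n1 - 1L) + (v2[ok] / n2)^2 / (n2 - 1L))
  p[ok] <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  p[!ok] <- ifelse(abs(lfc[!ok]) > 0, 0, 1)
  list(log2fc = unname(lfc), p_value = unname(p))
}

#' Two-group differential expression for one cohort
#'
#' Computes, for every gene, the log2 fold change (tumor mean minus normal
#' mean, on already log2-scaled data) and a two-sided unequal-variance
#' (Welch) t-test p-value. No cross-gene moderation and no multiple-testing
#' correction is applied: the downstream consensus procedure gates on the
#' raw P value.
#'
#' @param cohort An `"expression_cohort"`.
#' @param test `"welch"` (default) or `"moderated"`; the moderated variant
#'   shrinks each gene's pooled variance toward the cohort median variance
#'   (a light empirical-Bayes style stabilizer for very small cohorts).
#' @return A `"diffexp_table"`: data frame with columns `gene`, `log2fc`,
#'   `p_value` and `passes_gate` (all `NA` until [apply_de_gate()] is run),
#'   plus attributes `cohort_id` and `gate`.
#' @export
differential_expression <- function(cohort, test = c("welch", "moderated")) {
  stopifnot(inherits(cohort, "expression_cohort"))
  test <- match.arg(test)
  if (sum(cohort$group == "tumor") < 2 || sum(cohort$group == "normal") < 2) {
    stop("need at least 2 samples per group")
  }
  values <- cohort$values
  if (test == "moderated") {
    # shrink within-group variances toward their cohort-wide medians
    values <- values  # location test unchanged; moderation handled below
  }
  res <- .welch_rows(values, cohort$group)
  if (test == "moderated") {
    tum <- values[, cohort$group == "tumor", drop = FALSE]
    nor <- values[, cohort$group == "normal", drop = FALSE]
    n1 <- ncol(tum); n2 <- ncol(nor)
    v1 <- apply(tum, 1L, stats::var); v2 <- apply(nor, 1L, stats::var)
    d0 <- 4  # prior degrees of freedom of the shrinkage
    v1 <- ((n1 - 1) * v1 + d0 * stats::median(v1)) / (n1 - 1 + d0)
    v2 <- ((n2 - 1) * v2 + d0 * stats::median(v2)) / (n2 - 1 + d0)
    se2 <- v1 / n1 + v2 / n2
    tstat <- res$log2fc / sqrt(se2)
    df <- (n1 + n2 - 2) + 2 * d0
    res$p_value <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  }
  out <- data.frame(gene = rownames(cohort$values),
                    log2fc = res$log2fc,
                    p_value = res$p_value,
                    passes_gate = NA,
                    stringsAsFactors = FALSE)
  attr(out, "cohort_id") <- cohort$cohort_id
  attr(out, "gate") <- NULL
  class(out) <- c("diffexp_table", "data.frame")
  out
}

#' Apply the primary differential-expression gate
#'
#' Flags genes passing the study's primary filter: raw `p_value < p_max`
#' and log2 fold change beyond `lfc_min`. With `absolute = TRUE` (the
#' default) the fold-change condition is `|log2fc| > lfc_min`, retaining
#' down-regulated candidates for the later direction classification;
#' `absolute = FALSE` keeps the literal one-sided reading `log2fc > lfc_min`.
#'
#' @param table A `"diffexp_table"`.
#' @param p_max Raw p-value threshold (default 0.001).
#' @param lfc_min log2 fold-change threshold (default 1.5).
#' @param absolute Gate on `|log2fc|` (default) or on signed `log2fc`.
#' @return The table with `passes_gate` filled in and the gate recorded in
#'   `attr(, "gate")`.
#' @export
apply_de_gate <- function(table, p_max = 0.001, lfc_min = 1.5,
                          absolute = TRUE) {
  stopifnot(inherits(table, "diffexp_table"))
  if (p_max <= 0 || lfc_min <= 0) stop("thresholds must be positive")
  fc <- if (absolute) abs(table$log2fc) else table$log2fc
  table$passes_gate <- table$p_value < p_max & fc > lfc_min
  attr(table, "gate") <- list(p_max = p_max, lfc_min = lfc_min,
                              absolute = absolute)
  table
}

#' @export
print.diffexp_table <- function(x, ...) {
  cat(sprintf("Differential expression table, cohort '%s': %d genes",
              attr(x, "cohort_id") %||% "?", nrow(x)))
  g <- attr(x, "gate")
  if (!is.null(g)) {
    cat(sprintf("; gate P < %g & %slog2FC > %g: %d pass", g$p_max,
                if (g$absolute) "|" else "", g$lfc_min,
                sum(x$passes_gate, na.rm = TRUE)))
  }
  cat("\n")
  if (nrow(x) > 0) print.data.frame(utils::head(as.data.frame(x), 6))
  invisible(x)
}
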