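# Cross-platform confirmation of array hits by qPCR, gluten-free-diet
# response classification, and 18S-based cell-yield estimation.

.round_half_up <- function(x) floor(x + 0.5)

#' Summarize qPCR confirmation of array-selected genes
#'
#' A gene is confirmed when its qPCR comparison (case versus control) is
#' significant at `alpha` and its case-group median RQ exceeds 1, i.e. the
#' upward direction reproduces. Selected genes without qPCR data are listed
#' as untested, not as failures.
#'
#' @param selected_genes Character vector of array-selected gene identifiers.
#' @param qpcr_comparisons Data frame with columns `gene_id`, `p`
#'   (two-sided case-vs-control p-value) and `median_rq_case` (case-group
#'   median relative quantity).
#' @param alpha Significance level (default 0.05).
#' @return An object of class `confirmation_report`: `per_gene` (data frame
#'   with `confirmed` flag), `n_tested`, `n_confirmed`, `percentage`
#'   (rounded half-up to an integer; `NA` when nothing was tested) and
#'   `untested`.
#' @export
confirmation_summary <- function(selected_genes, qpcr_comparisons,
                                 alpha = 0.05) {
  need <- c("gene_id", "p", "median_rq_case")
  if (!all(need %in% names(qpcr_comparisons)))
    stop("qpcr_comparisons needs columns: ", paste(need, collapse = ", "))
  tested <- qpcr_comparisons[qpcr_comparisons$gene_id %in% selected_genes, ]
  untested <- setdiff(selected_genes, tested$gene_id)
  confirmed <- tested$p <= alpha & tested$median_rq_case > 1
  per_gene <- data.frame(gene_id = tested$gene_id, p = tested$p,
                         median_rq_case = tested$median_rq_case,
                         confirmed = confirmed, stringsAsFactors = FALSE)
  n_tested <- nrow(tested)
  n_confirmed <- sum(confirmed)
  structure(list(
    per_gene = per_gene,
    n_tested = n_tested,
    n_confirmed = n_confirmed,
    percentage = if (n_tested > 0L)
      .round_half_up(100 * n_confirmed / n_tested) else NA_real_,
    untested = untested,
    alpha = alpha
  ), class = "confirmation_report")
}

#' @export
print.confirmation_report <- function(x, ...) {
  if (x$n_tested == 0L) {
    cat("Confirmation report: no genes tested\n")
  } else {
    cat(sprintf("Confirmation report: %d of %d tested genes confirmed (%d%%)\n",
                x$n_confirmed, x$n_tested, x$percentage))
  }
  if (length(x$untested))
    cat("untested:", paste(x$untested, collapse = ", "), "\n")
  invisible(x)
}

#' Classify the response to a gluten-free diet
#'
#' Compares treated-patient expression against controls, gene by gene:
#' `normalized` when the treated-versus-control comparison is not significant
#' (expression returned to the control range), `persistent_elevated` when it
#' is significant with RQ above 1, and `decreased_below` when significant
#' with RQ below 1. A significant comparison at RQ exactly 1 is degenerate
#' and reported as normalized with a warning.
#'
#' @param active_vs_ctrl Data frame with `gene_id`, `rq`, `p` for the
#'   active-disease versus control comparison (used to align the gene set).
#' @param treated_vs_ctrl Data frame with `gene_id`, `rq`, `p` for the
#'   treated versus control comparison.
#' @param alpha Significance level (default 0.05).
#' @return Data frame: `gene_id`, `category` (factor with the three levels),
#'   `rq_treated`, `p_treated_vs_ctrl`.
#' @export
classify_gfd_response <- function(active_vs_ctrl, treated_vs_ctrl,
                                  alpha = 0.05) {
  for (df in list(active_vs_ctrl, treated_vs_ctrl))
    if (!all(c("gene_id", "rq", "p") %in% names(df)))
      stop("both comparisons need columns gene_id, rq, p")
  if (!setequal(active_vs_ctrl$gene_id, treated_vs_ctrl$gene_id))
    stop("both comparisons must cover the same genes")
  tv <- treated_vs_ctrl[match(active_vs_ctrl$gene_id,
                              treated_vs_ctrl$gene_id), ]
  sig <- tv$p <= alpha
  if (any(sig & tv$rq == 1))
    warning("significant comparison at RQ exactly 1; reported as normalized")
  category <- ifelse(!sig | tv$rq == 1, "normalized",
                     ifelse(tv$rq > 1, "persistent_elevated",
                            "decreased_below"))
  data.frame(
    gene_id = tv$gene_id,
    category = factor(category, levels = c("normalized",
                                           "persistent_elevated",
                                           "decreased_below")),
    rq_treated = tv$rq,
    p_treated_vs_ctrl = tv$p,
    stringsAsFactors = FALSE
  )
}

#' Estimate cell yield from total 18S rRNA
#'
#' Purified intestinal epithelial cells contain approximately 1 U of 18S rRNA
#' per cell (1 U = the 18S amount in 10 pg of the RNA standard), so the total
#' unit count approximates the cell count. The estimate carries an
#' `approximate` attribute as a reminder that the per-cell content is an
#' empirical constant, not an exact one.
#'
#' @param total_units Non-negative total 18S amount(s) in U.
#' @param units_per_cell 18S content per cell in U (default 1).
#' @return Estimated cell count(s), with attribute `approximate = TRUE`.
#' @export
cells_from_18s <- function(total_units, units_per_cell = 1) {
  if (any(total_units < 0)) stop("total_units must be non-negative")
  stopifnot(units_per_cell > 0)
  structure(total_units / units_per_cell, approximate = TRUE)
}
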