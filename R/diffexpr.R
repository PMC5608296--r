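# Median-ratio differential expression with the study's zero conventions,
# empirical RQ-cutoff calibration, and final gene selection.

.check_matrix <- function(m, what) {
  if (!is.matrix(m) || !is.numeric(m))
    stop(what, " must be a numeric matrix (genes x samples)")
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    stop(what, " must have unique gene identifiers as rownames")
  m
}

.row_medians <- function(m) apply(m, 1L, stats::median)

#' Per-gene relative quantity and exact rank test
#'
#' For each gene, negative signals are set to 0, group medians are taken,
#' a control median of 0 is replaced by `zero_substitute`, the relative
#' quantity RQ is the ratio of the case median to the (substituted) control
#' median, and an exact two-sided Mann-Whitney U test compares the two groups.
#' Genes with RQ < 1 are retained but flagged, since the analysis focuses on
#' upregulation.
#'
#' @param case,ctrl Numeric gene-by-sample matrices sharing the same gene
#'   universe (rownames). Signals are in arbitrary units and may be negative
#'   on input.
#' @param zero_substitute Value substituted for a control median of 0
#'   (default 0.01 AU).
#' @return A data frame with one row per gene: `gene_id`, `median_case`,
#'   `median_ctrl` (post-substitution), `rq`, `u_stat`, `p`, and the logical
#'   `rq_ge_1`.
#' @export
gene_rq_table <- function(case, ctrl, zero_substitute = 0.01) {
  .check_matrix(case, "case")
  .check_matrix(ctrl, "ctrl")
  if (!setequal(rownames(case), rownames(ctrl)))
    stop("case and ctrl matrices must share the same gene universe")
  ctrl <- ctrl[rownames(case), , drop = FALSE]
  case <- pmax(case, 0)
  ctrl <- pmax(ctrl, 0)

  med_case <- .row_medians(case)
  med_ctrl <- .row_medians(ctrl)
  med_ctrl_sub <- ifelse(med_ctrl == 0, zero_substitute, med_ctrl)
  rq <- med_case / med_ctrl_sub

  tests <- lapply(seq_len(nrow(case)), function(i) {
    exact_mwu(case[i, ], ctrl[i, ])
  })
  data.frame(
    gene_id = rownames(case),
    median_case = unname(med_case),
    median_ctrl = unname(med_ctrl_sub),
    rq = unname(rq),
    u_stat = vapply(tests, `[[`, numeric(1), "u_stat"),
    p = vapply(tests, `[[`, numeric(1), "p_two_sided"),
    rq_ge_1 = unname(rq >= 1),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Calibrate the RQ cut-off against the empirical significant fraction
#'
#' For each candidate cut-off c, computes the fraction of genes with RQ above
#' c whose exact test p-value is at or below `alpha`. The chosen cut-off is
#' the smallest grid value at which that fraction exceeds `alpha` -- i.e. the
#' point where significant genes become more frequent than expected by chance
#' alone. Callers should pre-filter to expressed genes with RQ >= 1.
#'
#' @param results Data frame from [gene_rq_table()] (columns `rq`, `p`).
#' @param alpha Significance level (default 0.05).
#' @param grid Strictly ascending RQ cut-offs (default 1.0 to 3.0 by 0.1).
#' @param banded If `TRUE`, the fraction at cut-off c uses only genes with RQ
#'   in (c, next grid value] instead of all genes above c.
#' @return An object of class `rq_calibration`: a list with `curve` (data
#'   frame of `cutoff`, `n_above`, `n_significant`, `frac_significant`; the
#'   fraction is `NA` where no gene lies above the cut-off), `chosen_cutoff`
#'   (`NA` if the fraction never exceeds `alpha`) and `alpha`.
#' @export
calibrate_rq_cutoff <- function(results, alpha = 0.05,
                                grid = seq(1, 3, by = 0.1),
                                banded = FALSE) {
  if (length(grid) == 0L) stop("cut-off grid must be non-empty")
  if (is.unsorted(grid, strictly = TRUE)) stop("grid must be strictly ascending")
  if (nrow(results) == 0L) stop("results must be non-empty")

  upper <- c(grid[-1L], Inf)
  curve <- do.call(rbind, lapply(seq_along(grid), function(i) {
    sel <- if (banded) results$rq > grid[i] & results$rq <= upper[i]
           else results$rq > grid[i]
    n_above <- sum(sel)
    n_sig <- sum(sel & results$p <= alpha)
    data.frame(cutoff = grid[i], n_above = n_above, n_significant = n_sig,
               frac_significant = if (n_above > 0L) n_sig / n_above else NA_real_)
  }))
  exceed <- which(!is.na(curve$frac_significant) &
                    curve$frac_significant > alpha)
  structure(list(curve = curve,
                 chosen_cutoff = if (length(exceed)) grid[min(exceed)] else NA_real_,
                 alpha = alpha, banded = banded),
            class = "rq_calibration")
}

#' @export
print.rq_calibration <- function(x, ...) {
  cat("RQ cut-off calibration (alpha =", x$alpha, ")\n")
  print(x$curve, row.names = FALSE)
  cat("chosen cut-off:",
      if (is.na(x$chosen_cutoff)) "none" else x$chosen_cutoff, "\n")
  invisible(x)
}

#' Selection criteria for genes of interest
#'
#' The defaults mirror the final screening rule: expressed at >= 15 AU,
#' case-group median signal >= 60 AU, RQ >= 1.8, exact test p <= 0.05,
#' upregulated only.
#'
#' @param expressed_min_signal Minimum case median signal (AU) for a gene to
#'   count as expressed (default 15).
#' @param min_signal_case Minimum case median signal (AU) for final selection
#'   (default 60).
#' @param min_rq Minimum relative quantity (default 1.8).
#' @param alpha Significance level (default 0.05).
#' @param up_only Restrict to RQ >= 1 (default `TRUE`).
#' @return A validated list of class `selection_criteria`.
#' @export
selection_criteria <- function(expressed_min_signal = 15,
                               min_signal_case = 60,
                               min_rq = 1.8,
                               alpha = 0.05,
                               up_only = TRUE) {
  stopifnot(expressed_min_signal >= 0, min_signal_case >= 0, min_rq >= 0,
            alpha > 0, alpha < 1, is.logical(up_only))
  structure(list(expressed_min_signal = expressed_min_signal,
                 min_signal_case = min_signal_case,
                 min_rq = min_rq, alpha = alpha, up_only = up_only),
            class = "selection_criteria")
}

#' Select genes of interest
#'
#' Applies the four filters in order -- expressed (case median at or above the
#' expressed threshold, and RQ >= 1 when upregulation-only), significant
#' (p <= alpha), fold change (RQ >= min_rq), signal (case median >= the final
#' signal threshold) -- and reports the count surviving each step.
#'
#' @param results Data frame from [gene_rq_table()].
#' @param criteria A [selection_criteria()] object.
#' @return An object of class `gene_selection`: `selected` (gene ids),
#'   `audit` (data frame of cumulative counts per filter), and `table`
#'   (`results` with a logical `selected` column).
#' @export
select_genes <- function(results, criteria = selection_criteria()) {
  stopifnot(inherits(criteria, "selection_criteria"))
  keep <- rep(TRUE, nrow(results))
  steps <- c(input = sum(keep))
  keep <- keep & results$median_case >= criteria$expressed_min_signal &
    (!criteria$up_only | results$rq >= 1)
  steps <- c(steps, expressed = sum(keep))
  keep <- keep & results$p <= criteria$alpha
  steps <- c(steps, significant = sum(keep))
  keep <- keep & results$rq >= criteria$min_rq
  steps <- c(steps, rq = sum(keep))
  keep <- keep & results$median_case >= criteria$min_signal_case
  steps <- c(steps, signal = sum(keep))

  table <- results
  table$selected <- keep
  structure(list(selected = results$gene_id[keep],
                 audit = data.frame(step = names(steps), n = unname(steps)),
                 table = table,
                 criteria = criteria),
            class = "gene_selection")
}

#' @export
print.gene_selection <- function(x, ...) {
  cat("Gene selection:", length(x$selected), "genes\n")
  print(x$audit, row.names = FALSE)
  invisible(x)
}
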