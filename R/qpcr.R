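# 18S standard-curve quantification, delta-delta-CT relative quantity,
# QC filtering, and group-comparison statistics for qPCR tables.

.check_qpcr_table <- function(table) {
  need <- c("gene_id", "sample_id", "ct")
  if (!all(need %in% names(table)))
    stop("qPCR table needs columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(table$ct)) || any(table$ct <= 0))
    stop("CT values must be positive and finite")
  invisible(table)
}

#' Fit a standard curve to a dilution series
#'
#' Least-squares line of CT against log10(amount), with replicate CTs averaged
#' per dilution point. The amplification efficiency is `10^(-1/slope)` (a
#' perfect doubling assay has slope -1/log10(2) = -3.3219 cycles per decade,
#' efficiency 2).
#'
#' @param series Data frame with columns `amount_pg` (or `amount`) and `ct`.
#' @return An object of class `standard_curve`: `slope` (cycles per log10
#'   amount), `intercept` (CT at 1 pg), `efficiency`, `r_squared`,
#'   `n_points`, and the averaged `points`.
#' @export
fit_standard_curve <- function(series) {
  amt_col <- intersect(c("amount_pg", "amount"), names(series))[1]
  if (is.na(amt_col) || !"ct" %in% names(series))
    stop("series needs columns amount_pg (or amount) and ct")
  amounts <- series[[amt_col]]
  stopifnot(all(amounts > 0), all(is.finite(series$ct)))
  pts <- stats::aggregate(list(ct = series$ct), list(amount_pg = amounts),
                          mean)
  if (nrow(pts) < 3L) stop("at least 3 distinct dilution amounts required")
  fit <- stats::lm(ct ~ log10(amount_pg), data = pts)
  slope <- unname(stats::coef(fit)[2])
  if (slope >= 0)
    stop("fit-quality error: standard-curve slope must be negative")
  ss_tot <- sum((pts$ct - mean(pts$ct))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else NA_real_
  structure(list(
    slope = slope,
    intercept = unname(stats::coef(fit)[1]),
    efficiency = 10^(-1 / slope),
    r_squared = r2,
    n_points = nrow(pts),
    points = pts
  ), class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "Standard curve: slope %.4f cycles/log10, efficiency %.3f, r^2 %.4f (%d points)\n",
    x$slope, x$efficiency, x$r_squared, x$n_points))
  invisible(x)
}

#' Quantify 18S rRNA from a CT value
#'
#' Inverts the standard curve to an amount in pg and converts to units via the
#' 10 pg = 1 U anchor of the RNA standard. With about 1 U of 18S rRNA per
#' epithelial cell, the unit count doubles as a cell-yield estimate (see
#' [cells_from_18s()]).
#'
#' @param ct Numeric vector of CT values (cycles).
#' @param curve A fitted [fit_standard_curve()] object.
#' @return Amounts in U (vectorized).
#' @export
quantify_18s <- function(ct, curve) {
  if (!inherits(curve, "standard_curve")) stop("curve must be a fitted standard_curve")
  amount_pg <- 10^((ct - curve$intercept) / curve$slope)
  amount_pg / 10
}

.mean_ct <- function(table) {
  stats::aggregate(list(ct = table$ct),
                   list(gene_id = table$gene_id, sample_id = table$sample_id),
                   mean)
}

#' Relative quantity by the delta-delta-CT method
#'
#' Per sample, replicate CTs are averaged; delta-CT is the target CT minus the
#' housekeeping (18S) CT in the same sample; delta-delta-CT subtracts the
#' median delta-CT of the reference-group samples for that gene; the relative
#' quantity is 2^(-delta-delta-CT). By construction the reference group has
#' median RQ 1 (exactly so for odd group sizes).
#'
#' @param table Long qPCR data frame: `gene_id`, `sample_id`, `ct` (one row
#'   per replicate).
#' @param sample_sheet Data frame with `sample_id` and `group`.
#' @param housekeeping Housekeeping gene identifier (default `"18S"`).
#' @param reference_group Group whose median delta-CT anchors the scale
#'   (default `"control"`).
#' @return Data frame: `gene_id`, `sample_id`, `group`, `delta_ct`,
#'   `delta_delta_ct`, `rq`, with the reference group recorded as an
#'   attribute.
#' @export
relative_quantity <- function(table, sample_sheet, housekeeping = "18S",
                              reference_group = "control") {
  .check_qpcr_table(table)
  stopifnot(all(c("sample_id", "group") %in% names(sample_sheet)))
  if (!reference_group %in% sample_sheet$group)
    stop("reference group '", reference_group, "' has no samples")
  mct <- .mean_ct(table)
  hk <- mct[mct$gene_id == housekeeping, ]
  targets <- mct[mct$gene_id != housekeeping, ]
  missing_hk <- setdiff(unique(targets$sample_id), hk$sample_id)
  if (length(missing_hk))
    stop("housekeeping CT missing for sample(s): ",
         paste(missing_hk, collapse = ", "))

  targets$delta_ct <- targets$ct -
    hk$ct[match(targets$sample_id, hk$sample_id)]
  targets$group <-
    sample_sheet$group[match(targets$sample_id, sample_sheet$sample_id)]
  if (anyNA(targets$group))
    stop("sample(s) missing from sample sheet: ",
         paste(unique(targets$sample_id[is.na(targets$group)]), collapse = ", "))

  ref_med <- tapply(targets$delta_ct[targets$group == reference_group],
                    targets$gene_id[targets$group == reference_group],
                    stats::median)
  if (anyNA(ref_med[unique(targets$gene_id)]))
    stop("reference group lacks measurements for some gene(s)")
  targets$delta_delta_ct <- targets$delta_ct -
    as.vector(ref_med[targets$gene_id])
  targets$rq <- 2^(-targets$delta_delta_ct)
  out <- targets[order(targets$gene_id, targets$sample_id),
                 c("gene_id", "sample_id", "group", "delta_ct",
                   "delta_delta_ct", "rq")]
  rownames(out) <- NULL
  attr(out, "reference_group") <- reference_group
  out
}

#' QC-filter samples by 18S rRNA content
#'
#' Removes samples whose 18S amount does not exceed the threshold (the assay
#' requires more than 25 U per reaction) and logs the exclusions.
#'
#' @param table Long qPCR data frame.
#' @param units_18s Named numeric vector: 18S amount (U) per sample.
#' @param min_units Threshold in U (default 25); samples at or below it are
#'   excluded.
#' @return List with `table` (retained rows) and `excluded` (data frame of
#'   `sample_id`, `units_18s`).
#' @export
qc_filter <- function(table, units_18s, min_units = 25) {
  .check_qpcr_table(table)
  if (is.null(names(units_18s))) stop("units_18s must be named by sample")
  samples <- unique(table$sample_id)
  missing <- setdiff(samples, names(units_18s))
  if (length(missing))
    stop("18S amount missing for sample(s): ", paste(missing, collapse = ", "))
  bad <- samples[units_18s[samples] <= min_units]
  list(
    table = table[!table$sample_id %in% bad, , drop = FALSE],
    excluded = data.frame(sample_id = bad,
                          units_18s = unname(units_18s[bad]),
                          stringsAsFactors = FALSE)
  )
}

#' Compare groups of per-sample quantities
#'
#' Three designs mirroring the study's statistics: `"mwu"` -- exact two-sided
#' Mann-Whitney U ([exact_mwu()]) for two groups; `"ttest"` -- classical
#' two-sided two-sample Student's t (equal variances); `"anova_dunnett"` --
#' one-way ANOVA F test plus per-treatment-versus-control comparisons adjusted
#' for multiplicity by a seeded Monte-Carlo max-|t| null (parametric residual
#' resampling at the pooled SD under H0).
#'
#' Group tests are intended to run on delta-CT values; since log2(RQ) is an
#' affine function of delta-CT, t statistics and rank tests are identical on
#' either scale (up to sign).
#'
#' @param values Numeric vector of per-sample quantities (delta-CT or
#'   log2 RQ).
#' @param groups Group label per value.
#' @param design One of `"mwu"`, `"ttest"`, `"anova_dunnett"`.
#' @param reference Reference/control group label (required for
#'   `anova_dunnett`; for two-group designs, defaults to the second group).
#' @param n_resample Monte-Carlo resamples for the Dunnett null
#'   (default 100,000).
#' @param seed Seed for the Monte-Carlo draw.
#' @return An object of class `group_comparison`: `design`, `comparisons`
#'   (one row per non-reference group with statistic and p-values; in Dunnett
#'   mode `p_unadjusted` and `p_adjusted` are Monte-Carlo estimates from the
#'   same draws, so adjusted >= unadjusted always, and `p_t` is the
#'   closed-form unadjusted t p-value), and for ANOVA the `f_statistic` and
#'   `p_f`.
#' @export
compare_groups <- function(values, groups,
                           design = c("mwu", "ttest", "anova_dunnett"),
                           reference = NULL, n_resample = 1e5, seed = 1L) {
  design <- match.arg(design)
  stopifnot(length(values) == length(groups), is.numeric(values))
  groups <- as.character(groups)
  levels <- unique(groups)
  if (length(levels) < 2L) stop("at least two groups required")

  if (design %in% c("mwu", "ttest")) {
    if (length(levels) != 2L)
      stop(design, " design requires exactly two groups")
    reference <- reference %||% levels[2L]
    other <- setdiff(levels, reference)
    x <- values[groups == other]
    y <- values[groups == reference]
    if (design == "mwu") {
      res <- exact_mwu(x, y)
      comp <- data.frame(group = other, reference = reference,
                         statistic = res$u_stat, p = res$p_two_sided,
                         stringsAsFactors = FALSE)
    } else {
      if (length(x) < 2L || length(y) < 2L)
        stop("t test requires at least 2 values per group")
      tt <- stats::t.test(x, y, var.equal = TRUE)
      comp <- data.frame(group = other, reference = reference,
                         statistic = unname(tt$statistic),
                         p = tt$p.value, stringsAsFactors = FALSE)
    }
    return(structure(list(design = design, comparisons = comp),
                     class = "group_comparison"))
  }

  # one-way ANOVA with Monte-Carlo Dunnett-style adjustment
  if (is.null(reference)) stop("anova_dunnett requires a reference group")
  if (!reference %in% levels) stop("reference group not found")
  n_g <- table(groups)
  if (any(n_g < 2L)) stop("ANOVA requires at least 2 values per group")
  fac <- factor(groups, levels = c(reference, setdiff(levels, reference)))
  fit <- stats::lm(values ~ fac)
  av <- stats::anova(fit)
  df_err <- av$Df[2L]
  s_p <- sqrt(av$`Mean Sq`[2L])
  treatments <- setdiff(levels, reference)
  m_ref <- mean(values[groups == reference])
  n_ref <- sum(groups == reference)
  est <- vapply(treatments, function(g) mean(values[groups == g]) - m_ref,
                numeric(1))
  se <- vapply(treatments, function(g)
    s_p * sqrt(1 / sum(groups == g) + 1 / n_ref), numeric(1))
  t_obs <- est / se

  # Monte-Carlo null: normal residuals at the pooled SD, all means equal
  set.seed(seed)
  n_tot <- length(values)
  idx <- split(seq_len(n_tot), groups)
  eps <- matrix(stats::rnorm(n_tot * n_resample), n_tot, n_resample)
  gmeans <- vapply(levels, function(g) colMeans(eps[idx[[g]], , drop = FALSE]),
                   numeric(n_resample))
  ss_within <- 0
  for (g in levels) {
    dev <- eps[idx[[g]], , drop = FALSE] -
      matrix(gmeans[, g], length(idx[[g]]), n_resample, byrow = TRUE)
    ss_within <- ss_within + colSums(dev^2)
  }
  s_star <- sqrt(ss_within / df_err)
  t_star <- vapply(treatments, function(g) {
    (gmeans[, g] - gmeans[, reference]) /
      (s_star * sqrt(1 / sum(groups == g) + 1 / n_ref))
  }, numeric(n_resample))
  max_abs <- apply(abs(t_star), 1L, max)
  p_unadj <- vapply(seq_along(treatments), function(k)
    mean(abs(t_star[, k]) >= abs(t_obs[k])), numeric(1))
  p_adj <- vapply(t_obs, function(t0) mean(max_abs >= abs(t0)), numeric(1))

  comp <- data.frame(
    group = treatments, reference = reference,
    estimate = est, statistic = t_obs,
    p_t = 2 * stats::pt(-abs(t_obs), df_err),
    p_unadjusted = pmax(p_unadj, 1 / n_resample),
    p_adjusted = pmax(p_adj, 1 / n_resample),
    stringsAsFactors = FALSE
  )
  rownames(comp) <- NULL
  structure(list(design = design, comparisons = comp,
                 f_statistic = av$`F value`[1L], p_f = av$`Pr(>F)`[1L],
                 df = c(av$Df[1L], df_err), n_resample = n_resample,
                 seed = seed),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Group comparison (", x$design, ")\n", sep = "")
  if (!is.null(x$f_statistic))
    cat(sprintf("one-way ANOVA: F(%d, %d) = %.3f, p = %.4g\n",
                x$df[1], x$df[2], x$f_statistic, x$p_f))
  print(x$comparisons, row.names = FALSE)
  invisible(x)
}
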