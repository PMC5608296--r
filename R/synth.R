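# Seeded generators for bead-array and qPCR datasets with the statistical
# structure the downstream analysis assumes: log-normal AU signals, small
# groups, planted multiplicative upregulation, IEL-only T-cell markers,
# 5-10% IEL admixture into observed IEC profiles, additive background noise
# producing occasional negative signals, and CT triplicates at efficiency 2.

DEFAULT_MARKERS <- c("CD3D", "CD3G", "CD2", "CD7", "CD8A", "CD247")

#' Configuration for the synthetic array generator
#'
#' Defaults emulate the study design: 18,401 genes on the array, four active
#' celiac (case) and four control IEC samples, five IEL samples, log-normal
#' baseline signals spanning below 15 to above 10,000 AU with roughly half the
#' genes expressed at >= 15 AU, 5-10% IEL admixture per sample, and six
#' T-lymphocyte marker genes expressed only in the IEL population.
#'
#' @param n_genes Total genes including the marker panel.
#' @param n_case,n_ctrl,n_iel Samples per arm.
#' @param frac_de Fraction of (non-marker) genes planted as upregulated in
#'   cases.
#' @param effect_rq_range Range of multiplicative effects (both >= 1) from
#'   which planted effects are drawn uniformly.
#' @param baseline_log_mean,baseline_log_sd Log-scale parameters of the
#'   baseline AU distribution.
#' @param cv_within Within-group coefficient of variation of the multiplicative
#'   log-normal sample noise.
#' @param contamination_fractions Per-case-sample IEL admixture fractions in
#'   \[0, 0.2\]; `NULL` draws them uniformly from `contamination_range`.
#' @param contamination_fractions_ctrl Same for control samples; `NULL` draws
#'   from `contamination_range`.
#' @param contamination_range Range used when fractions are not given
#'   (default 0.05-0.10).
#' @param marker_genes Identifiers of IEL-only marker genes (zero signal in
#'   pure IEC).
#' @param marker_iel_log_mean,marker_iel_log_sd Log-scale parameters of marker
#'   expression in the IEL profile.
#' @param background_sd SD (AU) of additive background noise applied after
#'   mixing; produces occasional negative signals. Set 0 for noiseless data.
#' @param de_baseline_min Planted genes are drawn only from genes whose
#'   baseline is at least this signal (AU), so planted effects act on
#'   expressed genes (default 15).
#' @param seed Integer seed; identical seeds give bit-identical datasets.
#' @return A validated list of class `array_sim_config`.
#' @export
array_sim_config <- function(n_genes = 18401L,
                             n_case = 4L, n_ctrl = 4L, n_iel = 5L,
                             frac_de = 0.02,
                             effect_rq_range = c(1.8, 10),
                             baseline_log_mean = 3.0,
                             baseline_log_sd = 2.2,
                             cv_within = 0.3,
                             contamination_fractions = NULL,
                             contamination_fractions_ctrl = NULL,
                             contamination_range = c(0.05, 0.10),
                             marker_genes = DEFAULT_MARKERS,
                             marker_iel_log_mean = log(2000),
                             marker_iel_log_sd = 0.3,
                             background_sd = 5,
                             de_baseline_min = 15,
                             seed = 1L) {
  stopifnot(n_genes > length(marker_genes), n_case >= 1, n_ctrl >= 1,
            n_iel >= 1)
  if (frac_de < 0 || frac_de > 1) stop("frac_de must be in [0, 1]")
  if (length(effect_rq_range) != 2L || effect_rq_range[1] < 1 ||
      diff(effect_rq_range) < 0)
    stop("effect_rq_range must be an ascending pair with lower bound >= 1")
  check_frac <- function(f, n, what) {
    if (is.null(f)) return(invisible())
    if (length(f) != n) stop(what, " must have one fraction per sample")
    if (any(f < 0 | f > 0.2)) stop(what, " must lie in [0, 0.2]")
  }
  check_frac(contamination_fractions, n_case, "contamination_fractions")
  check_frac(contamination_fractions_ctrl, n_ctrl,
             "contamination_fractions_ctrl")
  if (any(contamination_range < 0) || any(contamination_range > 0.2) ||
      diff(contamination_range) < 0)
    stop("contamination_range must be an ascending pair within [0, 0.2]")
  if (anyDuplicated(marker_genes)) stop("marker genes must be unique")
  stopifnot(cv_within >= 0, background_sd >= 0, de_baseline_min >= 0)
  structure(as.list(environment())[
    c("n_genes", "n_case", "n_ctrl", "n_iel", "frac_de", "effect_rq_range",
      "baseline_log_mean", "baseline_log_sd", "cv_within",
      "contamination_fractions", "contamination_fractions_ctrl",
      "contamination_range", "marker_genes", "marker_iel_log_mean",
      "marker_iel_log_sd", "background_sd", "de_baseline_min", "seed")],
    class = "array_sim_config")
}

.lognorm_noise <- function(n_genes, n_samples, sigma) {
  if (sigma == 0) return(matrix(1, n_genes, n_samples))
  matrix(exp(stats::rnorm(n_genes * n_samples, 0, sigma)), n_genes, n_samples)
}

#' Generate a synthetic bead-array dataset
#'
#' Draws pure IEC case/control and IEL expression matrices, plants
#' multiplicative upregulation in a random subset of expressed genes, and
#' forms the observed IEC matrices by convex admixture of the IEL expectation
#' profile: observed sample j = (1 - f_j) * pure_j + f_j * IEL profile +
#' additive background noise. Marker genes have zero pure-IEC signal and high
#' IEL signal, so their observed IEC signal is purely contamination.
#'
#' @param config An [array_sim_config()] object.
#' @return A list of class `synthetic_array` with matrices `pure_iec_case`,
#'   `pure_iec_ctrl`, `iel_matrix`, `observed_iec_case`, `observed_iec_ctrl`,
#'   the expectation vector `iel_profile` used for mixing, a `sample_sheet`
#'   data frame, the `truth` block (planted genes, true effects, admixture
#'   fractions, seed) and the `config`.
#' @export
generate_array_dataset <- function(config = array_sim_config()) {
  stopifnot(inherits(config, "array_sim_config"))
  set.seed(config$seed)
  cf <- config
  n_mark <- length(cf$marker_genes)
  n_other <- cf$n_genes - n_mark
  gene_ids <- c(cf$marker_genes, sprintf("G%05d", seq_len(n_other)))
  is_marker <- gene_ids %in% cf$marker_genes

  baseline <- numeric(cf$n_genes)
  baseline[!is_marker] <- stats::rlnorm(n_other, cf$baseline_log_mean,
                                        cf$baseline_log_sd)

  n_de <- round(cf$frac_de * cf$n_genes)
  candidates <- which(!is_marker & baseline >= cf$de_baseline_min)
  if (n_de > length(candidates))
    stop("not enough genes above de_baseline_min to plant ", n_de, " effects")
  de_idx <- sort(sample(candidates, n_de))
  true_rq <- stats::runif(n_de, cf$effect_rq_range[1], cf$effect_rq_range[2])
  effect <- rep(1, cf$n_genes)
  effect[de_idx] <- true_rq

  sigma_w <- sqrt(log(1 + cf$cv_within^2))
  mk_mat <- function(expect, n, prefix) {
    m <- expect * .lognorm_noise(cf$n_genes, n, sigma_w)
    dimnames(m) <- list(gene_ids, sprintf("%s%02d", prefix, seq_len(n)))
    m
  }
  pure_case <- mk_mat(baseline * effect, cf$n_case, "CD_")
  pure_ctrl <- mk_mat(baseline, cf$n_ctrl, "CTR_")

  iel_profile <- numeric(cf$n_genes)
  iel_profile[!is_marker] <- stats::rlnorm(n_other, cf$baseline_log_mean,
                                           cf$baseline_log_sd)
  iel_profile[is_marker] <- stats::rlnorm(n_mark, cf$marker_iel_log_mean,
                                          cf$marker_iel_log_sd)
  names(iel_profile) <- gene_ids
  iel_mat <- mk_mat(iel_profile, cf$n_iel, "IEL_")

  f_case <- cf$contamination_fractions %||%
    stats::runif(cf$n_case, cf$contamination_range[1], cf$contamination_range[2])
  f_ctrl <- cf$contamination_fractions_ctrl %||%
    stats::runif(cf$n_ctrl, cf$contamination_range[1], cf$contamination_range[2])
  names(f_case) <- colnames(pure_case)
  names(f_ctrl) <- colnames(pure_ctrl)

  admix <- function(pure, f) {
    obs <- sweep(pure, 2L, 1 - f, `*`) + outer(iel_profile, f)
    if (cf$background_sd > 0)
      obs <- obs + matrix(stats::rnorm(length(obs), 0, cf$background_sd),
                          nrow(obs), ncol(obs))
    dimnames(obs) <- dimnames(pure)
    obs
  }
  obs_case <- admix(pure_case, f_case)
  obs_ctrl <- admix(pure_ctrl, f_ctrl)

  sample_sheet <- data.frame(
    sample_id = c(colnames(pure_case), colnames(pure_ctrl), colnames(iel_mat)),
    group = c(rep("active_cd", cf$n_case), rep("control", cf$n_ctrl),
              rep("active_cd", cf$n_iel)),
    population = c(rep("IEC", cf$n_case + cf$n_ctrl), rep("IEL", cf$n_iel)),
    stringsAsFactors = FALSE
  )

  structure(list(
    pure_iec_case = pure_case,
    pure_iec_ctrl = pure_ctrl,
    iel_matrix = iel_mat,
    iel_profile = iel_profile,
    observed_iec_case = obs_case,
    observed_iec_ctrl = obs_ctrl,
    sample_sheet = sample_sheet,
    truth = list(de_genes = gene_ids[de_idx],
                 true_rq = stats::setNames(true_rq, gene_ids[de_idx]),
                 contamination_fractions = f_case,
                 contamination_fractions_ctrl = f_ctrl,
                 seed = cf$seed),
    config = cf
  ), class = "synthetic_array")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a synthetic qPCR dataset with an 18S standard series
#'
#' Simulates CT triplicates for a panel of genes across sample groups, with a
#' per-gene abundance relative to 18S rRNA, group-specific fold changes, a
#' given amplification efficiency, and Gaussian replicate noise on the cycle
#' scale. A two-fold 18S dilution series anchored at the 10 pg = 1 U standard
#' is generated alongside. With efficiency 2 and no noise, doubling the true
#' abundance lowers CT by exactly one cycle.
#'
#' @param genes Character vector of target gene identifiers (the housekeeping
#'   gene `"18S"` is added automatically).
#' @param group_sizes Named integer vector of samples per group; defaults to
#'   the confirmation-cohort design (14 active, 5 treated, 9 controls).
#' @param fold_change Numeric matrix (genes x groups) of true fold changes
#'   relative to baseline; defaults to all 1 (null). Rows must be named by
#'   gene and columns by group.
#' @param efficiency Amplification factor per cycle, in (1, 2].
#' @param ct_noise_sd SD (cycles) of replicate noise.
#' @param n_replicates Replicates per (gene, sample) and per dilution point.
#' @param ct_at_unit CT of the 1 U (= 10 pg) standard (default 27 cycles).
#' @param amount_18s_range Range (U per reaction) from which per-sample 18S
#'   amounts are drawn log-uniformly (default 50-1000 U).
#' @param dilution_series_pg Amounts (pg) of the standard dilution series
#'   (default a two-fold ladder 160 down to 1.25 pg).
#' @param seed Integer seed.
#' @return A list of class `synthetic_qpcr` with `table` (long data frame of
#'   gene_id, sample_id, replicate, ct), `standard` (amount_pg, replicate,
#'   ct), `sample_sheet`, and a `truth` block (per-sample 18S amounts in U,
#'   per-gene baseline delta-CT, fold changes, efficiency, seed).
#' @export
generate_qpcr_dataset <- function(genes,
                                  group_sizes = c(active_cd = 14L,
                                                  treated_cd = 5L,
                                                  control = 9L),
                                  fold_change = NULL,
                                  efficiency = 2,
                                  ct_noise_sd = 0.15,
                                  n_replicates = 3L,
                                  ct_at_unit = 27,
                                  amount_18s_range = c(50, 1000),
                                  dilution_series_pg = 10 * 2^(4:-3),
                                  seed = 1L) {
  if (efficiency <= 1 || efficiency > 2)
    stop("efficiency must be in (1, 2]")
  stopifnot(length(genes) >= 1, all(group_sizes >= 1), n_replicates >= 1,
            ct_noise_sd >= 0)
  if (is.null(names(group_sizes))) stop("group_sizes must be named")
  groups <- names(group_sizes)
  if (is.null(fold_change)) {
    fold_change <- matrix(1, length(genes), length(groups),
                          dimnames = list(genes, groups))
  }
  stopifnot(identical(rownames(fold_change), genes),
            identical(colnames(fold_change), groups),
            all(fold_change > 0))
  set.seed(seed)

  sample_ids <- unlist(lapply(groups, function(g)
    sprintf("%s_%02d", toupper(substr(g, 1, 3)), seq_len(group_sizes[[g]]))))
  sample_group <- rep(groups, group_sizes)
  n_s <- length(sample_ids)

  logE <- log(efficiency)
  amount_18s <- exp(stats::runif(n_s, log(amount_18s_range[1]),
                                 log(amount_18s_range[2])))
  names(amount_18s) <- sample_ids
  delta_ct_base <- stats::setNames(stats::runif(length(genes), 5, 15), genes)

  ct_18s <- ct_at_unit - log(amount_18s) / logE
  grid <- expand.grid(gene_id = c("18S", genes), sample_id = sample_ids,
                      replicate = seq_len(n_replicates),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ct_true <- ifelse(
    grid$gene_id == "18S",
    ct_18s[grid$sample_id],
    ct_18s[grid$sample_id] + delta_ct_base[grid$gene_id] -
      log(fold_change[cbind(
        match(grid$gene_id, genes),
        match(sample_group[match(grid$sample_id, sample_ids)], groups))]) / logE
  )
  grid$ct <- ct_true +
    if (ct_noise_sd > 0) stats::rnorm(nrow(grid), 0, ct_noise_sd) else 0

  std <- expand.grid(amount_pg = dilution_series_pg,
                     replicate = seq_len(n_replicates),
                     KEEP.OUT.ATTRS = FALSE)
  std$ct <- ct_at_unit - log(std$amount_pg / 10) / logE +
    if (ct_noise_sd > 0) stats::rnorm(nrow(std), 0, ct_noise_sd) else 0

  structure(list(
    table = grid[order(grid$gene_id, grid$sample_id, grid$replicate), ],
    standard = std,
    sample_sheet = data.frame(sample_id = sample_ids, group = sample_group,
                              stringsAsFactors = FALSE),
    truth = list(amount_18s = amount_18s, delta_ct_base = delta_ct_base,
                 fold_change = fold_change, efficiency = efficiency,
                 ct_at_unit = ct_at_unit, seed = seed)
  ), class = "synthetic_qpcr")
}
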