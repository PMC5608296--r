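mk_mat <- function(rows, samples = paste0("s", seq_len(ncol(rows)))) {
  dimnames(rows) <- list(rownames(rows) %||% sprintf("g%d", seq_len(nrow(rows))),
                         samples)
  rows
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("RQ follows the zero and substitution conventions", {
  case <- mk_mat(rbind(g1 = c(90, 100, 110, 120),
                       g2 = c(17, 18, 19, 18),
                       g3 = c(-5, -1, 2, 1)))
  ctrl <- mk_mat(rbind(g1 = c(45, 50, 55, 60),
                       g2 = c(0, 0, -3, 0),
                       g3 = c(1, 2, 3, 4)))
  tab <- gene_rq_table(case, ctrl)
  expect_equal(tab$rq[tab$gene_id == "g1"], (100 + 110) / 2 / 52.5)
  # negative control signals clamp to 0, zero median substitutes to 0.01
  expect_equal(tab$median_ctrl[tab$gene_id == "g2"], 0.01)
  expect_equal(tab$rq[tab$gene_id == "g2"], 18 / 0.01)
  # negatives clamp in the case group before the median
  expect_equal(tab$median_case[tab$gene_id == "g3"], 0.5)
  # definitional identity for every gene
  expect_equal(tab$rq * tab$median_ctrl, tab$median_case)
  expect_error(gene_rq_table(case, ctrl[1:2, ]), "gene universe")
})

test_that("calibration curve counts cumulative significant fractions", {
  res <- data.frame(gene_id = paste0("g", 1:6),
                    rq = c(1.2, 1.5, 1.9, 2.5, 3.5, 4.0),
                    p = c(0.5, 0.028, 0.5, 0.028, 0.028, 0.5))
  cal <- calibrate_rq_cutoff(res, alpha = 0.05, grid = c(1, 2, 3))
  expect_equal(cal$curve$n_above, c(6, 3, 2))
  expect_equal(cal$curve$frac_significant, c(3 / 6, 2 / 3, 1 / 2))
  expect_equal(cal$chosen_cutoff, 1)
  # no gene above a cut-off: fraction reported as missing
  cal2 <- calibrate_rq_cutoff(res, grid = c(1, 5))
  expect_true(is.na(cal2$curve$frac_significant[2]))
  expect_error(calibrate_rq_cutoff(res, grid = numeric(0)), "non-empty")
  expect_error(calibrate_rq_cutoff(res, grid = c(2, 1)), "ascending")
})

test_that("a single zero cut-off with all genes significant is chosen", {
  res <- data.frame(gene_id = c("a", "b"), rq = c(2, 3), p = c(0.01, 0.02))
  cal <- calibrate_rq_cutoff(res, grid = 0)
  expect_equal(cal$curve$frac_significant, 1)
  expect_equal(cal$chosen_cutoff, 0)
})

test_that("planted strong effects push the chosen cut-off below their RQ", {
  # every planted gene has true RQ >= 3 and the minimal 4v4 p; nulls are flat
  res <- data.frame(
    gene_id = paste0("g", 1:300),
    rq = c(runif(60, 3, 6), runif(240, 1, 1.3)),
    p = c(rep(2 / 70, 60), rep(0.69, 240))
  )
  cal <- calibrate_rq_cutoff(res, alpha = 0.05, grid = seq(1, 3, 0.1))
  below3 <- cal$curve$cutoff < 3
  expect_true(all(cal$curve$frac_significant[cal$curve$cutoff >= 1.3 & below3] > 0.05))
  expect_lte(cal$chosen_cutoff, 3)
})

test_that("the unconditional null rejection rate stays at the exact-test floor", {
  # all-null 4 vs 4: the only attainable p <= 0.05 is complete separation,
  # 2/70 of assignments, so the expected significant fraction is ~2.86%
  set.seed(77)
  n <- 2000
  sig <- sqrt(log(1 + 0.3^2))
  case <- mk_mat(matrix(rlnorm(n * 4, 3, sig), n), paste0("c", 1:4))
  ctrl <- mk_mat(matrix(rlnorm(n * 4, 3, sig), n), paste0("k", 1:4))
  rownames(case) <- rownames(ctrl) <- sprintf("g%d", 1:n)
  tab <- gene_rq_table(case, ctrl)
  expect_lte(mean(tab$p <= 0.05), 0.05)
  expect_equal(mean(tab$p <= 0.05), 2 / 70, tolerance = 0.35)
})

test_that("selection applies the four filters literally", {
  res <- data.frame(
    gene_id = paste0("g", 1:5),
    median_case = c(100, 59, 200, 80, 10),
    median_ctrl = c(50, 11.8, 117.6, 26.7, 1.1),
    rq = c(2.0, 5.0, 1.7, 3.0, 9.0),
    p = rep(0.0286, 5)
  )
  sel <- select_genes(res)
  expect_setequal(sel$selected, c("g1", "g4"))
  expect_equal(sel$audit$n, c(5, 4, 4, 3, 2))

  # single-gene exclusions: signal filter, then RQ filter
  expect_false("g2" %in% sel$selected) # 59 AU < 60
  expect_false("g3" %in% sel$selected) # RQ 1.7 < 1.8
})

test_that("raising any threshold never adds genes", {
  set.seed(13)
  res <- data.frame(
    gene_id = paste0("g", 1:400),
    median_case = rlnorm(400, 4, 1.5),
    median_ctrl = rlnorm(400, 4, 1.5),
    rq = rlnorm(400, 0.2, 0.6),
    p = sample(c(2 / 70, 4 / 70, 0.2, 0.69, 1), 400, replace = TRUE)
  )
  base <- select_genes(res)$selected
  tighter <- list(
    selection_criteria(min_signal_case = 120),
    selection_criteria(min_rq = 2.5),
    selection_criteria(alpha = 0.029),
    selection_criteria(expressed_min_signal = 80)
  )
  for (crit in tighter) {
    expect_true(all(select_genes(res, crit)$selected %in% base))
  }
})
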