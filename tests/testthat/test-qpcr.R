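noiseless_qpcr <- function(genes = "IRF1", fc = NULL,
                           sizes = c(active_cd = 5L, control = 5L), seed = 2L)
  generate_qpcr_dataset(genes, group_sizes = sizes, fold_change = fc,
                        efficiency = 2, ct_noise_sd = 0, seed = seed)

test_that("standard-curve closed forms hold", {
  q <- noiseless_qpcr()
  curve <- fit_standard_curve(q$standard)
  expect_equal(curve$efficiency, 2, tolerance = 1e-10)
  expect_equal(curve$slope, -1 / log10(2), tolerance = 1e-10)
  expect_equal(curve$r_squared, 1, tolerance = 1e-10)

  # slope -3.3219 cycles per decade inverts to efficiency ~2
  s <- data.frame(amount_pg = c(1, 10, 100), ct = 30 - 3.3219 * (0:2))
  expect_equal(fit_standard_curve(s)$efficiency, 10^(1 / 3.3219))

  expect_error(fit_standard_curve(data.frame(amount_pg = c(1, 10), ct = 2:1)),
               "3 distinct")
  expect_error(fit_standard_curve(data.frame(amount_pg = c(1, 10, 100),
                                             ct = 1:3)), "negative")
})

test_that("quantification inverts the curve through the 10 pg = 1 U anchor", {
  q <- noiseless_qpcr()
  curve <- fit_standard_curve(q$standard)
  ct_10pg <- curve$intercept + curve$slope * 1 # log10(10) = 1
  expect_equal(quantify_18s(ct_10pg, curve), 1)
  expect_equal(quantify_18s(ct_10pg - 1, curve), 2) # one cycle = 2x at eff 2

  # round-trip: simulated 18S CTs map back to the planted amounts
  hk <- aggregate(ct ~ sample_id, q$table[q$table$gene_id == "18S", ], mean)
  got <- quantify_18s(hk$ct, curve)
  expect_equal(got, unname(q$truth$amount_18s[hk$sample_id]),
               tolerance = 1e-8)
})

test_that("delta-delta-CT identities hold exactly", {
  fc <- matrix(c(4, 1), 1, 2, dimnames = list("IRF1", c("active_cd", "control")))
  q <- noiseless_qpcr(fc = fc)
  rq <- relative_quantity(q$table, q$sample_sheet)
  expect_equal(log2(rq$rq), -rq$delta_delta_ct, tolerance = 1e-12)
  # reference group median RQ is exactly 1 for an odd group size
  expect_equal(median(rq$rq[rq$group == "control"]), 1)
  # planted four-fold effect: delta-delta-CT = -2, RQ = 4
  expect_equal(unique(round(rq$delta_delta_ct[rq$group == "active_cd"], 10)), -2)
  expect_equal(unique(round(rq$rq[rq$group == "active_cd"], 10)), 4)
})

test_that("relative_quantity validates housekeeping and reference inputs", {
  q <- noiseless_qpcr()
  no_hk <- q$table[q$table$gene_id != "18S", ]
  expect_error(relative_quantity(no_hk, q$sample_sheet), "housekeeping")
  expect_error(relative_quantity(q$table, q$sample_sheet,
                                 reference_group = "nope"), "no samples")
})

test_that("QC filter removes samples at or below the 18S threshold", {
  q <- noiseless_qpcr()
  samples <- unique(q$table$sample_id)
  units <- setNames(rep(100, length(samples)), samples)
  units[samples[1]] <- 24
  units[samples[2]] <- 26
  out <- qc_filter(q$table, units, min_units = 25)
  expect_identical(out$excluded$sample_id, samples[1])
  expect_false(samples[1] %in% out$table$sample_id)
  expect_true(samples[2] %in% out$table$sample_id)
  # nothing below threshold: output equals input
  all_ok <- qc_filter(q$table, setNames(rep(100, length(samples)), samples))
  expect_identical(all_ok$table, q$table)
  expect_equal(nrow(all_ok$excluded), 0)
})

test_that("two identical groups give t = 0 and p = 1", {
  v <- c(1, 2, 3, 1, 2, 3)
  g <- rep(c("a", "b"), each = 3)
  res <- compare_groups(v, g, design = "ttest", reference = "b")
  expect_equal(res$comparisons$statistic, 0)
  expect_equal(res$comparisons$p, 1)
})

test_that("mwu design delegates to the exact test", {
  set.seed(31)
  x <- rnorm(4); y <- rnorm(5)
  res <- compare_groups(c(x, y), rep(c("cd", "ctr"), c(4, 5)),
                        design = "mwu", reference = "ctr")
  ref <- exact_mwu(x, y)
  expect_equal(res$comparisons$statistic, ref$u_stat)
  expect_equal(res$comparisons$p, ref$p_two_sided)
})

test_that("rank and t statistics are invariant to the delta-CT vs log2-RQ scale", {
  set.seed(32)
  dct <- rnorm(12, 8, 1.5)
  g <- rep(c("a", "b"), each = 6)
  l2rq <- -(dct - median(dct[g == "b"])) # log2 RQ is affine in delta-CT
  m1 <- compare_groups(dct, g, "mwu", reference = "b")
  m2 <- compare_groups(l2rq, g, "mwu", reference = "b")
  expect_equal(m1$comparisons$p, m2$comparisons$p)
  t1 <- compare_groups(dct, g, "ttest", reference = "b")
  t2 <- compare_groups(l2rq, g, "ttest", reference = "b")
  expect_equal(abs(t1$comparisons$statistic), abs(t2$comparisons$statistic))
  expect_equal(t1$comparisons$p, t2$comparisons$p)
})

test_that("Monte-Carlo Dunnett adjustment is coherent and matches multcomp", {
  set.seed(33)
  v <- c(rnorm(5, 0), rnorm(5, 1.4), rnorm(5, 0.3), rnorm(5, -0.5))
  g <- rep(c("ctrl", "t1", "t2", "t3"), each = 5)
  res <- compare_groups(v, g, "anova_dunnett", reference = "ctrl",
                        n_resample = 4e4, seed = 10)
  cmp <- res$comparisons
  # adjusted never below unadjusted, by construction from the same draws
  expect_true(all(cmp$p_adjusted >= cmp$p_unadjusted))
  # MC marginal p agrees with the closed-form t p
  expect_equal(cmp$p_unadjusted, cmp$p_t, tolerance = 0.12)
  # F statistic matches aov
  expect_equal(res$f_statistic,
               summary(aov(v ~ factor(g)))[[1]]$`F value`[1])

  if (requireNamespace("multcomp", quietly = TRUE)) {
    dn <- summary(multcomp::glht(
      aov(v ~ g0, data = data.frame(v = v, g0 = relevel(factor(g), "ctrl"))),
      linfct = multcomp::mcp(g0 = "Dunnett")))
    expect_equal(unname(cmp$p_adjusted),
                 unname(as.vector(dn$test$pvalues)), tolerance = 0.05)
  }
})

test_that("single-comparison Dunnett collapses to the two-sample t", {
  set.seed(34)
  v <- c(rnorm(6, 0, 1), rnorm(6, 1, 1))
  g <- rep(c("ctrl", "trt"), each = 6)
  res <- compare_groups(v, g, "anova_dunnett", reference = "ctrl",
                        n_resample = 5e4, seed = 11)
  tt <- t.test(v[g == "trt"], v[g == "ctrl"], var.equal = TRUE)
  expect_equal(res$comparisons$p_adjusted, tt$p.value, tolerance = 0.05)
  expect_equal(res$comparisons$p_t, tt$p.value, tolerance = 1e-10)
})
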