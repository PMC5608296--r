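test_that("identical seeds give bit-identical datasets", {
  a <- generate_array_dataset(quick_config())
  b <- generate_array_dataset(quick_config())
  expect_identical(a, b)
  c <- generate_array_dataset(array_sim_config(n_genes = 300L, frac_de = 0.1,
                                               seed = 8L))
  expect_false(identical(a$observed_iec_case, c$observed_iec_case))
})

test_that("no planting requested leaves the truth block empty", {
  ds <- generate_array_dataset(array_sim_config(n_genes = 200L, frac_de = 0,
                                                seed = 2L))
  expect_length(ds$truth$de_genes, 0)
  expect_length(ds$truth$true_rq, 0)
})

test_that("zero admixture and zero background reduce observed to pure", {
  ds <- generate_array_dataset(array_sim_config(
    n_genes = 200L, contamination_fractions = rep(0, 4),
    contamination_fractions_ctrl = rep(0, 4), background_sd = 0, seed = 3L))
  expect_equal(ds$observed_iec_case, ds$pure_iec_case)
  expect_equal(ds$observed_iec_ctrl, ds$pure_iec_ctrl)
})

test_that("marker genes carry exactly the planted admixture fraction", {
  ds <- generate_array_dataset(array_sim_config(
    n_genes = 200L, contamination_fractions = rep(0.10, 4),
    background_sd = 0, seed = 4L))
  markers <- ds$config$marker_genes
  expect_true(all(ds$pure_iec_case[markers, ] == 0))
  ratios <- ds$observed_iec_case[markers, ] / ds$iel_profile[markers]
  expect_equal(unname(as.vector(ratios)), rep(0.10, length(ratios)))
})

test_that("observed matrices satisfy the convex mixing identity", {
  ds <- generate_array_dataset(array_sim_config(
    n_genes = 150L, background_sd = 0, seed = 5L))
  f <- ds$truth$contamination_fractions
  recon <- sweep(ds$pure_iec_case, 2L, 1 - f, `*`) +
    outer(ds$iel_profile, f)
  expect_equal(ds$observed_iec_case, recon)
})

test_that("planted effects and the null center are faithful at scale", {
  ds <- generate_array_dataset(array_sim_config(
    n_genes = 5000L, frac_de = 0.05, effect_rq_range = c(2, 8), seed = 6L))
  med_ratio <- apply(pmax(ds$pure_iec_case, 0), 1L, median) /
    apply(pmax(ds$pure_iec_ctrl, 0), 1L, median)
  de <- ds$truth$de_genes
  rel <- med_ratio[de] / ds$truth$true_rq
  expect_gt(median(rel), 0.9)
  expect_lt(median(rel), 1.1)
  null_genes <- setdiff(rownames(ds$pure_iec_case),
                        c(de, ds$config$marker_genes))
  expect_gt(median(med_ratio[null_genes]), 0.95)
  expect_lt(median(med_ratio[null_genes]), 1.05)
})

test_that("invalid array configurations are rejected", {
  expect_error(array_sim_config(frac_de = 1.2), "frac_de")
  expect_error(array_sim_config(effect_rq_range = c(0.5, 2)), "effect_rq_range")
  expect_error(array_sim_config(contamination_fractions = rep(0.5, 4)),
               "\\[0, 0.2\\]")
  expect_error(array_sim_config(contamination_fractions = c(0.1, 0.1)),
               "per sample")
  expect_error(array_sim_config(marker_genes = c("CD2", "CD2")), "unique")
})

test_that("qPCR generator honors the efficiency-2 cycle arithmetic", {
  genes <- c("IRF1", "SPINK4")
  fc <- matrix(c(2, 1, 4, 1), nrow = 2, byrow = TRUE,
               dimnames = list(genes, c("active_cd", "control")))
  q <- generate_qpcr_dataset(genes,
                             group_sizes = c(active_cd = 3L, control = 3L),
                             fold_change = fc, efficiency = 2,
                             ct_noise_sd = 0, seed = 9L)
  mct <- aggregate(ct ~ gene_id + sample_id, q$table, mean)
  sheet <- q$sample_sheet
  dct <- function(g, s) {
    mct$ct[mct$gene_id == g & mct$sample_id == s] -
      mct$ct[mct$gene_id == "18S" & mct$sample_id == s]
  }
  s_act <- sheet$sample_id[sheet$group == "active_cd"][1]
  s_ctr <- sheet$sample_id[sheet$group == "control"][1]
  # fold 2 at efficiency 2: delta-CT exactly 1 cycle lower than the reference
  expect_equal(dct("IRF1", s_ctr) - dct("IRF1", s_act), 1)
  expect_equal(dct("SPINK4", s_ctr) - dct("SPINK4", s_act), 2)

  # noiseless two-fold dilution ladder steps by exactly one CT
  std <- aggregate(ct ~ amount_pg, q$standard, mean)
  std <- std[order(-std$amount_pg), ]
  expect_equal(diff(std$ct), rep(1, nrow(std) - 1L))

  expect_identical(q, generate_qpcr_dataset(genes,
    group_sizes = c(active_cd = 3L, control = 3L), fold_change = fc,
    efficiency = 2, ct_noise_sd = 0, seed = 9L))
})

test_that("qPCR generator rejects invalid efficiencies", {
  expect_error(generate_qpcr_dataset("A", efficiency = 1), "efficiency")
  expect_error(generate_qpcr_dataset("A", efficiency = 2.5), "efficiency")
})
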