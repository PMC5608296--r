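# iecdeg

Differential expression analysis for **purified intestinal epithelial cells
(IECs)** in celiac disease, where two things complicate an otherwise
ordinary two-group comparison:

* purified epithelium carries 5--10% admixed signal from intraepithelial
  lymphocytes (IELs), so immune genes highly expressed in T cells
  masquerade as epithelial upregulation; and
* group sizes are tiny (four arrays per arm is typical), so only exact
  rank tests are trustworthy and fold-change thresholds need empirical
  calibration.

`iecdeg` is for transcriptomics analysts working with sorted or
bead-purified cell populations profiled on expression arrays (signals in
arbitrary units, AU) with qPCR follow-up. It provides:

* **Contamination correction** — estimate the IEL admixture fraction *f*
  from a T-cell marker panel (CD3D, CD3G, CD2, CD7, CD8A, CD247; markers
  have zero pure-epithelial signal, so observed marker signal / IEL
  reference signal = *f*), then subtract *f* × IEL reference from every
  gene: `estimate_contamination()`, `correct_contamination()`.
* **Exact differential expression** — per gene, relative quantity
  RQ = median(case) / median(control) with negative signals clamped to 0
  and a zero control median replaced by 0.01 AU, plus an exact two-sided
  Mann–Whitney U test (tie-aware, full permutation null; at 4 vs 4 the
  minimal p is 2/70 ≈ 0.0286): `gene_rq_table()`, `exact_mwu()`.
* **Cut-off calibration and selection** — the fraction of significant
  genes above each candidate RQ cut-off (`calibrate_rq_cutoff()`), and the
  final screen (case median ≥ 60 AU, RQ ≥ 1.8, p ≤ 0.05, expressed at
  ≥ 15 AU): `select_genes()`.
* **qPCR quantification** — 18S standard curves (1 U = 18S content of
  10 pg RNA standard), RQ = 2^(−ΔΔCT) with median-of-controls reference,
  > 25 U QC filter, cell yield ≈ 18S units, and group comparisons (exact
  MWU, Student's t, one-way ANOVA with seeded Monte-Carlo Dunnett
  adjustment): `fit_standard_curve()`, `relative_quantity()`,
  `compare_groups()`, `cells_from_18s()`.
* **Concordance** — qPCR confirmation summaries and gluten-free-diet
  response categories (normalized / persistent_elevated / decreased_below):
  `confirmation_summary()`, `classify_gfd_response()`.
* **Synthetic data** — seeded generators reproducing the whole data
  regime (log-normal AU signals, planted effects, IEL-only markers, convex
  admixture, negative background-subtracted signals, CT triplicates at
  efficiency 2): `generate_array_dataset()`, `generate_qpcr_dataset()`.

See `vignettes/iecdeg-methods.Rmd` for the model details and design
rationale.

## Worked example

Simulate a 2,000-gene screen with 5% of genes planted as upregulated
(effects 3–10×) on well-expressed baselines, 5–10% IEL admixture, then run
the full pipeline with the fixed 10% correction:

```r
library(iecdeg)

cfg <- array_sim_config(n_genes = 2000, frac_de = 0.05,
                        effect_rq_range = c(3, 10), de_baseline_min = 60,
                        seed = 42)
ds  <- generate_array_dataset(cfg)

estimate_contamination(ds$observed_iec_case,
                       apply(ds$iel_matrix, 1, median))$pooled_fraction
#> [1] 0.1056997

res <- run_pipeline(pipeline_config(ds$observed_iec_case, ds$observed_iec_ctrl,
                                    iel = ds$iel_matrix,
                                    contamination = "fixed", fraction = 0.10))
res
#> iecdeg pipeline run (ok)
#> contamination: fixed, fraction 0.100
#> genes 2000 | expressed 617 | significant 111 | selected 100
#> calibrated RQ cut-off: 1

sel <- res$selection$selected
c(sensitivity = mean(ds$truth$de_genes %in% sel),
  false_discovery = mean(!sel %in% ds$truth$de_genes))
#>     sensitivity false_discovery
#>               1               0

head(res$selection$table[res$selection$table$selected,
                         c("gene_id", "median_case", "rq", "u_stat", "p")], 4)
#>    gene_id median_case       rq u_stat          p
#> 41  G00035    401.1253 7.317348     16 0.02857143
#> 56  G00050    274.3991 3.380609     16 0.02857143
#> 72  G00066   1904.3319 6.139941     16 0.02857143
#> 75  G00069    502.8057 3.138551     16 0.02857143
```

Reading the numbers: the marker-based estimate recovers the planted
admixture (~0.10); of 2,000 genes, 617 pass the 15 AU expressed filter, 111
are significant by the exact test, and the 100 passing all four selection
filters are exactly the 100 planted genes. Every selected gene sits at
U = 16 (complete separation of 4 vs 4) and hence at the minimal attainable
p = 2/70, which prints as 0.028 in truncated display form
(`format_p_truncated(2/70)`).

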