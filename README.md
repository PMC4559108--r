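# urostab

Stability screening of the human urine metabolome under collection
conditions, from LC-MS peak tables.

Urine sitting at room temperature during collection changes: commensal
bacteria overgrow and metabolise sugars, amino acids and nucleosides,
and some metabolites (ascorbic acid, urobilinoids, ...) are chemically
unstable in solution. `urostab` is for metabolomics analysts who need
to know *which* metabolites move with storage time and *why*: it
processes feature tables from a designed stability study — pooled urine
stored at room temperature (`RT`), at 4 °C (`C4`) or with boric-acid
preservative (`Pres`), sampled in triplicate over 0–72 h, with pooled
QC injections every 10 samples — and classifies each robustly unstable
metabolite as affected by **bacterial overgrowth** or by **chemical
instability**.

The attribution rule exploits the design: bacteria grow neither in the
cold nor with preservative, so

* Spearman correlation with storage duration significant (BH FDR
  < 0.01) **only at RT** → bacterial overgrowth;
* significant at RT **and** at 4 °C and/or with preservative →
  chemical instability.

Around that rule the package implements the full pipeline:

| stage | function(s) |
|---|---|
| synthetic study generator + ground truth | `sim_config()`, `simulate_study()`, `simulate_turbidity()` |
| feature-table / library / results I-O | `read_feature_table()`, `read_library()`, `write_results()` |
| QC-loess drift correction, block scaling, order filter | `loess_drift_correct()`, `median_fallback()`, `block_scale()`, `injection_order_filter()` |
| blank / QC-CV / outlier filtering | `blank_filter()`, `cv_filter()`, `detect_outlier_observations()` |
| accurate-mass + RT annotation (MSI levels) | `annotate()`, `ppm_error()`, `demo_library()` |
| per-condition Spearman screen, FDR, onsets | `correlate_with_time()`, `bh_fdr()`, `onset_time()` |
| PCA, 2-component PLS1, Q², permutations, VIP | `preprocess()`, `pca()`, `pls()`, `q2()`, `permutation_test()`, `vip()` |
| robust selection + bacterial/chemical calls | `select_robust()`, `classify()`, `classify_calls()`, `summarize_calls()` |
| orchestration | `pipeline_config()`, `run_pipeline()` |

Because the original raw data require a full peak-detection stack, the
package ships a synthetic-data generator that emulates the study design
(two experiments, both ion modes, planted drift and planted unstable
metabolites with a logistic bacterial-growth coupling) together with a
ground-truth ledger, so every stage — and the pipeline end to end — is
testable offline. See `vignettes/urine-stability-methods.Rmd` for the
model, every tunable parameter, and what the generator does and does
not emulate.

## Worked example

The `analysis/` directory holds the study as numbered drivers
(`01_simulate.R` … `07_classify.R`), each writing its tables under
`results/`. A condensed in-session version:

```r
library(urostab)

cfg <- sim_config(ion_modes = "positive", seed = 20141223)  # full design
res <- run_pipeline(pipeline_config(sim = cfg, n_perm = 999, seed = 1))

res$summary$class_counts
#>                     class  n
#> 1               bacterial 12
#> 2                chemical  7
#> 3 stable_or_indeterminate  0

res$mva[["Exp2.positive"]][c("q2", "perm_p", "vip_p_concordance")]
#> $q2
#> [1] 0.5990306
#> $perm_p
#> [1] 0.001
#> $vip_p_concordance
#> [1] 1

head(res$calls[res$calls$class == "chemical",
               c("feature_id", "sign", "onset_rt_h", "onset_c4_h")], 3)
#>    feature_id sign onset_rt_h onset_c4_h
#> 13      P0063    -         12         12
#> 14      P0068    +         12          8
#> 15      P0077    -          8          8
```

Reading: the 12 planted bacteria-affected and 7 chemically unstable
metabolites are all recovered with no false positives among the 281
stable features; the two-component PLS of storage duration on the
Exp. 2 positive-mode block cross-validates at Q² ≈ 0.60 with the
smallest achievable permutation p (0.001 at 999 permutations); the
top-VIP and smallest-p metabolite sets coincide. The chemical calls
carry onset times in both the RT and 4 °C arms (the earliest time point
whose triplicates all lie beyond the T0 range) — at a 3-fold planted
effect these trends establish within the first sampling day in both
arms.

Running the numbered drivers instead reproduces the same analysis with
all intermediate tables on disk, for both ion modes:

```sh
Rscript analysis/01_simulate.R   # design + ground truth
Rscript analysis/02_normalize.R  # median QC CV 9.5% -> 1.7% (Exp. 1)
Rscript analysis/03_filter.R
Rscript analysis/04_annotate.R
Rscript analysis/05_univariate.R
Rscript analysis/06_multivariate.R
Rscript analysis/07_classify.R   # 38/38 planted correctly classed
```

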