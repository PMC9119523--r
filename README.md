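# stemsig

Tumors partially reactivate transcriptional programs of embryonic and
induced pluripotent stem cells (ESC/iPSC). How strongly, and how
uniformly, differs between tumor types, between patients, and between
single cells of one tumor — which matters for any diagnostic built on
stem-cell markers. `stemsig` is an R package for transcriptomics
researchers who want to quantify that heterogeneity in bulk RNA-seq
cohorts (with matched normal tissue and stem-cell references) and in
single-cell UMI data.

## What it computes

- **Signature assembly.** A stemness gene set is built from independent
  datasets: genes enriched in the stem-like group of tissue atlases
  (log2FC and expression-level `E` cutoffs, over at least
  `n_comp` comparisons), genes decaying along ESC differentiation time
  courses, and genes that drop upon knockdown of pluripotency
  transcription factors. The per-dataset lists are intersected, curated
  genes added, and tissue-specific, proliferation and cell-cycle genes
  removed.
- **Purity correction.** Per gene, `Y ~ β₀ + β₁·P` is fit by OLS, where
  `Y` is TMM-normalized log₂(CPM) and `P` the consensus tumor purity
  (CPE); downstream analysis uses `Y − β₁·P`. Samples without a tumor
  compartment get CPE imputed from Normal(0.08, 0.03) truncated to
  [0, 1].
- **Stemness axis.** PCA restricted to the signature genes; PC1 is
  oriented so ESC/iPSC score negative. Tumor samples on the stem side of
  the median are the *Stem* cluster, and the **signature intensity** of
  tumor type *j* is `I_j = N_j^Stem / (N_j^Stem + N_j^Normal)` with a
  95% Wilson interval (no continuity correction).
- **Survival.** Per tumor type (balanced per-tumor-median clusters), a
  Cox model with the Stem indicator gives the hazard ratio, Wald CI,
  logrank p, and BH-adjusted p-values across types.
- **Single cells.** Depth-normalized cells are projected onto the bulk
  PC1 loadings; one-way ANOVA eta-squared splits score variance into
  intertumoral vs intratumoral parts, and lesion classes
  (normal/primary/metastatic) are compared by rank-sum tests.
- **Simulators.** `simulate_bulk()`, `simulate_survival()`,
  `simulate_cells()` and `simulate_assembly_fixture()` generate every
  input with known ground truth, seed-deterministically.

## Worked example

```r
library(stemsig)
sim <- simulate_bulk(seed = 1)            # 2000 genes, 400 samples
lc  <- tmm_log2_cpm(sim$expr)
cor <- correct_purity(lc, seed = 1)
ax  <- fit_stemness_axis(cor$corrected, sim$truth$signature_genes)
print(ax)
#> stemness_axis on 'signature': 200 genes, 400 samples
#>   variance explained: PC1 58.9%, PC2 0.6%
#>   orientation: -1 (stem side = negative PC1)

md  <- cor$corrected$metadata
tum <- md$group == "tumor"
cl  <- assign_clusters(predict(ax)[md$sample_id[tum]], md$project[tum])
signature_intensity(cl)
#>   project n_stem n_normal intensity      ci_lo     ci_hi
#> 1      TA     11       59 0.1571429 0.09007621 0.2598825
#> 2      TB     31       39 0.4428571 0.33249529 0.5591645
#> 3      TC     35       35 0.5000000 0.38595718 0.6140428
#> 4      TD     63        7 0.9000000 0.80767085 0.9507107
```

PC1 carries most of the signature-subspace variance and the four
simulated tumor projects, whose planted stemness levels increase from
TA to TD, show monotonically increasing intensity: TA sits almost
entirely in the Normal cluster, TD almost entirely in Stem. Survival on
clusters with a planted hazard ratio of 2 for Stem:

```r
cl2  <- assign_clusters(predict(ax)[md$sample_id[tum]], md$project[tum],
                        "per_tumor_median", patient_id = md$patient_id[tum])
surv <- simulate_survival(clusters = cl2, hr = 2, seed = 1)
cluster_survival(cl2, surv)
#>   project  n n_events       hr     ci_lo    ci_hi       p_wald    p_logrank estimable        p_adj
#> 1      TA 70       54 3.572487 1.9988235 6.385088 1.727683e-05 5.943116e-06      TRUE 3.455366e-05
#> 2      TB 70       58 1.690256 0.9759841 2.927267 6.103947e-02 5.841427e-02      TRUE 8.138596e-02
#> 3      TC 70       59 4.243348 2.2853264 7.878964 4.702689e-06 1.171614e-06      TRUE 1.881076e-05
#> 4      TD 70       58 1.516988 0.8953166 2.570323 1.213933e-01 1.188383e-01      TRUE 1.213933e-01
```

Each row is one tumor project: `hr` is the Stem-vs-Normal hazard ratio
with its Wald 95% CI, and at 70 patients per project the estimates
scatter around the planted value of 2 (the replicate-level coverage is
asserted in the test suite).

`run_pipeline()` chains all stages, writes plain-text outputs, and
records an MD5 manifest so identical inputs and seeds reproduce
identical files. See the vignette
(`vignettes/stemness-signature-analysis.Rmd`) for the model details and
design choices.

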