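# crpcPanel

Evaluation of a castration-resistance gene panel for hormone-treated
prostate cancer, combining single-cell subgroup analysis with bulk-cohort
outcome statistics.

## Scientific background

Most prostate adenocarcinomas respond initially to androgen-deprivation
(hormone) therapy, but a fraction progress to castration-resistant
prostate cancer (CRPC). A practical question is whether a small
expression panel, measured in the primary tumor, separates
hormone-treated patients who later recur from those who do not, and
whether higher panel scores track shorter time to recurrence.

This package implements the full analysis chain for that question on
single-cell and bulk RNA-seq data:

* **Normalization** — `log2(CPM + 1)` per cell/sample and per-gene
  z-scores (sample SD, optionally within strata such as dataset to
  absorb batch location/scale).
* **Single-cell subgroup structure** — subgroup cell compositions,
  pseudobulk mean profiles, Pearson similarity between subgroups, and
  *featured genes*: genes whose mean is a strict maximum in one
  subgroup, significant one-vs-rest (moderated t + BH), and expressed
  (value > 0) in more than 20% of that subgroup's cells.
* **Bulk cohort statistics** — phenotype-rule stratification (normal /
  tumor / recurrent / non-recurrent / hormone-therapy subsets), a
  moderated two-sample t-test with empirical-Bayes variance shrinkage
  (`s̃² = (d₀s₀² + d s²)/(d₀ + d)`, df `d₀ + d`; `d₀ = 0` is exactly the
  pooled t-test), and a DE screen on mean-CPM log ratios with BH
  adjustment (called at |log2FC| > 1, adjusted p < 0.05).
* **Signature scoring** — module/panel scores as sums of per-gene
  z-values (exactly linear over disjoint gene sets) and Welch t
  comparisons between sample groups.
* **Ligand–receptor communication** — directed intensity between two
  cell populations, `Σ meanA(ligand) × meanB(receptor)` over
  secreted→membrane pairs, with a label-permutation p-value
  (`(1 + #{perm ≥ obs}) / (1 + N)`, or the exact enumeration when the
  arrangement count is small).
* **Evaluation** — rank-based ROC AUC (midranks, identical to
  brute-force pairwise counting), Pearson score–time correlation with
  t-based p, and median-split group comparisons.
* **Simulators** — a negative-binomial single-cell generator with
  planted subgroup markers and optional planted ligand–receptor
  signal, and a bulk-cohort generator with the study's group sizes
  (e.g. 14 recurrent vs 53 non-recurrent hormone-therapy samples), a
  planted additive panel shift, and recurrence times linear in the
  true score plus noise. These provide ground truth for power and
  calibration checks.

The built-in panels are `crpcPanel6()` (PEG10, CCDC74A, PPIB, GAPDH,
AR, EPCAM) and `crpcPanel12()` (adding FAP, IL10, TGFB1, TIGIT, LAG3,
PDCD1).

## Worked example

Simulate a bulk cohort with a 2-SD panel shift planted in the recurrent
groups, stratify it by the phenotype rules, and evaluate the 6-gene
panel:

```r
library(crpcPanel)
library(SummarizedExperiment)

sim <- simulateBulk(panelShift = 2, seed = 7)
st  <- stratifyCohort(sim$se)
lengths(st)
#>        normal         tumor     recurrent non_recurrent        HT_YES
#>            52           452            59           393            14
#>         HT_NO
#>            53

ev <- evaluatePanel(sim$se, crpcPanel6())
print(ev$contrasts, digits = 3)
#>                     contrast n_pos n_neg mean_pos mean_neg     t        p auc
#> 1            tumor_vs_normal   452    52    0.164   -1.423  4.13 8.88e-05 0.6
#> 2 recurrent_vs_non_recurrent    59   393    8.056   -1.021 38.55 4.06e-59 1.0
#> 3            HT_YES_vs_HT_NO    14    53    7.995   -0.743 16.15 1.63e-15 1.0

ev$timeAnalyses$HT_YES$correlation
#> $r
#> [1] -0.7615635
#> $p
#> [1] 0.001533062
#> $n
#> [1] 14
```

The planted shift separates the recurrent hormone-therapy samples
(AUC = 1.0 on this cohort) and higher scores go with shorter
recurrence times (r = −0.76 over the 14 recurrent HT samples), while
the unshifted tumor-vs-normal contrast stays near chance.

On the single-cell side, simulate three subgroups with planted markers
and recover them as featured genes:

```r
sc  <- simulateSC(seed = 3)
v   <- log2CPM(as.matrix(assay(sc$sce, "counts")))
ann <- as.data.frame(colData(sc$sce))

composition(ann, "sim", "epithelial")
#>   dataset_id subgroup n_cells percent
#> 1        sim      SG1     200   33.33
#> 2        sim      SG2     200   33.33
#> 3        sim      SG3     200   33.33

head(featuredGenes(v, ann), 3)
#>    gene subgroup mean_in_subgroup max_other_mean expressed_fraction    t    p_adj
#> 1 G0001      SG1             12.6           4.77              0.890 16.3 2.18e-48
#> 2 G0002      SG1             13.0           4.87              0.915 16.7 4.07e-50
#> 3 G0003      SG1             12.2           5.99              0.855 13.8 7.18e-37
```

All 30 planted markers are recovered at their home subgroup.

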