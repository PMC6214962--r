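# piatac

Analysis of **protein-indexed single-cell ATAC-seq (Pi-ATAC)** experiments:
assays in which each FACS-sorted cell yields both a chromatin-accessibility
profile (fragment counts in peaks) and the index-sorter's record of that
cell's antibody-stain fluorescence. The package is written for analysts who
have fragment files, MACS2 peak calls and exported index-sort tables in
hand and want to go from there to per-cell transcription-factor activity
and its relationship to protein state.

The statistical core is the **bias-corrected motif deviation z-score**. For
feature (motif or k-mer) *k* with member peaks *m(k)*, cell *j*:

```
E_ij  = (row_i total / grand total) * column_j total        # technical null
Y_kj  = ( Σ_{i∈m(k)} X_ij − Σ E_ij ) / Σ E_ij               # raw deviation
z_kj  = ( Y_kj − mean_b Ỹ^b_kj ) / sd_b Ỹ^b_kj              # B matched backgrounds
```

where the `b = 1..B` background sets replace every member peak by one of its
`k_nn` nearest peaks in (GC, log mean accessibility) space — cancelling the
GC-linked technical variation that raw deviations inherit. Per-feature
**variability** is the standard deviation of `z` across cells (≈ 1 under
the null; χ² test with BH correction). Around that core sit peak selection
and per-cell QC (≥ 500 fragments, FRiP ≥ 0.5 × cohort median), barnyard
species classification (500-fragment cutoff, 96% purity), motif/k-mer
annotation, protein–deviation correlation and group tests, Hartigans' dip
test of bimodality, pseudo-bulk aggregation curves, and a synthetic-data
generator with known ground truth that makes every stage testable without
sequencing data.

## Worked example

A synthetic tumour-like experiment: 2,000 peaks × 300 cells, one planted
program (feature_001, active in half the cells) and a protein channel
("HIF1A") coupled to that program's activity.

```r
library(piatac)

cfg <- sim_config(
  n_peaks = 2000, n_cells = 300, n_features = 50, peaks_per_feature = 100,
  gc_confound_r = 0.5, gc_bias_sd = 0.1, feature_gc_skew = 1,
  programs = list(list(feature = 1, cells = 1:150, beta = 1)),
  channels = list(list(name = "HIF1A", feature = 1, slope = 200,
                       noise_sd = 267, background = 1000)),
  seed = 7)
ex <- generate_accessibility_experiment(cfg)

bg  <- sample_background_peaks(ex$peaks, B = 50, k_nn = 25, seed = 7)
dev <- corrected_deviations(ex$counts, ex$annotation, bg)
dev
#> deviation_matrix: 50 features x 300 cells; B = 50, k_nn = 25; 0 undefined entries

head(significant_features(motif_variability(dev)), 3)
#>       feature variability      p_value      q_value n_cells
#> 1 feature_001    5.596614 0.000000e+00 0.000000e+00     300
#> 2 feature_021    1.303935 4.519708e-13 1.129927e-11     300
#> 3 feature_036    1.182106 6.532342e-06 1.088724e-04     300
```

The planted feature tops the variability ranking (5.6 versus ≈ 1 for null
features — the mild excess of runners-up is the shared program bleeding into
features whose member peaks overlap it). Linking the stain to chromatin:

```r
intens <- setNames(transform_intensity(ex$index_table$HIF1A),
                   ex$index_table$cell_id)
ct <- correlate_protein_deviation(dev, intens)
head(ct[order(ct$p_value), ], 3)
#>        feature         r      p_value      q_value   n significant
#> 1  feature_001 0.3064601 6.068337e-08 3.034169e-06 300        TRUE
#> 10 feature_010 0.1923326 8.118892e-04 1.768550e-02 300        TRUE
#> 46 feature_046 0.1863780 1.182169e-03 1.768550e-02 300        TRUE

dip_test(dev$z[1, ex$truth$activity[1, ] == 1], n_boot = 2000, seed = 7)
#> Hartigans' dip test: dip = 0.0221, p = 0.9290 (n = 150, 2000 bootstrap draws)
```

The coupled channel correlates most strongly with the planted feature
(r = 0.31 here: a binary program seen through z-score noise and the asinh
transform), and within the program-active cells the feature's accessibility
is unimodal, as simulated. `run_pipeline(pipeline_config(...))` chains all
stages (QC → annotation → deviations → protein link → clustering) and
writes TSV tables plus a manifest that makes reruns byte-identical.

See `vignettes/piatac-methods.Rmd` for the models, parameter choices and
limitations.

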