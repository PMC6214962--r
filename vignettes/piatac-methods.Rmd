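---
title: "Models and methods behind piatac"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind piatac}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`piatac` analyses protein-indexed single-cell ATAC-seq (Pi-ATAC)
experiments, in which every FACS-sorted cell carries two coupled
measurements: a sparse chromatin-accessibility profile (fragment counts in
peaks) and the fluorescence intensities of antibody stains recorded by the
index sorter for the well the cell landed in. This vignette explains the
statistical models the package implements, the tunable parameters that
matter, what the synthetic-data generator does and does not emulate, and the
design choices made where the design was genuinely open.

## 1. Peak preparation and per-cell quality control

Peaks enter as MACS2 narrowPeak calls on aggregated data. The pipeline

1. removes peaks overlapping exclusion lists (ENCODE blacklist, nuclear
   mitochondrial homologs) by a 1-bp-overlap rule,
2. re-windows every peak to a fixed width (default 500 bp) centred on its
   summit, keeps the `top_n` (default 50,000) peaks by the caller's
   $-\log_{10} q$ score, and resolves overlaps among re-windowed peaks
   greedily in score order (ties broken by chromosome, then start, so the
   result is deterministic), and
3. counts a fragment into a peak when the two intervals share at least 1 bp;
   each fragment counts at most once.

A cell passes QC when it has at least `min_fragments` (default 500)
fragments mapped to the genome **and** its fraction of fragments in peaks
(FRiP) is at least `frip_factor` (default 0.5) times the cohort median FRiP.
The reference median is taken over the per-cell FRiP values of cells meeting
the fragment cutoff: a single aggregate proportion has no median, so the
per-cell median is the only self-consistent reading of a median-based rule;
a cohort-level aggregate FRiP is one flag away for sensitivity analyses.

Species mixing ("barnyard") controls are classified per cell: below the
fragment cutoff the cell is `low_quality`; otherwise it is assigned to a
species when that species holds at least 96% of its fragments, and called
`hybrid` otherwise. At depths of several hundred fragments the binomial
noise of a contamination fraction up to ~2% stays far below the 4%
tolerance, while a 50/50 doublet sits ~46 binomial standard deviations away
from the purity threshold — which is why clean mixtures classify perfectly
and doublets are flagged essentially always.

## 2. Annotation: motifs and k-mers

The peak-by-feature membership matrix $M$ is boolean. Two feature families
are supported:

* **PWM motifs** (JASPAR-format text). A peak is a member when some
  position, on either strand, reaches a log-odds score whose null
  exceedance probability under an iid background base model is at most
  `p_threshold` (default $5\times10^{-5}$, the convention of standard motif
  scanners). The null distribution is computed exactly by dynamic
  programming over the integerised score distribution (4,000 bins), so the
  threshold is not a heuristic percentage of the maximum score. The
  background is the peak-set average base composition by default —
  deterministic and cheap; a per-peak background would interact with the
  GC-matched backgrounds downstream and is deliberately not the default.
* **k-mers** (k = 6, 7, 8 by convention). One feature per canonical k-mer —
  a k-mer and its reverse complement are collapsed because accessibility is
  unstranded; a no-collapse flag exists for replication attempts. A peak is
  a member when the k-mer occurs at least once in its sequence. Zero-member
  features are pruned, which downstream code requires.

## 3. The deviation statistic

Let $X_{ij}$ be the fragment count of peak $i$ in cell $j$. The expectation
under the technical null spreads the cell's depth over peaks proportional to
peak popularity:

$$E_{ij} = \frac{\sum_j X_{ij}}{\sum_{ij} X_{ij}} \sum_i X_{ij}.$$

For feature $k$ with member set $m(k)$, the raw deviation in cell $j$ is

$$Y_{kj} = \frac{\sum_{i \in m(k)} (X_{ij} - E_{ij})}{\sum_{i \in m(k)} E_{ij}},$$

flagged undefined (never zeroed) when the expected count vanishes. A feature
covering all peaks has $Y \equiv 0$ by construction, which the tests assert.

Raw deviations confound biology with sequence composition: GC content
couples to amplification efficiency, and that coupling varies from cell to
cell. The correction draws, for every peak, `B` (default 50) background
peaks from its `k_nn` nearest peaks in the standardised
$(\mathrm{GC}, \log(1+\text{mean accessibility}))$ plane — so feature $k$'s
background set at iteration $b$ is a multiset of the same size and covariate
profile as the member set. With $\tilde Y^b_{kj}$ the raw deviation of the
$b$-th background set,

$$z_{kj} = \frac{Y_{kj} - \mathrm{mean}_b\, \tilde Y^b_{kj}}{\mathrm{sd}_b\, \tilde Y^b_{kj}},$$

with the $n-1$ denominator in the standard deviation and entries flagged
where the background spread collapses (e.g. `k_nn = 1`, where every
background set equals the member set).

**Choosing `k_nn`.** `k_nn` is the matching bandwidth and should be read as
a *fraction* of the peak count: the package default of 250 targets
realistic peak sets of tens of thousands; the analyses in this package's
tests use roughly 1% of the peaks (e.g. 50 of 4,000). Too large a
neighbourhood lets the sampled backgrounds shrink toward the covariate
centre, which leaves features with GC-skewed member sets under-corrected;
too small a neighbourhood collapses the background spread. Per-member-peak
nearest-neighbour sampling was chosen over binned Mahalanobis sampling
because it is simpler, exactly seed-deterministic, and matches the stated
matching criteria; it is a documented divergence from the internal scheme
of other implementations of this statistic.

**Variability.** The variability of feature $k$ is the standard deviation of
$z_{kj}$ over cells with defined entries; it is close to 1 when the feature
is no more variable than its matched backgrounds. Significance of
$H_0: v = 1$ is assessed by $(n-1)v^2 \sim \chi^2_{n-1}$ (upper tail) with
Benjamini–Hochberg adjustment across features. The $\chi^2$ form is this
package's documented choice — the analytic null follows from $z$ being
approximately standard normal under $H_0$ — and a resampling alternative
(`method = "background"`) recomputes the variability of each background
set's own deviations (centred and scaled by the remaining sets,
leave-one-out) and reports the exceedance fraction, at resolution
$1/(B+1)$. The two agree in feature ordering; the $\chi^2$ default has far
finer resolution at the same cost.

## 4. Protein linkage

Index-sort intensities are transformed by $\operatorname{asinh}(x/150)$ by
default — near-linear around zero, logarithmic at high intensity, the
conventional compromise for fluorescence data; the correlation analyses use
Pearson correlation on the transformed scale with a $t$-distribution
p-value on $n-2$ degrees of freedom and BH adjustment across features.
Stain groups default to explicit cutpoints recorded in the configuration
(gates are drawn manually on the sorter; reproducing them is a matter of
record-keeping, not inference), with a deterministic 1-D k-means
(quantile-seeded, labels ordered by cluster mean) as the unsupervised
alternative.

Group comparisons use the two-sided Wilcoxon rank-sum test — exact when
both groups have at most 10 cells and no ties, normal approximation with
continuity correction otherwise — with **one pooled BH family** over all
features × group pairs, the conservative reading of a figure-level multiple
testing correction. Subgroup–stain enrichment uses Pearson chi-squared on
2×2 tables without continuity correction; tables with a zero expected cell
are flagged, not tested.

**Bimodality.** Hartigans' dip statistic — the maximum distance between the
empirical CDF and the closest unimodal CDF — is implemented in C++ via the
classic shrinking-modal-interval construction over the greatest convex
minorant and least concave majorant. The implementation is validated two
ways: against hand-derivable values (two equal point masses give exactly
1/4; equally spaced points give the quantisation floor $1/(2n)$), and
against an independent oracle in the test suite that solves the defining
minimax problem directly by bisection over a unimodal-feasibility check.
P-values come from a uniform bootstrap null with a fixed seed (the
recommendation of the statistic's authors) rather than interpolated
critical-value tables: the dip is scale- and shift-invariant, so the
uniform is a representative unimodal null.

**Down-sampling control.** To separate group effects from group-size
effects, `downsampled_variability()` redraws `target_n` cells (default 42)
without replacement from every group `n_sim` times (default 100) and
recomputes per-feature variability on the drawn z-score columns. The
backgrounds are not refitted per draw: the z-scores are per-cell quantities
and the variability is the only statistic that depends on the cell set.

## 5. Pseudo-bulk aggregation and information content

Aggregation is an exact column sum. The information-content analysis draws,
for each group size (default 5, 10, 20, 50, 100, 150) and each of `n_sim`
simulations, that many cells uniformly without replacement, downsamples each
cell to `frags` (default 500) fragments, aggregates, and computes Pearson
correlation against a bulk reference over all peaks. Per-cell downsampling
is multivariate hypergeometric (without replacement — subsampling reads from
an alignment), whereas mimic cells drawn from a bulk profile use multinomial
draws from the bulk proportions, since bulk depth is orders of magnitude
above `frags` and the distinction is negligible there. Correlations are
computed on raw counts in peaks; the bulk reference defaults to the mean of
the replicates' raw counts (normalised references are a caller-side choice).

## 6. The synthetic-data generator

The generator emits the full object bundle with known truth. Counts are

$$X_{ij} \sim \mathrm{Poisson}\!\left(d_j\, p_{ij}\right), \qquad
p_{ij} \propto r_i \exp\!\Big(\textstyle\sum_k M_{ik}\beta_k a_{kj} + g_j\,\mathrm{gcz}_i\Big),$$

normalised within each cell so the expected column total equals the cell's
log-normal depth $d_j$. Here $r_i$ is a log-normal per-peak baseline,
$a_{kj}$ the planted activity of feature $k$ in cell $j$ (an indicator
subset or continuous weights), and the two GC terms build the technical
confound the correction must remove:

* peak GC is drawn correlated with $\log r_i$ at `gc_confound_r`
  (default 0.5);
* `gc_bias_sd` gives every cell its own GC slope
  $g_j \sim N(0, \sigma_g)$ on the standardised peak GC — the per-cell
  amplification bias;
* `feature_gc_skew` biases each feature's member-peak sampling along a
  feature-specific GC direction, the way real motifs have distinctive base
  composition.

The last two knobs exist because a GC–baseline correlation alone is
absorbed *exactly* by the row-share × column-total expectation and produces
no null inflation: only the interaction of cell-level GC bias with
GC-skewed member sets does. The null-calibration analyses use
$\sigma_g = 0.1$ and skew 1 — a modest per-cell amplification wobble
(±10% per GC standard deviation) and a realistic motif composition skew —
chosen as plausible magnitudes for a single-batch experiment and documented
here once. Under those conditions matched backgrounds calibrate (mean
variability ≈ 1.0, ~0–4% of null features at $q<0.05$) while GC-blind
(uniform) backgrounds inflate the mean variability to ~1.4: the
"uncorrected" control is z-scoring against uniformly sampled background
sets, because literal raw deviations live on a relative scale far below 1
and cannot sit on the variability's null scale.

Protein channels are `background + slope * a + N(0, noise_sd)` truncated at
zero (a log-normal option exists); in the coupling-recovery analyses the
noise is set so the intensity–activity correlation is 0.6, and the measured
intensity–z correlation comes out slightly lower (~0.52–0.58) through z-score
noise and the asinh transform — attenuation that any real analysis of this
kind inherits.

Barnyard mixtures give singlets a binomial $1-c$ share of their own species
(contamination $c$) and doublets a ~50/50 binomial split at doubled depth.
Bulk replicates are deep Poisson draws around the same baseline profile.

One master seed drives everything through deterministically derived
per-component sub-streams, so adding draws to one stage never shifts
another's.

**What the generator does not emulate:** fragment-length structure, TSS
enrichment, chromosome-level organisation beyond a single synthetic contig,
copy-number or batch structure, spectral spillover between protein
channels, and read-level errors. Passing tests therefore demonstrate the
statistical machinery — expectation model, matching, calibration, linkage —
under the generative assumptions above, not robustness to every artefact of
real sequencing data.

## 7. Numerical and reproducibility choices

* All interval types are 0-based half-open; narrowPeak summits are stored
  absolute. Strand is ignored throughout (accessibility is unstranded).
* Undefined quantities propagate as flags (`NA` + `undefined` mask), never
  silent zeros; variability and correlations skip flagged entries.
* Peak ranking ties break by (score desc, chrom, start); clustering uses
  average linkage on $1 - r$ distance with constant rows/columns dropped
  with a warning; cluster counts are configuration, never auto-chosen.
* `run_pipeline()` writes every table with fixed formatting plus a manifest
  (package version, seed, resolved configuration, input checksums);
  rerunning a configuration reproduces byte-identical tables, which the
  test suite checks by checksum.
* Problem sizes in the shipped analyses (e.g. 4,000 peaks × 500 cells ×
  200 features for the null calibration, 20 seeds; 100 curve simulations
  per size) are chosen as the smallest sizes at which the distributional
  claims are stable, so the whole suite runs on a laptop in minutes.

## 8. Known limitations

* The background sampler is quadratic in peak count (brute-force 2-D
  nearest neighbours, chunked); fine to ~50k peaks, the intended scale.
* The $\chi^2$ variability test assumes approximately normal z-scores;
  with few background iterations ($B \lesssim 10$) the z tails are heavy
  and the resampling method is the safer choice.
* Motif scanning uses one background composition for the whole peak set;
  strongly heterogeneous peak sets may warrant the per-peak option.
* The dip test's bootstrap p-value has resolution `1/n_boot`; n_boot
  below ~1000 is too coarse for 5% decisions.
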