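---
title: "Fluorescence phenomic profiling: model, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fluorescence phenomic profiling: model, design choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(phenoscreen)
```

## The method

`phenoscreen` implements an intensity-based phenomic profiling pipeline for
cell-line panels screened against a diversity-oriented fluorescent probe
library. A panel of cell lines (the reference layout is the NCI-60: 60 human
cancer lines from 9 tissues of origin, including a 2-member prostate class)
is stained with hundreds of untargeted fluorophores from two scaffold
families (rosamine `RS`, BODIPY `BD`) and imaged at several time points.
The analysis runs in five stages, each a plain function over tibbles:

1. **Quantification** (`quantify_screen()`). The images of one condition
   (2 sites x 2 replicates = 4 per well condition) are pooled into a single
   pixel multiset. Otsu's threshold — the split maximizing between-class
   variance of the pixel histogram — defines the "cell area", and the mean
   intensity over threshold-positive pixels is the condition's measurement.
   Thresholding after pooling matches the combine-then-threshold order of
   classical high-content pipelines built on `graythresh`/`im2bw`.
2. **Kinetic features** (`build_feature_matrix()`). The phenotype of a
   (probe, line) pair is the fold change `I(48 h) / I(1 h)` of mean
   foreground intensity. A ratio of two measurements of the same well
   cancels any acquisition factor that is constant across the two time
   points, which is what makes it usable for screens acquired over years.
3. **Clustering** (`hierarchical_cluster()`, `origin_purity()`). Average-
   linkage clustering of log2 folds on both axes gives the heatmap view;
   cutting the line dendrogram at k = 9 and scoring majority-origin purity
   quantifies the "well classified by simple clustering" impression.
4. **Stepwise discriminant analysis** (`forward_stepwise_select()`,
   `fit_lda()`). Wilks' lambda, `det(W)/det(T)`, is the selection
   criterion; candidate probes enter and leave by partial-F tests at
   alpha-to-enter = alpha-to-remove = 0.150, the convention of the SYSTAT
   procedure this mirrors. The fitted model exposes per-class linear
   classification score functions
   `c_k(x) = mu_k' S^-1 x - 1/2 mu_k' S^-1 mu_k + log pi_k`.
5. **Validation** (`jackknife_classification()`, `score_plot()`,
   `subset_comparison()`). Leave-one-out refitting yields the jackknifed
   classification matrix; the top-two score coordinates give the score
   plot; running the selection separately on each probe family and on the
   combined pool shows what scaffold diversity buys.

## The synthetic screen generator

No image set for the original screen was ever deposited, so the package
ships a generator (`generate_screen()`) that produces screens with the
statistical structure the analysis assumes, plus the ground truth needed to
test every stage. Per condition record the foreground mean is

```
I = B_pl * f_pl(t) * b_plate * e
```

* `B_pl`: lognormal baseline per (probe, line), `meanlog log(800)`,
  `sdlog 0.3` — 16-bit counts, well separated from a background of 60.
* `f_pl(t)`: the turn-on fold, interpolated geometrically from 1 at the
  1 h baseline to the full fold at 48 h. The expected fold is the product
  of a (probe series x origin) effect and a (probe, line) effect, so both
  origin-level turn-on and single-line signatures can be planted and read
  back from the emitted ground-truth tables.
* `b_plate`: one lognormal batch factor per plate (`sigma` 0.3), applied to
  foreground *and* background — it emulates acquisition gain. Aligned
  across time points by default, in which case the kinetic fold cancels it
  exactly; `batch_aligned = FALSE` draws it independently per time point
  to break that cancellation on purpose.
* `e`: condition-level lognormal noise (CV 0.20) per (probe, line,
  concentration, channel, replicate, time), shared by the two sites of a
  well — the biological and handling variability that survives averaging.

Images are 128 x 128, 16-bit: random ellipses are placed until 70% of the
area is covered, foreground pixels get lognormal noise (CV 0.30) around the
condition mean, and values are rounded and clipped. Blob morphology is
deliberately crude — only intensity statistics feed the analysis. Plate
maps pair 2 probes with blocks of up to 5 lines and avoid the two
evaporation-prone edge columns on each side.

The **reference demonstration screen** (`demo_screen()`, and
`screen_config()` defaults) is the desk-scale analog of the published
design: 100 probes (50 BD + 50 RS) x the real NCI-60 panel x 500 nM x one
channel x 2 sites x {1, 48} h x 2 replicates = 48,000 images per screen.
30 probes are informative (15 per family): each targets one origin with a
fold drawn uniformly in [2, 4] and carries its own lognormal off-target
signature (sdlog 0.3) across the other origins — probes respond to several
origins with distinct patterns, not as single-line switches, which is how
the informative probes of the real screen behaved. BD informative probes
target origins 1–6 and RS probes origins 4–9, so each family alone covers
only part of the panel and the family comparison has something to find.
The unused 24 h time point of the full design is omitted from the
demonstration screen; the analyzed feature is defined at 48 h / 1 h.

Two generation routes share one random state: `generate_screen()` renders
(or lazily re-renders) every image, while `simulate_intensity_table()`
draws the same hierarchical means and skips the pixels. The pixel route
adds only the sampling error of a mean over ~11,000 foreground pixels plus
the Otsu truncation bias discussed below, so multi-replicate statistical
properties are checked on the fast route and the image route is exercised
end-to-end at full scale once. A test asserts the two routes agree.

## What the synthetic screens do not show

Passing tests on generated screens show the pipeline recovers planted
structure under lognormal noise, batch gain, and the stated design; they do
not show that real screens satisfy those assumptions. In particular the
generator has no localization patterns, no morphology or texture signal,
no focus failures, no well-position effects beyond the excluded edge
columns, and its noise family (lognormal throughout) is an assumption the
original publication never states.

## Numerical and design choices

* **Otsu histogram**: 256 equal-width bins over the observed pooled range,
  mirroring 8-bit `graythresh` behaviour on arbitrary-range data. Ties
  break toward the smallest threshold; "positive" means strictly greater
  than the threshold (the inequality side is unstated in the original
  methods; it only matters for pixels exactly at the boundary). A constant
  pooled image raises a degenerate-histogram error; `quantify_screen()`
  maps it to a flagged record rather than guessing.
* **Otsu truncation bias**: with a tight background and a wide lognormal
  foreground, the maximum-between-class-variance split often sits inside
  the foreground's lower tail, so foreground means are biased a few percent
  high. The bias is close to scale-free and largely cancels in the 48 h/1 h
  ratio; it is the main reason image-route and condition-route intensities
  agree only to a few percent rather than to pixel-sampling error.
* **Fold-change floor**: baselines below 1 count are refused
  (`baseline_floor`), and any flagged line drops the whole feature so the
  retained matrix has no holes.
* **Collapse policy**: one feature per (probe, concentration, channel) by
  default — lossless, since how the original analysis merged its 2
  concentrations x 2 channels is unstated. The `"brightest"` policy (top
  concentration, brighter channel at baseline) matches the single-trace
  view of per-probe figures.
* **log2 folds** for clustering and LDA (flag, default on): standard for
  ratio data, symmetric in turn-on and turn-off.
* **Clustering defaults**: Euclidean distance, average linkage — the
  original parameters are unstated, so no claim of matching its dendrogram
  is made; leaf order is canonicalized smallest-leaf-index-first.
* **Priors**: equal across the 9 origins. Panel class sizes (2–9) reflect
  how the panel was assembled, not prevalence; proportional priors are a
  flag.
* **Selection outside the jackknife**: the classical jackknifed
  classification matrix refits score functions per fold but keeps the
  selected feature set fixed; `jackknife_selected()` provides the honest
  (and slower) double loop for comparison.
* **Guards**: stepwise never enters more than `n - g - 1` features; a
  candidate whose within-class scatter condition number would exceed 1e10
  is skipped; the pipeline additionally caps selection at 35 features so
  the leave-one-out pooled covariance stays well inside its degrees of
  freedom on a 60-line panel. An optional ridge
  (`ridge * mean(diag(S))` on the diagonal) is off by default.
* **F-tail p-values** come from `stats::pf` (the incomplete-beta routine);
  a test pins them to direct numerical integration at 1e-10.

## Redundancy and what "selecting the informative probes" means

With 9 classes the between-class mean space has rank 8. Once a dozen or so
strong probes span it precisely, the remaining informative probes are
statistically redundant: their F-to-enter is marginal and stepwise stops —
exactly the behaviour that kept only 37 of 557 probes in the original
screen. On the reference conditions the procedure recovers the large
majority of planted informative probes across replicates (the recovery
property is asserted in aggregate over five fixed-seed replicates), but no
stepwise procedure will enter all of them, and per-replicate recovery
fluctuates with which probes happen to span the discriminant subspace
first.

## Problem sizes

The validation suite runs the full image pipeline once at the reference
scale (48,000 rendered images), uses condition-level sampling for
multi-replicate properties, and keeps oracle checks (exhaustive Otsu
search, eigenvalue identities, explicit leave-one-out loops) at small n
where brute force is exact. The same sizes are used by
`scripts/acceptance.R`.

## Known limitations

* Quadratic discriminants, per-cell segmentation, and morphology/texture
  features are out of scope.
* The jackknifed accuracy of the reference screen is an upper-bound-style
  estimate (selection outside the loop); use `jackknife_selected()` for
  the conservative variant.
* With a 2-member class, leaving one member out leaves a 1-member class;
  with a 1-member class the held-out sample is necessarily misclassified
  and the run says so. Neither case is silently repaired.
* `fit_lda()` refuses singular pooled covariances instead of regularizing
  by default; perfect within-class agreement (exactly identical feature
  rows) is therefore a fitting error, not a silent success.
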