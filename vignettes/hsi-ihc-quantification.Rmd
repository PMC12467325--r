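---
title: "Quantifying DAB immunostaining from hyperspectral microscopy: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying DAB immunostaining from hyperspectral microscopy: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsiscore)
```

## The problem

Immunohistochemistry (IHC) visualises a protein — here DKK-3 in oral
squamous cell carcinoma tissue cores — with the brown DAB chromogen over a
hematoxylin nuclear counterstain, and pathologists summarise each core with
semi-quantitative scores: the H-score
$$H = 1\cdot\%_{\text{weak}} + 2\cdot\%_{\text{moderate}} + 3\cdot\%_{\text{strong}} \in [0, 300],$$
and the Allred score, the sum of a proportion score (0–5, from the
percentage of positive tumour cells) and an intensity score (0–3), giving a
total in $\{0\}\cup\{2..8\}$.

Visual scoring is subjective; visible/near-infrared hyperspectral imaging
(HSI) records a full reflectance spectrum per pixel and offers an
observer-independent route to the same scores. This package implements that
route end to end — reflectance calibration, spectral windowing,
classification, cell delineation, OD binning, scoring — together with the
agreement statistics used to compare scoring methods, and a synthetic-tissue
generator that provides ground truth for validating every stage.

## The spectral model

A transmitted-light pixel follows base-10 Beer–Lambert mixing over the
constituent endmembers (DAB, hematoxylin, unstained background):
$$R(\lambda) = 10^{-\sum_e c_e A_e(\lambda)},$$
so absorbance $A = -\log_{10} R$ is linear in stain concentration. All
classification and OD measurement therefore operate on absorbance.
Endmembers are sums of Gaussian peaks in OD; the defaults are

| endmember | centre (nm) | width (nm, $\sigma$) | peak OD |
|---|---|---|---|
| DAB | 560 | 80 | 1.10 |
| hematoxylin | 600 | 45 | 0.65 |
| background | 700 | 200 | 0.015 |

The DAB default concentrates its absorbance in 520–650 nm, where the
chromogen absorbs most strongly, so DAB-positive pixels show higher OD
there than in the near infrared. The background is a *near*-flat tilt
rather than exactly zero: a perfectly flat spectrum has zero variance, so
Pearson correlation against it is undefined and unstained pixels could
never be positively classified. A peak OD of 0.015 (under the 0.02 ceiling
the generator enforces) is optically negligible but gives background pixels
a definite spectral shape.

## The synthetic-tissue generator

`generate_layout()` places non-overlapping disc cells (nucleus disc inside
a cytoplasm disc) uniformly at random; `render_cube()` renders them:
DAB at a tier-dependent concentration over positive-cell cytoplasm,
hematoxylin over every nucleus, background elsewhere (a negative cell's
cytoplasm carries no chromogen and renders as background), plus additive
Gaussian reflectance noise clipped to $[0, 1.5]$.

Deliberate design choices:

* **Deterministic tier apportionment.** The positive-cell count and its
  weak/moderate/strong split are largest-remainder apportionments of the
  requested percentages, not multinomial draws, so the layout's implied
  H-score is exact and recovery tests can assert equality rather than
  proximity.
* **Tier concentrations 0.3 / 0.7 / 1.2** (relative DAB units). With the
  default DAB endmember these give cell-mean ODs of about 0.28 / 0.66 /
  1.13 over 520–650 nm, straddling the OD bin thresholds
  (0.2 / 0.45 / 0.9) with comfortable margin on both sides.
* **Disc cells, no overlap.** Connected-component cell recovery is then
  exact, so any scoring error is attributable to the spectral stages.
* **Default conditions:** 128×128 px cores, 101 bands (500–1000 nm at
  5 nm — the camera range; the 5 nm pitch is a package choice matching
  commodity VIS-NIR cameras), 50 cells, 70% positive at a 30/40/30 tier
  mix, reflectance noise sd 0.02.

What the generator does *not* emulate: real tissue architecture, stain
co-localisation, scattering, slide artefacts, focus and illumination
gradients. Passing recovery tests therefore demonstrate the correctness of
the computational chain under the stated optical model, not performance on
real slides.

## Classification

Two routes, both anchored on annotation ROIs (on synthetic data, the
ground-truth masks play the role of the pathologist's ROIs):

* **Correlation functions (CF, default).** Each pixel's windowed absorbance
  spectrum is compared with each class's ROI-mean reference spectrum by
  Pearson correlation; the pixel takes the arg-max class if the best
  correlation reaches `min_corr` (default 0.8), else `UNCLASSIFIED`.
  Pearson correlation is invariant to positive affine rescaling of the
  pixel spectrum, so staining *intensity* does not disturb class
  assignment — only spectral *shape* does. Cosine similarity is available
  as an alternative. A zero-variance pixel has correlation defined as 0.
* **PCA segmentation.** A PCA model is fitted to the mean-centred
  absorbance spectra (covariance, not correlation, since the bands share
  units); the first three components feed a false-colour image
  (1st–99th percentile stretch per channel) and a nearest-centroid
  segmentation in score space. The default distance is **angular** —
  the spectral angle between a pixel's projection and each class
  centroid direction. We chose it over plain Euclidean distance after
  observing that a Euclidean centroid cannot represent a class whose
  amplitude spans three staining tiers: weak-tier DKK3 pixels lie closer
  to the nuclei centroid than to the DKK3 centroid, which Euclidean
  assignment misclassifies wholesale. Euclidean remains available via
  `distance = "euclidean"`.

Determinism: eigenvector signs are fixed (largest-magnitude entry
positive), and similarity/distance ties break by the fixed class order
`DKK3_POSITIVE < NUCLEI < BACKGROUND`.

The default analysis window is 520–725 nm, where DAB and hematoxylin
differ most; per-pixel DAB OD is measured as the mean absorbance over
520–650 nm.

## Cell delineation and scoring

Nuclei are 8-connected components of `NUCLEI` pixels of at least 4 px
(sub-resolution specks are noise). Cytoplasm is assigned by simultaneous
label propagation outward from all nuclei for `ring_radius = 3`
iterations: each DKK3-positive pixel within chessboard distance 3 of a
nucleus joins its *nearest* nucleus only, so cells partition the stained
area and fractions sum correctly. A cell's mean DAB OD over its cytoplasm
pixels is binned by lower-inclusive thresholds 0.2 / 0.45 / 0.9 into
negative/weak/moderate/strong; tier fractions over all cells give the
H-score, and the Allred proportion score uses the standard published bins
(0; (0,1); [1,10]; (10,33]; (33,66]; >66 percent). The core's Allred
intensity category is the arithmetic mean tier of positive cells rounded
half-up — a deterministic choice among the unstated alternatives (mode,
dominant tier), documented here as this package's convention.

## Agreement statistics

`build_report()` compares scoring methods pairwise:

* **Cohen's kappa** on dichotomised scores — Allred low (0–6) vs high
  (7–8); H-scores split at the pooled mean over all methods and cases
  (strictly-above = high). Pooled-mean pooling is the default because it
  reproduces the reference study's published visual and digital category
  columns; per-method pooling is available. Kappa uses
  $\kappa = (P_o - P_e)/(1 - P_e)$ with the degenerate rule $\kappa = 1$
  if $P_o = 1$, else 0, when $P_e = 1$; bands follow Landis–Koch.
* **Spearman's rho** (average ranks for ties) on raw scores.
* **Wilcoxon signed-rank**, two-sided, zeros dropped, average ranks for
  tied magnitudes. The exact p-value is the tail mass of the full
  $2^n$ sign-assignment null distribution, computed by convolution over
  doubled ranks (identical to literal enumeration, but practical at any
  realistic n); a tie-corrected normal approximation with continuity
  correction is the large-n alternative.
* **Shapiro–Wilk** is reported as a descriptive normality gate only; the
  non-parametric suite always runs regardless, mirroring standard
  practice for score data.

## The bundled reference data and known non-reproductions

`reference_study_data()` bundles the published summary tables of a DKK-3
TMA study (97 scored cores; six cases additionally scored from HSI), and
`reproduce_reference_results()` recomputes every derivable quantity and
prints it beside the published value. Two published numbers are *not*
derivable from the published per-case data and are flagged with
`agrees = FALSE` rather than silently adjusted: the visual-vs-HSI kappa
(published 0.42; unweighted kappa on the published dichotomised vectors
gives 0.25) and the visual-vs-HSI Spearman rho (published 0.67; the six
published H-score pairs give ≈ 0.24). Similarly, the published HSI
category for case 4 does not follow from pooled-mean dichotomisation of
the published H-scores; the bundled fixture keeps the published vector
verbatim and the recomputed categories are available separately.

## Numerical and degenerate-input conventions

* Reflectance is clipped to $[0, 1.5]$ (specular ceiling); absorbance uses
  a reflectance floor of $10^{-4}$ (OD cap 4) and clips small negative ODs
  from super-unity reflectance to 0.
* A spatially constant cube is rejected by `fit_pca()` as
  degenerate-variance rather than returning arbitrary eigenvectors.
* An empty core scores all zeros and is flagged non-representative; a
  failing core in a batch is logged and skipped, never fatal.
* All randomness flows from explicit seeds (core *i* of a run uses
  `seed + i` for layout and `seed + i + 500000` for noise); equal configs
  give byte-identical outputs.
* ENVI I/O writes little-endian doubles (BSQ), so cube round-trips are
  bit-exact; TIFF stores 32-bit floats and round-trips to ~7 significant
  digits.

## Validation scale

The test suite validates parameter recovery on batches of twenty seeded
128×128×42-band (after windowing) cores — noiseless recovery is exact;
at reflectance noise 0.02 the recovered H-scores stay within ±10 of the
generator-implied values — and calibrates the exact Wilcoxon test's type-I
error on 2000 simulated paired samples of n = 20. These sizes were chosen
as the smallest that exercise the pipeline at realistic core dimensions
while keeping the suite quick on a laptop.

## A worked example

```{r example, eval = FALSE}
cfg <- pipeline_config(noise_sd = 0.02, seed = 1)
cores <- simulate_cores(cfg, 6)
scores <- run_analyse(cfg, cores = cores)
scores[, c("core_id", "n_cells", "pct_positive", "h_score",
           "allred_total", "implied_h_score")]

# method agreement, e.g. CF vs PCA routes
cfg_both <- pipeline_config(classifier = "both", seed = 1)
run_analyse(cfg_both, cores = simulate_cores(cfg_both, 6),
            out_dir = "analysis")

# recompute the bundled reference-study statistics
reproduce_reference_results()
```

## Known limitations

The optical model omits scattering and chromogen co-localisation; cells
are discs and never touch, so the delineation stage is easier than on real
tissue; classifier anchoring uses ground-truth-derived ROIs, emulating
expert annotation rather than replacing it; and the intensity-bin
thresholds are calibrated to this generator's optics — real acquisitions
would need threshold recalibration against a stained control series.
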