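---
title: "Modeling tissue microstructure from in vivo DTI: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling tissue microstructure from in vivo DTI: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtihisto)
```

# The problem

Diffusion tensor imaging (DTI) is sensitive to tissue microstructure but
notoriously hard to interpret: a change in fractional anisotropy can come
from cellularity, myelinated-axon organization, astrocyte morphology, or
any mixture of them. `dtihisto` implements a quantitative bridge between
the two worlds for region-of-interest (ROI) studies of experimental brain
damage: it quantifies histology micrographs into scalar tissue parameters,
computes scalar DTI metrics from tensor eigenvalues, compares groups with
estimation statistics, and asks — via cross-validated multivariate
regression — how much of the histology DTI can actually predict.

The package is exercised end to end on synthetic data with exact ground
truth, so every stage is testable without any imaging data. This vignette
explains the models, the defaults and their units, the design decisions
that were genuinely open, and what the synthetic phantoms do and do not
demonstrate about real data.

# DTI scalar metrics

From sorted tensor eigenvalues $\lambda_1 \ge \lambda_2 \ge \lambda_3$
(mm$^2$/s), `computeScalarMetrics()` returns

* MD $= (\lambda_1+\lambda_2+\lambda_3)/3$, AD $= \lambda_1$,
  RD $= (\lambda_2+\lambda_3)/2$;
* FA $= \sqrt{1/2}\,\sqrt{\sum_i (\lambda_i - \lambda_j)^2} \big/
  \sqrt{\sum_i \lambda_i^2}$ (unitless, $[0,1]$);
* the Westin shape indices CL $= (\lambda_1-\lambda_2)/T$,
  CP $= 2(\lambda_2-\lambda_3)/T$, CS $= 3\lambda_3/T$ with $T$ the trace.

The trace-normalized Westin convention is the default because it is the
one under which the identities $CL + CP + CS = 1$ and
$AD = 3\,MD - 2\,RD$ hold jointly — identities the predictive model
relies on when it excludes AD and CL to keep the design non-singular. The
$\lambda_1$-normalized variant is available via `westinNorm = "lambda1"`
for comparison with literature that uses it, but it does not satisfy the
sum-to-one identity. Negative eigenvalues (possible in noisy tensor fits)
are rejected with an error by default; `negatives = "clamp"` exists for
real data, but silent clamping is deliberately not the default because it
hides fit pathologies. In `metricsMap()`, zero-trace voxels (background)
are emitted as `NA` rather than propagating NaN.

# Histology quantification

## Cell density

`countCells()` counts dark-stained somata: invert (stain is dark), flatten
the background by subtracting a heavily smoothed copy (Gaussian SD 25 px
by default), threshold (Otsu within the ROI by default — a deterministic,
parameter-free stand-in for per-image manual threshold adjustment),
binary opening (3 px), connected components, an area filter, and an
optional distance-transform watershed that splits touching blobs. Cell
density is reported per mm$^2$ so typical values stay in the
$10^2$–$10^4$ range.

The area bounds default to [7, 700] µm$^2$: below ~7 µm$^2$ an object is
sub-nuclear debris; above ~700 µm$^2$ it is a clump or artefact rather
than a single soma. Both bounds are configurable since they depend on
cell type and stain.

## Structure-tensor anisotropy

`structureTensorField()` convolves the image with directional derivatives
of a 2D Gaussian (kernel size 11 px, $\sigma$ = 3 px by default — the
scale of interest for myelin and astrocyte-process texture at
high-magnification pixel sizes of ~0.114 µm), forms the per-pixel
gradient outer product, and integrates it with a Gaussian window. The
integration $\sigma$ defaults to the derivative $\sigma$; the window over
which tensors are "summed" is otherwise a free choice, and making the two
scales equal keeps the method single-parameter. All convolutions use
reflect padding so image borders do not generate spurious gradients.

Per-pixel anisotropy is the normalized eigenvalue difference
$AI = (\mu_1-\mu_2)/(\mu_1+\mu_2) \in [0,1]$ — the standard 2D
structure-tensor coherence measure. The ROI value is the **mean of
per-pixel AI** over valid pixels, consistent with a pixel-wise reading of
the method; the alternative (AI of the ROI-summed tensor,
`aggregate = "tensor"`) is exposed for sensitivity analysis and is
systematically lower whenever orientations vary across the ROI. Pixels
whose tensor trace falls below $10^{-6}$ of the ROI maximum (or an
absolute floor of $10^{-9}$, which catches numerically flat images) are
excluded as flat; an ROI with no valid pixels is an error, not a zero.

## Skeleton morphometry of astrocytes

`preprocessGfap()` reproduces a classical astrocyte-process enhancement
cascade with fixed, published-style parameters: bandpass keeping
structures between 3 and 40 px (realized as a difference of Gaussians
with $\sigma$ = size/2 — the passband semantics of an FFT bandpass
without its dialect quirks; the DC level is restored so the
dark-stain-on-bright-ground polarity survives), rolling-ball background
subtraction (radius 200 px; implemented as grayscale opening with a disc,
computed at reduced scale for large radii as image-analysis GUIs do),
linear rescale of [10, 254] to [0, 255], unsharp mask
($\sigma$ = 1.5 px, weight 0.6), a 3×3 median "despeckle", an inclusive
intensity threshold window $[0, u]$ with region-specific upper levels
(corpus callosum 218, cortical layer V 223, layer VI 219, hippocampal
CA3b 223), and binary cleanup (despeckle, 3×3 closing, median-deviation
outlier removal with radius 2 px and threshold 50 — values that are
conventional but not canonical, hence configurable).

`skeletonizeAndAnalyze()` thins the binary image with the Guo–Hall
two-subiteration algorithm (topology-preserving, unit-width, 8-connected;
the algorithm is recorded in the result because branch counts at junction
clusters can differ by ±1 across thinning variants), classifies skeleton
voxels by 8-neighbour count (endpoint < 2, slab = 2, junction > 2),
merges adjacent junction voxels into junctions, and traces branches as
slab paths. Branch length is the geometric path length (steps of 1 or
$\sqrt2$ pixels × pixel size); branch attachments are measured to the
junction-cluster **centroid**, which removes the systematic length loss
that nearest-voxel attachment incurs at merged junction clusters.

Components with **no junction voxels** and total length below the 0.7 µm
cutoff are deleted before totals are computed. The published filter rule
targets components with exactly two endpoints below the cutoff; the
no-junction formulation is the same set plus the degenerate single-voxel
residue (one endpoint, zero length) that thinning can leave behind from a
planted fragment — an inclusive reading that keeps the filter idempotent.
The cutoff is compared in micrometres after geometric measurement, not
converted to a pixel count, because sub-cutoff fragments at 0.114 µm/px
span 3–6 pixels where rounding would dominate. Per-component deletion
happens **before** summation into per-image totals; reported
`averageLength` is total branch length over branch count, `NA` when no
branches survive.

# Estimation statistics

Group comparisons report Cohen's d (treated minus control, pooled SD),
a 95% BCa bootstrap CI (5000 stratified resamples by default; bias
correction from the bootstrap distribution, acceleration from the
delete-one jackknife), a studentized two-sided permutation test (Welch's
t as the studentized statistic — "studentized" is read as an
unequal-variance t-type statistic; 100,000 permutations by default, with
the add-one convention so p is never zero, and automatic exhaustive
enumeration when the label assignments number at most 20,000 — note the
default study design, 4 controls vs 13 treated per region, has only 2,380
assignments and is therefore always exact), and Benjamini–Hochberg
q-values adjusted within the reporting family of each call. CIs are
deliberately **not** multiplicity-adjusted, matching standard
estimation-statistics reporting. Effect-size bands use the conventional
0.8/0.5/0.2 thresholds on |d|. Both treatment models in the synthetic
cohort carry one shared "SE" label, so the driver pools them as a single
treated group by construction.

# The predictive model

For each histology parameter $y$, the model is ordinary least squares
over all animals $k$ and regions $j$ concatenated:
$$y_{kj} = \mathbf{b}^\top \mathbf{x}_{kj} + c + e_{kj}, \qquad
\mathbf{x} = (\mathrm{FA}, \mathrm{RD}, \mathrm{MD}, \mathrm{CP},
\mathrm{CS}).$$
AD and CL are excluded because the identities above make the
seven-parameter design exactly singular; `fitMultivariate()` checks the
design rank and names the offending identity if they are reintroduced.
Reported are $R^2$, adjusted $R^2 = 1-(1-R^2)(n-1)/(n-p-1)$,
$F = (R^2/p)/((1-R^2)/(n-p-1))$, and a 95% CI for $R^2$ from an
accelerated bootstrap that resamples **whole animals** — rows within an
animal are dependent (the model's i.i.d. assumption is knowingly wrong
across regions of one animal), so row-level resampling would be
anticonservative. Predictors enter on their native scales; a
standardized option is unnecessary for fit quality and was not added
because the reference analysis reports raw-scale regressions.

Predictive accuracy uses two schemes. Leave-one-animal-out CV holds out
all of one animal's regions, pools every held-out prediction, and reports
the cross-validated Pearson R and
$$Q^2 = 1 - \frac{\sum_{k,j}(y_{kj}-\hat y_{kj})^2}
              {\sum_{k,j}(y_{kj}-\bar y)^2},$$
with $\bar y$ the mean of the true values; $Q^2 \le 0$ means no better
than predicting the mean. Leave-one-region-out CV reports the held-out
Pearson R per region — read as "R on that region's rows when it is
excluded from training" — plus the pooled R over all folds' concatenated
predictions; both readings of a per-region table are computable from the
returned predictions.

# Synthetic data: what it emulates and what it does not

Phantom generators provide every input with exact ground truth:

* **Nissl-like phantoms** — dark anti-aliased disks (radius 3–5 µm) at
  known density on a bright background, optionally with Gaussian noise;
  placement enforces a minimum centre distance by default, with an
  overlap mode to exercise the watershed split.
* **Fiber phantoms** — dark anti-aliased segments whose axial
  orientations come from a von Mises distribution (Best–Fisher sampler on
  doubled angles); $\kappa = 0$ is uniform, $\kappa \ge 500$ is treated
  as perfectly parallel. Anti-aliased rendering, then 8-bit quantization,
  gives the smooth gradients the structure tensor needs.
* **Astrocyte phantoms** — trees with 3 or 4 primary processes radiating
  from each soma at compass angles ≥ 90° apart, optionally bifurcating
  once at ±45°. Centrelines are stamped with 8-connected Bresenham
  segments and dilated to the process width (0.342 µm at 0.114 µm/px), so
  the ground-truth topology (branches, junctions, endpoints,
  triple/quadruple points) and centreline length are exact by
  construction. The ≥ 90° angular separation is a deliberate constraint:
  arms separated by 45° have diagonally adjacent first pixels, which
  makes the planted topology itself ambiguous at the junction. Process
  lengths default to 2.3–3.4 µm — short cellular processes at
  high-magnification scale — and sub-cutoff fragments (0.3–0.55 µm) can
  be planted to exercise the fragment filter.
* **Cohort tables** — the default design is 17 animals (4 controls, 13
  treated) × 4 regions = 68 rows. Eigenvalue triples are drawn per
  (group, region) from Gaussian distributions with realistic rat-brain
  means (strongly anisotropic corpus callosum; near-isotropic cortex;
  a treated-group CA3b with raised FA and lowered CS) and ~5%
  inter-animal spread, rejected if non-positive and sorted. The five
  predictors are then **computed** from the triples, so they inherit the
  structural collinearity of real DTI scalars. Responses follow
  $y = \mathbf b^\top \mathbf x + c + \varepsilon$; when a target
  population $R^2$ is requested, the noise SD is calibrated as
  $\mathrm{sd}(\mathbf b^\top\mathbf x)\sqrt{(1-R^2)/R^2}$ from the
  realized signal.

One global integer seed drives a per-operation stream split, so identical
specs and seeds are bit-reproducible while operations do not share
streams.

What passing phantom tests does **not** show: phantoms have no staining
gradients, no section artefacts, no out-of-focus blur, no overlapping
cell processes, and disk-shaped somata; counting and skeleton accuracy on
them is an upper bound, not an estimate, of real-data accuracy. The
cohort generator draws independent rows, so it cannot expose violations
of the within-animal dependence that the animal-block bootstrap and
leave-one-animal-out CV exist to handle — it can only verify that those
procedures are computed correctly.

# Numerical choices and degenerate inputs

* Convolutions: truncated kernels, reflect padding throughout.
* Thinning iterates to a fixed point; voxel-class conservation
  (endpoint + slab + junction = skeleton total) is asserted in tests.
* Zero pooled SD makes Cohen's d an error at the scalar level; the table
  driver converts it to an `NA` row with a warning so one degenerate cell
  cannot abort a whole report.
* A degenerate bootstrap distribution (all replicates equal) yields a
  zero-width CI with a warning.
* Permutation p-values use the add-one convention in sampled mode
  (never below $1/(n_{perm}+1)$) and the exact proportion in exhaustive
  mode; the raw proportion is also reported.
* Empty ROIs, masks outside bounds, unsorted eigenvalues, zero trace,
  non-binary skeleton input, unknown region names, and duplicate
  (animal, region) keys are all hard errors before computation.

# Known limitations

* The coefficients of the five-predictor model are intrinsically poorly
  determined: the predictors are five functions of three eigenvalues, so
  the design is nearly rank-4 and individual coefficient estimates have
  standard errors comparable to or exceeding the coefficients themselves
  at realistic noise (population $R^2 \approx 0.8$, $n = 68$). Model-level
  quantities ($R^2$, cross-validated R, $Q^2$) are stable; per-coefficient
  inference is not, and no package setting can change that — it is a
  property of the measurement geometry. The package therefore reports
  model-level accuracy prominently and treats coefficient recovery as a
  diagnostic.
* 2D skeletons only; a 3D extension would change voxel classification
  and lengths.
* The ROI summary is the mean (median by option); no spatial
  registration between DTI and histology is attempted — correspondence
  is by region label, as in ROI-based study designs.

# Problem sizes used in the test-suite and acceptance runs

Identity checks use $10^5$ random triples; skeleton recovery uses 50
phantoms (40 plain, 10 with planted fragments) at 300–400 px; BCa
coverage uses 500 simulations of 20 + 20 observations with 1000
resamples; model recovery uses 200 cohorts of 68 rows; counting accuracy
uses 25 + 25 phantoms of 256 px. These sizes give Monte Carlo error well
inside each asserted tolerance while keeping a full run around two
minutes on one core.
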