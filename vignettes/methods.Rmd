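---
title: "Semi-automated tissue segmentation of dual-echo neonatal brain MRI: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-automated tissue segmentation of dual-echo neonatal brain MRI: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neoseg)
```

## The problem

Quantitative brain volumetry in extremely preterm newborns requires
segmenting clinical dual-echo MRI — a proton-density-weighted (PD) and a
T2-weighted channel acquired together and inherently co-registered — into
cerebrospinal fluid (CSF), cortical gray matter (GM), cerebral white matter
(WM) and regions of diffuse white matter signal abnormality (WMSA), and
combining that tissue map with a manually produced map of nine subcortical
structures. Neonatal scans have low contrast (incomplete myelination), low
SNR, and severe partial-volume mixing at the 0.36 × 0.36 × 1.98 mm voxel
geometry typical of axial dual-echo volumetry, which is why the method is
*semi*-automated: the automated stages handle the three bulk tissue classes,
while structural parcellation and the WMSA decision remain human-approved
inputs.

`neoseg` implements the full computational chain: brain extraction,
denoising, intensity standardization, a nonparametric Parzen-window initial
classification in the joint (PD, T2) intensity plane, refinement by a hidden
Markov random field fitted with expectation-maximization (HMRF-EM),
morphological post-correction, structural-map merging, mask-driven WMSA
relabeling, the accuracy indices (Dice SI, CEI/OEI/UEI) and the reliability
statistics (within-subject SD, repeatability, ICC) used to evaluate such
pipelines — plus a seeded phantom generator so every stage is testable
without any clinical data.

## Pipeline stages and their models

### Brain extraction

`extract_brain_mask()` emulates seeded region growing on the T2 channel: the
4-connected component of voxels inside a user-chosen intensity band
`[low, high]` is grown from a seed placed in the bright subarachnoid CSF,
per axial slice. The band is carried to neighbouring slices, each seeded by
its overlap with the previous slice's region; because the CSF rim can shift
inward by more than its own width where the brain tapers, the *filled*
region (not the raw rim) seeds the next slice. Each slice is finalized by
hole-filling, so the mask retains all intrameningeal tissue. A precomputed
mask can be supplied instead (the equivalent of manual editing).

### Denoising

`anisotropic_diffusion()` is Perona–Malik diffusion per axial slice with
exponential conductance $g(d) = \exp(-(d/\kappa)^2)$, written in
conservative flux form so the global mean is preserved to machine precision.
Defaults: 10 iterations, $\lambda = 0.25$ (the 2-D stability limit),
$\kappa$ = twice the median absolute neighbour difference (a robust noise
scale, so genuine class edges with contrast well above the noise are
preserved). These defaults are the package's own choices and are plain
function arguments.

### Intensity standardization

`fit_normalization()` / `apply_normalization()` implement landmark-based
histogram standardization: within-mask percentiles at 1%, 10%, …, 90%, 99%
are mapped piecewise-linearly onto a standard scale (default 0–100) learned
by averaging the training volumes' mapped landmarks. The transform is
monotone, affine-invariant, and a volume normalized against a model fitted
on itself reproduces the standard landmarks exactly. A degenerate (constant)
intensity distribution is an error, never silently passed through.

### Parzen-window initial classification

For each class $c$ with training samples $\xi_i \in \mathbb{R}^2$ (PD, T2)
the density is the Gaussian kernel estimate

$$\hat p_c(x) \;=\; \frac{1}{n_c}\sum_{i=1}^{n_c}
\frac{1}{2\pi h_c^2}\exp\!\left(-\frac{\lVert x-\xi_i\rVert^2}{2h_c^2}\right),$$

evaluated on a 256 × 256 grid spanning the standardized intensity range, and
each in-mask voxel is assigned the class with the largest density at its
(PD, T2) position. The nonparametric estimate is what lets skewed
distributions (CSF, and WMSA had it been modelled) be represented without a
Gaussian assumption. Choices that matter:

* **Bandwidth.** $h_c = s_c\, n_c^{-1/6}$, where $s_c$ is the root mean of
  the two per-axis sample variances — a Silverman-type rate for a 2-D
  Gaussian kernel. The formula is a documented package rule; explicit
  bandwidths can be passed instead.
* **Grid lookup.** Nearest bin. Voxels where the top two class densities are
  within 50% of each other — the only places where half-bin quantization
  could flip the argmax — are re-evaluated with the exact kernel sums, so
  gridded and direct classification agree essentially everywhere.
* **Ties and off-support voxels.** Exact ties break by the fixed priority
  CSF > GM > WM. Voxels with zero density under every class are assigned the
  class of the nearest training sample in (PD, T2) Euclidean distance.
* **Mass checks.** Each class density must integrate to 1 ± 10⁻³ on the
  grid; lower mass means the grid does not cover the samples and is an
  error, not a warning.

### HMRF-EM refinement

Voxel intensities $y_i \in \mathbb{R}^2$ are modelled with per-class
Gaussian emissions and a Potts prior over labels: the local energy of class
$k$ at voxel $i$ is

$$U_i(k) = \tfrac12\log\lvert\Sigma_k\rvert
 + \tfrac12 (y_i-\mu_k)^\top \Sigma_k^{-1} (y_i-\mu_k)
 + \beta \sum_{j \in N_i} \mathbf{1}[\ell_j \neq k],$$

with $N_i$ the 8-neighbourhood within the axial slice (a 6-neighbourhood in
3-D is available; the in-plane default matches the 5.5:1 slice-thickness
anisotropy). Fitting alternates: (E) posterior weights from the emissions
and the Potts prior evaluated at the current neighbour labels; (M)
closed-form mean/covariance/proportion updates; a bias-field update; and up
to five raster-order ICM sweeps (`icm_sweep()`, compiled) that greedily
minimize $U_i$. Iteration stops when fewer than `tol` (default 10⁻⁴) of the
in-mask voxels change label, or after `max_em` (default 20) iterations.
With $\beta = 0$ and bias correction off the procedure reduces exactly to
Gaussian-mixture EM with a uniform prior, which is how it is cross-checked
against an independent mixture implementation.

**Covariance model.** `mrf_config(cov_model = )` offers `"tied"` (one pooled
covariance, the default) and `"full"` (per-class). The default is tied
because of a failure mode we measured on phantoms: after edge-preserving
denoising the within-class variance is tiny while partial-volume voxels at
class boundaries deviate by many within-class SDs; with per-class
covariances the intermediate class (GM, which borders both CSF and WM)
inflates along the mixing axis and swallows entire boundary shells,
depressing its Dice overlap by 5–7 points. The tied model keeps decision
boundaries symmetric between neighbouring classes and recovers the lost
accuracy; with well-separated clusters the two models agree.

**Bias field.** The multiplicative gain per channel is
$\exp(\mathrm{smooth}(\log y - \log \hat y))$, smoothed in-plane with a
Gaussian at 25 mm (configurable), gauge-fixed to mean 1 over the mask.
Inside EM the fitted value $\hat y$ is the posterior-weighted mixture of
class means — at boundaries the mixture interpolates, so partial-volume
voxels do not masquerade as bias; the exported `estimate_bias()` defaults to
the crisp-label residual and accepts posterior weights. Smoothing at scales
comparable to the field of view attenuates the recovered amplitude (the
estimate is a low-pass projection); the direction and shape of the field are
recovered, which is what the correction needs.

**Degeneracies.** A class whose posterior mass empties is a reported
class-collapse error, never silently reseeded. Near-singular covariances
(condition number above 10⁸) are ridge-regularized with a warning. The whole
stage is deterministic given its initialization.

### Post-processing and merging

Partial-volume averaging at the brain surface misclassifies subarachnoid CSF
as WM, so `relabel_surface_wm()` erodes the mask per slice with a 3 × 3 box
(2 erosions by default, 3 configurable — misclassification is confined to
the outermost 2–3 voxels) and relabels WM in the peeled rim as CSF,
touching nothing else. `merge_structural()` pastes the nine structural codes
over the tissue map (structural always wins). `relabel_wmsa()` converts CSF
to WMSA only inside a rater-approved mask — the package never invents WMSA
on its own, preserving the human-in-the-loop semantics — and
`suggest_wmsa_candidates()` proposes interior CSF components near the
ventricles (not connected to the subarachnoid surface, within a configurable
distance) for that review. All three edits are monotone and voxel-count
conserving, so the edit chain is auditable.

### Accuracy and reliability statistics

For a class with true/false positives and false negatives (TP, FP, FN)
against a reference segmentation:

$$\mathrm{SI} = \frac{2\,\mathrm{TP}}{2\,\mathrm{TP}+\mathrm{FP}+\mathrm{FN}},
\qquad \mathrm{CEI} = \frac{\mathrm{TP}}{\mathrm{Ref}},\quad
\mathrm{OEI} = \frac{\mathrm{FP}}{\mathrm{Ref}},\quad
\mathrm{UEI} = \frac{\mathrm{FN}}{\mathrm{Ref}},$$

so CEI + UEI = 1 and SI = 2CEI/(2CEI + OEI + UEI). Undefined cases (empty
reference, or both maps empty for SI) are reported as `NA`, never as 0 — a
zero would silently deflate averages. Reliability of repeated volume
measurements uses the within-subject SD (root of the one-way ANOVA residual
mean square), repeatability (2.77 × within-subject SD, the 95% limit for the
difference of two repeats), and the intraclass correlation. The ICC model is
selectable because the evaluation convention only says "ANOVA models":
one-way random ICC(1,1) for intra-rater designs (occasions interchangeable)
and two-way random single-measure absolute-agreement ICC(2,1) for
inter-rater designs, both with F-based 95% confidence limits and the model
name in the output.

## The phantom generator

`phantom_spec()` / `generate_phantom()` build a seeded two-channel head
phantom with complete ground truth: nested ellipsoidal shells (skull,
subarachnoid CSF rim, cortical GM ribbon, WM core), lateral-ventricle CSF,
nine structural blobs deep in the WM core, and WMSA lesions hugging the
ventricle borders. Defaults are fixed study conditions, chosen once:

* grid 128 × 128 × 24 at 0.36 × 0.36 × 1.98 mm (the acquisition voxel
  geometry at a reduced in-plane matrix — full problem size, tractable on
  one CPU);
* class means in (PD, T2): CSF (210, 220), GM (150, 130), WM (120, 90), on
  a 0–255-style scale with CSF bright on both channels, WM dark, GM
  intermediate; WMSA means sit between WM and CSF, close to CSF, so lesions
  misclassify as CSF exactly as they do clinically;
* per-class SD 6 and additive noise SD 5 per channel, putting the smallest
  class-mean separation (GM–WM, 50 units) at ≈ 6.4 total SDs;
* a linear left–right bias ramp of ±10%, partial volume emulated by a
  0.4 mm in-plane Gaussian PSF applied to the ideal class-mean image (the
  truth label stays the dominant class), and 2 periventricular lesions.

What the phantom deliberately does **not** model: cortical folding, spatially
correlated tissue texture (its within-class variability is white, so
denoising removes nearly all of it — real tissue retains correlated
heterogeneity), Rician noise statistics, motion, and myelination gradients.
Consequently, passing phantom tests demonstrates the correctness and the
boundary behaviour of the algorithms, not clinical-grade accuracy; phantom
Dice values are optimistic relative to clinical scans, whose reported
automated-stage accuracy is lower.

The generator is the package's only stochastic component (one seed in the
spec); everything downstream is deterministic, so pipeline reruns are
bit-identical.

## Numerical and design notes

* Voxel indices are 1-based (idiomatic R); per-slice operations act on the
  acquisition (axial) plane.
* Label codes: 0 background, 1 CSF, 2 GM, 3 WM, 4 WMSA, 10–18 the nine
  structures (single code per structure, no left/right distinction). The
  scheme is serialized as a JSON sidecar with every label map.
* Large-kernel Gaussian smoothing (the bias field) runs on a downsampled
  copy of each slice and is resized back; the field is band-limited far
  below the resampling scale.
* ICM ties break toward the smaller class code, matching the CSF > GM > WM
  priority used at the Parzen stage; sweep order is raster (x fastest).
* Problem sizes used by the test-suite and the acceptance script: unit tests
  run mostly on 48 × 48 × 10 phantoms; the end-to-end checks run the full
  128 × 128 × 24 default over five seeds, with training sets of 200 samples
  per class drawn from two independent phantoms.
* The region-growing thresholds, like the seed, are operator inputs by
  design; the worked examples use a band that keeps the CSF rim connected
  under the default noise and bias.

## Known limitations

The automated stage classifies exactly three classes; WMSA is downstream and
mask-driven. The bias model is in-plane only. Structural blobs in the
phantom share the WM intensity distribution, so merging is exercised
geometrically, not photometrically. The ICC confidence limits assume
balanced designs, which the input checks enforce.
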