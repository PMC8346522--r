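---
title: "Quantifying collagen fiber orientation disorder in tumor-associated stroma"
author: "cfodts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying collagen fiber orientation disorder in tumor-associated stroma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfodts)
```

## The problem and the measurement

Stromal collagen reorganizes as a carcinoma invades: fibers near an
aggressive tumor tend to align, while indolent disease keeps a more
isotropic, disordered fibrous matrix. Collagen-specific imaging
(second-harmonic generation, polarized light) can measure this but is not
part of clinical routine. This package measures fiber orientation disorder
directly on H&E-style RGB images, producing one interpretable patient
vector and a survival model on top of it.

The disorder statistic, CFOD-TS, is defined per square tumor neighborhood:

1. detect linear (fiber-like) structures in tumor-associated stroma and
   assign each an axial orientation $\Theta \in [0^\circ, 180^\circ)$;
2. discretize orientations into 18 bins of $10^\circ$;
3. count every ordered pair of distinct fibers into an $18\times18$
   symmetric co-occurrence matrix $C$ (so $\sum C = n(n-1)$ for $n$
   fibers);
4. report the Shannon entropy $H = -\sum_{ij} P_{ij}\log_2 P_{ij}$ of
   $P = C/\sum C$, in bits.

Fully aligned neighborhoods concentrate $C$ in one diagonal cell and give
$H = 0$; isotropic neighborhoods spread mass widely and give large $H$
(bounded by $2\log_2 18 \approx 8.34$ bits). Averaging over neighborhoods
at nine fields of view (50–250 µm) and two regions (whole tumor and its
500 µm leading-edge band) yields the 18-feature patient vector.

### The co-occurrence construction

The all-pairs count within a neighborhood is the simplest construction
that makes the matrix total analytic and keeps the diagonal the signature
of same-orientation pairs. A distance-windowed variant (only fiber pairs
whose centroids are within a radius) would add a spatial notion of
co-occurrence; the all-pairs form was chosen as the default because it is
parameter-free, and the construction is isolated in
`orientation_cooccurrence()` so an alternative kernel can be swapped in
without touching any caller. Entropy is reported in bits (base 2); any
other base is a monotone rescaling and would change no ordering or test in
the package.

## Fiber detection

Detection follows the derivative-of-Gaussian jet / Basic Image Feature
scheme. The unit-normalized luminance is convolved with Gaussian
derivative kernels up to second order at one scale $\sigma$ (separable,
reflective boundary; kernels renormalized so polynomial images give exact
derivatives). From the scale-normalized invariants — Laplacian
$\lambda = \sigma^2(L_{xx}+L_{yy})$, shear magnitude
$\gamma = \sigma^2\sqrt{(L_{xx}-L_{yy})^2 + 4L_{xy}^2}$ and gradient
magnitude $\eta = \sigma\sqrt{L_x^2+L_y^2}$ — each pixel takes the argmax
of seven class scores: flat $\varepsilon L$, slope $2\eta$, dark blob
$+\lambda$, light blob $-\lambda$, dark line $(\gamma+\lambda)/\sqrt2$,
light line $(\gamma-\lambda)/\sqrt2$, saddle $\gamma$. A locally dark
ridge has positive Laplacian across the ridge, so fibers (dark eosin
strands) land in *dark line*; the sign convention is verified on rendered
ridges in the test suite rather than assumed. Ties are broken by a fixed
class priority (flat, slope, dark blob, light blob, dark line, light line,
saddle).

Eight-connected components of dark-line pixels inside the stroma mask
become fiber segments; each segment's orientation is the major axis of its
pixel second-moment ellipse, measured counterclockwise from the horizontal
axis in display convention. Components smaller than `min_segment_px` are
dropped (orientation is ill-posed for tiny sets), as are exactly isotropic
components.

### Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| working resolution `mpp` | 0.5 | µm/px | ≈20× magnification; fibers ~1 µm wide remain resolvable while quartering the pixel count of 40× |
| detection scale `sigma_px` | 2 | px | matches ~1 µm half-width fibers at 0.5 µm/px; configurable for thicker stroma |
| flatness gain `epsilon` | 0.05 | — | on unit luminance, keeps blank glass flat-classified at typical noise |
| `min_segment_px` | 10 | px | smallest set with a stable second-moment orientation |
| `min_stroma_ratio` | 0.2 | — | neighborhoods mostly epithelium or glass carry no usable fiber signal |
| `min_fibers` | 10 | fibers | entropy of fewer than ~10 orientations is dominated by sampling noise |
| band width | 500 | µm | the leading-edge definition: tumor within 500 µm of its boundary |
| FOVs | 50–250 by 25 | µm | no single neighborhood size is privileged; the sweep is part of the feature set |

Neighborhoods are a non-overlapping grid anchored at the tumor bounding
box; a cell belongs to the leading edge when its center lies in the band
(an unambiguous, scale-free rule). Detection runs once per tile and each
segment is assigned to the cell containing its centroid; this makes the
per-FOV maps exactly recomputable from the same segment table and avoids
re-detecting at every FOV.

## Tissue masks

When epithelium/stroma masks are supplied they are used as-is. Otherwise a
stain-deconvolution heuristic separates hematoxylin from eosin optical
densities with the standard H&E stain matrix: cell-dense
hematoxylin-dominant pixels become epithelium, eosin-dominant fibrous
pixels stroma, and low-density glass neither. This heuristic is a
deliberately simple, fully transparent segmenter: it is adequate for the
package's phantoms and for well-stained tissue, but it is not a learned
segmenter and will not match one on difficult real slides — supplying
curated masks is always the preferred path. The tumor mask is built from
epithelium by disk dilation (default 50 µm) and hole filling, so scattered
epithelial patches merge into one region containing the intervening
stroma; the leading-edge band comes from the Euclidean distance transform
of the tumor interior.

## The survival model

`cfod_cox()` standardizes the 18 features (z-scores; missing slots imputed
by training means), fits the LASSO-penalized Cox partial likelihood over a
decreasing penalty path, and picks the largest penalty retaining exactly
$k = \mathrm{round}(0.1\,n)$ features — the budget rule, not
cross-validation, fixes the model size, because the scientific design
fixes the feature count relative to the cohort. If no path point has
exactly $k$ nonzero coefficients the nearest count below is used with a
warning. The risk score is the linear functional
$\beta^\top z(x)$; the dichotomization threshold scans the 10th–90th score
percentiles and keeps the most significant training log-rank split, ties
resolved toward the median. Both choices are optimized on the training
data, so the training p-value is anti-conservative by construction; the
model object carries that note, and validation (`run_validate`) applies
the frozen transform with a hash assertion that nothing was refit.

Conventions: five years is 1826.25 days; tied event times use the Breslow
approximation; hazard ratios take the low-risk group as reference; groups
with zero events are reported with a divergence flag rather than silently.
The short/long DFS comparison takes short = event before five years,
long = follow-up of at least five years, excluding patients censored
earlier, and uses the Wilcoxon rank-sum test with normal approximation.
Oncotype DX categories follow the TAILORx cuts (low < 11, intermediate
11–25, high > 25).

## Synthetic data: what it emulates, and what it does not

`generate_fiber_tile()` renders anti-aliased dark line segments (eosin
tones via the stain model, so the deconvolution heuristic sees realistic
colors) on a lighter stroma background, with orientations drawn from an
axial von Mises distribution: a von Mises draw on the doubled-angle circle,
halved — the standard treatment for undirected axial data, with
$\kappa = 0$ the uniform limit and $\kappa \to \infty$ perfect alignment.
`generate_wsi_phantom()` embeds a disk tumor with scattered hematoxylin
epithelium blobs and draws fiber orientations with separate concentrations
inside and outside the leading-edge band, so the edge/core disorder
contrast is constructible at will. Defaults — fiber width 1 µm, lengths
10–30 µm, density 0.006 fibers/µm², additive Gaussian noise of 5/255 —
were chosen once for detector testability: dense enough that 50 µm
neighborhoods pass the validity filter, sparse enough that fibers remain
resolvable at $\sigma = 2$ px.

`generate_survival_cohort()` skips the imaging layer and draws the
18-feature table directly: feature means increase and spreads decrease
with FOV, and leading-edge and whole-tumor features at matched FOV
correlate at $\rho = 0.8$, mirroring the structure real extractions show.
Event times follow an exponential proportional-hazards model
$h_0 e^{\beta^\top z}$ with uniform censoring calibrated to a target
fraction; the default $\beta$ puts negative weight on eight features, so
*lower* disorder means *higher* hazard — the biological direction.

What the phantoms do **not** emulate: nuclei and cellular texture, stain
variability and batch effects, fiber crossings as distinct instances,
scanner artifacts, or any learned-segmenter failure mode. Passing tests on
phantoms therefore demonstrate that the measurement chain is correct and
directionally faithful, not that the segmentation or detection would reach
any particular accuracy on clinical slides.

## Numerical choices and degenerate inputs

- Entropy sums its probability terms in sorted order, making the value
  exactly invariant under bin permutations (and hence under rotations by
  multiples of 10°).
- Neighborhoods with fewer than two fibers have an all-zero co-occurrence
  matrix; their entropy is undefined and the validity filter removes them.
- Isotropic pixel sets (equal second moments) have no orientation and are
  dropped; single-pixel segments never pass the area filter.
- The exactly-$k$ path search takes the *largest* qualifying penalty, the
  most-regularized model at that size.
- The von Mises sampler is Best–Fisher rejection; no circular-statistics
  dependency is used.
- One top-level seed expands into fixed per-stage substreams so a stage
  can be re-run in isolation without disturbing the others.
- Problem sizes in the test suite are chosen at desk scale: phantoms of
  0.06–4 mm², cohorts of 78–600 patients, and 20–100 seed replicates per
  statistical property.

## Known limitations

- The stain-deconvolution segmenter is a heuristic stand-in; real-slide
  epithelium/stroma quality depends on staining and should be reviewed or
  replaced by supplied masks.
- Single-scale detection misses fibers far from the default width unless
  `sigma_px` is adjusted; no multi-scale fusion is on by default.
- Crossing fibers merge into one component and contribute one orientation.
- The threshold scan's training p-value is not valid inference; only
  held-out validation is.
- The package analyzes single-level crops, not whole-slide pyramids.
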