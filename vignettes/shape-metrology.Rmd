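---
title: "Soft shape classification of nanoparticle contours: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Soft shape classification of nanoparticle contours: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanoshape)
```

## The problem

Nanoparticle performance — optical, catalytic, biomedical — depends on
particle shape, and every synthesis produces a *distribution* of shapes.
Quantifying that distribution from transmission-electron-microscopy (TEM)
images by hand is laborious and subjective; supervised classifiers need the
very shape labels one is trying to discover. `nanoshape` implements an
unsupervised pipeline: particle contours are extracted from a calibrated
micrograph, each contour is reduced to a size-, position- and
rotation-invariant shape descriptor, and the descriptor cloud is modelled
by a Gaussian mixture fitted with expectation-maximization. The mixture's
posterior responsibilities give each particle a *soft* class membership:
for visibly distinct shape families the classification collapses to hard
labels and the class count collapses to the true number, while for a
continuum of irregular shapes the responsibilities quantify the class
mixing instead of forcing arbitrary hard boundaries.

## Shape descriptors

For a filled contour with central second moments $\mu_{20},\mu_{02},
\mu_{11}$ and area $m_{00}$, the scale-normalized moments are
$\nu_{pq} = \mu_{pq}/m_{00}^{1+(p+q)/2}$, and the first two Hu invariants
are

$$H_1 = \nu_{20}+\nu_{02}, \qquad
  H_2 = (\nu_{20}-\nu_{02})^2 + 4\nu_{11}^2 .$$

$H_1$ is the trace and $\sqrt{H_2}$ the eigenvalue gap of the normalized
inertia tensor, so the tensor's eigenvalues are
$\lambda_{1,2} = (H_1 \pm \sqrt{H_2})/2$. The package reports
$\eta_{1,2} = 2\sqrt{\lambda_{1,2}}$: with this scaling a unit-area ellipse
has $\eta_1,\eta_2$ equal to its semi-axes, every ellipse satisfies
$\pi\,\eta_1\eta_2 = 1$, and the aspect ratio $\eta_1/\eta_2$ is the
semi-axis ratio. Convex particle projections live close to this ellipse
curve, which is what makes the two-invariant reduction sufficient; the
higher invariants $H_3\ldots H_7$ are computed behind the `n_hu` flag but
are not part of the default feature set.

Moments are evaluated in closed form from the polygon vertices by Green's
theorem, never by rasterization, after resampling the boundary to at least
256 equally spaced arc-length points. Exact integration makes the
similarity invariance of $H$ hold to numerical precision (the test suite
demands $10^{-4}$ relative), and makes descriptor accuracy independent of
image resolution. The classification feature is
$\log_{10}(H + \varepsilon)$ with $\varepsilon = 10^{-12}$: circularly
symmetric shapes have $H_2$ exactly zero and the feature must stay finite.

## Contour extraction

The preprocessing chain is deliberately conventional: optional denoising
(isotropic Fourier low-pass with the DC term untouched, or Gaussian blur),
intensity thresholding with polarity resolved by the imaging modality
(bright-field particles are darker than background, dark-field brighter),
hole filling so internal contrast (core–shell particles) cannot fragment a
component, connected-component labelling, and Moore boundary tracing of
each component. On a binarized image boundary tracing yields the same
closed contour an edge detector would link, without hysteresis parameters;
no separate grayscale edge-detection path is provided. Components touching
the image border are excluded outright — their shape is unmeasurable.

Two conventions matter downstream:

* **Area.** A traced boundary passes through boundary pixel *centers* and
  under-measures area by roughly half a pixel of perimeter. Extracted
  contours are rescaled uniformly about their centroid so the polygon area
  equals the component's pixel count, which is unbiased for compact shapes.
  With the default thresholding this recovers a rendered disk's diameter
  to a quarter pixel.
* **Triage.** Solidity (area over convex-hull area, threshold 0.95) splits
  contours into isolated particles and aggregates; components below
  `min_area` are debris. Every contour lands in exactly one bucket;
  aggregates are routed to the template-fitting stage rather than
  discarded.

## Mixture model and class-count selection

The feature cloud is fitted by a full-covariance Gaussian mixture via EM
(k-means++ initialization, 10 restarts under a fixed master seed,
log-sum-exp E-step, covariance eigenvalues floored at $10^{-6}$ times the
mean feature variance). The floor matters because log-Hu features of a
shape family are strongly correlated along the aspect-ratio continuum; the
restarts matter because EM only finds local optima. Components whose
weight collapses are pruned rather than crashing the fit. The EM
log-likelihood trace is retained and checked non-decreasing in every fit
of the test suite.

The class count is selected from $K = 1..K_{max}$ by the
entropy-penalized BIC (the integrated-complete-likelihood criterion),
followed by pruning of components with weight below 1%. Plain BIC is also
available, and the two differ in an instructive way: measured log-Hu
features have a heavy left tail in $\log H_2$ — aspect-ratio measurement
noise near the isotropy point $AR \to 1$ is amplified without bound by the
logarithm — and BIC will happily spend a mixture component on that tail,
because BIC counts *density components*. The entropy penalty charges a
component for every point it cannot claim confidently, so ICL counts
*distinct classes*, which is the quantity a metrologist wants. On the
well-separated hexagon/rod benchmark ICL selects $K = 2$ across all tested
seeds while BIC occasionally returns 3 (an independent mixture
implementation reproduces the same BIC behavior, so this is a property of
the criterion, not of the optimizer).

Summary statistics are responsibility-weighted: the class's effective
number $\Sigma_k = \sum_i r_{ik}$, its fraction $\Sigma_k/N$, and weighted
means and standard deviations of effective diameter
($d = 2\sqrt{A/\pi}\,\times$ pixel size) and aspect ratio. For a
correctly specified mixture, $E[r_k(X)\,g(X)] = \pi_k E_k[g(X)]$ for any
statistic $g$ — soft weighting is unbiased for the per-class parameters
even when the classes overlap heavily, which is precisely where hard
assignment fails.

## Separating aggregates: curvature-sign fitting

Thickness-dominated TEM contrast makes particle interiors regions where
the intensity Laplacian has a definite sign. The difference-of-Gaussians
operator $G(\sigma) - G(1.6\sigma)$ approximates that Laplacian; its sign
map (the "binary DoG") shows particles as dark regions separated by
bright creases wherever two particles touch. Aggregated particles are then
identified by fitting *known shapes* — templates averaged from the
already-classified isolated particles — under bounded affine
transformations, scoring each pose by the fraction of its boundary ring
that lands inside the mask.

Implementation choices that the idea as just stated leaves open, and how
this package resolves them:

* **Noise robustness.** In signal-free background the sign of the
  band-passed noise is a fair coin, so a pure sign map is half-full of
  speckle. Responses weaker than 3 times the image-wide median absolute
  DoG response are therefore excluded (`magnitude_floor`; set it to 0 for
  the pure sign map). Holes are *not* filled by default: the informative
  structure for fitting is the strong edge band plus the separating
  creases, and filling seals crease junctions inside three-particle
  clumps, inviting "bridge" fits that straddle two particles.
* **Pose search.** Rotation is scanned in 3° steps over one
  rotational-symmetry period of the template (detected automatically; a
  6-fold hexagon template needs only 0–60°), per-axis scales over
  {0.9, 1.0, 1.1}, skew fixed at 0 by default; all grids are arguments.
  The translation dimension is solved exactly for every pose by a single
  FFT cross-correlation of the rasterized ring with the mask (the
  correlation is rounded back to integer counts, so the FFT introduces no
  floating-point leakage; equality with the brute-force sliding overlap is
  a tested invariant). The pose grid only needs to land within the
  translation scan's tolerance basin, which is what keeps the coarse grid
  sufficient.
* **Acceptance.** Candidates above `score_min` compete greedily by
  *signed boundary evidence* — covered ring pixels minus uncovered ones,
  minus a mild prior on $|\ln s_x| + |\ln s_y| + |skew|$. Unlike raw
  precision this compares across template sizes (a full-size ring
  explaining an entire edge band beats a smaller template's ring hiding
  inside thick black) and penalizes inflated rings. Each accepted fit
  claims its interior: those mask pixels are cleared and the remaining
  candidates rescored, which suppresses duplicates and parasitic
  sub-fits without any hand-tuned exclusion radius. Accepted fits must
  also stay below 20% mutual IoU.

The working mask is dilated by 1 px (the ring half-width) before scoring:
the sign transition sits within half a pixel of the true boundary, so a
correctly scaled ring straddles it otherwise.

## The synthetic scene generator

No public micrograph data accompanies the method, so validation runs
against a bundled generator that emulates the three imaging scenarios the
pipeline targets — well-dispersed distinct shapes (hexagonal platelets
plus rods), densely packed irregular rounded shapes on a fluctuating
background, and bright-on-dark cube-like particles with core–shell
contrast — plus touching/connected/aggregated groups.

Design choices, fixed once:

* **Geometry.** Every family is built from an isotropic base shape
  (regular polygon with circular corner fillets; 6-fold hexagon, 4-fold
  rounded square, circle) stretched anisotropically. Because the base's
  second-moment tensor is isotropic, the stretch factor *is* the inertia
  aspect ratio the descriptor pipeline measures, so generator truth and
  estimate are directly comparable with no calibration constant. `size`
  is the equal-area-circle diameter, matching the effective-diameter
  output convention.
* **Aspect-ratio law.** Class aspect ratios are drawn with
  `sample_aspect_ratio()`: the excess $AR - 1$ is log-normal with the
  requested mean and sd. A truncated normal would put a point mass of
  perfectly isotropic particles at exactly $AR = 1$ — a sampling artifact
  no real ensemble exhibits, and one that lands $\log H_2$ at the
  $\varepsilon$ floor.
* **Contrast.** Projected thickness is a unit slab (platelet-like
  particles have flat tops) plus a 0.3-amplitude spherical-cap dome, then
  blurred by a 0.7 px Gaussian point-spread function. The blurred slab
  edge places the half-amplitude intensity level exactly at the true
  boundary — mid-level thresholding is then unbiased — while the dome term
  supplies the definite interior Laplacian sign the binary DoG relies on.
  A pure dome profile was rejected: it biases threshold contours several
  percent small.
* **Backgrounds.** Constant, linear gradient, or "fluctuating" (low-order
  2-D polynomial plus band-limited noise) to stress thresholding the way
  dense quantum-dot fields do. Bright-field and dark-field polarity are
  exact mirror images.
* **Determinism.** One integer seed drives every stochastic draw; equal
  seed and parameters give bit-identical scenes.

What the generator does **not** emulate: electron-optical aberrations,
dynamical diffraction contrast, detector MTF, carbon-film texture,
beam-induced drift. Passing tests therefore demonstrate the pipeline's
*algorithmic* correctness (descriptor math, mixture recovery, aggregate
separation under thickness-like contrast), not robustness to every
instrumental artifact of real micrographs.

## Validation conditions and problem sizes

The test suite and the acceptance script regenerate everything from code:
analytic oracles at 512 boundary points; similarity invariance over 200
random convex polygons; a 38-hexagon + 5-rod scene (512×512 px at
2 nm/px, noise sd 0.02, sizes 64.5 ± 3.0 and 49.0 ± 1.1 nm, aspect ratios
1.03 ± 0.02 and 1.76 ± 0.05) for class-count reduction and hard-fraction
recovery; 50 replicates of a two-component Gaussian mixture in log-Hu
space anchored to the continuum scenario (aspect ratios 1.12 ± 0.05 and
1.25 ± 0.08, weights 0.57/0.43 stratified exactly, n = 500) for weight
and class-mean recovery; and 20-particle aggregate scenes (320×320 px,
30 nm hexagons with a 0.76-scale rod minority) containing isolated,
touching, connected and 3-particle-aggregate groups. These sizes keep the
whole suite within a desktop-scale run while leaving each statistical
check adequately powered; they are the package's chosen validation
conditions, not measurements of any published specimen.

## Known limitations

* Convex (and mildly irregular) particle projections only; strongly
  non-convex shapes need descriptors beyond two Hu invariants.
* Template fitting assumes aggregate members resemble the isolated
  classes up to a bounded affine map — the method's stated premise; a
  genuinely novel shape occurring only inside aggregates will be
  mis-explained by the nearest known template.
* The DoG magnitude floor is relative to the image-wide median response;
  images that are nearly all particle (no background) shift that
  reference.
* Deeply overlapping particles (beyond slight contact) merge their
  curvature signatures; the crease that separation relies on fades with
  overlap depth.

## A worked example

```{r example, eval = FALSE}
library(nanoshape)

spec <- tibble::tibble(
  label = c("hex", "rod"), n = c(38L, 5L),
  shape_family = c("hexagon", "rod"),
  size_mean = c(64.5, 49), size_sd = c(3, 1.1),
  ar_mean = c(1.03, 1.76), ar_sd = c(0.02, 0.05))
scene <- make_ensemble(spec, dim = c(512L, 512L), pixel_size = 2,
                       noise_sd = 0.02, seed = 7)

cfg <- run_config(pixel_size = 2, seed = 1)
res <- run_analyze(cfg, image = scene)
res$summary          # two classes; sigma 38 / 5
plot_eigenvalues(res$descriptors, res$classification)
plot_diameters(res$descriptors, res$classification)

agg <- run_aggregates(cfg, res)   # templates + binary-DoG fitting
agg$merged_summary
```
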