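---
title: "Hyperspectral analysis of animal coloration with avicube"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hyperspectral analysis of animal coloration with avicube}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A hyperspectral data-cube records radiance along two spatial dimensions and
one spectral dimension: every pixel carries a complete reflectance spectrum
rather than three broad camera channels. For animal-coloration work this
means a single scan of a museum specimen yields, at once, whole-surface
spatial coverage and spectrophotometer-grade spectral resolution, including
the near ultraviolet that many birds see but humans and RGB cameras do not.
`avicube` implements the full analysis chain for such cubes: calibration to
reflectance, spatial sampling of plumage patches, spectral preprocessing,
a visual-system-independent embedding of the sampled spectra, an avian
visual model (tetrahedral colour space and receptor-noise contrasts), and
an optional 3D step that attaches surface-normal angles to every sample.
A synthetic-scene generator with exact ground truth stands in for specimen
imagery, so every stage is testable offline.

## Calibration model

Push-broom imagers expose one sensor line at a time while the subject is
translated, so illumination varies across image columns and bands but not
lines. Two references convert raw radiance to reflectance:

1. **Flat-field** (`flat_field()`): a *bright image* of a uniform white
   target spanning the field of view is averaged over its lines, giving a
   per-(column, band) reference; each pixel spectrum is divided by its
   column's reference. This removes directional-lighting non-uniformity.
2. **White standard** (`standard_spectrum()`, `to_reflectance()`): every
   scene contains a near-perfect diffuse reflector; sampled spectra are
   divided by the standard's per-band median spectrum, times its nominal
   reflectance. The default `nominal = 1` reproduces the common
   divide-by-the-99%-standard practice; `nominal = 0.99` gives the
   physically exact scaling.

On noiseless synthetic scenes this chain recovers patch reflectance to
machine precision (the test suite asserts `< 1e-12`), and calibrating the
standard's own pixels returns the nominal value at every band. Values above
1 can legitimately occur at specular highlights and are kept, not clipped
(a message flags values above a configurable cap). Negative sensor values
are clamped to zero at ingestion, with a count reported: reflectance is
physically non-negative, and silent NaN propagation downstream is worse
than clamping.

Dark-current subtraction is deliberately out of scope: the calibration
implemented here is the bright-image division plus white-standard ratio,
nothing more.

## Sampling

`grid_locations()` lays a square lattice over each patch mask, choosing the
spacing so the in-mask count approximates a per-patch target (default
1000) — this equalises sample counts across patches and specimens of
different sizes. The search is deterministic: it starts from
`floor(sqrt(mask_area / target))`, steps integer spacings outward, and
refines fractionally (lattice coordinates rounded to pixels) when integer
spacings bracket but miss the ±10 % tolerance; ties resolve toward the
smaller spacing (more samples). The grid origin is anchored at the mask
bounding box offset by half a spacing — no randomness anywhere. Grids are
laid per patch, not once per image: a shared image-wide grid intersected
with patches could not hit per-patch targets.

At each location `extract_sample()` takes the per-band **median** of a
10 × 10 pixel window (100 pixels at interior locations), making isolated
hot or saturated pixels inconsequential. Windows are truncated at image
edges rather than discarded, to avoid biasing against patch boundaries.
Locations whose window touches the white standard are excluded. Pixel
coordinates are 1-based `(row, col)` everywhere in the package, matching R
matrix indexing.

## Spectral preprocessing

Three steps, in order (`prep_spectra()` chains them):

- `interpolate_1nm()`: piecewise-linear interpolation onto the integer
  1 nm grid, 325–700 nm. Near-UV imagers are noise-limited below 325 nm,
  so the native grid (e.g. 294 bands spanning 274–812 nm, ~1.83 nm
  spacing) is restricted to the reliable window.
- `smooth_spectra()`: Savitzky–Golay filtering, window 45 nm and
  polynomial order 2 by default. On a 1 nm grid the nm window maps
  directly to 45 filter points. Edge windows are handled by fitting the
  polynomial to the truncated window, so polynomials up to the filter
  order pass through unchanged everywhere — the suite checks quadratic
  invariance to 1e-9. This default is deliberately strong smoothing: its
  purpose is stable ultraviolet extrapolation, where small noise near
  325 nm would otherwise produce large extrapolation differences. Lighter
  windows are appropriate when no extrapolation is needed; the window is a
  parameter, not a constant.
- `extrapolate_uv()`: avian sensitivity extends to 300 nm, below the
  imager's reliable range. A monotone (Fritsch–Carlson, shape-preserving)
  cubic Hermite interpolant is fitted to the smoothed 325–700 nm curve and
  its *leftmost cubic segment* is evaluated on 300–324 nm. "Monotonic
  cubic fit, extended leftward" is the design choice here: it honours both
  the cubic and the monotone requirement, is deterministic, and cannot
  oscillate. Extrapolated values are clamped to `[0, 1.5 × max(R)]` to
  stay physical; the result is exactly continuous at 325 nm. The fit
  window is exposed (`fit_window`) for users who prefer fitting only a
  neighbourhood of 325 nm.

The final grid is exactly 300–700 nm at 1 nm (401 points). Because avian
receptor sensitivity below 325 nm is comparatively low, visual-model
outputs are robust to the extrapolation choice: replacing the extrapolated
segment with a constant changes chromatic contrasts between the synthetic
patch spectra by well under 0.1 JND (asserted in the suite, measured at
~0.015).

## Visual-system-independent embedding

`pca_embed()` first subtracts each spectrum's own scalar mean reflectance
— brightness removal, leaving spectral *shape* — then applies ordinary
dataset-centred PCA, retaining 20 components. "Subtract the mean
reflectance from each spectrum" is ambiguous between a per-spectrum scalar
and the dataset mean spectrum; both are implemented
(`center = "per_spectrum"` / `"mean_spectrum"`), with the per-spectrum
scalar as default since brightness normalisation is the shape-based
practice this step serves. One PCA is fitted per patch by request
(`by = "patch"`): different patches need not share principal axes.

`manifold_embed()` reduces the 20-D scores to 2-D with UMAP
(`n_neighbors = 15`, `min_dist = 0.1`, seed 42, all configurable; single
thread for exact reproducibility). All-identical input collapses to the
origin rather than erroring. `density_contours()` then estimates a
Gaussian kernel density per group on a shared 256 × 256 grid over the
pooled bounding box padded 10 %, with Scott's-rule bandwidths per group
(floored for degenerate groups, with a warning). The contour level for
each group is chosen so the region above it integrates to the requested
mass (default 80 %) — the highest-density region — and the mode is the
grid argmax. `mode_spectra()` returns the `k = 50` samples nearest each
mode in the 2-D map, summarised by per-band median and MAD: the group's
"most typical" colour.

On 20,000 standard-normal draws the 80 % HDR contains 0.81 of the points
and its equivalent-area radius is within 3 % of the closed form
`sqrt(-2 ln 0.2)`; the small positive bias is kernel smoothing, which
widens the estimated density by about `n^(-1/6)` in bandwidth.

## Avian visual model

`vs_bird_receptors()` builds a violet-sensitive (VS) tetrachromat on the
300–700 nm grid. Curves come from the Govardovskii et al. (2000) A1
pigment nomogram (alpha plus beta band, peak-normalised) at configurable
peak wavelengths; the defaults 416 / 478 / 542 / 607 nm (VS, SWS, MWS,
LWS) are typical average-VS values from the comparative avian-vision
literature — they are template approximations, not a copy of a published
curve table, and measured curves can be supplied as CSV instead. Cone
abundances default to (1, 1, 1, 2), the Rock-dove ratios; the chromatic
Weber fraction defaults to 0.1.

Under an ideal (flat) illuminant with von-Kries adaptation to an ideal
white background, quantum catches reduce to
`Q_i = sum(R * S_i) / sum(S_i)`, so perfect white gives `Q_i = 1` for all
cones. Relative catches map to the tetrahedron via

    x = ((1 - 2s - m - u)/2) * sqrt(3/2)
    y = (-1 + 3m + u) / (2 * sqrt(2))
    z = u - 1/4

placing the achromatic point at the origin and each pure-receptor vertex
at distance 0.75.

Chromatic contrast follows the tetrachromatic receptor-noise-limited
model: signals `f_i = ln(Q_i^A / Q_i^B)`, noise
`e_i = w * sqrt(n_max / n_i)` with the Weber fraction anchored to the most
abundant cone (so `e = (0.141, 0.141, 0.141, 0.1)` at the defaults), and
dS the standard ratio of six pairwise terms to four triple-product terms.
The tests cross-check this against an algebraically independent
formulation — dS as the weighted least-squares residual of the signals
about their optimal common offset — agreeing to 1e-10 on 1000 random
catch quadruples. Luminance contrast is `dL = |ln(Q_D^A / Q_D^B)| / w_D`
through the double cone (nomogram at the LWS peak by default; `w_D = 0.1`
— both conventions are stated rather than assumed silently, and
configurable). A catch floor of 1e-9 precedes the logs so synthetic black
pixels cannot produce infinities; floored values are reported.

Two colours are called discriminable at `contrast >= 3` (inclusive) by
default — a deliberately conservative threshold for museum-specimen
comparisons, since the model assumes discrimination at the physiological
limit under ideal conditions. `patch_contrasts()` compares the median
spectrum of each patch on each specimen pairwise, the stated
simplification for specimen-level comparisons. `cone_catch_image()`
applies the same model per pixel, producing 4/5-channel stimulation images
(32-bit float TIFF) for downstream pattern analysis; per-pixel spectra are
extended to 300 nm either by constant extension (default, fast) or the
full preprocessing rules.

## 3D registration and angle binning

Specimens are imaged at a fixed height, so scale is constant and a
scaled-orthographic (weak-perspective) camera is the right model — this
makes pose estimation a closed-form fit rather than an iterative
perspective solve. `estimate_pose()` solves the least-squares 2 × 3
projection of centred mesh landmarks onto centred image landmarks and
factors it by SVD into rotation × scale, reporting reprojection RMSE.
Noiseless recovery is exact to 1e-8; at least 4 non-coplanar landmarks pin
the full rotation (coplanar sets leave the out-of-plane component
ambiguous, and collinear sets error).

`render_normals()` rasterises the posed mesh orthographically with a depth
buffer at the image's resolution and reports, per pixel, the surface
normal of the frontmost triangle as two angles: roll (positive = facing
left of camera) and pitch (positive = facing up), both `atan2` forms in
`[-pi, pi]`. Background pixels are invalid (`NA`), never silently zero.
Face normals are the default; vertex-normal interpolation
(`normals = "vertex"`) gives smoother fields on curved surfaces — on a
sphere it matches the analytic normal to under 1 degree away from the
silhouette. `bin_by_pitch()` attaches the window-centre normal to each
sample (nearest pixel; samples are 10 × 10 medians so the centre is the
natural representative), drops invalid-normal samples with a count, and
summarises each pitch bin by per-band median ± MAD — the standard display
for angle-dependent (iridescent) reflectance.

## The synthetic generator

`scene_spec()` / `simulate_cube()` emulate the acquisition geometry the
pipeline targets: a 120 × 160 scene on the instrument-like 294-band
274–812 nm grid (so interpolation faces the same ~1.83 nm arithmetic as
real cubes), four elliptical plumage patches with distinct spectrum models
(carotenoid-like sigmoid step, structural Gaussian peak at 530 nm, flat
white, brown linear ramp — the canonical plumage reflectance shapes), a
white-standard rectangle at nominal 0.99, a linear column illumination
gradient (default amplitude 0.2, emulating a directional source nearer one
side of the stage), and additive Gaussian radiance noise (default sd 0.01,
a realistic signal-to-noise for cooled line-scan sensors; no published
sensor noise model was available, so additive Gaussian is the neutral
choice). A matching bright cube is returned, built from the same gradient,
plus the masks and true spectra. Everything is driven by one seed;
identical seeds give bit-identical cubes.

`simulate_scene3d()` adds the 3D case: an ellipsoid specimen viewed
orthographically, per-pixel pitch from the analytic ellipsoid normal, an
iridescent reflectance whose Gaussian peak shifts as
`lambda0 - k * pitch` (default k = 100 nm/rad), a matching UV-sphere-style
triangle mesh, and ≥ 4 exact landmark correspondences.

What the generator does *not* emulate — and therefore what passing tests
do not show about real data: feather microstructure and specular BRDFs
(patches are uniform Lambertian fields plus noise), fluorescence,
spatially correlated sensor noise, registration error between bright and
scene cubes, and segmentation error in the patch masks (masks are exact).
Tests demonstrate that the *algorithms* are correct under controlled
conditions, not that museum imagery is free of these effects.

## Problem sizes and numerical choices

The validation runs use sizes chosen to exercise every code path at full
fidelity: 120 × 160 × 294 scene cubes, ~200 samples per patch end-to-end,
20,000 draws for the HDR check, a 192 × 96 sphere mesh rasterised at
96 × 96. Tolerances asserted in the suite: calibration 1e-12 (noiseless),
Savitzky–Golay quadratic invariance 1e-9, tetrahedral vertex radius 1e-12,
dS cross-check 1e-10, pose recovery 1e-8, sphere normals 1 degree, mode
spectrum recovery 0.02 reflectance units, iridescence slope 10 %.

Tie-breaks and degenerate inputs are all deterministic and documented:
band selection ties resolve toward the lower wavelength; grid-spacing ties
toward the smaller spacing; `target_n = 1` returns the pixel nearest the
mask centroid; all-identical embeddings collapse to the origin;
zero-variance KDE groups get a floored bandwidth with a warning; zero
bright-reference or standard bands become `NA` with counts reported rather
than infinities.

## Limitations

- The ENVI reader supports the common integer and float data types and
  `bil`/`bip`/`bsq` interleaves; exotic header variants (offsets into
  multi-file datasets, BSQ tiling) are out of scope.
- Perspective registration is deferred; the orthographic model is right
  for fixed-height stage imaging but not for close-range or wide-angle
  setups.
- Receptor curve defaults are nomogram approximations. For publication
  work, supply measured curves via the CSV source and state their
  provenance.
- The embedding is for visualisation and retrieval; no statistical testing
  on embedded coordinates is provided (PCA scores are amenable to MANOVA
  and friends if desired).
- Automatic patch segmentation is not attempted; masks are user input.
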