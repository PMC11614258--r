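# avicube

Hyperspectral imaging is becoming the gold standard for quantifying animal
coloration: one scan of a specimen yields a **data-cube** — a complete
reflectance spectrum at every pixel — combining the spatial coverage of
photography with the spectral resolution of spectrophotometry, ultraviolet
included. `avicube` is an R toolkit for analysing such cubes in the context
of animal (especially avian plumage) coloration. It is written for
researchers who have (or want to simulate) calibrated hyperspectral scans
of specimens and need to get from raw cubes to colour spaces, perceptual
contrasts, and angle-resolved reflectance.

The pipeline:

1. **Cube I/O** — ENVI header + binary reader/writer (`bil`/`bip`/`bsq`),
   band slicing, RGB composites (`read_envi()`, `slice_band()`,
   `render_rgb()`).
2. **Calibration** — bright-image flat-field for illumination
   non-uniformity, then division by the in-scene white standard's median
   spectrum (`flat_field()`, `standard_spectrum()`, `to_reflectance()`).
3. **Sampling** — deterministic uniform grids over patch masks, equalising
   counts across patches; 10 × 10 windowed-median sample spectra
   (`grid_locations()`, `extract_sample()`, `build_sampleset()`).
4. **Preprocessing** — 1 nm interpolation (325–700 nm), Savitzky–Golay
   smoothing (45 nm window, order 2), monotone-cubic UV extrapolation to
   300 nm (`prep_spectra()`).
5. **Visual-system-independent space** — per-patch PCA (20 components,
   per-spectrum brightness removed) + UMAP to 2-D; kernel-density
   highest-density-region contours and density-mode spectra
   (`pca_embed()`, `manifold_embed()`, `density_contours()`,
   `mode_spectra()`).
6. **Avian visual model** — quantum catches under an ideal illuminant,
   tetrahedral coordinates

       x = ((1 − 2s − m − u)/2)·√(3/2),  y = (−1 + 3m + u)/(2√2),  z = u − ¼

   (achromatic centre at the origin, pure-receptor vertices at radius
   0.75), and receptor-noise-limited contrasts: ΔS from the tetrachromatic
   Vorobyev–Osorio formula with noise e_i = w·√(n_max/n_i) (Weber fraction
   w = 0.1 anchored to the most abundant cone, abundances 1:1:1:2), ΔL =
   |ln(Q_D^A/Q_D^B)|/w_D, and a conservative ≥ 3 JND discriminability call
   (`vs_bird_receptors()`, `quantum_catch()`, `tetra_coords()`,
   `rnl_chromatic()`, `rnl_luminance()`, `patch_contrasts()`,
   `cone_catch_image()`).
7. **3D geometry** — scaled-orthographic pose from landmark
   correspondences, depth-buffered surface-normal (roll/pitch) maps, and
   pitch-binned median ± MAD spectra for iridescence analysis
   (`estimate_pose()`, `render_normals()`, `bin_by_pitch()`).
8. **Synthetic scenes** — fully ground-truthed cubes, masks, meshes, and
   landmarks so the entire pipeline is testable with no downloads
   (`scene_spec()`, `simulate_cube()`, `simulate_scene3d()`).

Result types are tibbles throughout (sample sets are wide tables with one
`wl_<nm>` column per band), with `tidy()`/`glance()` for embeddings and
`autoplot()` methods for band images, embeddings, density contours, and
normal maps. A thin CLI over the same functions lives at
`inst/cli/avicube.R` (subcommands `simulate`, `render`, `calibrate`,
`sample`, `prep`, `embed`, `vision`, `normals`).

## Worked example

Simulate a scene (four plumage patches, a 99 % white standard, a 20 %
lighting gradient, sensor noise), calibrate, sample, preprocess, embed,
and model avian vision:

```r
library(avicube)
library(dplyr)

sc  <- scene_spec(noise_sd = 0.01, gradient = 0.2, seed = 7)
sim <- simulate_cube(sc)

cube <- flat_field(sim$cube, sim$bright)
#> <hypercube> 120 lines x 160 samples x 294 bands (274.0-812.0 nm)

ss <- build_sampleset(cube,
                      sim$masks[setdiff(names(sim$masks), "standard")],
                      sim$masks$standard,
                      species = "synthetic", specimen = "s1",
                      target_n = 200, nominal = sc$standard$nominal)
count(ss, patch)
#>   patch          n
#> 1 back         215
#> 2 belly_vent   210
#> 3 breast       210
#> 4 shoulder     215

pp  <- prep_spectra(ss)                 # 300-700 nm at 1 nm, smoothed
emb <- manifold_embed(pca_embed(pp, n_components = 20), seed = 42)
emb
#> <spectral_embedding> 850 spectra, 20 components, with 2-D map

rec <- vs_bird_receptors()
#> <receptor_system> peaks 416/478/542/607 nm; abundances (1,1,1,2);
#>   Weber 0.10/0.10 (+double cone)

quantum_catch(pp, rec) |>
  group_by(patch) |>
  summarise(across(c(Q_lws, q_mws, x, y, z), mean))
#>   patch      Q_lws q_mws        x         y        z
#> 1 back       0.235 0.362 -0.0206   0.0718   -0.134
#> 2 belly_vent 0.832 0.250 -0.0000   -0.0000   0.0000
#> 3 breast     0.378 0.295  0.240   -0.0147   -0.177
#> 4 shoulder   0.332 0.269  0.0439   0.0005   -0.0545
```

Reading the catch table: the flat white `belly_vent` patch sits at the
achromatic origin (x = y = z ≈ 0) with the highest long-wavelength catch
(it is the brightest patch); the structural-green `back` patch pulls
toward the MWS vertex (largest `q_mws`, positive y); the carotenoid-step
`breast` patch pulls toward the LWS vertex (positive x). Retrieving each
patch's most typical spectrum from the embedding and comparing to the
generator's truth:

```r
ms <- mode_spectra(density_contours(tidy(emb), "patch"), tidy(emb), pp, "patch")
# back-patch mode-spectrum max abs error vs truth: 0.00089
```

i.e. the full calibrate → sample → smooth → embed → retrieve chain
recovers the generating reflectance to under 0.001 despite the lighting
gradient and sensor noise.

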