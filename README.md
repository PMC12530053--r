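# sed3d — 3D fibril orientation mapping from scanning electron diffraction

`sed3d` reconstructs per-pixel three-dimensional fibril axes from scanning
electron diffraction (SED / 4D-STEM) data acquired at a few tilt angles
about a single axis. It was built for semicrystalline fibrillar
biocomposites — cellulose in plant cell walls is the motivating case — where
the (200) reflection's diffraction vector lies normal to the fibril's long
axis, so each diffraction pattern fixes the fibril's in-plane direction and
a short tilt series resolves the full 3D axis. The package maps helical
cell-wall textures quantitatively: per-layer orientation statistics,
left/right handedness, helix pitch, colour-wheel and cylinder-glyph
visualisations. A complete synthetic phantom and diffraction forward model
make every stage testable without microscope data.

Intended users: electron microscopists and quantitative image analysts
working on orientation mapping of beam-sensitive, weakly scattering
nanocrystalline materials.

## The method

At each scan pixel and tilt `omega_i`, the Bragg-peak azimuth `phi_i` on the
(200) ring is extracted from 360 virtual detectors and yields a unit vector
on the circle orthogonal to the fibril axis,

```
q'_i = [cos(phi_i), sin(phi_i), 0]^T ,   q_i = R_y(-omega_i) q'_i ,
```

back-rotated into zero-tilt sample coordinates. The fibril axis `â` is the
direction best-orthogonal to all `q_i`. Two measurements solve exactly via
`â ∝ q_1 × q_2`; more are solved by iterated averaged projections

```
P_i(â) = â − (â·q_i) q_i ,   b_k = (1/N) Σ_i P_i(â_k) ,   â_{k+1} = b_k/|b_k| ,
```

which converges to the smallest-eigenvalue eigenvector of the q scatter
matrix (the suite asserts this against a dense eigensolver). Axes with zero
component along the tilt axis give the same azimuth at every tilt and are
flagged degenerate rather than guessed. Angles are reported as an in-plane
angle from +x (mod 180°) and a signed out-of-plane angle from the beam axis,
whose sign tracks the helical handedness.

## Worked example

Simulate a three-layer transverse cell-wall phantom, reconstruct it from
0/±45° azimuth maps with 3° azimuthal noise, and summarise per layer:

```r
library(sed3d)

layers <- data.frame(r_in_um = c(0.6, 1.4, 2.2), r_out_um = c(1.4, 2.2, 3.0),
                     in_plane_deg = c(33, 47, 27), out_of_plane_deg = c(56, -61, 60))
ph   <- make_phantom(layers, "annular", shape = c(64L, 64L), step_nm = 100)
maps <- simulate_azimuth_maps(ph, tilts = c(0, 45, -45),
                              noise = noise_spec(azimuth_sigma_deg = 3, seed = 42))
fld  <- reconstruct_field(align_series(maps))
layer_stats(fld, ph$labels, erode = 1)
#>   label n_pixels in_plane_deg out_of_plane_deg in_plane_sd out_of_plane_sd handedness
#> 1     1      336         32.8             55.8        2.20            2.01       left
#> 2     2      624         46.8            -61.0        2.31            2.35      right
#> 3     3      864         26.9             59.9        2.12            2.45       left
```

Each row is one wall layer: the circular mean in-plane angle and arithmetic
mean signed out-of-plane angle recover the ground truth (33°, 56°), (47°,
−61°), (27°, 60°) to a fraction of a degree, the dispersions reflect the
injected 3° azimuthal noise, and the alternating sign of the out-of-plane
angle is read out as alternating left/right helical handedness.

The published per-layer orientations of oat husk cell walls ship with the
package and reproduce the printed inter-layer crossing angles:

```r
tab <- oat_layer_orientations("transverse")
rel <- interlayer_relationship(tab, pairs = list(c(1,2), c(2,3), c(3,4), c(6,7)))
rel$pairwise_deg        # 64.4, 62.0, 60.0, 54.8
round(rel$mean_deg, 1)  # 60.3 — consecutive opposite-handed layers cross at ~60°
```

A YAML-configured pipeline (`run_pipeline()`, or the
`inst/scripts/sed3d.R` driver) chains
simulate → azimuth → align → reconstruct → analyze → render, reading and
writing HDF5 stacks and CSV sidecars, each stamped with the config hash and
seed.

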