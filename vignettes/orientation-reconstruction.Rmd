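---
title: "Reconstructing 3D fibril orientations from scanning electron diffraction tilt series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing 3D fibril orientations from scanning electron diffraction tilt series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sed3d)
```

## The measurement model

Scanning electron diffraction (SED) rasters a quasi-parallel, nanometre-sized
electron beam across a thin section and records a full 2D diffraction pattern
at each position, giving a 4D data set. In semicrystalline fibrillar
materials such as plant cell walls, the cellulose I-beta (200) reflection is
the most intense feature; its diffraction vector is normal to the long axis
of the fibril. A single pattern therefore constrains the fibril's in-plane
direction (perpendicular to the Bragg azimuth) but says nothing about its
out-of-plane inclination.

`sed3d` implements the few-tilt reconstruction that resolves this: the same
field of view is scanned at a small number of tilts about a single vertical
axis (typically 0 and +/-45 degrees). The method assumes the nanocrystalline
texture is axially symmetric about a single fibril axis per probed volume, so
each tilt contributes one measured azimuth `phi` and hence one unit vector

    q' = [cos(phi), sin(phi), 0]

lying on the circle orthogonal to the fibril axis in the tilted frame. After
back-rotation to zero-tilt sample coordinates, `q = Ry(-omega) q'`, the
fibril axis `a` is the direction simultaneously orthogonal to all the `q_i`.

## Stages and the parameters that matter

**Azimuth extraction** (`ring_profile()`, `azimuth_map()`). 360 square
virtual detectors (default 0.04 x 0.04 1/A) are placed on a ring at the
(200) radius. The ring radius defaults to 0.258 1/A (d200 of cellulose
I-beta, about 3.88 A) and is configurable, since other materials put the
working reflection elsewhere. Friedel symmetry makes the profile 180-degree
periodic, so antipodal halves are averaged ("folded"); folding by the mean
rather than the sum keeps per-detector intensity units. The peak position is
refined to sub-bin precision with a circular three-point parabolic fit
(disable with `refine = FALSE`). The azimuth origin is the detector +x
(column) axis, counter-clockwise positive - an arbitrary but globally fixed
convention that also defines the in-plane angle reference in all outputs.

**Quality filtering.** Each folded profile is scored by the ratio of the
first Fourier harmonic to the DC term: one well-defined Bragg pair
concentrates power in exactly one period per half-turn, while flat or noisy
rings score near zero. The default validity threshold of 0.10 was calibrated
once against the package's own render model at its default background level,
where it admits well under 5 percent of pure-noise frames while keeping
essentially all true Bragg frames; it is a configuration value
(`ring_config(quality_threshold = )`), not a constant of nature, and should
be re-examined for detectors or doses far from the defaults.

**Tilt alignment** (`align_series()`). Tilting compresses the field of view
by `cos(omega)` perpendicular to the tilt axis; maps are first corrected by
the exact geometric stretch and can then be refined by maximizing normalized
cross-correlation over all eight projective degrees of freedom, using
total-intensity virtual images as the correlation channel (azimuth maps are
unsuitable: their values are angles). Azimuths are warped with
nearest-neighbour sampling only - interpolating between angular values would
fabricate orientations - and warped validity masks are eroded by one pixel
to suppress edge artifacts. The zero-tilt map is the reference frame.

**Axis solving** (`averaged_projections()`, `reconstruct_field()`). With two
measurements the axis is the normalized cross product. With more, the
package iterates averaged projections: project the current estimate onto
each measurement's orthogonal plane, `P_i(a) = a - (a . q_i) q_i`, average,
and renormalize to the unit sphere. The signed projection form is used
deliberately: because azimuths are defined modulo 180 degrees, the sign of
each `q_i` is arbitrary, and only the signed form is invariant to it (a
variant with `|a . q_i|` is available via `verbatim_projection = TRUE` for
comparison). On non-degenerate input the iteration is a power iteration on
`I - S`, with `S` the q scatter matrix, and converges to the eigenvector of
the smallest eigenvalue of `S`; the test suite asserts this equivalence
against a dense eigensolver. Defaults: step-norm tolerance `1e-10`, at most
1000 iterations, deterministic initialization from the cross product of the
two most orthogonal measurements (no randomness, so reconstructions are
reproducible).

**Degeneracy.** With a single vertical tilt axis, any axis with zero
y-component yields the same azimuth (90 degrees) at every tilt and cannot be
resolved in 3D. Such pixels are detected from the scatter matrix: a relative
gap below 0.05 between the two smallest eigenvalues, or both eigenvalues at
numerical zero (below `1e-14` - the relative gap is meaningless for an
exactly degenerate noiseless pixel, where both are floating-point dust).
Degenerate pixels are reported in a mask, never interpolated over.

**Angle conventions** (`angles_from_axis()`). All axes are reported in the
positive-z hemisphere (the fibril axis is a direction without sign). The
in-plane angle is measured from +x in `[0, 180)`; the out-of-plane angle is
signed, with magnitude measured from the beam axis (0 = along the beam,
90 = in-plane) and sign copied from the y-component. In-plane summary
statistics are circular with period 180; out-of-plane summaries are
arithmetic on the signed angle, because the sign encodes helical handedness
and must not wrap. `layer_stats(erode = )` can shrink each region before
averaging: interface pixels mix neighbouring layers (finite beam size,
registration residuals), and excluding a one-pixel boundary band gives
noticeably cleaner per-layer means; the pipeline does this by default.

**Handedness and helix geometry.** For a fibril winding around a cell, the
sign of `(a . tangent)(a . cell_axis)` distinguishes right- from left-handed
winding and is invariant to the axis sign ambiguity; windings within 2
degrees of pure hoop or pure axial orientation are reported indeterminate.
The helix pitch follows from `pitch = circumference / tan(helix_angle)`.
Note one unresolved worked example from the oat husk literature values: an
inner layer with 31 um circumference is quoted with a 25 um pitch, which is
consistent with neither `C / tan(33)` (47.7 um) nor `C * tan(33)` (20.1 um);
the package implements the stated definition and leaves the discrepancy
flagged rather than silently adopting either reading.

## What the synthetic generator emulates

`make_phantom()` builds ground-truth axis fields in two geometries that
mirror how cell walls are sectioned: concentric annular layers around a
lumen (transverse) and stacked bands (longitudinal). Annular layers can be
specified either by a constant (in-plane, out-of-plane) pair or by a helix
angle plus handedness, in which case the axis follows the local hoop tangent
and sweeps through the degenerate zero-y directions at the top and bottom of
the ring - exactly the unmappable directions real reconstructions show.
Defaults follow the published oat husk study conditions: tilts 0/+45/-45
about the vertical axis, scan steps of 40-200 nm, azimuthal noise sigma of
3 degrees (the level found to match real measurement scatter), and
signal-free lumen/resin regions.

`render_patterns()` adds the detector level: a centred direct beam, Poisson
background, and a Friedel pair of Gaussian spots at the (noisy) forward
azimuth on the (200) ring; beam-parallel axes excite the whole ring
uniformly. Only the (200) pair is rendered because it is the only
reflection the analysis chain uses; rendering additional rings would test
robustness, not correctness. Intensities are Poisson; peak amplitude is
expressed as a signal-to-noise ratio against the background fluctuation.

What the generator does *not* emulate - and therefore what passing tests do
not establish about real data: dynamical scattering, dose-dependent
crystallinity fading, detector point spread, partially overlapping fibril
populations within one probe position, and specimen drift beyond the
geometric tilt foreshortening. Conclusions about those effects need real
tilt series.

## Numerical choices and problem sizes

Azimuth bins are one degree wide; sub-bin refinement brings single-pattern
precision to a fraction of a degree at realistic SNR. Beam centring uses
bilinear (not Fourier) interpolation, which is robust for sparse counting
data. Virtual detectors count pixels by centre-in-box. Ties in peak finding
break toward the lowest bin. The vectorized field solver runs all pixels'
iterations simultaneously; 256 x 256 fields solve in well under a second.

The validation suite runs the full rendered-frame chain at 128 x 128 scan
positions x 3 tilts x 128 x 128 detector pixels (about fifty thousand
patterns), the scale at which per-layer angle recovery is verified to within
1 degree; the noise-propagation study uses 16k pixels. A noiseless
seven-layer helical phantom patterned on the transverse oat husk layer
table reconstructs to within 0.5 degrees on more than 99 percent of
non-degenerate pixels, and injecting 3-degree azimuthal noise yields a
recovered-axis angular deviation of about 3 degrees, matching the published
uncertainty analysis.

One design point deserves emphasis: solver-fidelity studies generate the
per-tilt azimuth sets directly on the common zero-tilt grid
(`simulate_azimuth_maps(foreshorten = FALSE)`), the same construction the
published noise study uses. The instrument-realistic path - foreshortened
tilted grids, nearest-neighbour warping back - is exercised separately and
end-to-end; its resampling places a small fraction of pixels one pixel
across a layer boundary, which is why per-layer statistics (robust to it)
rather than per-pixel identity are the contract for that path.

## Known limitations

* One axis per scan pixel: the method projects through the section
  thickness and cannot separate two crossing fibril populations in depth.
* Directions with zero component along the tilt axis are fundamentally
  unrecoverable from a single tilt axis and are only flagged.
* The azimuth zero, and hence all in-plane angles, is a detector-frame
  convention; comparing against other instruments requires knowing their
  convention.
* The electron dose bookkeeping treats the beam as a uniform disk of the
  stated diameter; width measures such as FWHM give proportionally larger
  dose estimates (the stated acquisition parameters - 2 pA, 5 ms, 8 nm -
  give 12.4 e-/A^2 under the disk reading).
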