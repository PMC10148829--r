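---
title: "Methods: fiducial registration of 3D fluorescence volumes to 2D FIB images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fiducial registration of 3D fluorescence volumes to 2D FIB images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryoFidReg)
```

# The registration model

A fiducial microsphere visible in both modalities has a 3D coordinate
$X = (x, y, z)^T$ in the fluorescence volume (nm) and a 2D coordinate in
the FIB image plane (nm). The model mapping volume to image is
rigid-rotation-then-parallel-projection:

$$X' = P(z)\, R_x(\theta_x) R_y(\theta_y) R_z(\theta_z)\,(X - \mu_{3D}),$$

with the elementary rotations in the Z–Y–X convention (the $z$ rotation
applied first to column vectors) and $P(z)$ the orthographic projection
that simply drops the third coordinate after rotation. FIB-side markers
are centred on their own centroid, $X'_{FIB} = X_{FIB} - \mu_{FIB}$.

Assumptions worth stating explicitly:

* **Translation is not a free parameter.** Under a parallel projection a
  rotation maps the centroid of a set onto the centroid of its image, so
  subtracting the two centroids accounts for the full translation
  exactly. Only the three angles are estimated.
* **The projection is strictly orthographic.** A FIB image is modelled
  as a parallel projection of the rotated volume; any foreshortening of
  the viewing geometry is assumed to be absorbed by the rotation itself.
  This is the simplest model consistent with the operator form above; we
  found no need for a perspective term at the length scales involved
  (tens of µm field, effectively infinite "camera" distance).
* **Both marker sets are in the same physical units (nm)** before
  solving. The model has no scale term, so unit conversion happens at
  the I/O boundary (voxel pitch for stacks, pixel size for FIB images).
  An *optional* isotropic scale can be co-estimated
  (`solverOptions(fitScale = TRUE)`) to absorb a pixel-size calibration
  error; it is off by default because the faithful model has none.

The objective is the registration residual

$$SD = \sqrt{\tfrac1n \sum_i \lVert X'_{3D,i} - X'_{FIB,i}\rVert^2},$$

the RMS 2D distance over corresponding markers, reported in nm.

# The solver

"Least squares over three Euler angles" leaves the optimizer open; this
package uses a deterministic multi-start with no randomness anywhere:

1. The squared residual is evaluated on a coarse grid over the three
   angles (default 15° steps within ±90° per angle). On the grid the
   objective is computed through precomputed second moments of the
   centred coordinates — algebraically identical to the definition, but
   $O(1)$ per angle triple instead of $O(n)$.
2. The best grid nodes that are mutually distinct (at least 1.5 grid
   steps apart; default 8 of them) seed Nelder–Mead refinement. Local
   refinement uses the *explicit per-marker sum*, not the moment form:
   the moment form cancels terms of size $\sum\lVert X'_{FIB}\rVert^2$
   and so carries an absolute floor of roughly that magnitude times
   machine epsilon, which matters precisely when the optimum is a
   near-zero residual. Nelder–Mead is restarted from its own optimum
   until the squared objective improves by less than `tol` (default
   $10^{-9}$ nm²; restarting rebuilds the simplex, which otherwise
   collapses prematurely near an exact optimum). On noiseless data the
   solve reaches the generating angles to machine precision.
3. The mirror candidate $(-\theta_x, -\theta_y, \theta_z)$ of the best
   solution is also refined. For a *planar* marker configuration
   (all beads at one z after centring) the projection is exactly
   invariant under this reflection, so the two solutions tie; the fit
   then sets `mirrorAmbiguity`, stores the alternative, and returns the
   candidate closer (smallest L2 in angle space) to a configurable
   prior (default $(0,0,0)$). A near-tie within 1% relative SD is
   treated the same way.

Degenerate inputs are refused with named errors: fewer than 3
correspondences (3 unknowns, 2 constraints per marker), and collinear 3D
configurations (the rotation about the line is unconstrained; detected
by the second singular value of the centred coordinate matrix).
Between 3 and 4 markers the solve proceeds with a warning.

# Marker localization

* **Volume side.** Scale-matched blob detection: anisotropic Gaussian
  smoothing at $\sigma = d/4$ per axis (in voxels), strict
  26-neighbour local maxima above `minContrast` (default 0.1) of the
  background-to-peak range (background = median), minimum-separation
  pruning at one bead diameter, then an iterative background-subtracted
  intensity-weighted centroid (window radius $0.75\,d$, background from
  the window's border shell, at most 10 iterations) for sub-voxel
  centres. Gaussian PSF fitting was deliberately omitted: at fiducial
  bead signal-to-noise the weighted centroid is accurate to a small
  fraction of a voxel and keeps the pipeline deterministic and
  dependency-light.
* **FIB side.** A bead embedded in ice appears as a bump; the apex of
  the bump marks the bead edge facing the advancing beam, so the centre
  is the apex displaced by $d/2$ along the milling direction (+y). The
  $d/2$ offset is applied in image-plane nm with no foreshortening
  correction by default — that is the operational rule as practised —
  but `fibCenterFromApex(..., foreshortening =)` exposes a multiplier
  for tilted viewing geometries rather than defaulting one on.

# Iterative refinement

`iterateRegistration()` alternates three steps until the SD improves by
less than `sdTol` (default 0.1 nm) or `maxRounds` (default 10):

1. solve the angles;
2. reject markers with residual beyond `outlierFactor` (default 2)
   times the RMS, never dropping below `minMarkers` (default 4), with a
   $10^{-6}$ nm absolute floor so numerically-zero residuals are never
   "outliers";
3. re-optimize each marker's z at fixed angles. The projected position
   is affine in z along $(r_{13}, r_{23})$ (third column, first two
   rows of $R$), so the 1D least-squares update is closed-form:
   $z^\* = z_0 - (e_0 \cdot a)/(a \cdot a)$ with $e_0$ the current 2D
   residual. Updates are clamped to ±`zBound` (default 500 nm, the
   axial optical resolution) around the *measured* z, and skipped with
   a warning below 5 kept markers (re-estimating one z per marker on
   top of 3 angles would overfit the $2n$ constraints).

These thresholds are engineering defaults for behaviour that is manual
and unquantified in practice, and all are exposed in
`refinementPolicy()`. Two structural choices deserve a note. The
centroid is held fixed *within* a z pass and recomputed between passes,
avoiding a coupled nonlinear system; each step can then only decrease
the objective over the kept set, which makes the non-increasing-SD
property testable. And z is identified only *relative to the set*: a
common shift of every z moves the centroid identically and leaves the
centred projection unchanged, so z corrections are meaningful as
relative adjustments anchored by the clamp window, not as absolute
heights.

# Targeting precision

The operational definition of precision is the residual on markers that
did *not* inform the fit. `heldoutDeviation()` solves on a fit
population, maps the held-out markers with the fit population's
centroids (they contributed nothing to the translation anchor), and
reports per-marker deviations and their RMS. `looCV()` is the
single-population variant.

`expectedSD()` is the analytic companion: independent Gaussian
localization noise ($\sigma_{xy}$ lateral, $\sigma_z$ axial,
$\sigma_{FIB}$ per FIB coordinate) propagated through
rotate-then-project gives

$$E[SD^2] = \sigma_{xy}^2 (2 - c) + \sigma_z^2 c + 2\sigma_{FIB}^2,
\qquad c = r_{13}^2 + r_{23}^2 .$$

At zero tilt $c = 0$ and axial noise is invisible; any tilt mixes the
(much larger) axial error into the image-plane residual, which is why z
localization precision and a bead spread bracketing the target in y are
the dominant factors in practice (`configurationQuality()` warns on
weak geometry).

**This closed form is the large-sample limit.** A fit on $n$ markers
re-estimates 3 angles and, implicitly, 2 translation components from
noisy data, so the held-out expectation is inflated by a factor of
roughly $(1 + 5/n)$ on $SD^2$ — about +9% on SD at $n = 20$, and
per-scene values scatter further because the angle-error term varies
from fit to fit. Comparisons against `expectedSD()` are therefore made
at large fit populations (the suite uses $n = 200$, where the
inflation is ~1%); at bead counts typical of a real experiment
(10–30), held-out SD should be *expected* to sit several percent above
the asymptotic formula. This is a property of held-out validation
itself, not an implementation artifact.

# The synthetic generator

`makeScene()` emulates a bead slide imaged by both modalities: beads
uniform in a 100 × 100 × 15 µm slab (a full field of view with beads
settled through the ice thickness), a ground-truth Z–Y–X rotation
(default (15, 8, 30)°, a moderate compound tilt representative of the
FIB viewing geometry plus an in-plane rotation), 1 µm beads, and
localization noise of $\sigma_{xy} = 100$, $\sigma_z = 250$,
$\sigma_{FIB} = 20$ nm. The fluorescence sigmas are one half of typical
~200 nm lateral / ~500 nm axial cryo-SIM optical resolutions — a
deliberately conservative reading (a FWHM-to-sigma conversion would
give ~2.35× smaller values). `simulateLocalizations()` is exactly the
forward model of the registration (projection of the true positions,
re-anchored to an arbitrary FIB offset) plus the Gaussian noise;
`renderSimStack()`/`renderFibImage()` render Gaussian spots (width =
bead radius ⊕ diffraction blur) on a 120 × 120 × 250 nm voxel grid and
FIB bumps whose apex sits $d/2$ before the centre in $-y$, so the
apex rule is testable end to end. A single seed fixes everything, with
a separate substream per stage so stage-level results do not depend on
upstream draw counts.

What the generator does **not** emulate: optical SIM reconstruction
artifacts, ice contamination and curtaining, bead clustering, partially
buried bumps with distorted apexes, or field-dependent distortions.
Passing tests therefore demonstrate correctness of the *registration
machinery* under the stated noise model, not robustness to every
real-world pathology; on real data the outlier-rejection step is the
main defence against the latter.

# Numerical and format choices

* Angles are radians internally, degrees in all user-facing output;
  wrapped to $(-\pi, \pi]$. SD is reported to 3 decimals (nm).
* Indices are 0-based in user-facing pixel/voxel coordinates; a voxel's
  physical coordinate is its centre, `index × pitch`; x = column,
  y = row; stack z increases with slice index; FIB +y is the milling
  direction.
* Overlay rendering is forward splatting with per-pixel maximum (a
  maximum-intensity projection along the view axis) followed by a small
  morphological closing to fill grid cracks — faithful to "project along
  z", cheap, and artifact-visible rather than artifact-hiding. How the
  merged image *should* be rasterized (MIP vs single plane) is an open
  presentation choice; MIP is the default here and the blend never
  alters FIB pixels where the projection is zero.
* Marker tables are plain CSV (`id,x_nm,y_nm[,z_nm[,channel]]`), with
  pixel-unit variants accepted when a conversion factor is supplied —
  a missing pitch or pixel size is a hard error, since units are
  load-bearing. Results serialize to JSON with a package version and a
  configuration hash. TIFF I/O uses a YAML sidecar for physical pixel
  sizes when writing (the available TIFF writer cannot embed a
  description tag); reading honours OME `PhysicalSize` metadata, with
  an explicitly configured value always winning, with a notice.

# Problem sizes used by the test suite

The suite validates on instances a single CPU handles in seconds:
6–12 beads for exact-recovery and oracle-equivalence checks (including
an exhaustive 0.5°-grid search over all three angles), 20-bead fit
populations with 200-bead evaluation populations across 50 seeds for
the noise-calibration checks, and a 12-bead rendered scene
(~230 × 230 × 25 voxels) for the end-to-end pipeline. These sizes match
or exceed realistic marker counts; only the evaluation populations are
larger than an experimenter would have, chosen to make the comparison
against the asymptotic noise model statistically sharp.

# Known limitations

* No perspective projection, anisotropic scale, shear, or
  correspondence-free (ICP-style) matching; correspondences are given
  by id.
* The z-refinement gauge ambiguity described above means absolute z
  corrections should not be over-interpreted.
* Bump-apex detection assumes an approximately symmetric bump peaked at
  the bead edge; heavily buried or touching beads violate this and are
  exactly the markers the rejection step is meant to catch.
* The expected-SD formula ignores marker-position covariance induced by
  the fit (the $(1+5/n)$ inflation discussed under *Targeting
  precision*).
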