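---
title: "Methods: random spherically constrained cryo-EM of proteins in liposomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: random spherically constrained cryo-EM of proteins in liposomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(liporsc)
```

## The method in one paragraph

A membrane protein reconstituted into a liposome sits in a spherical
bilayer. In a projection image the vesicle contributes a strong,
azimuthally symmetric membrane signal, and the particle's orientation is
no longer uniformly unknown: if the vesicle has radius $R$ and the
particle is picked at projected distance $r$ from the vesicle centre, the
membrane normal — which coincides with the particle's symmetry axis for a
transmembrane channel — is tilted by $\theta = \arcsin(r/R)$ away from the
beam, up to the two-fold ambiguity $\{\theta, 180^\circ - \theta\}$
between the near and far side of the sphere. The in-plane angle is the
bearing from vesicle centre to particle, and only the azimuth about the
membrane normal is uniformly random. `liporsc` implements this workflow:
fit and subtract a spherical-bilayer model of every vesicle, pick and
distance-screen particles, attach sphere-derived orientation priors,
assign orientations by constrained projection matching, and reconstruct
under C1/C2/C4 symmetry with gold-standard FSC resolution estimation.

## The spherical-bilayer membrane model

The bilayer's excess scattering density across its midplane is modelled
as three Gaussians: two headgroup peaks at $\pm 19$ Å from the midplane
($\sigma = 4$ Å) and an acyl-chain trough at the midplane
($\sigma = 6$ Å, negative amplitude). The form and values are package
defaults chosen to reproduce the familiar two-ring projected appearance
of vesicles; all are overridable through `bilayer_profile()`. A vesicle
of midplane radius $R$ is the spherically symmetric density
$g(\rho) = p(\rho - R)$, and its projection is the Abel-type integral

$$P(r) = 2\int_0^\infty g\!\left(\sqrt{r^2+z^2}\right)\,dz ,$$

evaluated by trapezoidal quadrature on a $0.25$ Å beam grid with the
(smooth) profile tabulated at $0.05$ Å and linearly interpolated. The
projection agrees with a brute-force voxelized line-sum oracle to well
under 1% RMS across the 75–350 Å radius range used by the fitter.

Only the *excess* density over solvent is projected; the solvent baseline
would diverge in an infinite line integral and is carried by the image's
local background term instead.

## Conventions

* **Coordinates.** Pixels are 0-based with physical position
  $x_\mathrm{Å} = \mathrm{pixel} \times \mathrm{pixel\ size}$. Matrix
  dimension 1 is $x$, dimension 2 is $y$. Boxes and maps are even-sized
  with the object centre at index $n/2+1$ (1-based), matching the
  centered-FFT layout used throughout.
* **CTF.** Underfocus positive, $\mathrm{CTF}(0) = -w$ (the
  CTFFIND/RELION sign convention), with
  $\mathrm{CTF}(f) = -(\sqrt{1-w^2}\sin\chi + w\cos\chi)$ and the
  standard defocus/spherical-aberration phase $\chi(f)$. Defaults:
  300 kV, $C_s = 2.7$ mm, $w = 0.07$, defocus $3.8\ \mu$m — the
  high-contrast regime in which vesicle membranes show strong fringes.
* **Euler angles.** ZYZ, $A = R_z(\psi)R_y(\theta)R_z(\phi)$, mapping the
  particle frame into the laboratory; the membrane normal is the particle
  $z$ axis, so $\theta$ is the RSC tilt and $\psi$ the in-plane bearing,
  and $\sin\theta = r/R$ holds by construction in the simulator.
* **Pixel size.** The default simulation pixel is 2.1 Å (a 4× binning of
  the 0.525 Å acquisition pixel), and reconstruction runs on 2×-binned
  (4.2 Å) particle boxes. These keep desk-scale runtimes while leaving
  the membrane fringes and subunit-scale features well sampled.

## What the synthetic generator emulates — and what it does not

`sample_dataset()` draws vesicle diameters from a log-normal truncated to
15–70 nm whose truncated mean is solved to equal 20 nm; places vesicles
at ~26 per 0.16 µm² of field without overlap; populates each with one or
two tetramers per 20-nm vesicle (other sizes scale the expectation by
surface area, capped at 12); orients each particle with uniform azimuth,
uniform in-membrane spin and area-uniform position on the sphere;
composes membrane + particle projections; applies the CTF; and adds
Poisson shot noise at 60 e⁻/Å². Contrast is calibrated once per dataset
so the CTF-convolved membrane of a 20-nm vesicle peaks at 10% fractional
contrast, with the particle's side-view projection peaking at half the
membrane's pre-CTF peak — plausible magnitudes for this defocus, stated
here because the paper-scale acquisition parameters (dose, pixel,
defocus) do not by themselves fix image contrast.

The particle is a tetrameric phantom (`make_channel_phantom()`): four
subunits of three Gaussian lobes each (intracellular gating-ring lobe,
shoulder lobe, transmembrane lobe) in C4 arrangement; `c2_shift = 5`
displaces two opposing subunits axially by 5 Å, breaking C4 to exact C2 —
the geometry underlying the symmetry-breaking analyses. Lobe widths
(σ = 6–7 Å) are chosen so a 5 Å displacement is resolvable at the 8.4 Å
Nyquist of the binned reconstruction; with much smoother lobes the
displacement would be invisible at desk scale, which would test nothing.

Deliberately not emulated: beam-induced motion and dose fractionation
(motion correction is upstream of this package's scope), astigmatism and
ice gradients, structural heterogeneity, multilamellar or deformed
vesicles, and protein-density variation between particles. Passing tests
therefore demonstrate the correctness and internal consistency of the
geometry, fitting, screening and reconstruction machinery — not
robustness to every pathology of real micrographs.

## Liposome fitting and subtraction

Detection is multi-radius template matching: CTF-convolved model
projections on a geometric radius ladder are cross-correlated
(normalized, with local image standardization) against a 2×-binned copy
of the micrograph; candidate centres are local maxima of the
best-over-radii score above `median + 8·MAD`, pruned so candidate circles
do not overlap. Each candidate's radius and centre are then refined on a
denser ladder with a local shift window — a small ring template can score
on an arc of a large vesicle, so radius and centre must be re-estimated
jointly — and finally re-centred at full resolution with parabolic
sub-pixel interpolation.

The fit proper refines (centre, radius) by Nelder–Mead simplex; at every
iterate the amplitude and constant background are solved in closed form
over an annulus of ±60 Å around the membrane circle. Two safeguards
matter in practice: the amplitude is constrained non-negative *during
optimization* (an unconstrained solve admits spurious anticorrelated
minima with the model half a CTF fringe off the true radius) while the
*reported* amplitude is the plain least-squares estimate, which is
unbiased around zero on blank regions; and candidates whose final
amplitude is not significantly positive (t < 5) are discarded as spurious
detections. The production path (`fit_liposomes()`) converges on a
2×-binned copy first and polishes at full resolution. The bilayer profile
shape is shared across vesicles and only scaled per vesicle.

Subtraction renders the sum of all converged fitted membrane models on
the full field, convolves once with the CTF (matching the imaging
model), and subtracts. Local background offsets belong to the image and
are retained.

## Picking, screening, extraction

Picking cross-correlates the subtracted micrograph (2×-binned; the
particle signal is concentrated at low resolution) against reference
projections at tilts 0°, 50° and 90°, each over 8 in-plane rotations,
with an auto threshold of `median + 8·MAD` and non-maximum suppression at
3/8 of the template edge. These two constants were calibrated on the
generator's own null (blank-noise fields) and operating point to hold
false positives near 0.15 per vesicle at ≥ 0.9 recall; both are exposed
as arguments.

The screen keeps picks whose distance to the nearest fitted membrane
*circle*, $\,|\,\lVert p - c\rVert - R\,|\,$, is at most 80 Å. Distance
to the projected circle — not to the vesicle centre — is the only reading
under which one cutoff is meaningful across a 15–70 nm size range, since
membrane proteins sit in the membrane. Extraction uses 27 nm boxes with
a 17 nm circular mask; each box is standardized from its out-of-mask
pixels, soft-masked (raised cosine), and de-meaned.

## Constrained orientation assignment and reconstruction

For each particle the search space is: exhaustive azimuth on a 5° grid ×
both near/far tilt branches, followed by local refinement of tilt and
in-plane angle within Gaussian prior widths of 10° (step 5°) around the
best candidate *of each branch* — refining only the single global stage-1
winner can lock in the wrong sphere side when the true azimuth falls
between grid points. Scoring is the normalized Fourier-plane correlation
between the particle spectrum and the CTF-multiplied central slice of the
reference, over frequencies below 2.5× the pixel size; this ranking is
equivalent to least-squares amplitude-fitted matching. A translational
refinement against the winning projection (cross-correlation peak with
parabolic sub-pixel interpolation, window ±box/16) recentres the particle
spectrum, and the angular search is repeated once. Near side-views the
two branches are genuinely near-degenerate (at θ = 90° exactly so), so a
minority of branch flips at realistic noise is inherent to the geometry
rather than an implementation defect.

Reconstruction is direct Fourier inversion: each particle's
(shift-corrected) spectrum, multiplied by its CTF, is inserted as a
central slice with trilinear spreading; the accumulated numerator is
divided by the accumulated CTF² weight plus a Wiener constant (5% of the
mean nonzero weight); Hermitian symmetry is enforced before inversion;
Cn symmetry is imposed afterwards by real-space averaging over the n
rotations about z. Particles are weighted by their assignment scores, and
the pipeline drops the lowest-scoring quartile before reconstruction —
the counterpart, reduced to a score screen, of the classification and
selection steps of the reference workflow, which also discarded a large
fraction of picks. Gold-standard halves are assigned by even/odd index
after a seeded shuffle; FSC uses 1-voxel shells and reports the
resolution by linear interpolation at the 0.143 crossing. Maps are
low-pass filtered to their FSC resolution for display and comparison
(beyond it they are noise by definition).

## Symmetry scoring and map comparison

`symmetry_correlation(map, n)` is the masked Pearson correlation between
a map and its rotation by 360°/n about z (trilinear resampling), within a
soft spherical mask covering the particle. On the default phantom the
5 Å displacement leaves C2 correlation ≈ 1 while depressing C4 by > 0.1.
Map-vs-phantom agreement is measured within a soft molecular-envelope
mask derived from the smoothed, thresholded reference — the standard
choice, since a ball mask dilutes the statistic with empty solvent.

## Problem sizes and determinism

The default pipeline simulates 24 micrographs of 768×768 px at 2.1 Å
(≈ 0.026 µm², ~4 vesicles each), yielding roughly 150–250 particles, and
completes in about 10 minutes on one CPU; the parameter-recovery suite
fits 100 single-vesicle fields spanning the full size range. These sizes
are the package's chosen desk-scale operating point: large enough for
the statistical targets (recovery bias/scatter, recall, end-to-end
correlation ≥ 0.9), small enough to rerun routinely. All randomness
descends from one root seed via derived per-stage seeds; identical
configurations reproduce results bit for bit.

## Known limitations

* Orientation assignment is template-based against a supplied reference
  (by default the same phantom that generated the data); there is no
  ab-initio reconstruction or marginalized refinement, so real-data use
  would inherit reference bias exactly as template matching always does.
* The desk-scale datasets cannot approach the sub-4 Å resolutions of the
  full-scale experiment; the binned Nyquist (8.4 Å) bounds everything.
* The liposome model is strictly spherical and unilamellar with a shared
  profile shape; deformed or multilamellar vesicles will fit poorly and
  should be rejected by the amplitude-significance screen.
* The membrane-distance screen and orientation priors assume the fitted
  vesicle geometry is correct; vesicles missed by detection silently
  remove their particles from the analysis.
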