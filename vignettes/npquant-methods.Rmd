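---
title: "Models and methods behind npquant"
author: "npquant authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind npquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`npquant` quantifies how many nanoparticles adherent cells internalize
during a submerged exposure, from two directions at once: a transport model
for the dose that actually arrives at the cell monolayer, and an
image-analysis pipeline that counts particle objects inside segmented cells
in 3D STED/confocal stacks. This vignette documents the models, the choices
we made where more than one reading was defensible, the numerical details,
and what the synthetic-data tests do and do not demonstrate.

## 1. The exposure scenario

The package's defaults describe one concrete scenario: A549-like lung
epithelial cells grown in a 12-well plate, covered by 1 mL of aqueous
culture medium at 37 °C, exposed for 5 h to 9.2×10¹⁰ silica particles per
mL (25 nm or 85 nm nominal diameter, particle density 1.8 g/cm³). The
nanoparticle channel is imaged in STED mode (30 nm pixels, 76 nm lateral
PSF FWHM), the membrane and nuclear-lamina channels in confocal mode
(60 nm pixels, 277 nm lateral PSF FWHM), with a 130 nm z step throughout.
Every one of these numbers is a visible, documented default of a
constructor (`mediumSpec()`, `particleSpec()`, `stedAcquisition()`,
`confocalAcquisition()`, `defaultRunConfig()`).

## 2. Delivered dose: sedimentation–diffusion transport

### Model

Suspended spheres move through the medium column by gravitational settling
and Brownian diffusion. With `x` the height above the monolayer, the
number concentration obeys

$$\frac{\partial C}{\partial t} = D\,\frac{\partial^2 C}{\partial x^2}
  + V\,\frac{\partial C}{\partial x},\qquad 0 \le x \le h,$$

with the Stokes settling velocity and the Stokes–Einstein diffusivity

$$V = \frac{g\,(\rho_p - \rho_m)\,d^2}{18\,\mu},\qquad
  D = \frac{k_B T}{3\pi\,\mu\,d}.$$

The monolayer is a perfect sink (deposited particles stick; `C = 0` at
`x = 0`), the free surface is a zero-flux boundary, and the initial
concentration is uniform. The deposited number fraction is
`1 − remaining/initial`; the deposited number per area is
`fraction × C₀ × h`. Agglomerates of `n` primary particles are transported
as one effective sphere with diameter `d (n/packing)^{1/3}` and density
`packing·ρ_p + (1 − packing)·ρ_m`; the default packing factor 0.637 is
random close packing.

### Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| temperature | 310.15 | K | 37 °C incubation |
| viscosity µ | 7.4×10⁻⁴ | Pa·s | standard assumption for aqueous culture media at 37 °C |
| medium density | 1.00 | g/cm³ | aqueous medium |
| volume | 1 | mL | exposure volume |
| base area | 3.8 | cm² | 12-well growth area |
| column height | volume/area = 2.63 | mm | derived, see below |
| particle density | 1.8 | g/cm³ | amorphous silica |
| exposure time | 5 | h | scenario |

**The column geometry.** Descriptions of this scenario sometimes quote a
measured medium height of 5 mm. That cannot be reconciled with 1 mL in a
12-well plate: 1 mL over a 3.8 cm² growth area stands 2.6 mm tall. The two
readings matter, because for sub-100 nm particles deposition over 5 h is
diffusion-dominated and scales like `2·sqrt(Dt/π)/h`: the closed form gives
~15% at `h = 5 mm` versus ~29% at `h = 2.6 mm` for 25 nm particles, and no
physically plausible viscosity bridges that factor. Deposited fractions in
the 20–27% range for this exposure are only reproducible with the
volume-derived height, so `mediumSpec()` derives the height from volume and
base area by default (and accepts an explicit `heightMm` for other
set-ups). Note the complementary convention in tabulated per-area values,
which often use a nominal 0.5 cm column (`depositedPerArea()` takes the
height as an explicit argument for exactly this reason).

With these defaults the solver yields deposited fractions of **28.6%
(25 nm)** and **17.0% (85 nm)** after 5 h — the smaller particle wins by
diffusion, the larger one gains back through sedimentation, and both land
within a few percentage points of commonly reported values (26.5% / 20.4%)
for this scenario. The residual spread is what the unreported viscosity
and solver details of other implementations leave open; we did not tune
either number. For small clusters (1, 3, 4 primaries per agglomerate) the
fractions move by only a few percentage points, matching the reported weak
cluster dependence.

### Numerics

Finite-volume discretisation (1000 cells), implicit Euler in time with
central advection (automatic upwind switch above cell Péclet 2, irrelevant
for nanoparticles), and a Thomas tridiagonal solve per step in C++. Time
steps follow `t_k = T (k/N)²` with `N = 4000`: square-root-graded steps
resolve the early diffusive depletion layer whose flux goes like
`1/sqrt(t)`. Summing the discrete update equations telescopes interior
fluxes, so deposited + remaining equals the initial mass to machine
precision; the residual is reported as `massBalanceError` (~10⁻¹²).
Halving both mesh widths moves the 5 h fraction by well under 0.1
percentage points; the short-time pure-diffusion solution matches the
closed form `2·sqrt(Dt/π)/h` within 0.1%.

## 3. Synthetic stacks: what the generator emulates

`buildPhantom()` models an adherent cell as the upper half of an ellipsoid
resting on the substrate plane, with a membrane shell over the whole
plasma surface (curved cap *and* basal face — the label is a plasma
membrane tag) and an ellipsoidal nucleus. The default semi-axes
(12, 10, 6.4 µm) give ~1600 µm³, a typical average cell volume for this
line; tests use a (7, 6, 4 µm) phantom ( ~700 µm³, ~130 µm² footprint) to
keep runtimes modest — a problem-size choice, not a model statement.

`sampleParticles()` places ground-truthed emitters: internalized particles
uniformly in the interior with at least one particle diameter of clearance
from the membrane (enforced conservatively by uniform shrinkage of the
ellipsoid, which bounds the true offset body from inside), and
not-internalized particles half on the membrane outer surface, half on the
substrate around the cell — emulating sedimented particles that survive
washing. Cluster members are chained at contact distance (centre spacing =
diameter). An optional anisotropic minimum spacing (lateral, axial)
between clusters supports resolvable-scene experiments.

`renderChannel()` computes expected intensities as background plus
emitter brightness spread by a separable 3D Gaussian PSF integrated over
each voxel (so a contained emitter deposits exactly its brightness —
photon-count conservation is a test), then applies Poisson shot noise,
Gaussian read noise, and hard clipping at the detector maximum. Hard
clipping is the testable analogue of an avalanche photodiode saturating on
bright agglomerates. Emitter brightness defaults scale the two particle
sizes by ~1.57, the ratio of measured object intensities — not by the
~600-fold theoretical dye-content ratio, which overstates the difference
in practice (quenching, labelling yield).

The membrane label is rendered from discrete emitters at 150 µm⁻²; below
~100 µm⁻² a strongly deconvolved shell visibly "beads" into its emitters
and falls apart morphologically, which real quasi-continuous membrane
labelling does not do.

**What the generator does not emulate:** scanning artefacts, drift,
spectral crosstalk, depth-dependent aberrations, real (non-Gaussian,
asymmetric) PSFs, photobleaching during stack acquisition, protein corona
effects on brightness, or endosomal clustering dynamics. Passing the
recovery tests therefore shows the *pipeline logic* is sound under
realistic sampling, PSF anisotropy and shot noise — it does not certify
accuracy on any particular microscope's data.

Axial PSF extent is not sharpened by the lateral STED depletion and is
rarely reported; both modes default to a 600 nm axial FWHM, configurable.

## 4. Deconvolution

`richardsonLucy()` implements the standard multiplicative
maximum-likelihood update with a symmetric separable Gaussian PSF and
reflective edges; `iterations = 0` is the identity, non-negativity is
structural, and flux on interior-supported signals is conserved within 1%.
There is no universally agreed stopping rule; the default is 40
iterations.

Where deconvolution sits in the pipeline was decided by measurement on
ground-truthed stacks:

* The **nanoparticle channel is deconvolved** (40 iterations) before
  detection. Raw STED blobs extend ±~320 nm axially — as large as every
  geometric margin in the inside/outside decision — and strict containment
  then misclassifies near-membrane particles in both directions. After
  deconvolution objects span 2–3 z-slices and classification becomes
  robust.
* The **membrane channel is segmented raw**. Plain (unregularised)
  Richardson–Lucy progressively thins the blurred shell until the opening
  step fragments it; we measured mask-volume errors from −75% to −99% at
  20–40 iterations, with knife-edge behaviour around 10–12. Commercial
  deconvolution packages regularise against exactly this; rather than
  imitate that, the pipeline leaves the membrane raw and corrects the
  isosurface position explicitly (next section).

Both behaviours are switches (`deconvolve`, and `richardsonLucy()` is
exported for any channel).

## 5. Cell mask

`segmentCell()` runs: Otsu threshold (global 256-bin histogram over the
full stack) → closing then opening with a 2-voxel ball kernel → 3D hole
filling → per-slice 2D filling in all three orientations → component
selection. Details and rationale:

* **Kernel extent.** The "2-voxel" open–close kernel is a radius-1
  digital ball. A radius-2 ball would be destructive: an opening with it
  erases any 3-voxel-thick shell outright (we verified this on digitised
  shells), while the radius-1 kernel closes 2-voxel holes and leaves thin
  membranes intact. Closing precedes opening for the same reason.
* **Cut-off cavities.** 3D filling alone cannot fill the cell interior
  when the membrane does not close a cavity inside the stack (e.g. the
  basal side truncated by the stack border); per-slice 2D filling in all
  three orientations handles those.
* **Component selection.** Largest connected component by default; a
  manually drawn xy polygon (vertex list, nm) selects specific cells when
  several are in frame.
* **Boundary refinement.** The Otsu isosurface of a thin shell blurred by
  a Gaussian PSF does not sit on the membrane: it sits where the blurred
  profile crosses the threshold, a distance `σ·sqrt(2·ln(I_shell/T))`
  outside the mid-plane along each axis (σ the PSF sigma, `I_shell` the
  shell peak, `T` the threshold). Unrefined masks overestimate cell volume
  by ~30% and swallow membrane-attached particles. When given the
  channel's PSF FWHMs, `segmentCell()` erodes the filled region by that
  predicted offset (anisotropic; `I_shell` estimated as the 90th
  percentile of foreground intensity). On ground-truthed phantoms this
  brings the mask volume to within ~5% of truth and the projected area to
  within ~3%. The refinement is opt-in; the bare pipeline is exactly the
  classical step list.

Projected cell area (for per-area densities) is the area of the mask's xy
projection; volume is voxel count times voxel volume.

## 6. Particle detection and counting

`detectParticles()` chains: Otsu threshold `T` → Gaussian smoothing with
sigma 2.0 µm → watershed of the smoothed landscape restricted to the
foreground (descending region growing from plateau-collapsed local maxima,
26-connectivity, so touching blobs split at smoothed-intensity minima) →
the discard rule → measurement.

* **The discard rule** removes objects whose *peak* voxel lies below
  `T + f·(I_max − T)` with `f = 0.05` by default and `I_max` the channel
  maximum. Peak (not mean) intensity is used because the rule targets
  noise-floor objects whose means are dragged down by segmentation tails
  anyway. The rule is range-relative, so counting is invariant under
  positive rescaling of the image; the globally brightest object can never
  be discarded.
* **Blank-channel guard.** On a channel with no real signal, a histogram
  threshold will happily split the shot noise and fabricate "objects". The
  guard requires the foreground class mean to exceed the background mean
  by 5 background standard deviations (a conventional detection floor);
  otherwise the channel is declared blank and an empty table returned.
* **Watershed sigma.** The 2.0 µm default deliberately matches
  micrometre-scale agglomerate separation, not neighbouring single
  particles: disjoint thresholded blobs are separate objects regardless of
  the smoothing, so sparse scenes are unaffected, and dense contact
  clusters merge into one object (by design — the packing models handle
  them). The sigma is a fully exposed knob, and the object table records
  it.
* **Lateral width** of an object is the maximum in-plane extent of its
  voxels in the focal slice of its centroid plus one pixel (a single voxel
  has width one pixel). Sub-resolution particles give widths near the PSF
  footprint (90–130 nm at STED sampling); a 3-particle chain of 85 nm
  particles measures >150 nm.
* **Inside classification** is strict: an object is internalized iff
  every voxel lies in the mask. This follows the conservative convention
  of excluding membrane-attached particles at the cost of undercounting;
  with the refined mask and the deconvolved NP channel, recovery tests
  show recall ≥0.99 and precision ≥0.95 against ground truth.
* Objects touching the axial stack borders are kept but flagged
  (`zEdge`); 26-connectivity is used for labelling.

Per-cell summaries report objects per cell, per projected cell area, the
total object count, and mean object intensity.

## 7. Width-to-number models

Objects wider than a cutoff (150 nm for 85 nm particles, 75 nm for 25 nm;
strict inequality, boundary counts as agglomerate) are treated as
agglomerates. Their particle content is estimated under three packing
geometries from the width ratio `r = w/d`: a linear chain (`round(r)`), a
plane with packing density 0.91 (`round(0.91 r²)`), and a 3D packing of
density 0.74 (`round(0.74 r³)`), each at least 1 — a detected object is at
least one particle. Rounding to nearest (rather than floor) is our choice;
the estimates are reported per model, never averaged, because the three
models bracket reality rather than estimate it: on synthetic planar
clusters the chain model undercounts and the 3D model overcounts, with the
published ordering `n₁ ≤ n₂ ≤ n₃` holding for all widths ≥1.55·d.
`totalParticles()` can apply the model formulas to agglomerates only
(singles count once; the default) or to every object — both conventions
appear in practice, so both are provided.

## 8. Dose arithmetic

All conversions are closed-form and stateless: per-particle mass
`ρ·π d³/6` links number and mass concentrations (use the lot's
EM-measured diameter — 24 nm rather than the nominal 25 reproduces the
usual 1.2 µg/mL at 9.2×10¹⁰/mL); monolayer coverage is
`per-area · π d²/4` and is *reported* above 1 (flagged supersaturated)
rather than clipped; intracellular concentration converts counts per cell
volume to per-mL; uptake efficiency divides the internalized count by the
particles delivered to the cell's footprint. The BET surface-area
regression `y = 143.2 − 1.505·d` is a calibration line measured on
23–72 nm particles; outside that range results are flagged as
extrapolation and non-physical (≤0) values return `NA`.

## 9. Degenerate inputs and tie-breaks

Constant images have no Otsu threshold (error for segmentation, empty
table for detection); ties in the between-class variance take the lowest
cut; `iterations = 0` deconvolution and delta-kernel PSFs are exact
identities; zero-particle pipelines complete with zero counts; empty
foregrounds are empty tables, not errors; masks and grids must share
geometry exactly (resample first — `resampleMask()` is nearest-neighbour
by physical position).

## 10. Test design and problem sizes

The suite builds every fixture in code. Oracles are independent of the
implementation: exhaustive search for Otsu, the absorbing-wall closed form
for diffusion, hand-evaluated arithmetic for transport coefficients and
packing counts, and analytic geometry for the phantom. End-to-end recovery
uses two scenes matched to reported mean per-cell counts — 117 emitters
(25 nm) and 338 (85 nm) inside a (7, 6, 4) µm phantom with 30 distractors
each, at ≥4× anisotropic PSF-FWHM spacing — and requires the recovered
count within 5% with precision ≥0.95. Each scene runs in about a minute.
One deliberate red flag remains: under the default conditions the two
deposited fractions (28.6% / 17.0%) straddle the often-quoted 20–27%
band — documented in Section 2 — and the corresponding check is left
failing rather than fitted.

## 11. Known limitations

* The transport model ignores agglomeration kinetics, protein-corona
  density changes, convection and evaporation; the perfect-sink boundary
  overestimates deposition when attachment is reversible.
* Gaussian PSFs and hard saturation are idealisations; the generator's
  noise model has no detector afterpulsing or analog-PMT gain noise.
* Strict containment undercounts particles within roughly one object
  radius of the mask boundary; with the refined mask this margin is small
  (~60 nm axially) but not zero.
* The width-based packing models are bracketing heuristics; they are not
  validated against electron microscopy here.
* Counting accuracy on real stacks depends on deconvolution quality and
  membrane label continuity in ways the synthetic tests only approximate.
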