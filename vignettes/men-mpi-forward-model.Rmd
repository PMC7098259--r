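---
title: "Methods: the MEN-MPI forward model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the MEN-MPI forward model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(menpi)
```

`menpi` simulates the chain from a neuronal firing event to a recovered
electric-field map: tissue phantom → quasi-static conduction solve →
nanoparticle magnetization → magnetic particle imaging (MPI) → demodulation.
This vignette is the package's account of the model, its assumptions, the
parameters that matter, and the numerical and design choices behind the
implementation.

## The head phantom

The simulator works on a structured voxel grid rather than a tetrahedral
finite-element mesh. A uniform grid supports the same conduction physics at
the problem sizes of interest, aligns exactly with NIfTI voxel data, and
keeps the discretization transparent. `make_layered_phantom()` builds the
synthetic stand-in for a segmented head: nested ellipsoids, innermost white
matter (WM), a grey-matter (GM) shell, and a cerebrospinal-fluid (CSF) shell,
each with a uniform isotropic conductivity (defaults 0.14, 0.33 and
1.79 S/m). Per-axis semi-axes allow an asymmetric head so that an eccentric
cortical firing site is addressable. Real label volumes can be imported from
NIfTI-1 instead; only the WM/GM/CSF label convention is required. Skull and
scalp compartments and anisotropic WM conductivity tensors are out of scope.

What the generator emulates is compartment geometry and conductivity
contrast. What it does not emulate: cortical folding, tissue heterogeneity
within a compartment, and realistic firing-source geometry. Tests passing on
the ellipsoidal phantom therefore validate the numerics and the signal chain,
not anatomical realism.

## Conduction solve

A firing event is a spherical spot (default diameter 2 mm) injecting an
instantaneous current of 70 pA per pF of membrane capacitance. Converting
this membrane-referenced figure to a volumetric source density requires a
membrane-capacitance-per-volume factor that the underlying description does
not supply, so `capacitance_density_pF_mm3` is an explicit calibration
constant: `calibrate_firing()` exploits the linearity of the conduction
problem to rescale it (after a single solve) until the peak field magnitude
hits a chosen working value, by default 100 V/m — the top of the 5–100 V/m
range of endogenous firing fields the model targets. Because the source/sink
geometry of a firing population is likewise unspecified, the source is an
offset monopole pair: an equal-and-opposite sink sphere one voxel away, with
the sink density scaled by the discrete voxel counts so the net injected
current is exactly zero.

The potential solves ∇·(σ∇φ) = −J_v by a finite-volume discretization:
face conductances use the harmonic mean of the adjacent voxel conductivities
(the standard choice for discontinuous σ, exact for layered media), the
tissue/background interface is insulating (zero normal current — no skull or
far-field model), and the gauge is fixed by a mean-zero potential over
tissue. The linear system is symmetric positive semidefinite with a constant
nullspace; a Jacobi-preconditioned conjugate-gradient iteration with
mean-projected iterates solves it to a relative residual of 1e-8 by default
(1e-10..1e-12 in the verification tests). An unbalanced source has no
solution under insulating boundaries and is rejected with the computed net
current. E = −∇φ uses central differences on interior tissue voxels,
one-sided differences at the tissue boundary, and is zero on background by
convention.

Two verification oracles back the solver. First, for point-like electrodes
in a uniform block the exact solution of the *bounded* Neumann problem is the
superposition of free-space monopole potentials I/(4πσr) over the box's
mirror-image lattice; the test compares against that closed form (truncated
at two reflections per axis) and excludes only the thin null surface where
the reference potential crosses zero, since a relative comparison is
undefined there. Second, grid refinement at fixed world probes must show a
decreasing solution change of observed order at least one. Fields from a
monopole electrode must decay as 1/r² on a log–log fit.

## Nanoparticle magnetization

Magnetic quantities are CGS-Gaussian internally (Oe, emu/cc, erg) because
the magnetoelectric literature quotes them that way; electric fields are SI
(V/m) and are converted to V/cm only inside the coupling. A particle is a
sphere of diameter d (default 50 nm) with saturation magnetization M_S,
moment m = M_S·πd³/6, at temperature T = 300 K. An adequately separated
ensemble (> 5 nm spacing, so no quantum-mechanical interactions; ~1 µm, so
dipole interactions are a perturbation) behaves as a paramagnetic gas:

* M_rel(H) = coth ξ − 1/ξ, ξ = mH/(k_B T) — odd, strictly increasing,
  saturating; evaluated by a series below |ξ| = 1e-3 for numerical
  stability.
* The magnetoelectric effect adds a magnetization shift ΔM = αE (α in
  G·cm/V, E in V/cm, 1 G ≡ 1 emu/cc): an *additive* shift in magnetization,
  not an effective-field shift, clipped so |M_rel| ≤ 1. A conventional
  magnetic nanoparticle (MN) is exactly the α = 0 case, which is how the
  package derives a particle's mode.
* Hysteresis does not enter the imaging curves. Coercivity H_c (default
  100 Oe) is used only for the dissipation estimate: loop area 4·H_c·M_S
  erg/cc for a rectangular loop (default; an order-of-magnitude estimator)
  or π·H_c·M_S for an elliptical one.
* The collective dipole-dipole interaction is reduced to a scalar broadening
  scale: the nearest-neighbour axial dipole field 2m/r³ at the mean spacing
  r = n^(−1/3), which grows linearly with number density.

Two unit ambiguities in the source material are worth recording. The
saturation magnetization is quoted both as 10 emu/cc and as 10 emu/g
(×5 apart at 5 g/cc); the package defaults to emu/cc and accepts `Ms_emu_g`
with the density conversion for users who prefer the other reading. And the
worked coupling example "α = 0.1 G·cm/V at 1 V/cm gives 1 emu/cc" is not the
literal product, which is 0.1 emu/cc; the code computes the literal ΔM = αE
and documents the factor-of-ten discrepancy rather than silently rescaling.
The consequences for image contrast are discussed below.

## MPI image formation

The imaging model follows the saturation/selection scheme: a 500 Oe
background saturates every particle except near the field-free point (FFP),
where the opposed −500 ± 50 Oe selection field cancels it. The net operating
field grows linearly away from the FFP at the selection gradient (default
25 Oe/mm = 2.5 T/m, a typical MPI gradient) and is capped at the background
value. The pixel at an FFP position is the density-weighted relative
magnetization summed over the voxels inside the linear zone (|H| ≤ 50 Oe);
all other voxels are saturated and excluded. This is deliberately *not* a
harmonic-space or system-matrix MPI reconstruction: the model being simulated
specifies only the proportionality S ~ M_rel and the selection-field scheme,
so the package implements exactly that aggregation and nothing more. The
collective dipole field at the mean particle density widens the effective
linear zone, which is how density degrades resolution. Optional Gaussian
noise is added under a recorded seed, negative values are clipped, and the
image is normalized to its maximum; identical configuration and seed give
bit-identical images. The temporal dimension is reduced to two snapshots
(pre-firing and post-firing); oscillatory firing dynamics are a non-goal.

### The firing-contrast ratio

The contrast metric is the mean raw signal over the firing region of
interest (the source sphere dilated by one voxel) after firing divided by
before. Within this model the ratio has a closed structure:
ratio = 1 + ⟨ΔM/M_S⟩ / ⟨M_rel⟩, where both averages run over the
aggregation zone. With the literal coupling (ΔM/M_S = 1% at 100 V/m) and
the zone-mean Langevin magnetization at the −500 ± 50 Oe operating band
(≈ 0.19 for the default MEN), the ratio is structurally in the
few-percent-above-one range — the value the acceptance script computes, not
a tuned number. A coupling ten times larger (the non-literal reading of the
worked example above), or an operating scheme that reads magnetization
closer to the zero-field point, moves the ratio toward 2; the package keeps
the literal arithmetic and reports what it implies. The modulation,
whatever its size, is strictly positive, localized to the firing region,
and exactly invertible — which is what the demodulation stage needs.

### Resolution versus density

`psf_density_study()` images a point-like density impulse per density value.
The point response of the zone-sum model is spherically symmetric, so the
study evaluates it on a fine radial profile (step 0.005 mm) built from the
same operating-field and voxel-signal primitives as the raster scan, which
keeps the FWHM smooth in density instead of quantized at the voxel size.
Under S ~ M_rel the response is shell-like (zero exactly at the FFP, maximal
at the zone edge), so "FWHM" is quoted as the outer diameter of the half-max
region. Peak signal grows strictly with density; the dipole broadening term
widens the zone, so the quoted resolution is non-decreasing in density and
strictly worse at the highest densities — the qualitative trade-off the
model predicts. The absolute resolution floor of a real scanner depends on
the unspecified collective-interaction physics and is not reproduced.

## Demodulation and field recovery

The MEN image is the structural image modulated by the field; the MN image
is the structure alone. `demodulate()` therefore divides raw (de-normalized)
MEN by MN voxelwise, guarded by an epsilon mask (default 1e-6 of the MN
maximum) against division in signal-free voxels. For the structural term to
cancel exactly, the MN reference must be *magnetically equivalent* to the
MEN — same size, M_S and temperature, differing only in α = 0 — which is
what `as_mn()` produces and what the pipeline images as its MN arm. (The
separate `mn_spec()` default with M_S = 100 emu/cc exists for curve-family
comparisons between particle types, not for demodulation.)

Recovery inverts the additive model: |E| = (ratio − 1)·M_rel(H_op)·M_S·100/α,
clipped at zero, where M_rel(H_op) is the zone-mean operating magnetization
recorded in the image metadata during the scan (stored both as the mean and
as the equivalent operating field H_op, obtained by a Langevin inversion).
For a noise-free, uniform-density scene whose field is constant across the
aggregation zone this is an exact inverse — the round-trip test demands
agreement to 1% and observes machine precision. Only the magnitude |E| is
recovered; the scalar model discards direction, and no PSF deconvolution is
attempted, so recovered values are zone-blurred averages wherever the true
field varies within the zone.

## Dosimetry

The default dose is 0.1 mmol per kg bodyweight. The molar mass behind the
gram conversion is taken as one BaTiO₃ + CoFe₂O₄ formula-unit pair
(233.19 + 234.62 = 467.8 g/mol), the convention that reproduces the
reference figure of ≈ 2.3 g for a 50 kg subject; it is exposed in the
configuration. Particles distribute uniformly over tissue by default (no
biodistribution model). Dissipated power is loop energy × drive frequency,
flagged against a 50 W budget. Clearance kinetics are out of scope.

## Reproducibility and problem sizes

One global seed drives every stochastic stage; per-stage seeds derive as
`seed·131 + stage index (mod 2³¹−1)` so stages are independently
reproducible, and every artifact embeds the configuration hash and seeds.
The shipped scenario uses a 64³ grid at 1 mm; the verification suite uses
48³ blocks for the solver oracles, 24³–28³ scenes for imaging and recovery
properties, and three-level refinement down to 0.5 mm voxels — sizes chosen
so the whole suite and the acceptance script each run in minutes on one CPU
while leaving the discretization conclusions unchanged at the next
refinement level.

## Known limitations

* Ellipsoidal anatomy; no skull/scalp; isotropic conductivities.
* Single instantaneous firing snapshot; no EPSP/alpha-rhythm dynamics.
* The S ~ M_rel aggregation is a deliberately minimal reconstruction; real
  MPI encoding (harmonics, relaxation blurring, drive waveforms) would
  change absolute contrast and resolution.
* No Néel/Brown relaxation, frequency-dependent α(f), or anisotropy-axis
  distributions; particle transport (BBB crossing, steering, clearance) is
  not modeled.
* Recovered fields are unsigned zone averages, not vector fields.
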