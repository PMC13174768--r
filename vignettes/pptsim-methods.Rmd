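---
title: "Simulating pair production tomography: models, parameters, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating pair production tomography: models, parameters, limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pptsim)
```

`pptsim` simulates the physics of pair production tomography (PPT): a
2.617 MeV gamma ray from the ²⁰⁸Tl daughter of a ²¹²Pb generator converts
in tissue into an electron–positron pair, the positron annihilates, and the
coincident 511 keV photons are detected on a PET ring. This vignette is the
package's own account of the models it uses, the parameters that matter,
and what its results do and do not show.

## Photon interaction data

Six materials are embedded (water, adipose, inflated lung at
0.26 g/cm³, brain, cortical bone, air), each with per-channel linear
attenuation coefficients on a fixed 14-point grid spanning 0.05–3 MeV,
interpolated log-log between grid points (the standard choice for smoothly
varying cross sections; the grid includes 0.511 and 2.617 MeV so the two
energies the simulator lives at are reproduced exactly from the stored
values).

* **Compton** is computed from the Klein–Nishina cross section per electron
  times the material electron density (ρ N_A ⟨Z/A⟩) from standard
  ICRP/ICRU compositions. Binding corrections, which matter below
  ~100 keV, are neglected; the simulator's photons live at 0.4–2.6 MeV.
* **Pair production** is an XCOM-style compilation for water (nuclear field
  plus triplet production folded together, since nothing downstream
  distinguishes them), scaled to other materials by ρ ⟨Z²/A⟩. The pure Z²
  scaling neglects Coulomb/screening corrections, a few-percent effect for
  low-Z tissues.
* **Photoelectric** is a parametrized ⟨Z^4.4/A⟩/E^3.1 power law anchored
  at water, 0.1 MeV. It is negligible above a few hundred keV and is
  included for completeness of the channel split.
* Coherent (Rayleigh) scattering is excluded throughout: it deflects
  without energy transfer and is small at these energies.

With these tables the total coefficient for water at 2.617 MeV gives a mean
free path of 23.45 cm, and the analytic one-centimetre-cube budget (see
below) lands at 97.4% / 2.5% / 0.050% for no-interaction / Compton / pair.

Positron stopping uses an ESTAR-style CSDA range table for water
(kinetic energies up to 2 MeV), scaled by the stopping-power ratio
⟨Z/A⟩ and the density for the other materials, with a dedicated
(scaled) table for cortical bone. `csda_range("water", 1.56)` — the
end-point energy of the pair spectrum — is 0.74 cm.

## Transport model

**Photons** are tracked by Woodcock delta-tracking: free paths are sampled
against the majorant total coefficient of the materials present, and
collisions at a voxel are accepted with probability μ_total(local)/μ_maj,
which reproduces exact exponential transport through the heterogeneous
grid without ray-casting through voxel boundaries. The interaction channel
is sampled proportionally to the local per-channel coefficients. Compton
scattering samples the Klein–Nishina differential cross section by the
standard composition–rejection method; scattered photons are re-tracked
until they escape or fall below a 50 keV cutoff (configurable). Compton
recoil electrons deposit locally; bremsstrahlung, annihilation in flight,
Doppler broadening and three-photon annihilation are not modelled.

**Pair production** shares the available kinetic energy
(E_γ − 1.022 MeV = 1.595 MeV at the signal line) between the positron and
electron. The default sharing density for the positron fraction x is the
symmetric extreme-relativistic Bethe–Heitler shape
x² + (1−x)² + (2/3)x(1−x) (a flat sharing is also available); both are
exactly symmetric under e⁺↔e⁻ exchange, so the kinetic-energy
distribution is centred at 0.798 MeV. Initial directions are
forward-peaked about the photon direction with characteristic angle
mₑc²/E — at these energies the annihilation position is insensitive to
this choice.

**Positrons** are transported by a condensed-history random walk: the CSDA
path is consumed in 20 equal fractions (configurable), with the geometric
step length rescaled by the local material's range table, and the
direction is deflected each step by a Gaussian multiple-scattering angle
θ₀ = Es/(βpc) · sqrt(step/X₀). We use the Rossi–Greisen electron
scattering constant Es = 21.2 MeV rather than the Highland 13.6 MeV form:
the Highland logarithmic correction is calibrated for step thicknesses
x/X₀ ≳ 10⁻³ and badly underestimates the scattering of sub-MeV electrons
split into twenty thin steps, which in water would inflate the mean
displacement well above the ~2.2 mm that full transport codes obtain.
With Es = 21.2 the simulated mean displacement of positrons from the
2.617 MeV pair spectrum in water is ≈2.0 mm with a 99.9th percentile of
≈6.3 mm. Positrons annihilate at rest at the end of the walk into two
back-to-back 511 keV photons on an isotropic axis; a Gaussian
acollinearity (0.5° FWHM) can be switched on and is off by default since
its effect (~0.1 mm at preclinical ring radii) is far below the positron
range.

The first-interaction budget tally records, per primary history, the
channel of the first interaction inside the grid; secondaries never enter
this tally, so the budget is well-defined whether or not secondary
tracking is enabled. Secondary tracking defaults to on (scattered photons
can themselves pair-produce, which feeds the broad background of the
spatial profiles) and is switched off for pure budget runs.

## Sources and phantoms

Phantoms are voxel grids centred on the origin. A "point" source occupies
one voxel volume centred on the origin and emits uniformly within it —
with the default 1 mm cube voxels this reproduces the finite source/
histogram resolution implied by the reference profile widths (a true
delta source would make the production-point profile singular as
exp(−μr)/r², with a fitted width set only by the bin width). Distributed
sources emit uniformly within each flagged voxel with voxel weights from
the source map.

Clinical-scale presets place cylindrical inserts in a 20 cm water
cylinder: six 2 cm material inserts (water, adipose, lung, brain, bone,
air — the air insert is also an emission region), or four water rods of
8/12/16/25 mm diameter. Exact insert coordinates are a convention
(centred axially, 5 cm radial offset, even angular spacing) and are
configurable; a small-animal phantom with an active background and two
cold 8 mm inserts (water, air) is also provided. Default voxel sizes are
1 mm for cubes and the small-animal phantom and 2 mm for the 20 cm
cylinders, which resolves the smallest 8 mm rod while keeping desk-scale
memory.

## Detection and reconstruction

The PET ring is idealized: crystals are perfect absorbers at their front
face on a cylinder (no depth-of-interaction, no inter-crystal scatter,
no dead time or randoms; each decay is an isolated time frame). Photons
are projected from their last interaction point to the ring, accepted
with a configurable efficiency inside the axial extent, blurred in energy
and time, and snapped to the nearest crystal centre. Two presets mirror
the two scanner classes loosely: "clinical" (410 mm radius, 3.2 mm pitch,
214 ps TOF) and "preclinical" (80 mm radius, 1.12 mm pitch, non-TOF).
The default energy window is 435–585 keV — wide enough for an 11% FWHM
photopeak, and excluding the 239 keV line of the parent — with a 4 ns
coincidence window; the acquisition windows of the reference experiments
are not published, so these are declared defaults, not inferences.
Coincidences are prompt pairs within the window; windows with more than
two in-window hits are discarded.

Reconstruction is list-mode MLEM/OSEM with a Siddon-style exact voxel
traversal of each LOR between crystal centres. The sensitivity image is
the per-voxel geometric acceptance of the ring (fraction of isotropic
emission axes whose both photons intersect the ring within the axial
extent, integrated over a deterministic spherical Fibonacci set), which
is the correct normalization for this idealized detector. TOF weighting
multiplies each LOR's voxel weights by a Gaussian centred at the position
implied by the arrival-time difference, with σ_x = c·FWHM_t/(2·2.355).
Attenuation, scatter and randoms corrections are omitted (the simulator
owns the ground truth and the chain is idealized); ordered subsets
partition events round-robin. The Gaussian post-filter is separable with
reflective boundaries, which preserves total intensity exactly.

## Profile analysis

Spatial localization is quantified on 1D histograms of event coordinates:
slice mode keeps events within a slab (default half-thickness 1 mm on the
two other axes, 0.25 mm bins), projection mode aggregates everything —
which widens the displayed profile, and is the right choice for
low-statistics materials. The model

f(x) = A·[1 + (x/σ)²]⁻¹ + B·exp(−C|x|)

is fitted by Levenberg–Marquardt with Poisson (chi-square) weights — the
appropriate weighting for count histograms, and noticeably more stable
for the width parameter than unweighted least squares at desk-scale
statistics. Starting values come from the raw histogram (σ₀ = half the
raw half-max width, A₀ = peak, B₀ = 0.1·A₀, C₀ = 1/(5σ₀)); parameters are
bounded below at zero, and any parameter can be held fixed (e.g. A = 0
for a pure exponential). The reported FWHM is 2σ of the Lorentzian
component — the exponential term is a broad background — and the numeric
FWHM of the total fitted curve is reported alongside for transparency,
since the convention used for the reference values is not stated. The
"end-point" of sampled range distributions is operationalized as the
99.9th percentile; the maximum of a histogram tail is not a stable
estimator.

## Study sizes and reproducibility

All presets default to 10⁶ primaries and every stochastic entry point
takes an explicit seed; a run with the same seed is bit-identical. The
package's own validation studies use 10⁶ primaries for the interaction
budget (binomial error ±0.016 percentage points on the no-interaction
fraction), 10⁷ for the 10 cm water-cube profile fits (≈1400 slab events
for the production profile), 10⁵ positrons for range statistics, and
2–3×10⁶ primaries per material for the central-cube efficiency ratios.
These sizes keep every study in seconds-to-a-minute on one CPU; the
reference study used 10⁸ primaries, so desk-scale profile-fit statistics
carry visibly larger seed-to-seed scatter (the annihilation-profile FWHM
fluctuates by roughly ±0.2 mm at 10⁷).

## What the synthetic studies do and do not show

The generator reproduces the *simulation* conditions of the reference
study: monoenergetic isotropic 2.617 MeV emission from point or
uniform-in-insert sources in simple geometric phantoms. It does not
emulate the full decay-chain spectrum (other lines are carried in
`emission_spectrum()` but only the signal line is transported), source
kinetics or biology, scanner microphysics (crystal scatter, dead time,
randoms at realistic activity timelines), or CT-based corrections of
measured data. Passing tests therefore demonstrate the internal
consistency of the transport/detection/reconstruction chain and its
agreement with the published simulation-level observables — not
quantitative agreement with any particular scanner's measured images.

## Numerical choices and degenerate inputs

Log-log interpolation reproduces stored table values exactly at grid
points; the pair channel is identically zero below 1.022 MeV with a
linear ramp to the first tabulated positive value. Delta-tracking uses a
per-photon majorant over the materials present at the photon's current
energy; a guard (10⁴ rounds) protects against pathological null-collision
loops. Zero-energy positrons annihilate in place; zero-length LORs yield
empty paths; empty coincidence lists are an error for reconstruction;
voxels never crossed by any LOR are excluded from EM updates, and voxels
with zero forward projection contribute nothing (1/q with q→∞). The EM
update never produces negative intensities.

## Known limitations

* The pair-production tables are a compact compilation, not a full
  cross-section engine; accuracy is a few percent for low-Z tissues and
  degrades for user-supplied high-Z materials (no Coulomb correction).
* The Gaussian small-angle multiple-scattering model has no single-
  scattering tail, so extreme-range outliers are slightly under-
  represented; the 99.9th-percentile positron displacement in water
  (≈6.3 mm) sits below the ≈7 mm that full transport codes report, within
  the tolerance used by the validation suite.
* Lung is "inflated lung" at 0.26 g/cm³; published material definitions
  for lung vary enough that lung-related efficiency ratios carry a wide
  tolerance.
* The detector has no randoms or dead time; sensitivity cascades reported
  by the presets are per-decay, not per unit activity.
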