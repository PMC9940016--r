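---
title: "Analytical planning and dosimetry for dynamically collimated proton PBS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analytical planning and dosimetry for dynamically collimated proton PBS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dcpt)
```

`dcpt` models the delivery of dynamically collimated pencil-beam-scanning
(PBS) proton fields to cubic water-phantom targets: plan generation, spot
weight optimization, delivery-file export, and the dosimetric metrics used
to characterize collimated fields against simulated measurements. This
vignette is the package's account of the science: the model and its
assumptions, the parameters that matter, the numerical choices, and the
limits of what the analytical engine can and cannot reproduce.

## The dose engine

### Depth dose

The range-energy relation is the classic power law $R = \alpha E^p$ with
defaults $\alpha = 0.0022$, $p = 1.77$ ($R$ in cm of water, $E$ in MeV).
These constants reproduce the catalog's planned energy spans to about 1 %
(e.g. a 7.75 cm distal range maps to 100.9 MeV). The pristine stopping
power of this relation is $S(r) \propto r^{1/p-1}$ at residual range $r$,
which the engine convolves with a Gaussian range kernel whose width
combines two physical effects in quadrature:

* range straggling, $\sigma_s = c\,R^{0.935}$ cm with $c = 0.012$ (the
  standard water value; it controls the distal fall-off), and
* the delivery system's beam momentum spread, projected into range as
  $\sigma_E/E \cdot pR$ with a default $\sigma_E/E$ of 0.7 %.

The energy-spread term is essential at desk scale: with straggling alone a
70-100 MeV layer has $\sigma \approx 0.5$-$0.9$ mm, and stacking layers
3 mm apart in range would leave a deeply rippled spread-out Bragg peak
(SOBP) that no weight optimization can flatten; 0.7 % is a typical value
for a cyclotron line at these energies. With it, the optimized central-axis
SOBP is flat to better than 10 % (the `sobp_metrics()` flatness of the
6 cm catalog plan is ~0.07).

No nuclear interactions are modelled: the Bragg curve has no buildup loss
and no low-dose lateral halo. The consequences are discussed at the end.

### Lateral model and collimation

Each beamlet is Gaussian in each lateral axis. Its spread at water depth
$z$ is split at the trimmer plane:

* $\sigma_{up}$ — the fluence width arriving at the trimmer: the in-air
  spot sigma (a four-point table versus energy, linearly interpolated,
  5.4 mm at 70 MeV to 3.2 mm at 160 MeV at the isocenter plane) projected
  geometrically to the trimmer plane, plus, when the polyethylene range
  shifter (4 cm, 4.1 cm water-equivalent) is in the beam, its Highland
  scattering angle times the shifter-to-trimmer drift;
* $\sigma_{down}$ — everything downstream: the effective angular spread
  (beam divergence $\sigma_{air}/\mathrm{SAD}$, plus the range-shifter
  angle when present) times the trimmer-to-point drift, in quadrature with
  in-water multiple Coulomb scattering
  $\sigma^2_{MCS}(z) = (14.1/X_0)\, f^2 \int_0^z (z-u)^2 / pv(u)^2\, du$,
  with the logarithmic Highland correction $f = 1 + 0.038\ln(z/X_0)$
  evaluated on the total path (the differential form diverges at zero
  path).

An engaged trimmer blade is a full stop: the upstream Gaussian is
truncated at the blade's medial edge and the truncated fluence is
convolved with the downstream Gaussian. The Gaussian product identity
gives the closed form
$f(x) = N(x; c, \sigma_t)\,[\Phi((e_{hi}-\mu^*)/s) - \Phi((e_{lo}-\mu^*)/s)]$
with $\sigma_t^2 = \sigma_{up}^2 + \sigma_{down}^2$,
$\mu^* = (c\,\sigma_{down}^2 + x\,\sigma_{up}^2)/\sigma_t^2$ and
$s = \sigma_{up}\sigma_{down}/\sigma_t$. Collimation is applied per axis
independently (crossed blade pairs), and can only remove fluence: the
collimated profile never exceeds the uncollimated one anywhere.

Partial transmission through the blade body is not modelled. The only
edge-scatter term is an additive halo: each engaged blade re-emits a
configurable fraction (default 3 %) of the fluence it intercepts as a
Gaussian centred on the edge, three times wider than the local edge sigma,
with an entrance-like depth dose decaying over an effective residual range
of 2 cm. The halo produces positive, depth-trending surface dose horns
without claiming their exact magnitude.

### Geometry and grids

The phantom surface sits on the isocenter plane; $z$ is water depth, grid
values live at voxel centers with half-open voxel ownership, and all
lateral quantities are magnified with depth through the per-axis virtual
source distances (defaults 2000/1900 mm — the source geometry is
configuration, not data). Dose is scored as a voxel average (four
sub-samples per axis), matching what a voxel-scoring transport engine
reports; this matters for sub-millimetre collimated edges on the 1 mm
grid. The engine returns Gy per proton times the beamlet weights, via the
stopping-power-to-dose constant $1.602\times10^{-7}$ Gy per (MeV/mm per
1/mm²).

The default grid is 1 mm isotropic, laterally ±35 mm about the axis and in
depth from the surface to 25 mm beyond the distal range — large enough for
every profile, penumbra tail and horn-search window the metrics need,
while keeping a full-plan dose computation to a couple of seconds.

## Planning rules

Candidate spots form a square 3 mm lattice containing the beam axis and
extending to the smallest index $k$ with $k \cdot \mathrm{spacing} \ge$
half-width + 2.5 mm margin. For the 30 mm catalog cubes this is the
13 × 13 = 169-spot lattice, identical in every layer, and 12 energy layers
(equally spaced in range, $n = \lfloor \mathrm{span}/3\,\mathrm{mm}
\rfloor + 1$ over the margin-expanded 3.5 cm span) give the 2028 candidate
beamlets per plan. With the range shifter the shifter WET is added to both
range endpoints.

Trimmer edges are stored at the isocenter plane and positioned so the ray
from the virtual source through the physical edge crosses the lateral
target boundary at the layer's nominal Bragg depth:
$e_{iso} = \pm 15\,\mathrm{mm} \cdot \mathrm{SAD}/(\mathrm{SAD} + d)$.
Edges beyond the ±75 mm travel retract the blade. One trimmer state per
layer, as delivered with the pause-after-layer mechanism.

## Optimization

The influence matrix is evaluated with the exact engine arithmetic on a
stride-2 sub-lattice of the dose grid (anchored on the beam axis laterally
and on the proximal target boundary in depth, so the boundary slabs are
sampled). Three voxel zones enter the least-squares objective:

* the **prescription target** — the PTV expanded by the 2.5 mm *depth*
  margin, at the 5 Gy prescription with unit weight. Prescribing the depth
  margin is deliberate: the proximal and distal layers are placed in that
  margin precisely so the SOBP is flat across the whole PTV; prescribing
  only the unexpanded PTV while penalizing the margin drives those layers
  to zero weight and underdoses the proximal PTV face.
* the **lateral margin ring** — covered by spot placement but neither
  prescribed nor penalized (zero weight). The trimmed field edge sits at
  the PTV surface, so demanding either full dose or zero dose there would
  distort the solution.
* a 5 mm **shell** beyond the margins with a zero-dose objective at weight
  0.1, to discourage edge overdose.

The solver is cyclic coordinate descent on the normal equations with exact
clipped single-coordinate updates (compiled; deterministic; objective
nonincreasing from a uniform warm start; converged when the projected
gradient falls below $10^{-10}\,\max|A^Tb|$). For the 2028-column catalog
problems it reaches a stable objective within ~2000 sweeps in seconds. An
independent active-set solver is used in the test suite as a cross-check
on small problems.

Coverage normalization rescales the optimized dose so 90 % of PTV voxels
sit at or above prescription (the threshold is the
$\lceil 0.9N \rceil$-th largest PTV dose, i.e. D90 = Rx). Because the
collimated field edge coincides with the PTV surface, the boundary voxel
ring can only reach 50-75 % of the plateau, so the normalized plateau sits
well above the prescription; penumbra and enhancement metrics are
normalization-insensitive by construction (plateau-relative, or differences
of identically normalized variants).

Proton numbers become monitor units through
$\mathrm{protons/MU} = D_{meas,ref}/D_{MC,ref}$, with $D_{MC,ref}$
computed by the engine itself (central-axis dose per proton of a single
uncollimated beamlet at 2 cm depth — energy dependent) and $D_{meas,ref}$
pure configuration. The default 0.1 Gy/MU puts mid-range layer spots near
2 MU, so the 0.05 MU deliverability floor trims only the low tail of the
weight distribution; the proximal layer, left at exactly zero weight by
the nonnegative optimizer (the entrance dose of the deeper layers already
covers the proximal margin slab), is removed as undeliverable — the
range-shifted catalog plan therefore delivers 11 of its 12 planned layers.
After any removal, coverage normalization is re-run until the delivered
spot set is stable.

## Synthetic measurements

The detector simulators make the measurement-comparison workflow
reproducible without physical data. They emulate:

* **chamber array**: uniform-disc response (radius
  $\sqrt{V/\pi h} \approx 2.26$ mm from the 32 mm³ volume and an assumed
  2 mm plate gap), 7.6 mm sampling, a second acquisition shifted half a
  pitch in both axes, merge, and interpolation to 1.5 mm. The merged
  quincunx lattice is a regular square lattice in the 45°-rotated frame
  ($u = x+y$, $v = x-y$), where bilinear interpolation is well defined.
  Volume averaging can only widen penumbras, and the widening grows as the
  true edge sharpens.
* **film**: bilinear resampling to 0.3 mm pixels plus seeded
  multiplicative Gaussian noise (1 %); unbiased, relative-dosimetry only.
* **multilayer chamber**: lateral integration over a 2.5 cm aperture,
  sampled every 2 mm in depth.
* **setup error**: rigid rotation/translation resampling, inverted by the
  registration metric to 0.1 mm / 0.1°.

What the synthetic data does *not* emulate: detector energy dependence,
recombination, film LET quenching (off by default), scanner optics, or any
measurement drift — so passing detector tests demonstrates the geometry
and sampling arithmetic of the instruments, not their radiological
response.

## Metric definitions and numerical choices

* **80-20 penumbra**: normalization is the mean of the central 50 % of the
  region between the half-maximum crossings (central-axis and maximum
  normalizations are selectable); crossings are found by linear
  interpolation scanning *inward from the profile tail*, so interior
  ripple or edge horns cannot masquerade as the field edge; the
  plan-level value is the mean of the four edges of the two central
  in-plane profiles.
* **SOBP**: plateau level = mean of samples at or above 90 % of the
  maximum; range = distal 90 % crossing; width = distal minus proximal
  90 % crossings; flatness = (max−min)/(max+min) over the plateau. The
  90-90 width of a catalog plan is the margin-expanded 3.5 cm span, which
  the layer-placement geometry forces.
* **gamma**: evaluated-plane points at or above 5 % of the normalization
  value; reference interpolated to a 0.2 mm search lattice within 3 × DTA;
  global (normalization-relative) dose differences; pass = γ ≤ 1. The
  statistic is deliberately asymmetric under swapping the planes.
* **quadratures**: MCS and shifter integrals use ≤0.5 mm trapezoid steps
  (tested against 0.05 mm oracles at 2-5 %); the Bragg kernel uses an
  81-node Gaussian quadrature; layer-count ties break by the floor rule;
  all randomness (film noise, setup errors) is seeded.

Problem sizes throughout are the package's own desk-scale choices: 1 mm
grids restricted to the irradiated region, stride-2 optimization sampling
(coverage-normalized results agree with stride-1 to well under 1 %), and
~2000 solver sweeps; a full catalog plan optimizes in well under a minute.

## Known limitations

The engine's collimated edge is the trimmer step blurred by air drift and
water MCS only. Two physical mechanisms are deliberately absent: the
nuclear-interaction halo, and partial transmission through the
trimmer-blade edge. Both add blur that does not scale with water depth, so
their absence is invisible at depth — at 15 cm the collimated penumbra is
MCS-dominated and matches measured-system expectations — but at shallow
and mid depths the analytical collimated edge is sharper than a
transport-calculated one by roughly 1 mm (e.g. ~1.9 mm rather than ~3 mm
at 6 cm). This propagates in both directions: a chamber-array simulation
of that too-sharp edge is widened proportionally more, and the
nonnegative optimizer compensates trimmed fluence with stronger outer-spot
weight boosts than a blurrier influence matrix would permit, which
enlarges the shallow-depth dose horns (their sign and depth trend —
positive everywhere, largest for the deepest target — are robust; their
magnitude is not). Uncollimated composite edges are similarly squared-off
harder than a transport engine would allow. Users who need absolute
shallow-depth collimated penumbras should treat the engine as a lower
bound and the trend across depth — which is insensitive to these
omissions — as the reliable quantity.
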