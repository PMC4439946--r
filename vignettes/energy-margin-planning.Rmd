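---
title: "Energy-margin planning for distal-edge-tracking proton therapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energy-margin planning for distal-edge-tracking proton therapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(detem)
```

## The problem

Intensity-modulated proton therapy (IMPT) delivered with distal edge
tracking (DET) places pencil-beam spots only on the distal edge of the
planning target volume (PTV) from each gantry angle: each spot's energy is
chosen so that its Bragg peak stops exactly at the far side of the target
along its ray. This uses far fewer spots than 3D modulation, but it is
also the delivery technique most sensitive to setup uncertainty: a rigid
patient shift of a couple of millimetres can change the water-equivalent
path length (WEPL) of a ray by far more than the geometric shift whenever
the ray skirts an air cavity or another density interface, pulling the
Bragg peak off the distal target surface and underdosing the clinical
target volume (CTV).

The *energy margin* (EM) counters this at the planning stage. For each
spot at beam's-eye-view (BEV) position $\vec{x}_0$, the delivered energy
is raised from the nominal distal-edge energy $E_0(\vec{x}_0)$ to

$$E_1(\vec{x}_0) \;=\; \max\{\,E_0(\vec{x}) :
  \vec{x}_0 - \vec{d} \le \vec{x} \le \vec{x}_0 + \vec{d}\,\},$$

the maximum nominal energy over all spots within the setup-uncertainty
neighborhood of half-width $d$ on each BEV axis. Shift components
parallel to the beam axis do not change a ray's range and play no role,
which is why the margin lives entirely in the BEV plane. The margined
plan ("EM") deliberately overshoots into normal tissue on the planning
image; the weight optimizer then suppresses spots whose margin is large
(exactly the spots most vulnerable to motion) while the remaining spots
still reach their target point under any in-tolerance shift. The package
compares EM plans against the unmargined originals ("ORG") through a
simulated fractionated course.

## Pipeline overview

`run_pipeline()` executes the full experiment; every stage is also an
exported function:

1. **Phantom** — `make_phantom()` builds a voxel phantom and the CTV /
   PTV / ring / body structure set.
2. **DET planning** — `build_det_plan()` casts a 3 mm BEV lattice of rays
   per gantry angle, converts the WEPL at each ray's distal PTV exit into
   a nominal energy, and applies the energy margin.
3. **Optimization** — `build_influence()` and `optimize_weights()` fit
   nonnegative spot weights to the dose-volume objectives, separately for
   the ORG (nominal energies) and EM (margined energies) plans.
4. **Course simulation** — `sample_shifts()` draws per-fraction rigid
   shifts and `simulate_course()` recomputes the delivered dose of both
   plans, fraction by fraction, against the *same* shift set.
5. **Evaluation** — `ntd_accumulate()`, `compute_dvh()` and
   `variation_report()` express the delivered course in normalized total
   dose and report planned-versus-delivered DVH metrics.

## The synthetic phantom

The default phantom is a water-density cylinder (160 mm diameter) holding
a 25 mm-radius spherical CTV with a 20 mm-radius spherical air cavity
abutting it laterally; the PTV adds a 5 mm isotropic margin and a 10 mm
ring of normal tissue surrounds the PTV as a worst-case
organ-at-risk surrogate. This emulates the canonical hard case for
proton planning — a target directly against a sinus-like cavity — on a
2 mm isotropic grid (a desk-scale choice; voxel size is metadata, not
method, and is configurable).

What the generator does *not* emulate matters for interpreting results.
Two smooth spheres can only touch at a point, so the CTV-cavity interface
is small, and the rest of the body is homogeneous water. A real
head-and-neck CT presents bone/air/tissue interfaces to essentially every
beam, so every ray's range is sensitive to lateral shifts. On this
phantom only rays near the cavity silhouette are range-sensitive;
elsewhere the 5 mm PTV margin absorbs the 2 mm-sigma random shifts almost
completely. Consequently the simulated course reproduces the *direction*
of the published robustness effects (the unmargined plan underdoses the
CTV while the margined plan's delivered CTV DVH stays at or above its
planned curve, and the blurring of the ring's high-dose region is
stronger without the margin) but not the multi-percent *magnitude* of CTV
underdose seen on patient anatomies: single systematic shifts at the
4 mm cutoff produce around ten times the D95 deficit that a 30-fraction
zero-mean course does. Tests assert the ordering and the margined plan's
guarantees; they cannot certify behavior on real CTs.

Materials are assigned by mass-density thresholds into Air, Adipose,
Water, Muscle and DenseBone. The printed thresholds leave the interval
boundaries open on both sides, so the package closes each interval at its
lower bound (a deterministic total partition). Each material carries a
relative proton stopping power (RSP) at a nominal density, scaled by the
voxel's density ratio; the nominal densities are chosen so that RSP
equals density for soft tissue — in particular a water-density voxel has
RSP exactly 1 — while dense bone stops protons at about 86% of its
density, the standard soft-tissue/bone asymmetry of analytic engines.

## The analytic pencil-beam engine

The engine replaces Monte Carlo transport with three components, which is
adequate because the planning method and the robustness protocol are
independent of the transport engine:

* **Range-energy model.** The Bragg-Kleeman power law
  $R(E) = 10\,\alpha E^{p}$ mm with $\alpha = 0.0022$, $p = 1.77$ —
  the conventional fit for therapeutic protons in water (about 76 mm at
  100 MeV) — exactly invertible for spot-energy selection.
* **Depth dose.** The pristine Bragg curve follows the stopping-power
  term $(R - w)^{1/p - 1}$, convolved with a Gaussian range spread
  $\sigma_R = p R \,\sigma_E / E$, the first-order propagation of the
  1% energy spread through the power law. The convolution uses exact
  per-cell weights for the integrable end-of-range singularity
  (midpoint rules fail there), and dose is cut to exactly zero beyond
  $R + 4\sigma_R$. Per-energy tables are sampled every 0.25 mm of depth.
* **Lateral spread.** $\sigma(w)^2 = \sigma_{\text{air}}^2 +
  \sigma_{\text{mcs}}(w)^2$ with $\sigma_{\text{air}} = 3$ mm at
  isocenter and a multiple-Coulomb-scattering term growing as
  $(w/R)^{1.5}$ to $0.02\,R$ at end of range — a conventional scattering
  magnitude, configurable through `beam_model()`. The lateral kernel is
  evaluated within 3.5 sigma.

Voxel dose for a spot maps each voxel into the beam frame and converts
its geometric depth to WEPL using the spot's central axis (traced by
exact voxel-boundary ray marching); this central-axis approximation is
the standard pencil-beam simplification and the only place the engine is
knowingly blind to lateral heterogeneity within a spot's own Gaussian
footprint. Unit spot weight is normalized to deposit 1 Gy at the Bragg
peak in uniform water, which makes optimizer weights interpretable.
Nuclear halo, neutron dose and absolute MU calibration are out of scope.

## Planning parameters

| Parameter | Default | Meaning |
|---|---|---|
| spot spacing | 3 mm | BEV lattice pitch of DET spots |
| $\sigma_{\text{air}}$ | 3 mm | lateral spot sigma in air at isocenter |
| energy spread | 1% of $E$ | Gaussian sigma of the beam energy |
| energy resolution | 1 MeV | energies quantized *up*, so quantization never causes undershoot |
| $d$ | 6 mm | EM neighborhood half-width per BEV axis |
| neighborhood | box | axis-aligned box per the component-wise inequality; a disc of radius $d$ is available (`shape = "disc"`) as the physically motivated alternative, since $d$ is the maximum setup shift projected on the BEV plane |
| prescription | 60 Gy in 30 × 2 Gy | PTV prescription |

The nominal energy of a spot is defined by the WEPL from phantom entry to
the ray's distal PTV exit on its central ray (not the maximum over the
spot's lateral extent — a deliberately simple reading that keeps E0 a
property of the lattice ray).

## Fluence optimization

The objectives are one-sided quadratic penalties, averaged per structure:
PTV below 58 Gy (weight 100) or above 60 Gy (weight 10), ring above 60 Gy
(weight 10), and a dose-volume term (weight 10) allowing at most 3% of
the ring volume above 54 Gy. The dose-volume constraint uses the standard
worst-voxel technique: at each evaluation the allowed fraction of hottest
ring voxels is exempted and every other ring voxel above the threshold is
driven back toward it.

The solver is a monotone accelerated projected-gradient scheme: FISTA
with backtracking estimation of the gradient's Lipschitz constant,
adaptive restart of the momentum whenever a step would increase the
objective, and an incumbent-keeping rule so the recorded objective
sequence is nonincreasing by construction. Weights are nonnegative at
every iterate. Three standard planning devices are layered on top, all
exposed as arguments of `optimize_weights()`:

* **Target tightening** (`tighten`, 0.5 Gy): one-sided penalties pull
  violating voxels only *to* their bound, so at equilibrium voxels sit
  asymptotically on the infeasible side. The solver therefore aims 0.5 Gy
  past each one-sided clinical bound (PTV minimum up, ring DVH dose
  down), so voxels settle strictly on the feasible side.
* **Allowance headroom** (`allowance`, 0.9): the internal DVH exemption
  is 90% of the clinical 3%, leaving room for influence-matrix
  sparsification and DVH binning between the sampled and continuous dose.
* **Priority escalation** (`rounds` = 5, `escalate` = 5): after each
  solver round, any objective still violated against its *clinical* value
  has its penalty weight multiplied and the solve continues warm-started
  — the usual constraint-driven rescaling of planning systems. With the
  defaults the ORG plan on the default phantom meets both the PTV minimum
  and the ring dose-volume objective.

A structural property of the margined plan is worth stating plainly: the
EM pushes every beam's Bragg peaks up to the margin depth beyond the
distal PTV surface, i.e., into the innermost ring shell, from all 24
full-arc directions at once. On this phantom the ring dose-volume
objective is then not attainable simultaneously with full PTV coverage —
escalating the DVH penalty by many orders of magnitude only trades
coverage for ring sparing along a frontier that stays above the 3% goal.
This matches the published observation that margined DET plans deliver a
visibly higher planned ring dose; the pipeline optimizes the EM plan with
coverage priority, as those plans evidently did. The planned target
coverage of the two plans still agrees closely (D98 and D95 within a
fraction of a percent of prescription; the EM interior runs slightly
hotter, which shows up at D50 at the percent level).

## Setup-uncertainty simulation

Per-fraction rigid shifts are drawn independently per axis from a
zero-mean Gaussian with 2 mm sigma, truncated at ±4 mm by rejection
(clipping would pile probability mass onto the cutoff, which a "cutoff"
does not imply). Because per-axis ±4 mm still allows 3D norms up to
6.9 mm while the stated maximum 3D shift is 6 mm, samples with norm above
6 mm are also redrawn by default (`max_3d = 6`, toggleable); both printed
constraints then hold simultaneously. Zero mean makes this a purely
random (not systematic) error model; rotations, intrafraction motion and
anatomy change are out of scope.

A shift is applied as a translation of every beam's isocenter by minus
the shift — an exact rigid equivalence with no resampling or
interpolation error — and the whole spot dose is recomputed through the
shifted geometry, so range undershoot and overshoot arise from the
retraced WEPLs rather than from translating a stored dose grid. One
consequence follows directly: in a uniform medium a shift purely along a
beam's axis changes nothing at all, since every voxel keeps its
water-equivalent depth. Both plans of a comparison are always delivered
against the same shift set, making the ORG/EM comparison paired by
construction.

## Evaluation

Delivered courses are summed in normalized total dose,

$$\mathrm{NTD} \;=\; \sum_{i=1}^{N} d_i\,
  \frac{\alpha/\beta + d_i}{\alpha/\beta + d_{\mathrm{ref}}},$$

with $\alpha/\beta = 10$ Gy for the CTV, 1.5 Gy for the ring and
$d_{\mathrm{ref}} = 2$ Gy, so a course of exact 2 Gy fractions reproduces
the physical dose and hot fractions are weighted up more strongly in
normal tissue. NTD is computed on two whole evaluation grids (one per
$\alpha/\beta$) and each structure is read from its own grid, since the
CTV and ring are disjoint.

Cumulative DVHs use 0.1 Gy bins; $D_{x\%}$ is the minimum dose of the
hottest $x\%$ of a structure, read from the curve with linear
interpolation (on step distributions this is the largest dose at which
the volume still reaches $x\%$). The variation report compares the
planned dose against the delivered NTD at CTV D98/D95/D50/D2 and ring
D2/D20/D50 as `(delivered - planned) / 60 Gy x 100%`, so underdose is
negative — the sign convention consistent with describing CTV loss as
negative variation — and a plan is called acceptably robust when no CTV
volume point varies below -3% of prescription.

## Numerical choices and degenerate inputs

* Margin expansion (`expand_margin`) is exact Euclidean-ball dilation
  with anisotropic spacing, computed by FFT convolution of the mask with
  the ball indicator; results are identical to a brute-force distance
  check. A zero margin is the identity; the ring construction clips to
  the body and is disjoint from the PTV by construction.
* Ray tracing is exact voxel-boundary marching (no interpolation); a ray
  that misses the grid yields an empty trace, and a spot whose beam
  misses the grid deposits zero dose rather than erroring.
* The energy-margin operator with $d = 0$ is the identity; margins are
  monotone in $d$ by neighborhood nesting.
* Influence entries below $10^{-3}$ of their column maximum are dropped;
  body voxels outside PTV and ring are subsampled at 10% for the
  optimizer (every PTV and ring voxel is kept).
* All randomness flows through explicit seeds; a rerun with the same
  configuration is bit-reproducible.

## Problem sizes

The default experiment uses an 88 x 88 x 56 grid at 2 mm spacing
(~430k voxels), about 7,500 spots over 24 beams (the same order as the
published full-arc plans), 30-fraction courses evaluated on the CTV and
ring voxels, and two to five shift-set seeds in the tests and acceptance
script — sizes chosen so a full planning-plus-robustness experiment is a
minutes-scale desktop computation.

## Known limitations

* No Monte Carlo physics: nuclear interactions, secondary particles and
  the halo are absent; dose-to-water is built into the RSP model rather
  than applied as a per-material stopping-power ratio at scoring time.
* The central-axis WEPL approximation ignores heterogeneity across a
  spot's lateral footprint, which smooths the very interface effects the
  margin targets; a full kernel-superposition engine would sharpen them.
* The phantom's point-tangent cavity under-represents real anatomical
  heterogeneity, so absolute robustness magnitudes are smaller than those
  reported on patient CTs (direction and ordering are preserved).
* The EM plan cannot meet the ring dose-volume objective at full coverage
  on this geometry (see above); the package reports the achieved value
  rather than forcing it.
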