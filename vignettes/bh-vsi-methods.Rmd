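---
title: "Breath-hold vessel size imaging: models, calibration and mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Breath-hold vessel size imaging: models, calibration and mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bhvsi)
```

## The problem

Vessel size imaging (VSI) estimates the mean radius of blood vessels in a
voxel from the differential size sensitivity of gradient-echo (GE) and
spin-echo (SE) transverse relaxation. Deoxygenated hemoglobin makes venous
blood paramagnetic; each vessel perturbs the magnetic field around it, and
diffusing water protons dephase in those perturbations. GE relaxation
responds to perturbers of all sizes, while SE relaxation — whose refocusing
pulse cancels the dephasing of spins that have not moved appreciably —
peaks for capillary-scale vessels and falls off for large ones. The ratio

$$q = \frac{\Delta R_2^*}{\Delta R_2}$$

between the GE and SE relaxation-rate *changes* induced by a change in
venous oxygenation is therefore a monotone index of vessel size, which a
simulation-derived calibration converts into a mean radius.

A breath-hold (BH) task supplies the oxygenation modulation without gas
delivery or contrast agent: holding after inspiration induces mild
hypercapnia, cerebral blood flow rises, and venous oxygenation increases
from roughly $Y = 0.6$ (free breathing, FB) to $Y = 0.75$ (BH). The package
implements both halves of that workflow:

1. a Monte-Carlo simulator of GE/SE relaxation around random cylinder
   networks, swept over radii to produce the $R(q)$ calibration;
2. a dual-echo block-design mapping pipeline that converts a
   simultaneously acquired GE/SE (SAGE EPI) breath-hold run into voxelwise
   $\Delta R_2^*$, $\Delta R_2$, $q$ and radius maps;
3. a synthetic phantom generator with known ground truth that makes the
   whole pipeline testable without scanner data.

## The virtual vascular voxel

A voxel is modelled as a cubic periodic cell (default edge 500 µm) seeded
with randomly oriented infinite cylinders of one radius per network. Axis
points are uniform in the cell, directions uniform on the sphere
(Marsaglia sampling), and cylinders are added until the Monte-Carlo
estimated intravascular fraction — tracked on a fixed panel of uniform test
points — crosses the target cerebral blood volume fraction (default 4%).
Because whole cylinders are added, the achieved fraction can overshoot the
target by up to one cylinder's marginal in-cell volume; the achieved value
is recorded and reported rather than hidden.

The periodic convention replicates every cylinder over the 26 neighbouring
images for containment and field queries. This avoids depletion of
vascular volume near the cell boundary and is the package-wide definition
of "inside a vessel": the brute-force oracle used in the tests applies the
same 27-image rule.

```{r network}
net <- generate_network(network_spec(radius = 5, voxel_edge = 200,
                                     target_fraction = 0.04, seed = 1))
net
```

## The off-resonance field

For field $B_0$ along $+z$, an infinite cylinder at angle $\theta$ to
$B_0$ with radius $R$ produces, at perpendicular distance $\rho > R$ and
azimuth $\phi$ (measured from the projection of $B_0$ onto the plane
normal to the axis),

$$\Delta\omega(\rho, \phi) = \delta\omega \left(\frac{R}{\rho}\right)^2
\sin^2\theta \cos 2\phi, \qquad
\delta\omega = \frac{\gamma B_0 \Delta\chi}{2},$$

and a uniform offset $\gamma B_0 \Delta\chi (3\cos^2\theta - 1)/6$ inside.
The susceptibility difference is $\Delta\chi = \Delta\chi_{do} \cdot
\mathrm{Hct} \cdot (1 - Y)$ with $\Delta\chi_{do} = 4\pi \times 0.264$ ppm
(SI volume susceptibility of fully deoxygenated erythrocytes, the standard
literature value; it is an explicit, overridable parameter of
`blood_model()` rather than a hidden constant). At the defaults
($\mathrm{Hct} = 0.4$, $B_0 = 3$ T) this gives $\Delta\chi \approx 5.3
\times 10^{-7}$ in FB and $\delta\omega \approx 213$ rad/s.

The field of a network is the linear superposition over all cylinders and
their 27 periodic images. Two evaluation modes exist: *exact* (direct
superposition at arbitrary points, the oracle) and *grid* (precomputed
lattice, default 0.8 µm spacing, trilinear interpolation). The lattice is
stored as a double-precision R array with a configurable node budget; at
the sweep's lattice sizes (at most $160^3$ nodes) this is ~33 MB. For
dense networks of thin cylinders the builder accepts a per-cylinder
distance cutoff for the $1/\rho^2$ dipole tail; at the sweep default
(cutoff $20R$) the truncated tail carries well under 1% of the field
variance. Pointwise relative interpolation error is unbounded at the
$\cos 2\phi$ zero crossings for any scheme, so grid accuracy is quantified
by the sup-norm error normalized to the maximum exact field over the
evaluation points; at 0.8 µm the measured error sits far inside the 2%
band the test suite enforces.

## The random walk and the signals

Extravascular spin packets are seeded uniformly in tissue by rejection
sampling and perform a discrete-time, continuous-space random walk:
per step of $\delta t = 0.1$ ms an isotropic Gaussian displacement with
per-axis standard deviation $\sqrt{2 D \delta t}$ ($D = 1$ µm²/ms) is
proposed; steps landing inside a vessel are rejected and the packet stays
put for that step (vessels are impermeable barriers; specular reflection
is deliberately not the default, reject-and-stay being the simplest scheme
consistent with impermeability). Phase accrues with the field at the
pre-step position — a first-order Euler discretization of the Bloch-Torrey
phase integral with $O(\delta t)$ error. Longitudinal relaxation is
omitted. In the static limit $D = 0$ the phase is evaluated in closed form
($\varphi = \Delta\omega(r_0)\, t$), which the test suite exploits as an
exact oracle: the GE magnitude must equal a direct complex sum over the
same seeded positions, and a spin echo must refocus static spins to
$|E(TE) - 1| < 10^{-9}$.

The extravascular dephasing factor is $E(t) = |\langle e^{i\varphi(t)}
\rangle|$; SE traces negate all phases at $TE/2$ (ideal instantaneous
refocusing). Signal magnitudes (matching magnitude images) combine the
simulated extravascular compartment with an analytic blood pool:

$$S(t) = (1 - f)\, E(t)\, e^{-t/T_{2,\mathrm{tissue}}} +
f\, e^{-t/T_{2,\mathrm{blood}}},$$

with $T_{2,\mathrm{tissue}} = 83.5$ ms and $T_{2,\mathrm{blood}} =
32.3$ ms (FB) / 53.2 ms (BH). Intravascular packets are never walked; the
blood pool enters only through its $T_2$, and a flag removes it entirely.

Rate changes between two states follow from the signal ratio at the echo
time, $\Delta R_2^{(*)} = -\ln(S_\mathrm{active}/S_\mathrm{baseline}) /
TE$. One sign subtlety deserves emphasis: BH *raises* the BOLD signal
(higher $Y$ means less dephasing and a longer blood $T_2$), so a BH/BH-FB
ratio larger than one would make the literal log-ratio negative. The
package therefore orients the ratio with the high-relaxation state (FB) as
"active", so that $\Delta R_2^*$ and $\Delta R_2$ are positive for a
positive BOLD response — the orientation in which rate maps are
conventionally displayed. Only the shared sign convention, not any
magnitude, depends on this choice, and $q$ is invariant to it.

## The calibration sweep and the $R(q)$ fit

`sweep_calibration()` runs one network and one random walk per radius.
Since the field is linear in $\Delta\chi$ and the walk geometry does not
depend on the field, the BH phase trajectories are the FB trajectories
scaled by $\Delta\chi_{BH}/\Delta\chi_{FB} = 0.625$ — numerically
identical to re-simulating with shared geometry and spin seeds, at half
the cost. FB and BH thus differ only in oxygenation (and blood $T_2$),
deliberately excluding vasodilation: the blood volume fraction is held at
4% in both states.

The calibration relation is computed from the extravascular signals alone
(`include_blood = FALSE`). With the blood pool included, its $T_2$
contrast dominates whenever the extravascular contribution is motionally
narrowed (capillary radii), putting a radius-independent floor under the
small-radius branch of $q$ and making $q(R)$ non-single-valued. The
extravascular-only relation decreases smoothly toward $q \to 1$ as
$R \to 0$, which is also the behaviour implied by a calibration whose
fitted constant term is negative (radius near zero at $q = 1$). The blood
compartment remains available both as a sweep flag and in the signal
traces.

Desk-scale geometry rules (all exposed as arguments): per-radius cell edge
$\max(128, 15R)$ µm — large enough that several cylinders are needed even
at $R = 100$ µm, keeping the achieved blood volume near target — lattice
capped at $160^3$ nodes, dipole cutoff $20R$, $2 \times 10^4$ spin packets
per radius with batch-means standard errors over 10 spin groups. The
nominal spin density of 5 µm⁻³ over a 500 µm voxel would correspond to
~$6 \times 10^8$ packets; the package refuses density-derived counts above
$10^7$ to prevent accidental cluster-scale runs, and the Monte-Carlo error
of the scaled-down defaults is reported row-wise in the table.

The calibration curve is a sixth-order polynomial in $\ln q$,

$$R(q) = \sum_{n=0}^{6} P_n \ln^n q,$$

fitted by iteratively reweighted least squares with the Tukey bisquare
weight (tuning constant 4.685, residual scale $\mathrm{median}|r|/0.6745$,
convergence when the largest weight change falls below $10^{-6}$, at most
50 iterations). Coefficients are stored and serialized lowest order first
and labelled as such in the JSON, because a bare six-number list is
ambiguous for a seventh-coefficient polynomial: `reference_curve()` ships
the published six printed values as a read-only comparison fixture
exposing *both* possible assignments (P0..P5 or P1..P6), and neither is
ever used as a silent default. Evaluation clips $q$ into the fitted range
rather than extrapolating — a degree-6 polynomial explodes outside its
support — flags clipped voxels, floors the radius at zero, and maps
$q \le 0$ to `NA` rather than raising.

```{r calibration, eval = FALSE}
tab <- sweep_calibration(radius_grid(12, 0.4, 100), n_spins = 20000,
                         seed = 1, verbose = TRUE)
curve <- fit_calibration(tab)
radius_from_q(curve, 2)
```

(The sweep takes a few minutes; it is exercised at full scale by the test
suite and is not run while building this vignette.)

## The mapping pipeline

`map_vsi()` expects motion-corrected, co-registered GE and SE 4D series
(the package deliberately does not reimplement realignment, slice-timing
or spatial normalization; a motion-parameter table can be supplied as
nuisance regressors) and proceeds as:

1. **Smoothing** — per-volume separable 3D Gaussian, default FWHM 5 mm,
   truncated at $3\sigma$ with renormalized rows so constants are
   preserved exactly.
2. **GLM** — per-voxel OLS on intercept, canonical double-gamma HRF
   (peak 6 s, undershoot 16 s, dispersions 1 s, ratio 6:1, 32 s support —
   the standard parameterization) convolved with the BH boxcar, its
   1-s-shift finite-difference temporal derivative (orthogonalized against
   the HRF column), and nuisance columns. The t-test is on the HRF beta.
3. **Joint mask** — voxels with $p < 0.001$ (uncorrected, per the
   protocol; this is a documented limitation, not an oversight) *and* a
   positive HRF beta in both echoes.
4. **Lag compensation** — a single global circular shift $s^*$ maximizing
   the cross-correlation between a mask-mean timecourse and the BH boxcar.
   The default timecourse is the demeaned observed mask-mean signal: the
   GLM-predicted response is a projection onto the *unshifted* regressors
   and systematically compresses lags beyond what the temporal derivative
   can absorb, whereas the observed-mean estimator recovers integer lags
   exactly (the phantom tests verify a 3-volume lag is returned as 3) and
   is effectively noise-free after averaging over the mask.
   `lag_source = "predicted"` restores the projection-based variant. The
   reported hemodynamic lag is $s^*$ minus the intrinsic lag of the
   HRF-convolved regressor itself.
5. **Block averaging** — voxelwise BH and FB means over the shifted
   labels, excluding by default the first 2 volumes after each state
   change. The response is still in transit there, so averaging the raw
   shifted labels dilutes the recovered plateau contrast by roughly twice
   as much as the 2-volume exclusion does; the phantom recovery tests
   bound the residual attenuation below 10%. The exclusion count is a
   flag (`transition_drop`), and the ratio $q$ is unaffected either way
   since both echoes share the attenuation.
6. **Maps** — $\Delta R_2^*$ and $\Delta R_2$ from the FB/BH mean-signal
   log-ratios at the respective echo times, $q$ as their ratio, radius
   through the calibration curve; nonpositive means are masked and
   counted, out-of-range $q$ clipped and flagged.

`region_summary()` reduces radius maps over region masks (per-subject mean
± SD) and compares two regions across subjects with a paired Wilcoxon
signed-rank test, reporting the all-differences-zero case as degenerate
rather than producing a spurious p-value.

## The synthetic phantom

`make_phantom()` builds dual-echo series on a 64 × 64 × 8 grid (the
protocol's 28-slice matrix is available by passing `dims`; the short
default keeps test runs fast) with nested box regions — background,
non-responding tissue, a responding "GM" shell and "WM" core separated by
a tissue gap so that region medians survive smoothing. The signal model
inverts the mapping equation:

$$S_e(v, t) = S_{0,e}(v)\, e^{TE_e\, \Delta R_{2,e}(v)\, h(t)}
\,(1 + \mathrm{drift} \cdot t) + \varepsilon,$$

where $h(t)$ is the HRF-convolved BH boxcar (peak-normalized, circularly
delayed by the configured lag; a pure boxcar variant gives the exact
noise-free inverse-model identity) and $\varepsilon$ is additive Gaussian
noise on magnitude — adequate at SNR ≫ 3 and chosen over Rician noise to
keep the identity clean. Default true rates ($\Delta R_2^* = 1.2$,
$\Delta R_2 = 0.35$ s⁻¹, temporal SNR ≈ 100, lag 3 volumes) are plausible
breath-hold magnitudes chosen for testing and are labelled as such; they
are not published values.

What passing phantom tests shows — and what it does not: the phantom
exercises detection, lag compensation, averaging and the algebra of the
maps under well-behaved noise. It does not emulate EPI distortion,
task-correlated motion, physiological noise spectra, partial-volume
mixtures, or vasodilation, so recovery there bounds algorithmic bias, not
in-vivo accuracy.

## Numerical choices and degenerate inputs

* Determinism: every stochastic component (generation, seeding, walking,
  phantom noise) derives from explicit integer seeds; equal seeds give
  bit-identical outputs.
* Echo times that are not multiples of $\delta t$ are hit exactly: the
  step schedule is the union of the $\delta t$ lattice and the requested
  record times.
* A flat timecourse in `lag_shift()` warns and returns shift 0;
  cross-correlation ties resolve to the smallest nonnegative shift.
* Constant series in the GLM produce $t = 0$, $p = 1$ (never 0/0).
* `q_from_rates()` and `radius_from_q()` mask undefined values (`NA`)
  instead of raising, so maps propagate; `relaxation_change()` on scalar
  nonpositive signals raises, and `compute_vsi()` pre-masks such voxels
  and counts them in QC.
* An identical FB and BH state yields zero rate changes and rows flagged
  invalid, never silently dropped.

## Problem sizes used in the packaged validation

The test suite runs the calibration at 12 radii spanning 0.4-100 µm with
$2 \times 10^4$ packets (a few minutes), phantom recovery and
false-positive checks over 10 seeds each, and the field/walker oracles on
single-cylinder and ~100-µm-cell geometries. These sizes were chosen so
the full validation completes comfortably on a single CPU while leaving
every assertion statistically meaningful; all of them scale up through
ordinary function arguments.

## Known limitations

* One radius per network; polydisperse and branching vasculature, flow,
  permeable walls and exchange are out of scope.
* The 27-image periodic convention truncates the infinite periodic line
  set; it is applied consistently everywhere, including the oracles.
* p-values in the joint mask are uncorrected at $\alpha = 0.001$.
* The blood-pool compartment of the signal traces is an explicit modelling
  assumption (the protocol's blood $T_2$ values enter only through it).
* Achieved blood volume overshoots the target by whole-cylinder
  granularity, most visibly for radii approaching the cell size; the
  achieved fraction is always recorded.
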