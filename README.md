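# bhvsi — breath-hold venous vessel size imaging

`bhvsi` estimates the mean venous vessel radius per voxel from a
breath-hold (BH) BOLD fMRI experiment, for researchers studying brain
microvasculature without contrast agents or gas-delivery hardware. Holding
the breath after inspiration mildly raises CO₂, dilates cerebral vessels
and increases venous oxygenation; the resulting change in blood
susceptibility changes the gradient-echo (GE) and spin-echo (SE)
transverse relaxation rates by different amounts depending on vessel
caliber. The vessel size index

```
q = ΔR2* / ΔR2,   ΔR2(*) = -ln(S_active / S_baseline) / TE
```

is converted to a mean radius through a simulation-derived calibration

```
R(q) = Σ_{n=0..6} P_n lnⁿ q
```

fitted with bisquare-robust least squares to a Monte-Carlo sweep of
GE/SE relaxation around random cylinder networks (4% blood volume,
oxygenation Y 0.6 → 0.75, Hct 0.4, B0 3 T, D 1 µm²/ms).

The package contains:

- **Geometry + field**: periodic virtual voxels of randomly oriented
  cylinders at a target blood volume fraction; the analytic dipole field
  of each cylinder, exactly or on a 0.8 µm lattice (`generate_network()`,
  `build_field_grid()`, `sample_field()`).
- **Dephasing simulator**: random-walk Monte Carlo of extravascular spin
  phase with impermeable vessel barriers; GE (FID) and ideal-refocusing SE
  signals with an optional analytic blood compartment (`seed_spins()`,
  `evolve_phases()`, `ge_signal()`, `se_signal()`).
- **Calibration**: radius sweeps, the robust sixth-order ln-q fit, and the
  q → R lookup with range clipping (`sweep_calibration()`,
  `fit_calibration()`, `radius_from_q()`).
- **Mapping pipeline**: smoothing, HRF + temporal-derivative GLM, joint
  GE+SE significance masking (p < 0.001, both increases), circular
  hemodynamic-lag compensation, BH/FB block averaging and voxelwise
  ΔR2*/ΔR2/q/radius maps from dual-echo (SAGE) NIfTI series
  (`map_vsi()` and the individual stages).
- **Synthetic phantoms**: dual-echo block-design series with known ground
  truth for end-to-end validation (`make_phantom()`,
  `make_null_phantom()`).

A thin command-line front end (`inst/cli/bhvsi.R`) exposes `simulate`,
`calibrate`, `map` and `synth` subcommands over the same functions.

## Worked example

Calibrate at desk scale, generate a phantom with known physiology, and map
it:

```r
library(bhvsi)

tab   <- sweep_calibration(radius_grid(12, 0.4, 100), n_spins = 20000, seed = 7)
curve <- fit_calibration(tab)

ph  <- make_phantom(phantom_spec(seed = 4))   # true GM: ΔR2* 1.2, ΔR2 0.35 s⁻¹, lag 3
res <- map_vsi(ph$ge, ph$se, ph$spec$design, curve)

res$lag_volumes
#> [1] 3
gm <- ph$spec$regions == 2 & res$mask
median(res$maps$dr2s[gm]); median(res$maps$dr2[gm]); median(res$maps$q[gm])
#> [1] 1.105611
#> [1] 0.3222357
#> [1] 3.427745
res$maps
#> <vsi_maps> 5600 voxels mapped (0 clipped, 0 undefined q)
#>   median dR2* 0.956 s^-1, dR2 0.282 s^-1, q 3.4, radius 14.4 um
```

The hemodynamic lag is recovered exactly; the region-median rate changes
come back within ~8% of truth (the small attenuation is the residual
transit of the hemodynamic response into the averaged blocks), and their
ratio q is recovered to three digits because the attenuation cancels
between echoes. The radius column is simply where the phantom's chosen q
lands on this sweep's calibration — the phantom prescribes rates, not a
vessel geometry.

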