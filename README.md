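# axonsens

Sensitivity of pulsed (PGSE) and oscillating (OGSE) gradient spin-echo
diffusion MRI sequences to axon diameter.

## The problem

Mapping axon diameters in vivo hinges on a weak effect: the diffusion MR
signal of white matter changes only slightly with the diameter of the
axons, and below some size the change drowns in noise. Sequence design
determines how much of that effect survives. `axonsens` is a deterministic
simulator and analysis toolkit for the question *which trapezoidal
PGSE/OGSE settings — gradient amplitude G, waveform duration δ, separation
Δ, lobe count N — maximise the sensitivity of the signal to axon diameter,
and what is the smallest diameter a given scanner and SNR can distinguish
from zero?* It is aimed at diffusion-MRI methods researchers who want
reproducible, scriptable answers for their own hardware limits, tissue
parameters and orientation scenarios.

## The model

White matter is a two-compartment substrate. Intra-axonal water (volume
fraction `f`) sits in impermeable parallel cylinders of diameter `a`:
diffusion is free along the axis and restricted across it, with the
transverse echo attenuation given by the Gaussian phase distribution (GPD)
approximation,

    ln S_perp = -gamma^2 * sum_m B_m * Int Int g(t1) g(t2) exp(-D mu_m^2 |t1-t2| / R^2) dt1 dt2,
    B_m = R^2 / (mu_m^2 (mu_m^2 - 1)),   R = a/2,

where `mu_m` are the roots of `J1'(x) = 0` and `g(t)` is the effective
gradient waveform. Extra-axonal water is an anisotropic Gaussian
(diffusion tensor) compartment with the tortuosity rule
`D_perp = D_par (1 - f)`. The proton-density-normalised composite signal is
`S* = exp(-TE/T2) (f S_r + (1-f) S_h)`; fiber orientation dispersion is a
Watson distribution over orientations applied to both compartments.
Sensitivity is `|dS*/da|`; practical resolvability compares the contrast
`|S*(a) - S*(a - eps)|` with the noise level
`sigma = exp(-TE0/T2) / SNR`.

All waveform integrals (b-values and the GPD double integral) are exact
per-segment closed forms on the trapezoidal breakpoints — no sampled
waveforms anywhere. A Monte Carlo random-walk simulator of restricted
diffusion in a cylinder (`mc_cylinder_signal`) and a noisy-realisation
generator (`empirical_distinguishability`) provide independent stochastic
validation of the deterministic pipeline.

## Worked example

```r
library(axonsens)

## a strong-gradient PGSE sequence (Connectom-class hardware)
p <- sequence_params(G = 0.300, delta = 0.036, Delta = "optimal", N = 1)
p
#> OGSE sequence: G = 300 mT/m, delta = 36 ms, Delta = 46 ms, N = 1 (PGSE)
#>   SR = 200 T/m/s (t_r = 1.5 ms), tau1/tau2/P180 = 10/20/10 ms
#>   TE = 112 ms, b = 264369.7 s/mm^2

tis <- tissue_model(f = 0.7, D_par = 1.7e-9, diameter = 4e-6, T2 = 0.070)
composite_signal(p, tis)          # T2-weighted two-compartment signal
#> [1] 0.1049929
sensitivity_full(p, tis) * 1e-6   # |dS*/da| per micrometre of diameter
#> [1] 0.03093843

## smallest diameter distinguishable from zero at SNR 20
a0_limit(noise_model(SNR = 20), p, tissue_model(diameter = 0),
         scenario_spec(0)) * 1e6
#> [1] 2.8
```

The numbers mean: at `b = 264 370 s/mm^2` a 4 µm axon population retains
10.5% of the unweighted signal; each micrometre of diameter change moves
the normalised signal by about 0.031; and with SNR 20 everything below
2.8 µm is indistinguishable from zero-diameter tissue with this sequence.

Why oscillating gradients matter in practice: tilt the fibers 10° away
from perpendicular and the PGSE sequence above loses essentially all its
sensitivity (`4e-8` per µm — its enormous b-value annihilates the signal
through free axial diffusion), while a 4-lobe OGSE with the same gradient
amplitude (`b = 15 565 s/mm^2`) keeps `0.011` per µm:

```r
o <- sequence_params(0.300, delta = 0.042, N = 4)
sensitivity_full(p, tis, scenario_spec(theta_deg = 10)) * 1e-6  # 3.9e-08
sensitivity_full(o, tis, scenario_spec(theta_deg = 10)) * 1e-6  # 0.0107
```

Higher-level drivers reproduce whole figure/table computations as tidy
CSVs with JSON manifests:

```r
run_experiment(experiment_spec("table2", out_dir = "results",
                               scenarios = "perpendicular",
                               G_values_mT = 300, SNR_values = 50,
                               N_values = 1))
```

## Layout

- `R/` — sequence construction and b-values, GPD cylinder engine, Watson
  dispersion, sensitivity/resolvability pipeline, experiment drivers,
  Monte Carlo validators.
- `src/` — the C++ random-walk inner loop.
- `inst/extdata/` — published reference tables (optimal durations,
  resolvability limits, plateau times, starred optima) used as inputs and
  comparison fixtures.
- `vignettes/axon-diameter-sensitivity.Rmd` — model assumptions, numerical
  choices, design decisions and limitations.
- `tests/testthat/` — unit, property and acceptance suites.
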