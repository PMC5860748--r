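# bundlerheo

Active microrheology of single semiflexible filament bundles.

Bundled actin carries much of the mechanical load in eukaryotic cells,
yet single bundles are hard to characterize: they are too anisotropic
for bulk rheology and too stiff for purely thermal (passive) bending
analysis. An alternative is *active* driving: attach a micron-sized
bead to one end of a bundle, oscillate it with an optical trap, and
watch how far the oscillation travels along the bundle before viscous
drag kills it. `bundlerheo` implements that measurement end to end —
for synthetic, ground-truth-annotated image stacks it generates itself,
or for real fluorescence recordings — and is aimed at single-filament /
single-bundle biophysics labs and at method development.

## The model

At low Reynolds number the transverse deflection y(x, t) of a rod with
bending stiffness κ (J·m) in a medium with transverse drag ζ (Pa·s per
unit length) obeys the overdamped beam equation

    ζ (y_t − u) = −κ y_xxxx,        u = 0 (quiescent medium)

Driving one end as y(0, t) = y₀ cos ωt injects two spatially decaying
waves. Lengths scale with the hydrodynamic length

    l_ω = (κ / (ζ ω))^¼

and the dimensionless dispersion relation k⁴ = i fixes the decay
constants C̃ = cos(π/8) ≈ 0.92 and S̃ = sin(π/8) ≈ 0.38 of the
steady solution

    y(η, t) = (y₀/2) [ e^(−S̃η) cos(C̃η − ωt) + e^(−C̃η) cos(S̃η + ωt) ],
    η = x / l_ω.

Fitting this profile to the tracked, band-passed contour yields l_ω,
hence the effective bending stiffness

    κ_eff = κ/ζ = l_ω⁴ · ω     [m⁴/s]     (κ in J·m when ζ is known).

A frequency sweep then distinguishes regimes: a wormlike chain (WLC)
has l_ω ∝ ω^(−1/4) and constant κ_eff; shear-coupled wormlike-bundle
(WLB) behavior shows up as κ_eff ∝ l_ω², the signature of mode
stiffnesses scaling as κ_n ∝ q_n^(−2).

Modules: closed-form + finite-difference core model, synthetic
fluorescence renderer (PSF, motion blur, photobleaching, Poisson/read
noise, 16-bit TIFF), subpixel contour tracker, Fourier band-pass and
profile fit, sweep assembly/classification, and a CLI. See the
vignette `vignettes/active-bundle-rheology.Rmd` for the method details
and design rationale.

## Worked example

Simulate a thin actin bundle driven at 0.3 Hz, track it, and recover
its stiffness:

```r
library(bundlerheo)

rod <- default_rod()           # thin depletion-bundled actin in 50 mPa·s medium
rod
#> <rod_model>
#>   kappa      6e-24 J·m   (lp = 0.001468 m)
#>   L          2e-05 m,  d = 6e-08 m  (L/d = 333)
#>   viscosity  0.05 Pa·s  ->  zeta = 0.0945 Pa·s
#>   kappa/zeta 6.349e-23 m^4/s

decay_constants()
#> <decay_constants> C~ = 0.9238795, S~ = 0.3826834 (k^4 = i)

drv   <- drive_protocol(amplitude = 1e-6, frequency_hz = 0.3, n_periods = 5)
stack <- render_stack(rod, drv, imaging_config(rng_seed = 42))
fit   <- analyze_stack(stack)  # preprocess -> filter -> track -> band-pass -> fit
fit
#> <hydro_fit> l_omega = 2.405e-06 m (se 1.7e-09) at 0.3 Hz [complex, end-driven]

effective_stiffness(fit$l_omega, fit$omega, zeta = rod$zeta)
#> kappa_eff = 6.307e-23 m^4/s   kappa = 5.96e-24 J.m
```

The fitted decay length (2.405 µm) and stiffness agree with the
ground truth (κ/ζ = 6.349e-23 m⁴/s, κ = 6e-24 J·m) to better than 1%
at the default signal-to-noise level. A full spectrum is one call,

```r
sweep <- run_sweep(rod, seed = 1)     # 8 frequencies, 0.04-2.5 Hz
classify_regime(sweep)                 # -> WLC_constant for this rod
```

and the same chain is scriptable from a shell via `exec/bundlerheo`
(`simulate`, `track`, `analyze`, `sweep`, `selftest`), with every
intermediate persisted as TIFF/CSV/JSON.

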