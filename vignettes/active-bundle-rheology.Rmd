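---
title: "Active single-bundle rheology: model, pipeline, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Active single-bundle rheology: model, pipeline, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bundlerheo)
```

## The measurement principle

A semiflexible filament bundle (for example actin bundled by depletion
forces) is attached at one point to a micron-sized bead held in an
optical trap. Oscillating the trap transversely at frequency $f$ drives
a bending wave into the bundle. At the micrometer scale the Reynolds
number is tiny, so inertia is irrelevant and the transverse deflection
$y(x,t)$ obeys the overdamped beam equation

$$\zeta\,(y_t - u) \;=\; -\kappa\, y_{xxxx},$$

where $\kappa$ is the bending stiffness (J·m), $\zeta$ the transverse
drag per unit length (Pa·s), and $u$ a background flow (zero here: the
trap moves the bead, not the fluid). Nondimensionalizing lengths by the
*hydrodynamic length*

$$l_\omega = \left(\frac{\kappa}{\zeta\,\omega}\right)^{1/4},
\qquad \omega = 2\pi f,$$

a traveling-wave ansatz turns the equation into the quartic dispersion
relation $k^4 = i$. Its first-quadrant root
$k = \tilde C + i\tilde S = e^{i\pi/8}$ gives the two constants
(`decay_constants()`, $\tilde C \approx 0.92$, $\tilde S \approx 0.38$)
that shape the steady end-driven solution

$$y(\eta,t)=\frac{y_0}{2}\left[e^{-\tilde S\eta}\cos(\tilde C\eta-\omega t)
+e^{-\tilde C\eta}\cos(\tilde S\eta+\omega t)\right],
\qquad \eta = x/l_\omega:$$

an excitation wave and a medium-reflected wave, both decaying on the
scale $l_\omega$. Measuring how the imposed oscillation decays along
the bundle therefore measures $l_\omega$, and with it the *effective
stiffness*

$$\kappa_\mathrm{eff} = \frac{\kappa}{\zeta} = l_\omega^4\,\omega
\quad [\mathrm{m^4/s}].$$

Sweeping $f$ probes the bundle at different length scales. A wormlike
chain (WLC) has one frequency-independent stiffness, hence
$l_\omega \propto \omega^{-1/4}$ and constant $\kappa_\mathrm{eff}$.
Crosslink- or friction-coupled bundles (wormlike-bundle, WLB, behavior)
have mode-dependent stiffness; in the shear-dominated regime the mode
stiffness scales with wave vector as $\kappa_n \propto q_n^{-2}$, and
since the drive predominantly excites the mode with $q^{-1} \propto
l_\omega$, this appears as $\kappa_\mathrm{eff} \propto l_\omega^{2}$.
`classify_regime()` separates these cases from fitted power-law
exponents.

The drag coefficient uses the standard low-Reynolds slender-body
result $\zeta = 4\pi\eta_m/(\ln(L/d) + 0.84)$ (`drag_coefficient()`,
$\eta_m$ medium viscosity). The logarithm makes $\zeta$ insensitive to
the poorly known bundle diameter, which is why $\kappa_\mathrm{eff}$
(which needs no $\zeta$) is the primary observable and $\kappa =
\zeta\,\kappa_\mathrm{eff}$ is derived only when geometry is supplied.
Since both conventions appear in the literature we always report
$\kappa/\zeta$ in m$^4$/s and, when possible, $\kappa$ in J·m, and do
not attempt any mixed unit.

## Pipeline

1. **Synthesis** (`render_stack()`): seeded fluorescence image stacks
   with ground truth (below), or real TIFF stacks via `read_stack()`.
2. **Preprocessing** (`preprocess_stack()`): rotate the deflection axis
   onto image *y* (bilinear interpolation; the tilt can be estimated
   from an undisturbed frame), crop to the anticipated amplitude band.
3. **Filtering** (`smooth_and_enhance()`): marginal Gaussian smoothing
   along *x* and a horizontal-line-enhancing ridge filter (negated
   second derivative of a Gaussian) along *y*.
4. **Tracking** (`track_contour()`): per column, subpixel peak
   localization; bead vicinity excluded; temporal continuity breaks
   ties between candidate peaks.
5. **Band-pass** (`bandpass()`): discrete Fourier projection at exactly
   the drive frequency over a whole number of periods, first and last
   periods excluded.
6. **Fit** (`fit_hydrodynamic_length()`): the analytic profile fit to
   the complex amplitude versus position; free parameters $l_\omega$,
   $y_0$, an x-origin offset, and a global phase.
7. **Spectrum** (`build_sweep()`, `classify_regime()`,
   `fit_power_law()`, `drift_test()`).

Each stage is a pure function of its persisted input (TIFF/CSV/JSON),
so any stage can be re-run and verified independently; the
`bundlerheo` command-line script exposes the same chain as
`simulate`/`track`/`analyze`/`sweep` subcommands.

## What the synthetic generator emulates — and what it does not

`render_stack()` draws the analytic steady-state contour as a Gaussian
line profile (PSF sigma 150 nm on 100 nm pixels by default), adds the
bead as a bright disk riding the driven point, integrates each frame
over the camera exposure (8 sub-samples, so motion blur at high drive
frequency is present), applies exponential photobleaching to signal
and bead but not background, then Poisson shot noise, Gaussian read
noise, and 16-bit quantization. Frame timestamps are exposure
midpoints, making motion blur symmetric and phase-neutral.

Deliberate simplifications:

* the contour is the *steady* closed-form solution, so start-up
  transients never enter rendered stacks (the finite-difference solver
  `solve_pde()` exists precisely to check that transients decay and
  the closed form is right);
* bundle thickness is sub-resolution and enters only through line
  brightness and drag, never as a resolvable width;
* no thermal contour undulations: the band-pass would suppress them,
  but their absence means passing tests bound *method* error, not
  thermal noise on real data;
* the bead is a kinematic boundary condition; trap stiffness and force
  are not modeled;
* no bundle merging dynamics: a thicker bundle is represented by a
  changed stiffness parameter between sweeps.

Defaults are chosen as realistic study conditions: drive amplitude
1 µm, frequencies 0.04–2.5 Hz (`default_frequencies()`; at the low end
one period is 25 s, at the high end the 50 ms minimum exposure is a
noticeable fraction of a period), 5 recorded periods, peak signal 150
photons/pixel over a background of 20 with 3 counts read noise, and a
bleach rate of 0.002 s$^{-1}$. The default rod (`default_rod()`,
$\kappa = 6\times10^{-24}$ J·m, 20 µm contour, 60 nm diameter, 50
mPa·s medium) gives $l_\omega$ from ~4.0 µm at 0.04 Hz to ~1.4 µm at
2.5 Hz, so the 25.6 µm field of view always spans at least six decay
lengths.

## Numerical choices

**Acquisition timing.** The frame interval is chosen commensurate with
the drive period (an integer number of frames per period, at most 20,
never shorter than the exposure, camera-bounded below at 60 ms). This
keeps the Fourier projection exact for noiseless sinusoids and mirrors
triggered acquisition; it also caps low-frequency recordings at 100
frames, which matters because photobleaching limits total light.

**Subpixel localization.** The column-wise peak is found by a parabola
fit in a 5 px window around the discrete argmax — applied to the
*logarithm* of the background-subtracted intensities with
intensity-squared weights (the standard weighted-log-parabola Gaussian
peak estimator). On the log scale a Gaussian line profile *is* a
parabola, so the estimator is unbiased at any subpixel shift; a
parabola on the raw intensities over the same window would carry a
bias of order 0.2 px at our PSF width, which the accuracy targets
(0.05 px) would not forgive. Columns with no peak above background
(5 robust standard deviations) are flagged, never interpolated, and
the fit's weighted residual is kept as a per-sample quality measure.

**Band-pass as projection.** The drive frequency is known exactly, so
the "band-pass" is a DFT projection over an integer period count
rather than an IIR/FIR filter: no passband ripple, no phase
distortion, exact orthogonality to DC and harmonics. The excluded
first and last periods play the role of the filter's border-effect
exclusion; a recording must retain at least three full periods after
exclusion.

**Profile fit.** The default fit target is the *complex* amplitude
(amplitude and phase), because the two-wave solution's interference
near the drive is phase-sensitive and the phase slope carries
independent information about $l_\omega$; an envelope-only mode is
provided for data whose phase reference is unreliable. Initial guesses
come from the leading wave, for which $\ln|Y|$ and $\arg Y$ are both
linear in $x$ (slopes $-\tilde S/l_\omega$ and $+\tilde C/l_\omega$);
the optimizer (Levenberg–Marquardt, log-parameterized in $l_\omega$
and $y_0$) is restarted from 0.6× and 1.6× the initial guess and the
lowest-deviance solution kept. The x-origin is free because the bead
exclusion zone removes the columns that would anchor it. Degenerate
inputs are rejected (flat profiles) or flagged (`short_span` when the
usable extent is below two fitted decay lengths, `wide_uncertainty`
when the standard error exceeds half the estimate).

**Finite-difference solver.** `solve_pde()` uses Crank–Nicolson with
second-order central stencils and ghost-node boundary conditions:
prescribed displacement with zero curvature (a torque-free pivot, the
condition the closed form satisfies) at the driven end, force- and
torque-free at the far end. The scheme is unconditionally stable, so
grid limits are accuracy requirements (≥ 10 nodes per $l_\omega$,
≥ 20 steps per period, validated up front). The drive starts as
$y_0\sin\omega t$: continuous with the straight initial rod, so the
slowly relaxing long-wavelength modes (hyperdiffusive decay rate
$\sim D(\pi/L)^4$, far below $\omega$ on a long rod) receive almost no
kick. The first period is discarded as transient by default.

**Classification rule.** The data decide between regimes through
explicit tolerances: $|a + 1/4| \le 0.05 + 2\,\mathrm{se}(a)$ on the
$l_\omega$–$\omega$ exponent $a$ declares WLC; otherwise a
$\kappa_\mathrm{eff}$–$l_\omega$ exponent within the same band of $+2$
declares shear-coupled WLB; anything else stays a free power law.
Sweeps with fewer than four frequencies return `"indeterminate"` —
never a silent default — and sub-decade spans carry a `low_power`
flag. The published observations that thick bundles soften below
roughly 0.2 Hz (5 s periods) is reported as metadata, not used as a
classification input. We note an ambiguity the classification
deliberately sidesteps: $\kappa_\mathrm{eff}\propto\omega^{-1/2}$
combined with the identity $\kappa_\mathrm{eff}=l_\omega^4\omega$
implies $l_\omega\propto\omega^{-3/8}$, while
$\kappa_\mathrm{eff}\propto l_\omega^{2}$ implies
$l_\omega\propto\omega^{-1/2}$; rather than privileging one chain of
reasoning, all three fitted exponents are reported and the WLB label
keys on the $\kappa_\mathrm{eff}$–$l_\omega$ exponent, which is the
directly mechanistic statement.

## Validation problem sizes

The test suite validates the pipeline at two scales, chosen to keep a
full run comfortably interactive: unit tests use a 128×64 px field
with a 10 µm bundle at 1 Hz (a render-track-fit cycle takes well under
a second), while end-to-end checks use the full 256×128 px study
conditions — a noiseless 8-frequency sweep for the $-1/4$ exponent
(recovered within ±0.02) and 20 seeded default-SNR sweep replicates
for κ_eff recovery (median relative error well under 15%) and
classification stability (≥ 95% WLC calls on constant-κ data). The
finite-difference comparison runs on a 20 µm rod (≈ 11 decay lengths)
with 15 nodes per $l_\omega$ and 120 steps per period, where the
steady-state L2 discrepancy from the closed form is below 1% of the
drive amplitude after one discarded transient period.

## Known limitations

* The tracker assumes exactly one roughly x-aligned contour per stack;
  crossing or strongly tilted bundles are out of scope (real
  recordings with non-orthogonal bundles should be excluded upstream).
* The complex-profile fit assumes the semi-infinite solution; rods
  shorter than about two decay lengths are flagged rather than fit
  with a finite-length model.
* Thermal persistence-length estimation from passive fluctuations is
  intentionally absent — this package implements the active method
  only.
* The drag model is the rigid slender-rod result; end effects and
  wall proximity corrections are not modeled and fold into
  $\kappa/\zeta$ rather than being separated.
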