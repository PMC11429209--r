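---
title: "Monofilament mechanics and verification methodology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monofilament mechanics and verification methodology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(monofil)
```

## The device and the problem

The 10 gf Semmes--Weinstein monofilament is a calibrated nylon filament
pressed perpendicularly against the plantar skin until it buckles. Euler
column theory makes it a force-limiting device: once the axial load
reaches the critical buckling force, further displacement bends the
filament instead of increasing the force on the skin, so the patient
receives a nominally fixed 10 gf stimulus. A patient who cannot feel it
has lost protective sensitivity and is at risk of diabetic foot
ulceration. In practice commercial filaments deviate substantially from
their rating, so the delivered force -- not the label -- is what needs to
be known. This package models that force analytically and provides the
statistical machinery of a metrological verification workflow.

## The mechanical model

**Buckling.** The filament is a slender circular column of diameter $d$
and length $L$ with second moment of area $I = \pi d^4 / 64$. The
critical force is

$$F_c = \frac{\pi^2 E I}{L_e^2}, \qquad L_e = k L,$$

where $E$ is the Young's modulus of the nylon and $k$ the effective-length
factor of the end supports. The handle end is always clamped; the skin
contact is pinned without slippage in the normal test ($k = 0.7$) or
pinned-and-sliding when the skin is too slick to hold the tip
($k = 2.0$). Since $F_c \propto 1/k^2$, slippage cuts the delivered force
to $(0.7/2)^2 = 12.25\%$ of the calibrated value -- the largest single
error source in the model. The fourth-power dependence on $d$ means a 10%
diameter tolerance moves the force by roughly 40%.

```{r buckling}
g <- monofilament(diameter = 0.61, length = 38)  # mm
fc <- critical_buckling_force(g, young_modulus = 2e9)
c(newtons = fc, gramforce = newton_to_gramforce(fc))
```

A filament with a typical nylon modulus of 2 GPa and this common geometry
delivers 19.33 gf -- nearly twice its 10 gf rating.

**Inverse estimation.** Manufacturers rarely state the material. Solving
the same equation for $E$ turns a bench-measured critical force into a
modulus estimate, $E = F_c L_e^2 / (\pi^2 I)$, an exact algebraic
inverse (round-trip identity is property-tested to $10^{-12}$ relative
error).

**Self-weight deflection.** Held horizontally, the filament droops under
its own distributed weight $w = V \rho g$ like a uniformly loaded
cantilever. The small-deflection closed form is

$$\delta = \frac{w L^3}{8 E I} \equiv \frac{q L^4}{8 E I},
\quad q = w/L,$$

valid while $\delta < L/10$ (flagged in the result). The relative change
of $\delta$ under geometric tolerances is material-independent:
$(1+\Delta_L)^4 / (1+\Delta_d)^2 - 1$, which is the closed-form oracle the
tolerance table is tested against.

**Environmental corrections.** Nylon softens with temperature and
absorbed moisture. Both are modelled as first-order linear corrections
about a manufacturer-declared reference state, $E(T) = E_0 (1 - \alpha (T
- T_0))$ and $E(H) = E_0 (1 - \beta (H - H_0))$. When both are supplied,
`modulus_at_environment()` composes them multiplicatively,
$E_0 (1 - \alpha \Delta T)(1 - \beta \Delta H)$: the two single-variable
laws are never stated jointly, so the composition is this package's
convention -- it reduces to either law when the other coefficient
vanishes and agrees with the additive form to first order. The
coefficients $\alpha, \beta$ have **no defaults**: they vary strongly
between nylon grades, and silently assuming one would defeat the purpose
of a calibration tool. Operations needing them fail loudly.

## Parameter choices and numerical conventions

- **Standard gravity** is fixed at 9.80665 m s$^{-2}$; it defines the
  gram-force and is not configurable.
- **Units.** All internal quantities are SI (m, N, Pa, kg m$^{-3}$);
  constructors and results accept/offer mm, gf and GPa because datasheets
  and clinical practice use them.
- **Density** defaults to 1140 kg m$^{-3}$ for extruded Nylon 6.6. The
  literature quotes 1100--1150 for this family; 1140 is the value that
  makes the package's deflection predictions consistent across the
  published reference cases we reproduce (81.81 µm for the 0.46 mm ×
  41 mm filament at 3.65 GPa; 55 µm for 0.71 mm × 38 mm at 1.68 GPa).
  Any other density can be passed explicitly.
- **Slenderness guard.** Euler theory assumes a slender column. The
  package warns (but still computes) when $L_e / (d/4) < 30$; the theory
  itself gives no sharp bound, and typical monofilament geometries sit
  near 170.
- **Display rounding** mirrors the bench instrument: one decimal below
  100 gf, whole units from 100 to 500 gf, half-away-from-zero, with range
  classification applied after rounding (99.96 → 100) and an overload
  error above 500 gf. Ties falling exactly on .05 follow the binary
  floating-point representation of the input.

## Curve and fatigue metrology

A measured compression cycle has a linear ramp followed by a buckling
regime. `extract_features()` reports the global maximum as the critical
force (the convention also used for per-cycle fatigue series), the mean
over the final 20% of the displacement span as the plateau force, the
least-squares slope of the leading samples as the initial stiffness, and
the first point where the centred-difference local slope drops below 20%
of that stiffness as the buckling breakpoint. The slope-drop window and
threshold are configurable; the two regimes are identified visually in
bench practice, so any numerical breakpoint rule is a convention and this
one is deliberately simple (no smoothing or spline fitting). A curve
whose slope never drops is flagged `no buckling detected` rather than
given a fabricated breakpoint.

`analyze_fatigue()` summarises per-cycle critical forces over repeated
compressions: first-cycle force, plateau mean/SD from cycle 3 onward
(most filaments settle after the second compression), percent decay, and
a monotone-decay flag with a 0.1 gf tolerance -- the instrument's display
resolution -- so that display-quantised series still count as monotone.

Verification verdicts compare a measured force (curve plateau or peak,
fatigue plateau or first cycle) against the nominal rating with a
symmetric, boundary-inclusive band, default ±10%. No standards body
currently fixes an acceptance band for monofilaments; the band is
therefore explicit in every report and configurable.

## Agreement statistics

Instrument validation compares a candidate force sensor against a
calibrated reference over repeated rounds at several reference points.
`bland_altman()` reports the bias (candidate − reference; the direction
is fixed and documented in the output), the sample SD of differences
(n − 1 denominator), and limits of agreement at ±1.96 SD, with no
small-sample t correction -- the conventional form of the method. The
per-reference-point summary and the mean relative error complete the
validation report.

## What the synthetic generators emulate -- and what they do not

The generators stand in for the motorised bench so every analysis
operation is testable without hardware:

- `generate_curve()` produces the two observed curve morphologies: a
  linear ramp at a set stiffness to the critical force, then either a
  flat plateau (overshoot 0) or an exponential relaxation toward
  `critical/(1+overshoot)` with a displacement constant of 10% of the
  span. The decay shape of real devices is not parameterised anywhere in
  the literature; the exponential with a fixed 10%-of-span constant is a
  modelling choice, exposed through the spec. Samples lie on the 0.08 mm
  stepper grid over a 10 mm span (the bench protocol), so the sampled
  peak equals the nominal critical force exactly only when
  `critical_force/initial_stiffness` falls on the grid; round-trip tests
  use on-grid breakpoints.
- `generate_fatigue()` decays exponentially from a first-cycle force to a
  plateau over 20 cycles, the bench protocol length.
- `generate_pairs()` adds a systematic bias and Gaussian noise to true
  forces, with an optional multiplicative jitter uniform on [1, 1.25]
  emulating the validation protocol's randomised reference points.
- Noise is additive Gaussian, clipped at zero, default SD 0.03 gf -- the
  instrument's stated precision below 100 gf. Forces can optionally pass
  through `display_round()` to emulate the reported resolution.

All generators are pure functions of their spec including the seed, and
they restore the caller's RNG state.

What passing these tests shows is that the *analysis pipeline* recovers
known ground truth under the stated noise model. Real bench data carry
features the generators deliberately omit: viscoelastic rate dependence
(the bench runs at 4 and 8 mm s$^{-1}$ and sees different overshoot),
manufacturing bimodality across device fleets, memory effects between
sessions, and transducer drift. Bench-measured quantities -- the
reference-point mean/SD tables, a fleet's measured force contours and
its ~0.28% mean relative error -- are properties of physical
instruments, not reproducible by this package; the generators emulate
their morphology so that the statistics that would be applied to them
are exercised end to end.

## Problem sizes and test design

The test suite regenerates every fixture in code: property tests loop
over 10--25 random geometries per law at fixed seeds; noisy-recovery
tests use curves of ~125 samples, 20-cycle fatigue series and up to
10^4 simulated measurement pairs, with statistical tolerances at
3σ/√n. The whole suite runs in a few seconds on one CPU. Deterministic
closed-form results are asserted at the precision the reference values
are printed with (e.g. forces to 0.005 gf); one forward-computed force is
asserted at ±0.031 gf because its printed 3-significant-figure modulus
input carries exactly that propagated half-ulp uncertainty.

## Known limitations

- Post-buckling shape (elastica), finite-element analysis, viscoelastic
  creep and moisture-diffusion kinetics are out of scope; the model is
  linear-elastic with small deflections.
- The linear environmental corrections are first-order empirical laws;
  far from the reference state they can predict non-physical moduli, and
  the package errors rather than extrapolating to $E \le 0$.
- Whether an overshooting curve implies a different effective boundary
  condition is an open question in the field and is not modelled.
- Deterministic sweeps only: the tolerance table and force grid do not
  sample manufacturing variation stochastically.
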