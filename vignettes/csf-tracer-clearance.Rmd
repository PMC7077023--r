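---
title: "Modelling CSF tracer clearance under filtration and lumbar drainage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling CSF tracer clearance under filtration and lumbar drainage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csfclear)
```

## The problem

After a subarachnoid haemorrhage, blood spreads through the cerebrospinal
fluid (CSF) of the cranial and spinal subarachnoid space (SAS). Two bedside
interventions compete for clearing it: a passive lumbar drain, which
withdraws CSF slowly at the lumbar spine, and dual-lumen filtration
("Neurapheresis") therapy, which aspirates CSF at the lumbar spine, filters
it, and returns it at the upper thoracic spine. `csfclear` provides a
desk-scale, one-dimensional model of this comparison: a blood-surrogate
tracer, initially mixed uniformly at a 10% volume fraction through a
321.9 mL CSF space, is cleared over 24 hours while cardiac-driven
oscillatory CSF motion provides the background transport.

The model follows the frozen-flow-field idea: the oscillatory velocity
field is not resolved in time during the transport solve. Its cycle-mean
residue — steady streaming — is what moves solute on the hour scale, and
the package represents it through a calibrated axial profile
`U_ss(z)` plus closure terms described below. Molecular diffusion is
excluded; for the large molecules of interest it is orders of magnitude
weaker than streaming, which the dispersion similitude analysis (below)
makes quantitative.

## The synthetic neuroaxis

No geometry accompanies this package; `neuraxis_profile()` generates a
subject-like stand-in. The axial coordinate has its origin at the foramen
magnum, positive cranial; the neuroaxis spans 75.6 cm in total with a
15 cm cranial extent. Piecewise-smooth parametric segments (cranial dome
with a ventricular bulge near +5 cm, cervical enlargement, thoracic taper,
lumbar narrowing, caudal thecal sac) are scaled so the integral targets
hold exactly:

* spinal SAS volume 100.3 mL, intracranial CSF 221.6 mL (total 321.9 mL),
* spinal-mean hydraulic diameter 5.87 mm,
* a local maximum of hydraulic diameter at the foramen magnum, and the
  largest areas/perimeters in the cranium.

Only integral quantities are constrained — the pointwise curves are a
design choice, not data — so analyses downstream should rely on the
integral targets only, which is what the calibration and the acceptance
checks do. Overall means come out at ~6.2 mm hydraulic diameter and
4.26 cm² area; the mean perimeter (~25 cm) is whatever the area and
diameter shapes imply, and we chose not to add a degree of freedom to pin
it independently. `compartment_volumes()` carries the compartment-level
bookkeeping (total spinal CSF = dura − cord − nerve roots, and the
four-way intracranial sum).

The cardiac waveform `cardiac_waveform()` is a zero-mean two-harmonic
signal, `sin θ + c cos 2θ`, with `c` solved so the caudal (systolic) peak
exceeds the cranial (diastolic) peak in the ratio 4.7/2.8 — the ratio of
the lumbar peak mean velocities the model is calibrated to. Its amplitude
is set so the peak systolic mean velocity over the spinal slices is
−4.7 cm/s; with the default geometry that gives a stroke amplitude of
about 4.5 mL/s at ω = 2π/0.9 s ≈ 6.98 s⁻¹. The cycle mean is zero by
construction: net flows enter the model only through the therapy ports.

What the generator does *not* emulate: nerve roots and cauda equina as
discrete obstacles (they act only through the area/perimeter profiles),
dural compliance, posture and spine curvature, and any subject
variability beyond an optional smooth seeded perturbation (`jitter`).
Tests passing on this geometry therefore validate the machinery and the
calibrated comparison, not anatomical fidelity for any individual.

## Hydrodynamic characterisation

`characterize_hydrodynamics()` reports, per slice, the Reynolds number
`Re = |Q| D_H / (ν A)`, the Womersley number `α = (D_H/2)√(ω/ν)`, and the
signed peak mean velocities `Q/A`. The oscillatory amplitude is carried in
full from the caudal inlet to the foramen magnum (a rigid model forces a
uniform flow rate at every spinal cross-section) and tapers linearly to
2% across the cranium toward the outlet, so the smallest mean velocities
occur in the cranial SAS. The taper fraction is a parameter; the true
cranial flow partition is three-dimensional and is not modelled. Note one
averaging subtlety: the mean of the pointwise Womersley profile differs
from the Womersley number evaluated at the mean hydraulic diameter;
`hydro_summary()` reports both conventions.

## Dispersion similitude

`similitude_table()` evaluates the order-of-magnitude shear-augmented
dispersion chain for oscillatory flow,

$$Sc = \nu/D,\qquad
  \beta^2 = (L/2)^2\,\omega/D,\qquad
  \alpha^2 = \beta^2/Sc,\qquad
  R_{max} = P^2 Sc/\alpha^2,\qquad
  \mathbf{D} = (1+R_{max})\,D,$$

for the four combinations of region (cortical SAS, characteristic gap
L = 2 mm; spinal SAS, L = 5.87 mm) and species (fluorescein tracer,
D = 4.25×10⁻¹⁰ m²/s; hemoglobin, D = 1.02×10⁻¹⁰ m²/s), with the
non-dimensional pressure parameter P = 152.6 adopted from the
oscillatory-dispersion literature and overridable per case. The momentum
diffusivity is that of water at room temperature, ν = 0.89×10⁻⁶ m²/s, as
used in the reference analysis (the `csf_fluid()` object derives
μ/ρ = 8.915×10⁻⁷ m²/s; the small difference matters because R_max scales
with Sc², so the stated ν is the default for this module).

Because `R_max · D = P²ν/α²` contains no molecular diffusivity, the
effective diffusivity is species-independent once `R_max ≫ 1` — the
similitude argument for using a fluorescein tracer as a surrogate for
hemoglobin. The table checks this numerically (< 2% between species in
each region).

The Sherwood number `Sh = hL/𝐃` is provided with the convective scale `h`
as an explicit argument, because two conventions circulate: a
peak-systolic velocity scale and a much smaller cycle-mean (streaming)
scale. Both are selectable; neither is privileged by the package.

## Steady streaming and the transport closure

`uss_profile()` implements the cycle-mean quantification for gridded
periodic fields: per cell, the arithmetic mean over one cycle of equally
spaced samples; per slice, the volume-weighted average of the *absolute*
cycle means (magnitude before averaging, so opposing anterior/posterior
currents do not cancel), and `qss_profile()` its non-dimensional form
`U_ss A / (2 Q_peak)`.

Computing streaming from first principles requires the nonlinear 3-D
oscillatory problem, which is out of scope. `parametric_streaming()`
instead builds `U_ss(z)` from summary structure: a plateau between the
aspiration (−44 cm, L2) and return (−15 cm, T2) ports whose mean is
imposed exactly — 0.37 mm/s under Neurapheresis therapy, 0.23 mm/s under
lumbar drain, a 60% enhancement attributable to the filtration flow
loop — a 0.15 mm/s baseline elsewhere in the spine, and a cranial level
attenuated 50-fold relative to the spinal mean. Port flows are spread
over Gaussian kernels of 1 cm half-width (physical catheters distribute
flow over a finite hole span), and the net continuity flow is obtained by
integrating the source densities, vanishing at both closed ends.

A one-dimensional frozen field cannot carry two pieces of 3-D physics,
and the closure in `transport_closure()` names them explicitly:

1. **Bidirectional streaming cannot advect net mass in 1-D.** Its mixing
   action is modelled as axial dispersion,
   `D_mix(z) = k_mix · U_ss(z) · D_H(z)`, the standard velocity-times-
   length closure. `k_mix` is fixed a priori at 0.05 — a few per cent
   mixing efficiency, consistent with the weak effective axial dispersion
   implied by slow clearance despite centimetre-per-second oscillatory
   velocities — and is deliberately *not* fitted, so that it cannot
   absorb arm-specific behaviour.

2. **The slow production-to-sink continuity flow does not sweep the whole
   cross-section.** CSF produced in the ventricles reaches the spinal
   canal through the basal cisterns and descends along preferential
   pathways. Treating the full 0.2 mL/min as a plug flow over the whole
   cross-section would deliver tracer to the drain at the upstream
   concentration all day and overshoot the observed clearance of a
   0.2 mL/min lumbar drain by a wide margin (a well-mixed tank with this
   throughput already ends at 4.1%; a plug column clears even more). The
   closure therefore injects only a fraction `sweep_efficiency` of the
   production flow into the 1-D column — at the foramen magnum, where
   cisternal outflow enters the spine — and routes the remainder as a
   clean shunt directly to the active sink. The aspiration/drain
   withdraws the swept part at the local concentration.

3. **Cranial mixing is not streaming-limited.** Cisternal and cortical
   recirculation exchanges cranial CSF with the foramen magnum region
   more effectively than the 50× attenuated streaming level would
   suggest; an additional cranial mixing coefficient `d_cranial` (m²/s),
   smoothly switched on above the foramen, represents it.

`sweep_efficiency` and `d_cranial` are calibrated by
`calibrate_transport()` against the *lumbar-drain arm only*: the global
24-h endpoint (6.5%) pins `sweep_efficiency`, the cranial 24-h endpoint
(6.6%) pins `d_cranial`. Both solves are monotone with wide brackets and
are alternated three times to resolve their weak coupling; the achieved
residuals are stored on the returned closure object. The Neurapheresis
arm is then a genuine prediction — nothing in its configuration is
fitted — and the test suite checks it against the reference 4.9% ± 1.0
percentage point, along with the monotone ordering (filtration below
drain at every stored time from one hour on). With these closures the
cranial endpoints of the two arms come out nearly identical, as they
should, since the arms differ only below the foramen magnum. One known
casualty of closure (2): because the swept production flow enters at the
foramen rather than traversing the cranium, cranial clearance is carried
entirely by `d_cranial`, and the *spatial* pattern of cranial clearance
is homogenised rather than advective.

## The finite-volume solver

`simulate_transport()` advances the tracer volume fraction on the slice
grid (default 3 mm) with:

* first-order upwind advection of the net bulk flow (the same
  discretisation family as the reference computation used for its volume
  fraction equation),
* backward-Euler conservative diffusion for `D_mix`, solved by a
  pre-factorised tridiagonal (Thomas) algorithm — unconditionally stable,
  exactly conservative (column sums of the implicit operator are one),
  and sign-preserving, so the explicit time step is limited only by the
  advective CFL condition and port withdrawal rates,
* port exchange: withdrawal at the local concentration, injection at the
  return concentration (0 = ideal filtration).

The default step is 0.5 s, reduced automatically to satisfy `CFL ≤ 0.9`
and to divide the 5-minute snapshot cadence (chosen to mirror bench-top
time-lapse imaging). The compiled kernel and a pure-R reference stepper
implement identical semantics; tests hold them to 10⁻¹³ of each other,
and the discrete bookkeeping (in-domain tracer + removed − injected =
initial) closes to ~10⁻¹³ relative over a full 24-h run. Degenerate
inputs behave sensibly: a single-cell domain reduces to the stirred-tank
ODE, zero-rate therapy leaves the field untouched, and a zero-duration
run returns the initial state only. In the strong-mixing limit the global
concentration follows the closed-form washout
`0.1·exp(−Q_asp t/V)` to 1% at 6 h; halving the grid spacing moves the
24-h endpoint by less than 0.2 percentage points.

Problem sizes: 252 cells × 172 800 steps for a 24-h arm (about a second
in the compiled kernel); the closure calibration performs ~70 such runs.

## Imaging emulation and agreement

`synthesize_stack()` renders a concentration field as a 16-bit-style
grayscale stack: static fixed-pattern background, signal
`gain · α · e^{−rt}` with a shared photobleach rate, additive Gaussian
pixel noise, and a quadratic axial lens warp of the pixel-to-position
mapping (the camera geometry, i.e. the corrected positions, is stored
with the stack, as it would be known from the bench setup). A baseline
vial at a known reference concentration is imaged alongside.
`quantify_stack()` inverts this: `α = ref · (I − I₀)/(I_b(t) − I₀)` with
the baseline interpolated from a log-linear single-exponential fit
(`baseline_decay_fit()`), then row-averaged and binned into 3-mm slabs
using the corrected positions. Whether `ref` is the baseline-vial
fraction or the initial fraction is a pure rescaling; the emulator
defaults to 0.1 so quantified maps share the transport model's scale.
With ideal optics and one pixel column per grid cell the quantification
is algebraically exact, which ties the image-side slab averaging to the
volume-weighted axial averaging of the field.

`agreement_stats()` compares two spatio-temporal maps: ordinary
least-squares of B on A (optionally through the origin — both regression
conventions are exposed) and Bland–Altman bias with 95% limits of
agreement `bias ± 1.96·SD` of the paired differences, the usual reading
of "95% confidence interval" dashed lines on such plots. `tidy()`,
`glance()` and `autoplot()` methods give tibble summaries and the
scatter/Bland–Altman panels.

## Limitations

The model is one-dimensional and frozen-field: no 3-D concentration
structure, no intra-ventricular oscillatory flow, no dural motion or
tissue uptake, no blood rheology or breakdown-product chemistry, and a
rigid constant-volume domain in which the 30° patient tilt is metadata
only (tracer and CSF share a density, so gravity cannot separate them
here). The closure constants are effective parameters calibrated at one
operating point; extrapolation to other drain rates, port positions or
pathologies should recalibrate against data for those conditions. The
parametric streaming profile carries only printed summary structure —
plateau means, baseline, cranial attenuation — not the full spatial
pattern of a resolved streaming field.
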