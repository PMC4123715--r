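---
title: "Thermodynamic gating: model, measurement pipeline and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermodynamic gating: model, measurement pipeline and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermogate)
```

## The scientific question

Heat-gated TRP-type channels open steeply with temperature (Q10 well above
20) over a broad voltage range, while classical voltage-gated potassium
channels appear only mildly temperature-sensitive (Q10 of 2–4).  Yet the
two families are structural homologues.  The hypothesis this package
operationalizes is that the pore-opening step itself carries a very large
enthalpy and entropy change in both families, and that in strongly coupled
voltage-gated channels this intrinsic heat sensitivity is *masked* by the
voltage sensor's obligatory control of the gate.  Anything that loosens the
coupling — depolarization that saturates the sensor, closed-state
inactivation, point mutations in the S4/S4–S5 region — should unmask a
large (or, for a sign-flipped transition, inverted) temperature
coefficient in a narrow voltage window at the foot of activation.

## The model and its assumptions

Every transition is an equilibrium two-state step with
\(K(V,T) = \exp\{-(\Delta H - T\Delta S - zFV)/(RT)\}\).  The channel is a
four-state allosteric scheme: states C, C′, O, O′ with weights
\(1, J, L, J\,L\,D\), where \(J\) is the voltage-sensor equilibrium
constant, \(L\) the pore-opening constant and \(D \ge 0\) the dimensionless
coupling factor.  Open probability is \(p_O + p_{O'}\); the mean gating
charge \(z_J(p_{C'}+p_{O'}) + z_L(p_O+p_{O'})\), min–max normalized, gives
the model Q-V curve.

Assumptions worth stating explicitly:

* **Equilibrium only.**  Heating at ~0.3 °C/s is slow relative to gating
  kinetics, so occupancies are evaluated from statistical weights at every
  sample; no rate constants exist anywhere in the package.  Non-equilibrium
  phenomena (ramp-rate artefacts, inactivation kinetics) are out of scope.
* **One effective voltage sensor.**  The scheme collapses the four
  subunit sensors into a single transition with an effective charge; the
  apparent charge \(q\) of a Boltzmann G-V fit is an effective quantity in
  the same sense, which is why fitted \(q \to z_J\) in the strong-coupling
  limit.
* **Closed-state inactivation as multiplicative availability.**  CSI is
  analysed in steady state as a falling Boltzmann of the conditioning
  voltage multiplying the activation curve, not as extra Markov states.
  This matches how triple-pulse (P1/P2/P3) data are reduced: availability
  = P3/P1.  Whether the activation curve should be multiplied by
  availability or by its complement is a genuine ambiguity; the package
  multiplies by availability as plotted, with
  `combined_probability(..., use_inactivation = TRUE)` exposing the
  alternative.

Units: SI internally (J/mol, J/(mol·K), volts, kelvin); all interfaces
speak mV, °C, pA, nS.  Constants are pinned at R = 8.314 J/(mol·K) and
F = 96485 C/mol; charge in e0 is a per-mole quantity (it multiplies F).
Configs may declare kcal/mol (×4184) or kJ/mol with an explicit unit tag;
nothing is converted silently.

## The shipped parameterizations

No printed parameter set exists for this four-state scheme, so the presets
are chosen to reproduce published *observables* — apparent charges,
midpoints and the bound-type Q10 claims — not to be unique fits:

| preset | key choices | phenotype |
|---|---|---|
| `trpv1_like` | two-state, ΔH = 510 kJ/mol, ΔS = 1.58 kJ/(mol·K), z = 0.76 | heat-gated over a broad range; G-V midpoint ≈ 115 mV near 44 °C |
| `shaker_like` | z_J = 5.1, ΔH_J = 88 kJ/mol, ΔS_J calibrated; ΔH_L = 418 kJ/mol, ΔS_L = 1.34 kJ/(mol·K), z_L = 0, D = 10⁴ | steep G-V at −54.2 mV (24 °C), mean Q10 < 4 |
| `ilt_like` | D = 5, sensor midpoint −20 mV (25 °C) | decoupled, Q10 peak ≫ 20 |
| `v2_like` | ilt_like with ΔH_L, ΔS_L sign-flipped | heat-deactivated, Q10 < 1 |
| `kv21_like`, `kv43_like` | D = 20 plus availability curves (−55 mV/3.5 e0 and −65 mV/4 e0) | partial decoupling via CSI |

The sensor entropy of `shaker_like` (373.84 J/(mol·K)) is the one
calibrated quantity: it is solved once, by root-finding on the noiseless
model G-V, so that the half-activation voltage at 24 °C equals −54.2 mV.
The 4-state scheme cannot jointly reproduce every published number; where
tension exists the midpoint/charge observables won.  One consequence worth
knowing: with the sign-flipped pore transition of `v2_like`, the open
state is intrinsically favoured (\(L \approx 1.7\times10^3\) at 25 °C), so
its open probability never falls below ≈ 0.999 at room temperature — the
"substantially open" voltage used for its Q10 is therefore the grid
voltage whose open probability is closest to 60%, and the measured
heat-deactivation coefficient (≈ 0.88 per 10 °C) is modest because the
probability is saturated.  The sign-flip realization itself is one
admissible hypothesis, deliberately kept as the exact mirror of the
heat-activated transition.

The CSI availability midpoints/charges and the patch-level defaults
(100 channels, 10 pS at 22 °C, 0.5 pA noise, 0.05 nS leak) are fixture
choices at realistic magnitudes for macroscopic inside-out patches, not
claims about any particular recording.

## What the generator emulates — and what it does not

`synthesize_sweep()` composes, per 10 kHz sample:
channel current \(N P_o(V,T)\gamma(T)(V-V_{rev})\) with
\(\gamma(T) = \gamma_{ref}\cdot 1.5^{(T-22)/10}\), ohmic leak reversing at
0 mV, and additive Gaussian noise.  The reversal potential follows the
Nernst relation from the configured solutions at the sample temperature.
Temperature tracks are linear ramps (default 0.3 °C/s) with optional delay
and ceiling; commanded voltages reproduce segment endpoints exactly, and a
given seed reproduces a record byte for byte.

Not emulated: capacitance transients, series resistance, perfusion
kinetics, channel-count (binomial) fluctuations, open-channel rectification
(driving force is strictly ohmic), and any binary acquisition format.
Passing round-trip tests therefore demonstrates the *pipeline's*
correctness on data satisfying the model's assumptions — it does not show
that real recordings are free of these artefacts, and leak subtraction in
particular inherits a real confound (below).

## Numerical and procedural choices

* **Overflow.**  State weights are accumulated in log space with
  max-subtraction; the evaluation is exact for exponents to ±700, checked
  to ±500.  Model Q10 at voltages where the colder open probability falls
  below 10⁻¹² is reported as undefined (`NA`), never as infinity.
* **Boltzmann fitting.**  Three free parameters (V₁/₂, q, Gmax) by
  Levenberg–Marquardt with deterministic initialization — midpoint from
  the half-maximum crossing by linear interpolation, charge from the
  maximal normalized slope via \(q = 4(RT/F)\,\max dG/dV\), Gmax from the
  top-plateau mean — followed by a second pass on conductances normalized
  to the first-pass Gmax.  No random restarts; a flat curve or a
  non-converged fit returns a flagged result carrying the initial values.
  Negative conductances are clipped to zero for fitting but retained in
  the data.
* **Q10 threshold rule.**  The activation threshold T₁ is the first
  0.5 °C temperature bin whose mean current departs from the pre-heating
  baseline by more than 3 baseline standard deviations.  Amplitudes I₁, I₂
  and the reported T₁, T₂ are means over 0.5 °C windows, so the identity
  \(Q_{10} = (I_2/I_1)^{10/(T_2-T_1)}\) holds exactly on the reported
  fields; with the window shrunk to a point the measurement reproduces
  closed-form values to machine precision.  The default interval is 10 °C
  with a 5 °C variant for channels that inactivate on further heating.
* **Q10 profile grids.**  The warmer G-V is linearly interpolated onto
  the colder curve's voltages; no extrapolation.  Profiles use
  conductance-corrected curves; using raw currents instead would fold the
  single-channel factor (≈1.5 per 10 °C) into every value.
* **Van't Hoff normalization.**  In the synthetic world the true
  \(N\gamma(22\,°C)\) is the open-probability normalization.  The fit is
  restricted to the regime where the channel opens a few percent: at the
  bottom of the range the leak estimate is contaminated by the equilibrium
  open background at the holding potential (the decoupled pore is open
  with probability \(L/(1+L)\) even at −100 mV), which is a genuine
  experimental confound, not a code artefact.  Restricting to ≈1–10% open
  probability keeps the recovered ΔH, ΔS within 5% at the default noise.
* **Ramp G-V.**  Instantaneous conductance per sample, voltage-binned at
  2 mV, with a 5 mV guard band around the reversal potential where the
  quotient is unstable.
* **Seeds.**  Every generator takes an integer seed, restores the
  caller's RNG state afterwards, and logs the seed in sweep metadata and
  run manifests.

## Problem sizes

The shipped experiments are desk-scale by design: step families of 12
voltages × 150 ms at 10 kHz, heating sweeps of 20–30 °C at 0.3 °C/s
sampled at 2 ms, 3–5 replicate patches per recovery experiment, and
10,000-draw property sweeps for the occupancy oracle.  The full test suite
and the reference computations each complete in well under a minute.

## Known limitations

* The four-state scheme cannot represent dual-allosteric modulation (for
  instance Ca²⁺-and-voltage gated channels); such behaviour is only
  mimicked qualitatively by moving J and D.
* Apparent charges near the decoupled limit are small-signal: with D close
  to 1 the G-V flattens and fits legitimately return failure codes.
* The Q10 threshold detector assumes a monotone activation (or
  deactivation) during heating; non-monotone currents (activation followed
  by inactivation) would need the 5 °C interval and a truncated sweep.
* Availability fitting mirrors the voltage axis and reuses the rising
  Boltzmann fitter; it assumes a single inactivation component.
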