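---
title: "The memristive integrate-and-fire neuron: model, calibration, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The memristive integrate-and-fire neuron: model, calibration, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memlif)
library(dplyr)
```

## The model

The leaky integrate-and-fire (LIF) neuron is a capacitor `C` charged by an
external current `I_ext` through a leak resistor `R`:

    tau dV/dt = -(V - V_rest) + R I_ext,    tau = R C.

When `V` reaches the threshold `V_th`, the simulator emits a stereotyped
action potential: the crossing sample is displayed at the peak `V_spike`
(20 mV) and the next sample is reset to `V_reset` (-80 mV). The peak sample
is cosmetic and excluded from the Euler update, which continues from the
reset value.

The memristive variant (MLIF) replaces the fixed leak resistor with a
flux-controlled memristor. The device's memristance `M` is a piecewise-linear
function of its accumulated flux: `M_max` (20 kOhm) below the lower
breakpoint (-0.75), `M_min` (100 Ohm) at and above the upper breakpoint
(0.25), and the unique straight line through those two corner points in
between. This construction deserves a note: the published linear middle
segments for this device family do not meet the published endpoint values at
the published breakpoints (for the charge-controlled variant the printed
intercept gives 19 950/50 Ohm instead of 20 000/100 Ohm; for the
flux-controlled variant the printed coefficients are on a scale four orders
of magnitude away from the bounds). We therefore define the middle segment by
continuity — the line through `(s_lo, M_max)` and `(s_hi, M_min)` — which
preserves the printed bounds, the printed charge-law slope (-1.99e8), and
continuity, all of which the downstream simulations depend on. The same
reasoning applies to the printed closed forms for the time constant and the
charge–flux map, which are dimensionally inconsistent; the package computes
`tau_M = M(t) C` with a constant capacitance and obtains state relations by
numerical integration.

In the MLIF membrane equation, `M` takes the role of `R` both in the time
constant and in the input coupling:

    tau_M dV/dt = -(V - V_rest) + gain * M I_ext,    tau_M = M C,

and the device flux integrates the membrane drive `V - V_rest`. Because the
device starts at a large memristance and depolarized episodes push the flux
up (lowering `M`), a sustained drive produces a dense initial burst whose
rate declines as `M I_ext` sinks toward the threshold margin — spike-frequency
adaptation emerges from the device physics, with no explicit adaptation
variable.

## Units and the input-coupling convention

Simulations run in model units: millivolts, milliseconds, nanoamperes,
resistances in ohms. These are mutually consistent for the LIF: 1 MOhm x 2 nF
gives `tau` = 2 ms, and `R[MOhm] * I[nA]` is exactly millivolts. They are
*not* sufficient for firing at the printed device values: in strict SI,
20 kOhm x 1.5 nA is 30 microvolts, which can never bridge the 15 mV gap
between rest (-65 mV) and threshold (-50 mV), for either model. Since the
source experiments clearly fire, the package adopts a dimensionless input
gain:

* **LIF**: `u = gain * R[MOhm] * I[nA]` mV with default gain 12, chosen to
  bracket the 15 mV threshold gap — a 1.0 nA drive is subthreshold (12 mV)
  and a 1.5 nA drive suprathreshold (18 mV), reproducing the
  silent-vs-firing contrast between those two amplitudes.
* **MLIF**: `u = gain * M[kOhm] * I[nA]` mV with gain 1, i.e. the
  kilo-ohm-times-nanoamp product read directly in millivolts.

A strict-SI mode (`input_scale = "si"`) is provided for completeness and is,
as the arithmetic above predicts, non-firing at the printed values.

The resting potential merits one paragraph. The point-neuron section of the
source model states -60 mV while the zero-input experiments, the cable
table, and the Morse application all use -65 mV. The package defaults to
-65 mV: beyond matching most of the printed material, the adaptation
mechanism requires it. The flux gained per firing cycle is the integral of
`V - V_rest` over the cycle; with rest at -60 mV (a 10 mV threshold gap over
a 20 mV reset depth) that integral is negative and the device never adapts,
while with rest at -65 mV it is positive and the adapting phenomenology
follows. Both parameterizations are available through `neuron_params()`.

## Calibrated constants

Three constants are calibrations this package fixes once, because the source
material does not print them:

* **`state_drive_gain` = 0.005** — the scale at which the membrane drive
  (mV x ms) enters the device flux (whose breakpoints span 1.0 state unit).
  Chosen so a 1.5 nA step produces an adaptation phase of about 25 ms
  (measured: 27.6 ms), the stated duration of the adaptation process. The
  cable compartments use 0.002, which lets a compartment sustain a spike
  train over tens of milliseconds before its device saturates.
* **Pulse-train timing** — period 100 ms, width 40 ms. The source never
  prints its pulse timing; spike counts under pulse trains are therefore
  qualitative, not sample-exact, and the package makes no claim to reproduce
  exact published counts (e.g. a specific number of spikes per second for
  the LIF).
* **Morse reference calibration** — `dt` = 0.0125 ms and initial memristance
  10 500 Ohm, found by the grid search shipped as
  `scripts/calibrate_morse.R` (re-runnable). At the fixed 13 nA amplitude
  the firing cycle is two samples wide for any firing initial memristance,
  so the dot width (0.05 ms) must span exactly 4 samples and the dash width
  (0.1 ms) exactly 8; `dt` = 0.0125 ms is the unique step with that
  property, and the initial memristance is the midpoint of the (wide)
  interval over which all 26 letters round-trip. The device state is
  re-initialized at each letter boundary, which is what makes the per-letter
  spike totals position-independent.

## The compartmental cable

The axon is a chain of "T" units: an MLIF compartment (membrane capacitance
1 uF, memristive leak in 100..20000 Ohm) coupled to its neighbours through
the axial resistance `r_i` = 100 Ohm, with sealed ends. The compartment
length is absorbed into `r_i`, so distances are compartment indices and the
length constant is `lambda = sqrt(M / r_i)` in compartment units. In passive
mode (no firing rule, device frozen — the electrotonic, sub-switching
regime) the steady-state profile of a 40-compartment chain matches
`v(x) = V0 exp(-x/lambda)` to well under 2%.

Active propagation needs one ingredient beyond the point-neuron firing rule:
a finite action-potential width. A one-sample peak cannot depolarize the
neighbouring compartment across the axial coupling time `r_i C_m` (0.1 ms),
so a firing compartment holds its peak for 0.1 ms and then sits at the reset
potential for a 0.2 ms refractory period, which keeps the wave travelling
one way (reflection and propagation failure are outside this model's scope).
With that, every compartment regenerates the spike at exactly the 20 mV
peak, spike counts are identical along the chain, and under a sustained
suprathreshold injection every compartment's memristance descends to the
100 Ohm bound. The injection amplitude for that experiment (300 nA) is
chosen so the drive stays suprathreshold over the device's entire
memristance range; the source states only that the stimulus is "large
enough", and the axial leak divides the effective input by roughly `2
lambda`, which is what makes the number large in model units.

The full neuron chains up to three memristive synapses (voltage response
`M_syn * i`, so response peaks order with stimulus amplitude), a memristive
dendrite, an MLIF soma, and the axon. With axial coupling off, each axon
unit instead receives a fixed 0.15 ms / 200 nA relay pulse per upstream
spike; because the per-step depolarization under that pulse is approximately
`dt x amplitude` regardless of the device state, each relay pulse yields
exactly one downstream spike and the chain is distortionless by
construction.

### Dendrite and STDP synapse

The dendrite is the same flux-controlled device used as a voltage-driven
filter: below a switching flux — set at the lower breakpoint plus 10% of the
breakpoint span, a calibration, since the source prints the stimulus
magnitudes (6.25 mV and 12.5 mV pulses, a 0.45 mV/ms ramp) but not the
switching level — the device stays near `M_max` and passes almost no
current; past it, conduction grows and previously invisible small pulses
produce clear responses. The shipped ramp slope crosses the switching level
at about 21 ms, reproducing the stated filtering window.

The STDP synapse defers its internals to a reference the source does not
reproduce, so the package implements the behaviour the source does state: a
flux-controlled synapse with a 1 V threshold, driven by the superposition of
a pre- and a post-synaptic biphasic template (0.9 V rectangular lobe, then
an exponentially decaying negative tail; a single template never crosses the
threshold). The conductance change is positive for post-after-pre, negative
for the reverse, decays as the pairing interval grows, and vanishes without
overlap. Only these qualitative properties are asserted; published curve
values are out of scope. The template peaks in effect at pairing intervals
just past the positive-lobe width, so monotone decay is asserted on the
grid beyond it.

## Spike analysis choices

Bursts are segmented at gaps exceeding three times the train's median
inter-spike interval (scale-free, robust to the gradual interval growth of
adaptation); the source never defines a cluster. The adaptation flag
compares the first cluster's internal rate against a late rate, requiring a
factor of 2; the late rate is the last cluster's internal rate when that
cluster is distinct, multi-spike, and lies in the final half of the horizon
(so periodic pulse-train responses, all of whose clusters fire at the same
internal rate, are not mistaken for adaptation), and otherwise the average
rate over the final half. The factor 2 is our operationalization — the
source shows adaptation but does not quantify it. Pattern labels follow:
silent; bursting when at least two multi-spike clusters occur and
multi-spike clusters persist into the late half; adapting-tonic when the
adaptation flag holds; tonic otherwise. Labels are invariant to uniform
time translation.

Mirror experiments (reversed stimulus with reversed device polarity) mirror
the trace about the resting potential exactly — provided the firing rule is
mirrored too, since threshold, peak and reset are asymmetric about rest.
`neuron_params(firing_polarity = ...)` selects the forward, mirrored, or
two-sided rule; the two-sided rule produces the forward-and-reverse action
potentials seen under biphasic stimulation.

## Numerical behaviour and limitations

* **Scheme.** Forward Euler with `dt` = 0.01 ms for the point-neuron and
  cable experiments. When `tau_M` falls below `dt` (small `M` with the 2 nF
  point-neuron capacitance) the per-step relaxation factor is clamped at 1,
  i.e. the membrane equilibrates within the step; such samples are flagged
  and masked from the Kirchhoff current decomposition, which is otherwise
  exact under the scheme.
* **Spike-count convergence.** LIF counts are quantized by the stimulus
  structure and move by at most one spike when `dt` is halved. MLIF burst
  totals equal the device flux budget divided by the per-cycle flux
  integral, which carries O(`dt`) quadrature error over a cycle only a few
  samples long; halving `dt` from 0.01 ms moves totals by roughly 14%, with
  the increments shrinking under further halvings. Exact count invariance
  under refinement is not a property of this scheme in the dense-burst
  regime.
* **Post-adaptation firing.** In this implementation a sustained
  same-amplitude drive eventually silences the MLIF (flux grows while `V`
  exceeds rest, so `M` continues to its lower bound); the source describes
  continued regular firing after adaptation. The adaptation signature
  (first-burst rate at least twice the late rate) holds either way.
* **Ramps.** Adaptation under constant drives arises because the climb time
  diverges as `M I_ext` approaches the threshold margin. A linear ramp
  removes that divergence: the growing current compensates the falling
  memristance and the firing rate accelerates into a stable dynamic
  equilibrium, while slow ramps (reaching ~2 nA over the panel) drain the
  flux budget before threshold and never fire. The shipped ramp experiment
  (0.2 nA/ms over 100 ms) shows the count contrast (MLIF fires far more
  than LIF) but no adaptation signature; this is a structural limitation of
  the calibrated model, not a tunable one.
* **Horizons.** Shipped experiments use 50–1000 ms horizons at `dt` =
  0.01 ms and 10–40 compartments, sized so every configuration runs in
  seconds on one CPU.

## What the synthetic stimuli do and do not show

All inputs are generated in-package: pulse trains, steps, single pulses,
ramps, seeded Gaussian noise, biphasic trains, and the Morse pulse programs.
They reproduce the *conditions* of the source experiments (amplitudes,
stated durations, the Morse timing table) but none of the variability of
physical devices — no parameter spread, no stochastic switching, no
temperature effects. Passing tests therefore demonstrate the internal
consistency of the model and its calibration, not the behaviour of physical
memristor hardware.

```{r example, fig.width = 6, fig.height = 3}
grid <- time_grid(0.01, 200)
stim <- make_stimulus(stimulus_spec("step", amplitude = 1.5), grid)
trace <- simulate_mlif(neuron_params(memristor = memristor_model()), stim, grid)
glance(trace)
autoplot(trace)
```
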