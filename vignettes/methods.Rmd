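---
title: "Locating the excitatory threshold of depolarizing GABA: models and methods"
author: "egabathr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating the excitatory threshold of depolarizing GABA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

GABA-A receptors are anion channels. Whether their activation inhibits or
excites a neuron depends on the reversal potential E_GABA (set mainly by
intracellular chloride) relative to the spike threshold, but also on the
shunting conductance the open receptors add, and on when and where
glutamatergic (AMPA) input arrives relative to the GABAergic input. In
immature neurons and after several pathologies, E_GABA is depolarized, and
the question "at which E_GABA does GABA become excitatory?" has no single
answer: the threshold value — which we call the threshold E_GABA — moves
with the spatiotemporal context of the excitatory drive.

`egabathr` provides the simulation machinery to locate this threshold in
compartmental neuron models: a cable solver, a cooperative sodium spike
mechanism, conductance-based GABA/AMPA synapses and tonic GABA, iterative
conductance-threshold searches, and the analyses (reciprocal plots,
AMPA-threshold-shift intersections, spike-probability crossings) that turn
threshold searches into a single number, plus a Goldman-Hodgkin-Katz
conversion from E_GABA to intracellular chloride.

## The membrane model

All compartments carry a passive leak `g_pas = 1.28e-5 S/cm^2` reversing at
`E_pas = -50.5 mV`, which is also the resting potential. The spike
mechanism, placed on the soma (or on the axon initial segment in the axon
variant), consists of:

* a **three-state Na+ channel** (closed/open/inactivated) with sigmoidal
  (Boltzmann) transition rates. The activation rates are evaluated at the
  *effective* voltage `v + cf * O_Na`: the cooperativity factor `cf` (mV per
  unit open fraction) shifts activation leftward as channels open, a
  phenomenological account of cooperative channel opening that produces the
  sharp spike onset of real neurons. Both state variables additionally relax
  with `-state/tau_Na`. The open fraction conducts Ohmically,
  `I_Na = gNa_max * O_Na * (v - e_Na)`.
* a **two-state delayed-rectifier K+ channel** with its own Boltzmann
  opening and closing rates (separate half-voltages for the two directions)
  and relaxation `-O_K/tau_K`, conducting `I_K = gK_max * O_K * (v - e_K)`.

### Choice of channel parameters

The channel equations fix the functional form but not the constants, and no
parameter table ships with this package's sources of reference data; the
parameter set is therefore the package's own, calibrated once against the
reference excitability of immature CA3 pyramidal neurons:

* resting potential -50.5 mV with the spike mechanism in place (the
  channels' resting currents nearly cancel; the residual shift is < 0.1 mV);
* long-step rheobase 4.25 pA in the ball model and 6.55 pA in the
  ball-and-stick model;
* a quasi-stationary spike threshold (strongest-subthreshold criterion)
  of -42.8 mV, with spike overshoot above +50 mV.

The calibration works on the steady-state current-voltage relation of the
soma. Writing the quasi-steady channel open fractions into the membrane
current balance gives a somatic I-V curve whose first local maximum is the
threshold fold: its voltage is the quasi-stationary spike threshold and its
current the long-step rheobase. Two structural choices matter:

1. **A narrow K+ activation window** (half-voltage -43.28 mV, slope 0.2 mV)
   just below the fold. It sharpens the fold into a corner and stabilizes
   the subthreshold branch, so that near-rheobase subthreshold stimuli
   *saturate* at the threshold voltage instead of creeping through the
   saddle-node ghost. This is what makes the strongest-subthreshold
   threshold a well-defined, duration-independent number (within 0.2 mV
   between 200 ms and 2 s steps) — mirroring its experimental behaviour.
2. **The cooperative shift feeds back on the fold.** Because the Na+
   density is large (1.93e-3 S/cm^2) while the open fraction at the fold is
   tiny (~7e-4), even the small cooperative shift `cf*O` moves the fold
   current by ~0.1 pA; the calibration solves the fold conditions with the
   self-consistent open fraction.

The axial resistivity (200 Ohm cm) and specific capacitance (1.45 uF/cm^2)
are set from the printed passive characterization of the same neurons: the
measured membrane capacitance (~144 pF) over the ball-and-stick membrane
area implies 1.45 uF/cm^2, and 200 Ohm cm reproduces the printed
ball-to-ball-and-stick rheobase ratio; the NEURON-default 35.4 Ohm cm
cannot (it implies a dendritic load ~25% too large). With these choices the
ball-and-stick input resistance is 0.80 GOhm; the printed 1.05 GOhm is not
reproducible from the printed g_pas and geometry under any axial
resistivity and we treat it as a reporting inconsistency of the source
data.

All parameters can be overridden from a YAML file via
`defaultChannelSet(file = ...)`.

## Numerics

Voltage is advanced by an implicit (backward Euler) step of the coupled
cable equation, solved directly on the tree by Hines elimination; channel
states advance by exponential Euler at the previous voltage, and synaptic
double-exponential states decay analytically between events. The staggering
is unconditionally stable in the axial and leak terms. The default
`dt = 0.025 ms` reproduces spike shape and all threshold estimators to
within 0.1 mV of halved-dt solutions; state variables are clipped to the
unit simplex with the largest clipping magnitude reported (it stays at
round-off for the default dt). Sweeps whose voltage leaves +-500 mV abort
with a `diverged` flag. Identical configurations reproduce sweeps
bit-identically.

Spherical somata are single isopotential compartments of area `pi*d^2`;
cylinders are split into `nseg` equal segments with half-segment axial
resistances. Refining the standard 301-segment dendrite threefold changes
somatic synaptic responses by well under 1%.

## Threshold searches

All thresholds use the same alternating search: ramp the control variable
up in coarse steps until a spike is detected, then alternately step down
(0.33 of the coarse step) until the spike vanishes and up (0.1 of the
coarse step) until it reappears, shrinking both steps tenfold over six
rounds. GABA searches use 1 nS coarse steps and count spikes within 800 ms
of the synaptic onset; AMPA searches use 0.01 nS steps and a window ending
where the spike-mechanism-free AMPA depolarization has decayed to 63% of
its peak; rheobase searches use 1 pA steps over the stimulus. A spike is a
somatic crossing of 0 mV (configurable; verdicts are insensitive to the
level for the full-height spikes of the calibrated model). Searches that
reach the conductance cap report "no threshold" — the sentinel that marks
E_GABA values at which GABA cannot excite at any strength.

The four spike-threshold estimators follow standard definitions: the
voltage at the first 10 V/s crossing of dV/dt; the voltage at the first
positive maximum of the third derivative (5-point central stencils); the
intersection of baseline and rising-phase line fits (baseline window 20 ms
before the dV/dt crossing; rising phase = samples with dV/dt in 50-200 V/s;
both configurable); and the strongest-subthreshold criterion. For the last
one the amplitude is walked down from the detected threshold and the peak
subthreshold voltage is returned once consecutive subthreshold sweeps agree
within 0.05 mV ("converged"); if no such plateau exists (short stimuli),
the peak of the strongest subthreshold sweep is used. This operational rule
excludes near-threshold sweeps whose spike is merely delayed past the
window, which would otherwise contaminate the estimate.

On the calibrated ball model the estimators order as expected:
strongest-subthreshold (-42.8 mV) < intersection (-39.4 mV) < dV/dt
(-35.9 mV) < third-derivative (-34.7 mV); the dynamic estimators sit
0.3-1.6 mV from their reference values, a residual of the re-derived channel
set that does not affect the threshold-E_GABA analyses, which are anchored
to the quasi-stationary threshold.

## Threshold E_GABA extraction

* **Reciprocal plot** (GABA-only input): the threshold conductance grows
  hyperbolically as E_GABA approaches the threshold from above, so `1/gThr`
  is nearly linear in E_GABA near the intercept; a line through the last
  `nFit = 2` finite points (configurable) is extrapolated to its abscissa
  intercept (refusing to extrapolate more than 2 mV beyond the grid).
* **Intersection** (GABA x AMPA): the AMPA threshold with GABA
  co-stimulation minus the baseline without it changes sign at the
  threshold E_GABA; linear interpolation between the bracketing grid
  points. The default E_GABA grids step by 0.5 mV.
* **Spike-probability crossing** (stochastic bombardment): the E_GABA at
  which p_AP with GABA crosses the no-GABA reference probability, with
  common random numbers across the grid.

Delay scans shift the AMPA onset relative to GABA; spatial scans place both
synapses at 20 equidistant dendritic positions and align their somatic peak
depolarizations using spike-mechanism-free control sweeps; tonic scans
replace the phasic GABA synapse with a uniform membrane conductance.
Playback mode records the GABAergic current (spike mechanism off) and
re-injects it as current, removing the shunt while keeping the
depolarization: its threshold E_GABA equals the resting potential exactly,
the clean dissection of the depolarization-versus-shunt balance.

## The synthetic branched morphology

The spike-probability experiments require a realistic dendritic tree; the
reconstructed morphology they emulate is not publicly available, so the
package generates a **synthetic** stand-in: a 15 um soma with 56 dendrites
whose segment counts are drawn log-uniformly between 2 and 193 (7 um
segments, up to two chained sections per dendrite), seeded and reproducible
down to the SWC export. Synapse sites are drawn uniformly per unit
dendritic length — the natural default; per-area and per-segment placement
would differ only through the diameter taper, which the generator does not
model. "Proximal" and "distal" halves split the tree at the length-weighted
median path distance. Stimulation follows the frequency mapping 2, 10, 20,
40 synapses per receptor for 1, 5, 10, 20 Hz over a 2 s window, each
synapse firing once at a uniform random time; spike probability is the
fraction of sweeps (reference protocol: 999; the test suite uses 99) with
at least one spike.

Because the morphology is synthetic, the package asserts *directions*, not
millivolt values, for these experiments: probability increases with AMPA
drive and with E_GABA (under common random numbers), the threshold E_GABA
is more depolarized at higher stimulation frequency and for proximal GABA
placement, and it grows with tonic GABA density. What passing these tests
shows about real data is correspondingly limited: they validate the
machinery and the qualitative spatial/temporal structure, not cell-specific
numbers, which require a reconstructed morphology (SWC import is
provided).

## Problem sizes and defaults

The packaged defaults are the study conditions: 0.025 ms steps, 800 ms GABA
windows, 2 s rheobase steps, 20 dendritic positions, 999-sweep probability
estimates. The test suite and the worked examples run reduced grids (a few
positions, 0.2-0.5 mV E_GABA spacing near the intercept, 99 sweeps, a
10-dendrite synthetic tree) — chosen as the smallest problems that still
pin each quantity to its tolerance; all are single-CPU minutes.

## Known limitations

* The channel constants are a re-derivation, not the original table; the
  dynamic threshold estimators and AP width differ in detail from the
  reference waveform (the quasi-stationary threshold and rheobases match to
  a few tenths of a percent). Quantities dominated by fast AP kinetics —
  the synchronous-input interaction thresholds — inherit a few tenths of a
  millivolt of bias.
* E_GABA is an imposed parameter: no chloride accumulation, bicarbonate
  dynamics or somato-dendritic chloride gradients.
* Dendrites are passive; no NMDA receptors or short-term plasticity.
* The AP waveform repolarizes through the Na+ relaxation and the narrow
  delayed rectifier; its decay phase is slower than a real AP, which does
  not enter any threshold analysis.
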