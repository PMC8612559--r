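# egabathr

When does depolarizing GABA excite a neuron?

GABA-A receptors pass chloride (and some bicarbonate). In immature neurons
and after trauma, stroke or epileptic activity, intracellular chloride is
elevated and the GABA reversal potential E_GABA sits above rest — GABAergic
input then *depolarizes* the membrane. Depolarizing is not the same as
excitatory: the open receptors also shunt excitatory current. The E_GABA at
which the net effect of a GABAergic input flips from inhibitory to
excitatory — the **threshold E_GABA**, written E_GABA^Thr — depends on how
strong the input is, where it sits on the dendrite, how it aligns in time
and space with glutamatergic (AMPA) drive, and whether it is phasic or
tonic.

`egabathr` is an R package for mapping this threshold in compartmental
neuron models. It is aimed at cellular/computational neurophysiologists who
want to relate measured chloride levels (or E_GABA values) to the
excitation/inhibition balance of small cells under defined synaptic
scenarios.

## What is inside

* **Cable models**: ball, ball-and-stick (soma d = 46.6 um, 1 mm passive
  dendrite, 301 segments), ball-stick-axon (spike mechanism on the axon
  initial segment), and seeded synthetic branched trees standing in for
  reconstructed morphologies; SWC import/export. Implicit (backward-Euler)
  cable integration with Hines tree elimination, dt = 0.025 ms.
* **Membrane mechanisms**: passive leak (g_pas = 1.28e-5 S/cm^2,
  E_pas = -50.5 mV = rest); a three-state cooperative Na+ channel whose
  activation rates see the effective voltage v + cf*O_Na (sharp spike
  onset); a two-state delayed-rectifier K+ channel. I_x = g_x^max * O_x *
  (v - e_x).
* **Synapses**: peak-normalized double-exponential (Exp2) conductances
  (AMPA: tau 0.1/11 ms, e_rev -12 mV; GABA: tau 0.1/37 ms, e_rev = E_GABA,
  the free parameter), tonic GABA conductance densities, current steps, and
  playback of recorded synaptic currents through current clamp.
* **Threshold machinery**: the alternating conductance-threshold search
  (coarse steps, then alternating 0.33x down / 0.1x up refinements over six
  rounds), rheobase searches, four AP-threshold estimators (10 V/s dV/dt
  crossing, first d3V/dt3 peak, baseline/upstroke line intersection,
  strongest-subthreshold), and the AP-feature error function (weights
  10/3/1/1/1 on threshold, rise, decay, half-width, peak).
* **Analyses**: E_GABA^Thr from reciprocal threshold-conductance plots, from
  AMPA-threshold-shift intersections (Delta gAMPA^Thr = gAMPA^Thr with GABA
  minus without), from spike-probability crossings under random synaptic
  bombardment (common random numbers); delay, spatial, dendritic-position
  and tonic scans; Goldman-Hodgkin-Katz conversion between E_GABA and
  intracellular chloride,
  `[Cl-]i = 10^(E/60) * (P_Cl*[Cl-]e + P_HCO3*[HCO3-]e) - P_HCO3*[HCO3-]i`.

## Worked example

Ball model: rheobase, quasi-stationary spike threshold, and the E_GABA at
which a GABA-only input stops being able to fire the cell.

```r
library(egabathr)
model <- buildModel(ballMorphology())

rb <- rheobaseSearch(model)
thresholdValue(rb)            # 4.253336 pA (in 30 sweeps)

st <- apThresholdST(model, search = rb)
st$value                      # -42.77216 mV

curve <- scanGGabaThr(model, c(-43, seq(-42.5, -40.5, by = 0.5)), cap = 100)
data.frame(egaba = curve@egaba, gthr = round(curve@gthr, 2))
#   egaba  gthr
# 1 -43.0    NA
# 2 -42.5    NA
# 3 -42.0 21.61
# 4 -41.5 12.15
# 5 -41.0  9.29
# 6 -40.5  7.69

egabaThrReciprocal(curve)
# Threshold E_GABA: -42.642 mV  [ reciprocal ]

round(ghkClFromEgaba(c(-50.5, -42.642)), 1)
# [1] 14.5 21.8
```

Read: a 4.25 pA step is just enough to fire the model; the largest stimulus
that never fires it peaks at -42.77 mV (the quasi-stationary threshold).
Below E_GABA = -42.5 mV no GABAergic conductance of any size evokes a spike
(the `NA` sentinels); above it the required conductance falls steeply, and
the reciprocal plot extrapolates the divergence point to -42.64 mV: GABA
alone is excitatory only within ~0.1 mV of the spike threshold. In chloride
terms (GHK), that is the difference between ~14.5 mM at rest-neutral E_GABA
and ~21.8 mM at the excitation threshold.

With AMPA co-stimulation the story changes: `deltaGAmpaCurve()` /
`egabaThrIntersection()` show GABA turning excitatory 1.5-2 mV *below* the
spike threshold for synchronous inputs, `delayScan()` pushes the threshold
toward the resting potential for delayed AMPA inputs (and
`recordPlayback()` shows the pure depolarization reverses exactly at
rest), `tonicScan()` puts the tonic-GABA threshold near -47.6 mV over two
orders of magnitude of density, and `estimatePAP()`/`egabaThrFromPAP()`
reproduce the frequency and placement dependence under random bombardment
of a branched tree.

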