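---
title: "Glycine modulation of cortical excitation-inhibition balance: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Glycine modulation of cortical excitation-inhibition balance: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glyqsp)
```

## The scientific problem

Negative symptoms in schizophrenia (avolition, anhedonia, flat affect) are
poorly served by current antipsychotics. Raising extracellular glycine — the
obligatory co-agonist at the NMDA receptor's glycine-B site — has been tried
repeatedly, with clinical results that are mixed and, strikingly,
non-monotone in dose. `glyqsp` implements a mechanistic,
quantitative-systems-pharmacology account of why an inverse U-shaped
dose-response is expected, built from four ingredients:

1. **Subunit-resolved glycine pharmacodynamics.** Glycine potentiation of
   the NMDA current is saturable and follows a Hill relation
   $g = g_{max}\,[Gly]^n / ([Gly]^n + EC_{50}^n)$, with EC50 and Hill slope
   that differ between NR2 subunit classes. NR2A/NR2B receptors dominate
   pyramidal-pyramidal (e-e) synapses; NR2C/NR2D dominate
   pyramidal-interneuron (e-i) synapses.
2. **A cortical excitation-inhibition circuit.** Because the two synapse
   classes are potentiated differently, the *ratio* of e-i over e-e
   potentiation changes with glycine. When the e-e class has the steeper
   Hill slope this ratio dips below 1 over an intermediate glycine band,
   transiently tipping a recurrent 20-pyramidal/10-interneuron circuit
   towards excitation — and cortical activation is what tracks clinical
   improvement in imaging studies of negative symptoms.
3. **A thermodynamic ceiling on glycine.** GlyT1 is an electrogenic
   2Na⁺/1Cl⁻/glycine cotransporter. Setting the free energy of one cycle to
   zero bounds extracellular glycine by
   $Gly_{out} = Gly_{in} (Na_{in}/Na_{out})^2 (Cl_{in}/Cl_{out})
   e^{F V_m / RT}$, which stays below ~10 µM over physiological ion
   gradients and astrocyte potentials. The micromolar optimum of the
   U-shape is therefore *reachable*, and the descending limb largely is
   not, under normal physiology.
4. **Imaging-calibrated readouts.** The circuit's outputs (a Balloon-model
   BOLD signal from the cortical network and the excitability of a ventral
   striatum medium-spiny-neuron population) are combined 40% cortical / 60%
   striatal into a proxy that is calibrated linearly against PANSS-negative
   changes from drug-dose trial records.

## Module tour

| Module | Exports (core) |
|---|---|
| Glycine pharmacodynamics | `hill_params`, `hill_activation`, `synapse_class_pd`, `effective_conductance`, `ei_over_ee_ratio`, `find_ratio_extremum`, `classify_dose_response`, `classification_map`, `subunit_averages`, `nr2_hill_studies` |
| GlyT1 transporter | `ion_conditions`, `equilibrium_glycine_out`, `max_equilibrium_over_ranges`, `mm_uptake_rate`, `transporter_sweep` |
| Cortical network | `network_config`, `pathology_config`, `apply_pathology`, `apply_receptor_effects`, `simulate_network` |
| Ventral striatum | `kir_params`, `kir2_current`, `msn_params`, `modulation_state`, `simulate_msn`, `striatal_population_readout`, `dopamine_release_scale` |
| BOLD hemodynamics | `balloon_params`, `simulate_bold`, `metabolic_rate`, `bold_summary`, `balloon_outflow` |
| Receptor competition | `synapse_context`, `steady_state_activation`, `relative_effect`, `occupancy_to_concentration` |
| Calibration | `readout_weights`, `composite_readout`, `pool_replicates`, `calibrate`, `predict_panss_change` |
| Sensitivity | `effect_size`, `sweep_spec`, `run_sweep`, `sensitivity_reference_rows` |
| Fixtures & pipeline | `synthetic_trial_spec`, `generate_synthetic_trials`, `default_run_config`, `run_dose_response`, `derive_seed`, `write_run_manifest` |

A thin command-line wrapper over these functions ships as
`system.file("cli", "glyqsp.R", package = "glyqsp")` with subcommands
`dose-response`, `transporter-range`, `bold-sim`, `msn-sim`, `network-sim`,
`calibrate`, `sensitivity` and `make-fixtures`.

## The pharmacodynamic core

The package ships the transcribed experimental determinations of glycine
EC50 and Hill slope per NR2 subunit (five studies; one lacks NR2D data):

```{r}
subunit_averages(nr2_hill_studies())
```

The e-e and e-i classes are each lumped into one Hill pair (the reported
simulations use lumped NR2A/B and NR2C/D values; per-subunit mixtures would
be a configuration extension). With the reference parameters — e-e EC50
0.35 µM, slope 1.84; e-i EC50 0.25 µM, slope 1.1 — the e-i/e-e potentiation
ratio passes through an interior minimum:

```{r}
pd <- synapse_class_pd(ee = hill_params(0.35, 1.84),
                       ei = hill_params(0.25, 1.1))
find_ratio_extremum(pd, window = c(0.01, 100))
```

Direct evaluation of the Hill forms puts the minimum near 0.937 at about
1.26 µM. The published figure for the same parameters quotes 0.93 at
1.1 µM and a re-crossing of 1 near 30 µM; pure Hill ratios approach 1 from
below and cannot re-cross it, so the plotted currents presumably carry
additional scaling. We therefore treat the minimum as a *band*
(ratio 0.90–0.96 at 0.8–1.6 µM) rather than an exact point, and the
acceptance tests assert the band.

`classify_dose_response` partitions parameter space into `beneficial_U`
(interior minimum below 1 at 0.5–10 µM, the band physiology can reach),
`subphysiological_minimum` (minimum below 0.5 µM), and `monotonic`. A note
on edge cases: with *exactly* equal Hill slopes the ratio is monotone for
any pair of EC50s, so the subphysiological class requires a slope
difference; the classification-map tests construct such cases explicitly
with the grid oracle.

### Extremum search

`find_ratio_extremum` scans 1000 log-spaced points and refines the
bracketed minimum by golden-section search (`stats::optimize`) to a
relative tolerance of 1e-10, breaking ties towards the lowest glycine.
The curves involved are smooth and unimodal-or-monotone, so the grid
density is not critical; the test suite checks agreement with a
100,000-point brute-force oracle to 1e-6 in the minimum value and one grid
step in its location.

## Transporter thermodynamics

`equilibrium_glycine_out` computes RT/F from the configured temperature
(never hard-coded) and uses a net inward charge of +1 per cycle. Reported
intracellular Cl⁻ differs between sources for the same preparation (6 vs
12 mM); both are exposed and the default range spans them. Extracellular
Na⁺ is not stated in the source material; the standard 140 mM is the
default and configurable. The astrocyte potential window defaults to the
union of reported values, [-75, -40] mV. Each factor of the equilibrium is
monotone, so the maximum over a box is the corner maximum,
cross-checked against a grid search in the tests. With
Na⁺ᵢ ∈ [10, 20] mM, Cl⁻ᵢ ∈ [6, 12] mM, glycineᵢ up to 5 mM:

```{r}
max_equilibrium_over_ranges()$gly_out_uM
```

about 2.3 µM — comfortably below the 10 µM bound the physiology argument
requires, and inside the beneficial band of the U-shape.

## The cortical circuit

The published circuit description names sizes (20 excitatory, 10
inhibitory), the stimulus protocol (transient current at t = 2000 ms), the
pathology axes, and the receptor-to-channel couplings, but not equations
or parameters. The package therefore integrates its own standard
formulation, recorded fully in `network_config` defaults:

* **Neurons.** Single-compartment Wang-Buzsaki-type membranes (transient
  Na⁺, delayed-rectifier K⁺, leak), plus a slow non-inactivating K⁺
  current and a high-voltage-activated Ca²⁺ current on pyramidal cells as
  neuromodulation targets.
* **Synapses.** Single-exponential AMPA (τ 2 ms) and GABA-A (τ 8 ms)
  conductances; NMDA with slow decay (τ 100 ms) and the standard
  voltage-dependent Mg²⁺ block. The NMDA conductance is split by synapse
  class; *baseline values represent full glycine potentiation* and
  `simulate_network(gly = ..., pd = ...)` scales them down by
  `effective_conductance`.
* **Noise.** Independent Poisson-driven excitatory conductance events per
  neuron; "background noise" is otherwise unspecified in the source.
* **Integration.** Fixed-step explicit Euler with dt ≤ 0.05 ms (default
  0.025 ms), incremental synaptic bookkeeping, and R's RNG so a seed fixes
  the spike train bit-for-bit.
* **Operating regime.** The default conductances place the circuit in an
  inhibition-stabilised regime: interneurons are driven mainly through
  e-i NMDA, and recurrent e-e NMDA (not tonic current) sustains pyramidal
  firing. Two consequences matter scientifically: scaling *both* NMDA
  classes together (what identical e-e/e-i pharmacodynamics would do) is
  largely compensated and leaves the pyramidal rate flat, while scaling
  them *differentially* moves the rate — so any glycine dependence of the
  outcome flows through the e-i/e-e ratio, which is the claimed mechanism.
  These conductances were chosen once, while building the healthy/lesioned
  baseline, and are package defaults, not fitted quantities.
* **Distractors.** The identity of the "distractor neurons" is not
  described in the source; they are implemented as a configurable
  excitatory subset receiving independent Poisson drive from stimulus
  onset.

Schizophrenia pathology is fractional: NMDA and GABA-A conductances scaled
by (1 − reduction), dopamine coupling gains by (1 − deficit), noise
amplitude by (1 + increase). The shipped default of 0.3 on each axis is an
explicit placeholder inside the published sensitivity sweep ranges — the
calibrated magnitudes are not printed anywhere and are user data.
Receptor couplings ship with the D1 pair (slow K⁺, gain −0.5; HVA Ca²⁺,
gain +0.5) active and all other receptors present at zero gain: coupling
magnitudes are calibration targets, not constants.

The population activities `u_e(t)`, `u_i(t)` are smoothed per-population
firing rates (20 ms bins, 5-bin moving average, 0.1 Hz floor) normalised
so the pre-stimulus mean is 1 by construction; the scalar network outcome
is the mean excitatory rate from stimulus onset to the end of the run.

## Ventral striatum

Medium spiny neurons are integrated with the printed inward-rectifier
form: conductance $\bar g_K / (1 + \exp(-(V - V_h)/V_c))$ with
$\bar g_K = 1.2$ mS/cm², $V_h = -111$ mV, $V_c = -11$ mV, $E_K = -90$ mV,
scaled by the D1 activation u. The printed sign convention ($V_c < 0$)
makes the conductance shut with depolarisation — inward rectification —
and the unit tests pin $g(V_h) = \bar g_K/2$ and the −12.6 µA/cm² current
at half-activation exactly. The remaining channels (A-type K⁺, slow K⁺,
Cl⁻, L-type Ca²⁺, spike currents) are standard textbook forms with
densities recorded in `msn_params`; they are labelled assumptions, since
the source cites prior work without equations. The slow K⁺ term stands in
for the undefined `I_Ksi` symbol of the printed membrane equation.

Three cell classes differ only in couplings: D1 scales Kir2 and L-type
Ca²⁺ in SP⁺ cells, D2 scales A-type K⁺ and presynaptic glutamate in Enk⁺
cells, dual cells carry both; M1 scales the Cl⁻ conductance, M2 and
alpha-1A scale the afferent and gating drives. All linear modulation
gains default to 0.5 and are calibration targets. Hippocampal/amygdala
gating is a time-series gate multiplying drive efficacy (default: open).
The population readout is a configurable weighted mean across classes
(default equal weights) — the combination rule is not stated in the
source and is a documented package choice.

## BOLD hemodynamics

The metabolic-hemodynamic cascade runs from delayed, sigmoid-transformed
neural drives through second-order glucose responses, an oxygen-glucose
index, a flow-inducing signal, and the venous balloon, to
$y = V_0(a_1(1-q) - a_2(1-v))$. Numerical choices:

* The implicit outflow/volume coupling is solved algebraically:
  $dv/dt = (f - v^{1/\alpha})/(t_0 + \tau)$, the standard Balloon outflow
  with Grubb exponent; $f_{out}(v{=}1, dv/dt{=}0) = 1$ exactly.
* Printed constants are kept verbatim: $a_e = 1.2$, sigmoid steepness
  $c = 2.5$ and threshold $d = 1.6$, $\tau = 10$ s, $a_1 = 3.4$. The
  $a_2$ weight is cited to an unrelated reference in the source and
  defaults to 1.0, configurable.
* The oxygen-glucose index $x(t)$ is used but never defined in the
  source; it defaults to the constant baseline $x_0$ (uncoupling off)
  with a hook (`x_fun`) to supply dynamics externally.
* The sigmoid's placement is not stated; it is applied to the *metabolic*
  drives, as $S(z)/S(1)$ so baseline activity 1 maps to 1. The flow
  branch sees the raw excitatory drive with its own delay.
* The flow gain defaults to ε = 10, chosen once so that the flow response
  exceeds the (constant-x) metabolic response and a sustained excitatory
  step yields the standard positive BOLD excursion; with constant x the
  uncoupling that normally attenuates oxygen consumption is absent, so
  the published flow parameters of the cited review would invert the
  sign of the response.
* Integration is fixed-step RK4 (via deSolve) at dt ≤ 0.01 s, so the
  step-halving convergence check (< 1% change in peak) is meaningful.

Starting at the baseline fixed point with unit drives, every state stays
at baseline to machine precision — asserted over 60 s in the tests.

## Receptor competition and calibration

The full time-resolved, voltammetry-calibrated synaptic release model of
the original platform is out of scope; `steady_state_activation` is a
documented steady-state approximation: mass-action competitive binding of
the neurotransmitter (intrinsic activity 1) and up to four agents, with a
single autoreceptor feedback gain iterated to a 1e-8 fixed point.
`occupancy_to_concentration` inverts the binding relation (analytically
without feedback, numerically with) so PET-style occupancies can be
converted into functional synaptic concentrations. Neurotransmitter
baselines and feedback gains are synapse-specific user data.

Calibration is a least-squares linear map (optionally patient-weighted)
from the composite proxy to PANSS-negative change, with Pearson r as the
headline diagnostic; a monotone-spline alternative was considered and
rejected for the default because 34 points spread over many drugs do not
constrain a flexible form.

## The synthetic trial generator

The 34-record retrospective clinical database behind the published
calibration is not deposited. `generate_synthetic_trials` emulates its
*schema* — 17 drugs × 2 doses, log-uniform receptor affinities over
1–1000 nM across seven receptors, forward receptor-competition runs for
D2 occupancy and per-receptor relative activations, fixed surrogate
weights mapping activations to cortical/striatal changes, the 40/60
composite, and patient counts of 20–200 — and places outcomes on a known
linear map (default slope −8 points per proxy unit, intercept −1) plus
Gaussian noise. Noise is either a raw SD or, by default, tuned so the
realised in-sample proxy-outcome correlation equals 0.65: the drawn noise
is residualised against the proxy and rescaled, which fixes |r| exactly
and leaves the least-squares slope unbiased. This mirrors the published
calibration quality (correlations above 0.6) as a *property of data with
known ground truth*; passing the recovery tests shows the calibration
machinery works, not that the clinical correlation is reproduced — the
real database would be required for that, and per-trial heterogeneity
(drug classes, trial durations, placebo response) is not emulated.

## Sensitivity analysis

`effect_size` implements the range-based statistic: the difference
between maximal and minimal relative outcome changes (as fractions)
divided by the fractional parameter range. The shipped reference rows
reproduce nine of the ten published effect sizes at three decimals from
their own printed extremes; the GABA-reduction row (range ±10%, extremes
−32.4% and +20.8%, printed 1.620) yields 2.66 under the stated formula
and is flagged as internally inconsistent rather than silently corrected.
Asymmetric printed ranges (e.g. ±41%, ±24%) are honoured per row.
`run_sweep` works on a model bundle (config + outcome function); the
default desk-scale outcome is `surrogate_outcome`, the peak excitatory
dominance `max 1/ratio` over a glycine grid, which tracks the network
outcome through the mechanism above without spiking simulations. The
full-circuit outcome can be substituted where its cost is justified.

## Problem sizes used by the test suite

The shipped tests run the spiking network at 30 neurons for 1.5–5 s of
simulated time; the dose-response property uses 7 log-spaced glycine
points × 10 paired seeds under the default pathology, and the calibration
recovery property uses 100 generator seeds of 34 trials each. These sizes
were chosen as the smallest at which the paired-seed statistics resolve
the effects cleanly (the interior-maximum margins exceed 8 standard
errors at 10 seeds); larger runs sharpen the same conclusions.

## Known limitations

* The network and MSN parameterisations are standard forms, not fits to
  the original platform's calibrated values, which are unpublished; the
  package reproduces mechanisms and bands, not the headline 2–2.5-point
  PANSS prediction.
* D-serine (racemase/ASC-transporter regulated) is not modelled; zinc,
  polyamine and neurosteroid modulation are assumed unchanged;
  comedication interactions are out of scope.
* Time-resolved transporter currents (stroke/trauma depolarisation
  regimes) are excluded; the GlyT1 module is equilibrium plus
  Michaelis-Menten kinetics.
* The steady-state receptor layer ignores release dynamics and
  facilitation/depression; the interface accepts an alternative backend.
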