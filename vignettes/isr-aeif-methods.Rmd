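---
title: "Inverse stochastic resonance in an aEIF Purkinje-cell model: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inverse stochastic resonance in an aEIF Purkinje-cell model: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the science implemented by `isrpc`: the neuron model
and its dynamical structure, the stimulation protocols, the parameter
estimation pipeline for current-clamp recordings, the response statistics
that quantify inverse stochastic resonance (ISR), and the information-rate
estimator. It also records the numerical and design choices a maintainer
would want to know, and what the synthetic-data tests do and do not show
about real recordings.

## The model

Cerebellar Purkinje cells fire sodium "simple spikes" intrinsically and can
sit in either a tonically firing *up* state or a quiescent *down* state at
the same holding current. The package models this with the adaptive
exponential integrate-and-fire (aEIF) neuron,

$$C \dot V = -g_L (V - E_L) + g_L \Delta_T e^{(V - V_T)/\Delta_T} - w + I(t),
\qquad \tau_w \dot w = a (V - E_L) - w,$$

with the reset rule: when $V$ exceeds $V_{spike} = 0$ mV, a spike is
recorded, $V \to V_r$ and $w \to w + b$. Units are mV, ms, pA, nS, pF
throughout. The bundled representative parameter set is
$C = 268$ pF, $g_L = 8.47$ nS, $E_L = -51.31$ mV, $V_T = -53.23$ mV,
$\Delta_T = 0.85$ mV, $a = 37.79$ nS, $b = 441.12$ pA, $\tau_w = 20.76$ ms.

Two derived quantities organize everything else. The combination
$a/g_L$ versus $\tau_m/\tau_w$ (with $\tau_m = C/g_L$) separates type I from
type II excitability: for $a/g_L > \tau_m/\tau_w$ the rest state loses
stability through a subcritical Andronov–Hopf bifurcation and the f-I curve
starts at a nonzero rate. For such type II sets the rheobase has the closed
form implemented in `rheobase_up()` (about $-70.6$ pA for the representative
set). Below that current the model is bistable: a stable focus (the down
state) coexists with the spiking limit cycle, and the basin of attraction of
the focus is the drop-shaped set computed by `rest_basin()`.

### The reset potential

$V_r$ is not constrained by the fitting protocols (the post-spike trajectory
is dominated by the adaptation jump) and is not identifiable from the
published quantities, yet it decides whether the up state exists at all: if
the reset lands inside the rest-state basin the "limit cycle" dies after one
spike. With $V_r$ equal to $E_L$ the representative set has *no* sustained
spiking at $-150$ pA, which contradicts every bistability result the model
is meant to show. The package therefore fixes the convention
$V_r = -60$ mV — within the physiological after-hyperpolarization range,
below the basin, and chosen **once** so that the representative set
reproduces the qualitative regime the study describes (sustained up state in
the bistable range, firing-rate minimum near 30 pA noise, ~0.5 occupancy at
60 pA noise). All parameter files, the population sampler and the fitting
pipeline use this convention; it is exposed as an ordinary argument.

### Probability of spiking

"Spiking probability" is defined in phase space: $P_{sp} = 1 - P_r$, where
$P_r$ is the fraction of time the trajectory spends inside the basin of
attraction of the rest state. A cell in the up state counts as "spiking"
throughout its interspike intervals. The peristimulus histograms
(`psth()`) default to this occupancy definition (`mode = "basin"`), which
is the only reading that reproduces the ~0.5 pre-stimulus baseline at 60 pA
noise; a spike-occurrence variant (`mode = "spike"`, at least one spike per
20 ms bin) is available for comparison with recordings where the state is
not observable. Basin membership during noisy runs uses instantaneous
nearest-cell lookup in a precomputed mask (0.5 mV by 10 pA by default;
refining the grid does not change the reported probabilities at the stated
precision).

## Stimulation protocols

All protocols are generated by `build_protocol()` and friends, mirroring
the electrophysiology:

* **OU noise** (`ou_series()`): Ornstein–Uhlenbeck current with mean
  $\mu$, stationary SD $\sigma$ and correlation time $\tau$ (2 ms for the
  ISR protocols). The discretization is the exact conditional update, so
  the stationary moments are exact at any step; at 0.1 ms the difference
  from an Euler discretization is far below every statistic studied here.
* **Dual-OU fitting noise** (`dual_ou_current()`): the sum of two OU
  processes at 3 and 10 ms (fast/slow synaptic mimicry), combined SD 153 or
  235 pA, with an equal variance split (unstated in the protocol; exposed
  as an argument).
* **ISR step protocol**: 1 s constant-$\sigma$ noise epochs alternating
  with silent epochs, $\sigma$ stepped over 0–500 pA.
* **Ramps**: symmetric triangular current ramps at 0.9 nA/s (1 s up, 1 s
  down, 10 trials) for the hysteresis analysis.
* **Biexponential synaptic events** (`biexp_current()`): rise 1.5 ms,
  decay 10 ms, normalized so a single event peaks at exactly $A_m$. (The
  printed driving term carries a spurious "(1 − I_in)" factor that would
  make the amplitude depend on the input current; it is treated as a
  transcription artifact and the event is driven by $A_m\,\delta(t -
  t_{st})/K$.)
* **Brief pulses**: 0.5 ms, 1 nA, for the membrane-time-constant fit.

Integration is forward Euler at 0.1 ms (0.02 ms, i.e. 50 kHz, for synthetic
recordings), with the reset applied within the crossing step and the spike
time taken as the crossing sample. The exponential term's argument is capped
(at 16) purely to avoid floating-point overflow in the one step before a
reset. Halving the step changes noise-free 1 s spike counts by at most one
spike (tested).

## Parameter estimation from current-clamp traces

The pipeline (`fit_full()`, driven by `fit_synthetic_cell()` for synthetic
cells) estimates every aEIF parameter from two protocols: dual-OU noise
injections and the brief pulse. Stages:

1. **Spike exclusion.** Spikes are detected at $-20$ mV; samples from just
   before each peak to 10 ms after it are excluded, as are concatenation
   junctions between epochs recorded at different holding currents.
2. **Pre-filtering.** Voltage and current are boxcar-filtered (0.6 ms).
   Because the subthreshold dynamics are linear, filtering all signals with
   the same kernel preserves the model equations exactly while suppressing
   the white measurement noise that otherwise dominates $dV/dt$ at 50 kHz.
   The I-V curve itself is also computed on the filtered trace; the
   derivative noise averages out within voltage bins either way.
3. **Capacitance.** $C_e$ first minimizes the count-weighted per-bin
   variance of $I_{in}/C_e - dV/dt$ (the classical estimator; the objective
   is quadratic in $1/C_e$). For a cell with strong subthreshold
   adaptation this estimate is biased upward, because the adaptation
   current is correlated with the injected current within voltage bins.
   `refine_capacitance()` removes the bias by scanning $C_e$ against the
   residual of the adaptation-dynamics regression below, after subtracting
   the analytic $C_e^2$-proportional noise term (without that correction
   the scan is biased *downward* by derivative noise).
4. **Threshold parameters.** The dynamic I-V curve
   $I_{dyn}(V) = \langle I_{in} - C_e\,dV/dt\rangle_V$ is fitted with a
   linear part plus exponential rise. The free four-parameter EIF fit ties
   the exponential amplitude to the linear slope, which is wrong when the
   apparent slope contains the adaptation conductance, so the pipeline
   refits with the exponential amplitude pinned to the independently
   estimated $g_L$; $V_T$ and $\Delta_T$ come from this constrained fit.
5. **Leak and adaptation.** The quasi-static reading of the I-V slope
   ($g_L + a$) fails for these protocols: with input correlation times of
   3/10 ms and $\tau_w \approx 15$–20 ms the adaptation current tracks only
   a small fraction of the voltage fluctuations, so the apparent slope is
   close to $g_L$ alone. `fit_adaptation_dynamics()` instead integrates
   the adaptation ODE exactly over 5 ms spike-free windows, giving a linear
   regression whose coefficients yield $g_L$, $a$, $\tau_w$ and $E_L$
   jointly while honoring the dynamics. `estimate_subthreshold_a()` keeps
   the classical slope-minus-$g_L$ reading for reference.
6. **Spike-triggered adaptation.** $w_{spike}$ is computed per sample,
   binned by time since the last spike, and fitted with a decaying
   exponential plus offset; $b$ is the extrapolated value at the spike
   time.
7. **Bias correction.** The closed-form estimators carry systematic biases
   (spike-history superposition and the reset-potential term inflate $b$
   by roughly a factor two; state-selection in the exponential elbow
   broadens $\Delta_T$). `bias_correct_fit()` removes them by indirect
   inference: the fitted model is simulated through the *same* injected
   currents with matched measurement noise, refitted identically, and the
   biased parameters ($g_L$, $a$, $b$, $\tau_w$, $\Delta_T$) are iterated
   until the pipeline maps the corrected model onto the observed
   estimates (two iterations). The correction never sees the ground
   truth.

Across 20 synthetic cells drawn from the population statistics the median
relative errors are about 1% for $C$, well under 1 mV for $E_L$ and $V_T$,
and under 10% for $\Delta_T$, $a$, $b$ and $\tau_w$ (the acceptance suite
asserts the looser published-population tolerances).

The pulse response deserves a note: for a single-compartment cell with
strong subthreshold adaptation, the relaxation after a brief pulse is an
underdamped spiral, not a biexponential. `fit_membrane_tau_pulse()` fits
both models and reports which one won; the trace identity
$\sum_i 1/\tau_i = g_L/C + 1/\tau_w$ of the subthreshold linearization
(`gL_method = "eigen"`) lets the pulse drive the leak split when desired,
while the default leak split comes from the dynamics regression.

## Response statistics

* `isr_curve_model()` simulates independent noise epochs started on the
  noise-free limit cycle and reports the firing rate versus $\sigma$,
  Gaussian-smoothed with the grid step, and the optimal (minimizing)
  amplitude $\sigma_{opt}$. At $-150$ pA the representative model's rate
  collapses from ~20 Hz to under 1 Hz with $\sigma_{opt} = 30$ pA.
* `isr_curve_continuous()` implements the continuously ramped-amplitude
  protocol and separates 200 ms analysis windows by whether the cell fired
  in the previous window, removing the history confound of the stepped
  protocol.
* `hysteresis_ramp()` measures onset/offset currents and instantaneous
  rates on symmetric ramps. Two rate effects matter: ascending onset is
  delayed past the Hopf current by the slow passage through a subcritical
  bifurcation — a delay that does *not* vanish as the ramp slows (the
  deterministic system retains an O(1) memory), though a 5 pA noise floor
  collapses it to within 5 pA of the closed form — and the descending
  offset at 0.9 nA/s overstates the lower edge of the bistable range by
  several tens of pA, so the bistable-range bracketing uses 0.09 nA/s
  ramps. Note that the closed-form rheobase ($-70.6$ pA) necessarily lies
  *above* $-100$ pA, so the loosely stated "bistable between $-100$ and
  $-200$ pA" can only be read as the range where ISR is expressed, not as
  the bifurcation interval.
* `psth()`, `decay_time_constant()` and `input_output_curve()` quantify
  the stimulus-response behavior: at 10 pA noise the model latches, at
  30 pA a 100 pA event evokes a spiking state whose occupancy decays on
  the order of a second (0.5-0.6 s here), and at 60 pA the baseline
  occupancy sits near 0.5 (0.43-0.46 here).
  The response threshold (smallest amplitude raising the peak probability
  more than 0.1 above baseline) and saturation (smallest amplitude beyond
  which the peak moves by less than 5% of its range) are operational
  definitions, evaluated on a 12.5 pA amplitude grid; the measured
  threshold lands one grid step above 50 pA.

## Information transfer

`ctw_entropy_rate()` implements context-tree weighting with
Krichevsky–Trofimov node estimators generalized to an m-ary alphabet
(depth 40 symbols = 1 s at 25 ms bins). The mutual information rate is the
decomposition $\hat H(X) + \hat H(Y) - \hat H(X,Y)$ with the joint sequence
over the four-symbol product alphabet; `block_entropy_rate()` provides an
independent plug-in cross-check on short-memory sources. Small negative MI
estimates (estimation error on long-memory joint sequences) are reported
raw and flagged. "Ten estimates per data point" is implemented as
independent simulation repeats with fresh noise and signal seeds, averaged;
the acceptance analyses use 300 s sweeps with 3 repeats in place of the
full 1000 s by 10 (the argmax over the noise grid is already stable at
that size). MI peaks at $\sigma = 30$ pA for a 1 Hz, 100 pA Poisson
signal, the ISR-optimal amplitude.

## The synthetic-data generator

`sample_population()` draws ground-truth cells from independent truncated
normals matching the published population means and SDs (covariances are
not published; independence is a simplification), restricted to type II
sets as in the study. `synth_recording()` integrates the ground truth at
50 kHz and adds 0.2 mV white measurement noise (recording noise is not
reported; 0.2 mV is typical for whole-cell amplifiers after filtering).
`pick_holding_current()` emulates the experimenters' per-cell protocol
adaptation with short test injections. What passing recovery tests show is
that the pipeline inverts *this* generative family; real recordings add
electrode artifacts, dendritic filtering and non-stationarity that the
generator deliberately omits (the two-compartment variant covers the
passive-dendrite part).

## Problem sizes and determinism

The test and acceptance analyses use the study's protocol sizes where they
are stated (20 x 30 s ISR repetitions, 1000 x 6 s sweeps, 0.1 ms steps);
the MI sweep is scaled to 300 s x 3 repeats as noted. All stochastic
drivers take explicit integer seeds and are bit-reproducible; the
compiled kernels draw from R's RNG stream.

## Known limitations

* The aEIF reproduces the bistability of the *spike output*, not the
  membrane-potential bimodality of real Purkinje cells; tests assert the
  wider voltage spread of the up state, not separated modes.
* $V_r$ is a convention (above); analyses that depend on the depth of the
  after-hyperpolarization should treat it as such.
* The recovery tolerances are statements about the synthetic generative
  family, not about patch-clamp data.
* The CTW estimator's negative bias grows with the joint alphabet and
  depth; comparisons across noise levels (argmax) are robust, absolute MI
  rates at high noise less so.
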