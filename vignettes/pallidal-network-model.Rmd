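---
title: "A conductance-based network model of the Parkinsonian globus pallidus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A conductance-based network model of the Parkinsonian globus pallidus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pallidalnet)
```

## The model

`pallidalnet` simulates a population of rodent globus pallidus (GP)
neurons — tonically active, mutually inhibitory pacemakers — receiving
rhythmic excitation from subthalamic (STN) units whose firing is modulated
by cortical slow-wave activity (SWA, ~0.8 Hz under anaesthesia). The
scientific question the model addresses is how, under Parkinsonian
(dopamine-depleted) conditions, the GP population splits into two anti-phase
oscillatory groups: neurons firing preferentially during the active phase of
the slow wave (TA) and neurons firing during the inactive phase (TI).

### GP neurons

Each GP neuron is a single electrical compartment obeying

$$C\frac{dV}{dt} = g_{leak}(E_{leak}-V) + \sum_X I_X + I_{syn} + I_{ext},$$

with ten voltage-gated channels: fast sodium (NaF), persistent sodium (NaP),
delayed rectifiers (Kv2, Kv3), A-type potassium (Kv4 fast and slow),
M-current (KCNQ), a high-voltage-activated calcium channel (HVA), and fast
and slow HCN channels. Each channel current has the form
$I_X = m^{\mu}h^{\rho}s^{\phi}\,g_X\,(E_X - V)$ with integer gate exponents
fixed per channel. Units are pF, nS, mV and ms throughout, so currents are
in pA. Maximal conductances and reversal potentials are model constants
(`mean_conductances()`): the population is made heterogeneous by sampling
NaP with a 50% coefficient of variation and both HCN conductances with 30%,
truncated at zero (`sample_population()`).

Gate kinetics — Boltzmann steady states
$x_\infty(V) = 1/(1+\exp((V_{1/2}-V)/k))$ with sigmoidal voltage-dependent
time constants — are **calibration data**, not code. They ship as
`inst/extdata/gate_kinetics.csv` and can be replaced wholesale by a user
with their own kinetics file (`load_gate_kinetics(path)`). The shipped set
was calibrated (by coordinate descent and randomized local search against
single-neuron simulations) so that the isolated-neuron surface reproduces
the modelled cell type:

* ~94% of a 500-neuron heterogeneous population pacemakes without input, at
  24–25 Hz on average;
* zeroing both HCN conductances slows pacemaking to ~16 Hz and silences
  ~12% of the population;
* hyperpolarizing current injections produce an HCN-dependent sag and
  prompt rebound firing; without HCN the sag disappears and the rebound is
  delayed;
* depolarizing current drives firing monotonically up to roughly 200 Hz;
* a unitary inhibitory synapse of 0.5 nS evokes a ~0.5 mV IPSP at a −65 mV
  holding potential.

### Calcium and HCN downregulation

Intracellular calcium is a dimensionless activity variable driven by the
HVA current and cleared by a first-order pump,
$d[Ca]/dt = \epsilon(I_{HVA} - k_{Ca}[Ca])$ with $\epsilon = 10^{-4}$ and
$k_{Ca}=15$; its relaxation time is ~667 ms, so it tracks firing rate on
the timescale of the slow-wave cycle. The HVA kinetics were calibrated so
that sustained firing maps to calcium roughly as
$[Ca]_{ss} \approx 0.0106 \times \mathrm{rate\,(Hz)}$: ordinary
in-network firing (~10–13 Hz) stays below the downregulation threshold,
while sustained active-phase firing above ~20 Hz crosses it.

When $[Ca] > T_{HCN} = 0.2$, both HCN maximal conductances are decremented
between 1 ms integration control steps by
$k_{HCN}\,\Delta t / (1+\exp((\theta-[Ca])/\sigma))$ with $\theta = 0.5$,
$\sigma = 0.1$, clamped at zero and never recovering
(`apply_downregulation()`). The decrement rate is $k_{HCN} = 0.6$ nS/ms
(i.e. $6\times10^{-4}$ µS/ms): at this rate a fully driven neuron loses its
177 nS HCN conductance within a few hundred milliseconds, which is what a
"rapid reduction in response to elevated firing" requires — a literal
reading of $6\times10^{-4}$ in nS/ms could remove at most ~4% of the
conductance over an entire run and would make the mechanism inert. The
discontinuity at $[Ca]=T_{HCN}$ (the sigmoid is evaluated only above
threshold) is kept as specified rather than smoothed.

### STN input

STN units are not modelled at conductance level. Each unit is an enhanced
integrate-and-fire generator — leaky accumulation of drive, an
exponentially decaying threshold with a post-spike jump, Gaussian noise,
and a 2 ms absolute refractory period — whose drive alternates between an
active and an inactive level following the slow-wave cycle
(`generate_stn_train()`). The cycle is 1300 ms: a 500 ms active phase at
30 Hz (healthy) or 60 Hz (Parkinsonian) and an 800 ms inactive phase at
0.5 Hz; a beta-band variant uses a 70 ms cycle (30 ms active + 40 ms
inactive). Because the underlying stochastic process is pinned only by its
ingredients and its rates, the per-phase drives are calibrated by bisection
against realized rates — the inactive drive in the context of the full
alternating protocol, since the active→inactive transition suppresses early
inactive-phase spiking. Realized phase rates match the targets to within a
few percent; results are memoized per protocol and the calibration runs
under a locally fixed RNG state so it never perturbs a caller's random
stream. Phase 0 of the cycle is, by convention, the onset of the active
phase; the phase advances linearly, so the active phase occupies
$[0, 2\pi \cdot 500/1300)$. The categorization module uses the same
convention, which is what makes the TA/TI assignment well defined.

### Synapses and wiring

Synapses are conductance-based with a difference-of-exponentials time
course: each synapse carries an opening and a closing variable, both
step-incremented by 1 on a presynaptic spike (a spike is an upward crossing
of 0 mV) and decaying with time constants $\tau_o < \tau_c$; the current is
$(c-o)\,g_{syn}(e_{rev}-V)$. GP→GP synapses are GABAergic
($\tau_o = 5$, $\tau_c = 40$ ms, $e_{rev} = -80$ mV); STN→GP synapses are
glutamatergic ($\tau_o = 0.2$, $\tau_c = 60$ ms). The AMPA reversal
potential is not pinned by the source material and is set to the standard
0 mV. Unitary conductances are Gaussian per synapse (30% relative s.d.,
truncated at zero) around means of 0.5/0.1 nS (healthy GP-GP/STN-GP),
doubled to 1.0/0.2 nS under Parkinsonian conditions. Each GP neuron
inhibits 20 randomly chosen others (never itself); each of the 50 STN units
excites 2 randomly chosen GP neurons. Scaling presets (200 GP/100 STN,
300 GP/150 STN) keep the fan-outs constant, lowering the coupling fraction.

The Parkinsonian condition is exactly three parameter changes: STN
active-phase rate 30→60 Hz, mean STN→GP conductance 0.1→0.2 nS, mean GP→GP
conductance 0.5→1.0 nS (`apply_condition()`).

### Numerics

The integrator is an adaptive Runge–Kutta–Fehlberg 4(5) with absolute and
relative error tolerances of $10^{-5}$ and a maximum step of 1 ms,
implemented in C++ with gate kinetics evaluated from lookup tables (0.05 mV
grid, linear interpolation). Because GP neurons couple only through spike
events, the network engine integrates each neuron independently with its
own adaptive step inside 1 ms control windows: STN spikes are delivered at
their exact times by restarting the integration there, while GP-spike
synaptic increments are exchanged at window boundaries. The latter imposes
a delivery latency of at most 1 ms — comparable to a physiological synaptic
delay — and halving or quartering the window does not change the category
composition of a healthy trial, while the per-neuron stepping makes a 13 s
network trial ~25× faster than a global-step integrator (about 15 s on one
CPU core). HCN downregulation is applied between windows, never inside the
ODE right-hand side. Between events, synapse variables for each
postsynaptic neuron are carried as conductance-weighted sums
($\sum_i g_i o_i$), which is exactly equivalent to per-synapse states
because the synapse equations are linear and increments are +1 per spike.

Spike times are linearly interpolated at the 0 mV upward crossing within an
integration step; with steps well below 1 ms around spikes the
interpolation error is negligible. Gates are clamped to $[0,1]$ and calcium
to $[0,\infty)$ after each accepted step; membrane potentials leaving
[−150, +90] mV raise an error identifying the neuron and time (numerical
blow-up detection). Initial conditions — unstated in the source material —
are $V = E_{leak}$ with every gate at its steady state for that voltage and
zero calcium; the analysis window (the latter half of each run by default)
excludes the burn-in transient.

All randomness derives from a single master seed per simulation through
named sub-seed streams (heterogeneity, connectivity, synaptic noise, STN
trains); a trial battery derives independent per-trial master seeds, so
re-running any configuration is bit-reproducible at the spike-train level.

## Categorization and analysis

Each neuron's spikes are mapped to unit phasors at their slow-wave phase;
the resultant $\omega = \sum_s e^{i\theta(s)}$ yields a mean firing phase
($\arg\omega$) and a phase confidence $c = |\omega|/n$ between 0 (uniform)
and 1 (perfectly locked). The rules, applied to the analysis window in
order: fewer than one spike per SWA cycle → QU (quiet); $c < 0.1$ → NM
(not modulated); otherwise TA or TI according to whether the mean phase
falls in the active or inactive part of the cycle. The ISI coefficient of
variation uses the sample (n−1) standard deviation.

Correlograms are lag histograms of spike-time differences normalized as
$X' = T X / (2 h N_A N_B)$ (T: common observation time; h: half the bin
width; $N_A, N_B$: spike counts), so independence gives an expectation of
exactly 1. The 95% bounds — not printed in the source material — use the
Poisson approximation $1 \pm 1.96/\sqrt{E[X]}$ with
$E[X] = 2hN_AN_B/T$. Auto-correlograms exclude zero-lag self-pairs. For
small trains the histogram equals exhaustive pair enumeration (this is a
test invariant).

## What the simulations show, and their limits

Running the standard experiments (`run_experiment()`) at these settings:

* **Isolated characterization** reproduces the target surface quoted above
  (this is what `scripts/acceptance.R` re-measures).
* **Parkinsonian networks** self-organize into the anti-phase TA/TI
  division: ~80% of neurons become slow-wave-modulated, TA firing in the
  active and TI in the anti-phase inactive part of the cycle, with TI
  firing near 6.4 Hz. The modulated fraction exceeds the healthy fraction
  in every battery, and disabling HCN downregulation lowers mean TA phase
  confidence.
* **Healthy networks** keep a lower rate (NM neurons ~13 Hz) but are more
  strongly entrained and more strongly silenced than the reference data
  (NM ~21% and QU ~22%, where ~68% and ~10% are expected; ISI CV ~0.45
  rather than ~0.12).

The healthy-network discrepancy has a single identified root cause: the
calibrated neuron is more fragile to sustained inhibitory conductance than
the original cell model. Under ~4 nS of tonic GABA conductance (the
self-consistent healthy network level) the reference neurons fire at
~12 Hz, whereas ours fall silent; the network therefore settles into a
competitive regime where strongly firing neurons silence weaker ones and
slow-wave modulation penetrates more deeply. An extensive search over the
kinetics parametrization did not find a set satisfying both the
isolated-neuron surface and this inhibition robustness: in this gate
parametrization, every mechanism that restores inhibited firing
(repositioned HCN activation, a NaP de-inactivation reserve, spike
threshold shifts) accelerates free pacemaking by a similar factor, because
the free-running interspike trough lies within a few millivolts of the
inhibited operating point. The original multicompartment-derived kinetics
evidently shape a flatter inhibition response; a user holding those
kinetics can drop them into the kinetics file directly. Downstream of the
same cause, HCN downregulation engages fewer neurons than in the reference
results (the post-downregulation intrinsic rate is ~22 Hz rather than
~17 Hz), and ~19% rather than <10% of healthy-network neurons experience
some downregulation.

The synthetic STN input emulates the *statistics* of slow-wave-modulated
subthalamic firing (phase-specific rates, refractoriness, independence
between units); it does not emulate spike-timing structure within bursts,
correlations among STN neurons, or pallido-subthalamic feedback, so passing
tests show that GP dynamics follow from the assumed drive statistics — not
that real STN spike trains are faithfully reproduced.

## Problem sizes and runtime

The shipped experiments and tests use desk-scale sizes chosen to keep a
full run comfortable on a single core: 500-neuron isolated
characterizations (2.5 s each), 13 s network trials of 100 GP + 50 STN
neurons (~15 s of wall clock each), batteries of 3–4 trials, and 6.5 s
runs for the post-downregulation protocol. Twelve-trial batteries and the
200/300-neuron scaling presets run with the same functions
(`run_trial_battery(cfg, n_trials = 12)`).

## Known limitations

* Gate kinetics are a calibrated stand-in constrained by behavior, not
  measurements; individual channels should not be interpreted
  biophysically.
* The healthy-network category composition deviates as described above.
* The beta-band variant reports STN–GP cross-correlograms only; phase
  categorization is unreliable at <1 spike per 70 ms cycle, so no
  quantitative claims are made there.
* No striatal input, no GP→STN feedback, no transmission delays beyond the
  ≤1 ms delivery quantization, no stochastic channel gating, no SK
  channels.
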