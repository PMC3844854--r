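# pallidalnet

A conductance-based spiking network model of the rodent globus pallidus
(GP) under rhythmic subthalamic (STN) drive, for studying how anti-phase
oscillatory neuron groups emerge under Parkinsonian conditions.

In rodent models of Parkinson's disease, GP neurons — normally tonically
active, uncorrelated pacemakers — become entrained to the ~0.8 Hz cortical
slow wave and split into two groups firing in anti-phase: one with the
active phase of the slow wave (TA) and one with the inactive phase (TI).
`pallidalnet` implements the computational account of this phenomenon as a
network of single-compartment Hodgkin–Huxley GP neurons

> C dV/dt = g_leak (E_leak − V) + Σ_X m^μ h^ρ s^φ g_X (E_X − V) + I_syn + I_ext

with ten voltage-gated channels (NaF, NaP, Kv2, Kv3, Kv4 fast/slow, KCNQ,
HVA, HCN fast/slow), calcium-gated activity-dependent downregulation of the
HCN conductance

> g_HCN(t+Δt) = max[0, g_HCN(t) − k_HCN Δt / (1 + exp((θ − [Ca])/σ))],

double-exponential conductance synapses (GABAergic GP→GP, glutamatergic
STN→GP), stochastic slow-wave-modulated STN spike generators, and the
analysis machinery: phase categorization of neurons by the resultant of
per-spike unit phasors (ω_k = Σ_s exp(iθ(s)), confidence c = |ω|/n,
labels TA/TI/NM/QU) and Brillinger-normalized cross/auto-correlograms
(X' = T·X/(2h·N_A·N_B)) with 95% confidence bounds.

The Parkinsonian (6-OHDA-like) condition is three parameter changes:
STN active-phase rate 30 → 60 Hz, mean STN→GP conductance 0.1 → 0.2 nS,
mean GP→GP conductance 0.5 → 1.0 nS.

## Worked example

```r
library(pallidalnet)

# one mean-parameter GP neuron, no input: intrinsic pacemaking
res <- simulate_isolated(mean_conductances(),
                         protocol = data.frame(duration = 2000, I_ext = 0))
res$spikes[[1]]
#> <spike_train> unit 1: 48 spikes on [0, 2000) ms (24.00 Hz)

# heterogeneous population (NaP 50% CV, HCN 30% CV, truncated at 0)
pop <- sample_population(500, seed = 1)
rr <- isolated_rates(pop)
#> pacemaking: 94.2%  mean rate: 24.5 Hz (sd 8.2)

# a Parkinsonian network trial: 100 GP + 50 STN neurons, 13 s
cfg <- network_config(condition = "parkinsonian", seed = 1)
cfg
#> <network_config> 100 GP + 50 STN, condition 'parkinsonian', 13000 ms, seed 1
#>   fan-outs: GP 20, STN 2 | g_GG 1 nS, g_SG 0.2 nS | active rate 60 Hz | downregulation on
sim <- simulate_network(cfg)

# categorize every neuron on the latter half of the run
reps <- categorize_result(sim)
table(vapply(reps, function(r) r$label, character(1)))
#> NM QU TA TI
#>  1 23 35 41
categorize(sim$spikes[[3]], cfg$protocol, window = c(6500, 13000))
#> <category_report> unit 3: TI (rate 3.54 Hz, c 0.283)
```

The isolated population pacemakes at ~24 Hz and the Parkinsonian network
self-organizes into the two slow-wave-locked groups: here 35 TA neurons
(firing in the active phase) and 41 TI neurons (firing in anti-phase), with
almost no unmodulated cells — the model's central result. `run_experiment()`
wraps the standard protocols (`"characterization"`, `"healthy_battery"`,
`"parkinsonian_battery"`, `"downregulation_ablation"`, `"hcn_blockade"`,
`"scaling_200"`, `"scaling_300"`, `"beta_band"`,
`"post_downregulation_pacemaking"`), and `inst/cli/pallidalnet` is a thin
command-line front end over the same functions.

See the vignette (`vignettes/pallidal-network-model.Rmd`) for the model's
assumptions, the gate-kinetics calibration (the kinetics ship as a
replaceable data file, `inst/extdata/gate_kinetics.csv`), numerical
choices, and known limitations — including where the healthy-condition
network deviates from the reference data and why.

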