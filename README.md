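# spinalcpg

A spiking-network model of the flexor-extensor spinal locomotor central
pattern generator (CPG), built to ask a timing question in ALS research:
*when* during disease progression does stabilizing inhibitory V1 synapses
onto motoneurons restore healthy motor output, and when does it backfire?

The package simulates one side of the lumbar CPG — flexor and extensor
rhythm-generating half-centers coupled by mutual inhibition, V2a excitatory
relays to the motoneuron pools, reciprocal Ia inhibition, Renshaw-cell
recurrent inhibition, and cholinergic V0c drive — then degrades it the way
spinal circuits degrade in the SOD1^G93A^ mouse model (staged V1
interneuron dysregulation, late V2a/motoneuron loss, cholinergic
compensation), applies interventions (V1 synaptic stabilization, cell
sparing, full rescue, slowed synaptic kinetics), and quantifies the
motoneuron output with the metrics used for locomotor rhythms.

## The model

Neurons are adaptive exponential integrate-and-fire (AdEx) units,

```
C dVm/dt = -gL (Vm - EL) + gL DeltaT exp((Vm - Vth)/DeltaT)
           - ge(t)(Vm - Ee) - gi(t)(Vm - Ei) - w + Ibias
tau_w dw/dt = a (Vm - EL) - w
if Vm > 0 mV:  Vm -> Vreset,  w -> w + b,  refractory for t_ref
```

integrated by forward Euler at 0.1 ms, with per-step Gaussian noise on each
neuron's bias current (SD equal to the bias). Synaptic conductances follow a
peak-normalized beta function — a difference of exponentials with separate
rise and decay constants scaled so a weight of 1.0 peaks at exactly 1 nS —
with probabilistic wiring (independent Bernoulli per neuron pair, normally
distributed weights). The flexor rhythm generator contains 30% intrinsically
bursting neurons and drives the rhythm; the extensor contains 10% and fires
tonically when isolated.

Output metrics per trial: Gaussian-smoothed (20 ms), instantaneous-rate-
rescaled population rate traces; peak detection (40% height floor, 0.1
prominence, 250 ms spacing); peak-interval frequency; crossing-based burst
durations; and the flexor-extensor phase difference in degrees folded to
[0, 180]. Statistics across 25-seed trial batteries: 3-SD outlier
exclusion, Wilcoxon signed-rank (flexor vs extensor, Pratt zeros),
Kruskal-Wallis + Dunn post hoc (conditions vs healthy), with the
conventional star thresholds.

## Worked example

```r
library(spinalcpg)

# healthy network, one 10 s trial
sim <- simulate_network(healthy_network(), duration_ms = 10000, seed = 1)
trial_metrics(sim)
#>   side avg_max_rate_hz  freq_hz burst_ms phase_deg n_intervals missing_flags
#> 1    F        91.11320 2.192502 101.9132  178.2301          19
#> 2    E        93.79429 2.198769 354.1893  178.2301          18
```

One healthy trial: both motoneuron pools fire below the 100 Hz reference
line, the rhythm runs at ~2.2 Hz on both sides, the extensor bursts are
much longer than the flexor bursts (the extensor-dominated step cycle of
slow locomotion), and the two pools are in near-perfect antiphase (178 of
180 possible degrees).

```r
# late-stage disease
late <- simulate_network(build_condition("P112_no_intervention"),
                         duration_ms = 10000, seed = 4)
trial_metrics(late)
#>   side avg_max_rate_hz  freq_hz burst_ms phase_deg n_intervals missing_flags
#> 1    F        98.34389 2.463690 141.8700  160.1392          21
#> 2    E        87.74096 2.465917  76.4053  160.1392          21
```

At P112 the disease signature appears: flexor-biased activity (flexor
~98 Hz vs extensor ~88 Hz) and a flexor-dominated step cycle (flexor
bursts now longer than extensor bursts), at a faster and less precisely
antiphase rhythm. Single trials vary; the battery-level statistics over 25
seeds are what the package's tests assert.

Batteries and statistics:

```r
healthy <- run_battery("healthy", seeds = 1:25)
p112    <- run_battery("P112_no_intervention", seeds = 1:25)
flexor_vs_extensor(p112, "avg_max_rate_hz")   # Wilcoxon signed-rank
across_conditions(list(healthy, p112), "freq_hz")  # KW + Dunn vs healthy
```

`condition_matrix()` lists all 19 named conditions (healthy, the three
untreated stages, sparing/stabilization/rescue combinations, and the
slowed-synaptic-dynamics variants); `run_experiment()` writes spike tables,
metric tables, variance-plot data and a provenance manifest for any subset
of them, and `exec/spinalcpg` wraps that as a command line
(`spinalcpg run --condition all --seeds 1:25 --out results/`).

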