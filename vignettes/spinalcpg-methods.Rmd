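---
title: "Modeling flexor-extensor CPG degeneration and synaptic intervention"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling flexor-extensor CPG degeneration and synaptic intervention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`spinalcpg` simulates the flexor-extensor central pattern generator (CPG) of
one side of the lumbar spinal cord as a spiking neural network, degrades it
the way ventral interneuron circuits degrade in the SOD1^G93A^ ALS mouse
model, applies candidate interventions, and quantifies the motoneuron
output. This vignette is the package's account of the model, the analysis
pipeline, the tunable parameters, and the design decisions taken where the
problem was genuinely open.

## The neuron model

Every neuron is an adaptive exponential integrate-and-fire (AdEx) unit:

$$C\frac{dV_m}{dt} = -g_L(V_m-E_L) + g_L\Delta_T e^{(V_m-V_{th})/\Delta_T}
  - g_e(t)(V_m-E_e) - g_i(t)(V_m-E_i) - w + I_{bias},$$
$$\tau_w\frac{dw}{dt} = a(V_m-E_L) - w,$$

with the reset rule: when $V_m > 0$ mV the neuron spikes, $V_m \to
V_{reset}$, $w \to w + b$, and the membrane is clamped at $V_{reset}$ for a
refractory period $t_{ref}$ (the adaptation variable keeps relaxing during
the clamp; synaptic conductances keep evolving). Integration is forward
Euler at $dt = 0.1$ ms; the exponential argument is capped at $+20$ before
exponentiation so the excursion between threshold crossing and reset
detection cannot overflow, while spike detection itself uses the plain
$V_m > 0$ rule. A pure-R reference integrator (`integrate_single_neuron()`)
run at $dt = 0.001$ ms serves as the accuracy oracle for the compiled
engine; at the default step the single-neuron spike count agrees with the
fine-step reference to within 5% across the drive range used in the model.

Two parameter sets are shipped (`adex_tonic()`, `adex_bursting()`). The
bursting set places the reset above the exponential threshold
($V_{reset} = -46 > V_{th}+\ldots$ effective rheobase at $E_L=-58$ mV), so
each spike re-triggers the next until the slowly accumulating adaptation
current ($b = 75$ pA per spike, $\tau_w = 280$ ms) terminates the burst;
$\tau_w$ is the main knob for the 2-3 Hz network rhythm. The tonic set is a
classical regular-spiking parameterization with moderate adaptation.
Motoneurons use the tonic template with a longer refractory period (7 ms)
and adaptation tuned so their instantaneous rates stay in the 50-100 Hz
range observed for spinal neurons during walking.

Gaussian white noise is added to each neuron's bias current at every step,
with mean 0 pA and standard deviation equal to that neuron's (absolute)
bias; it is sampled once per neuron per step and added without $dt$
scaling — a discrete-noise reading of the stated procedure rather than a
Wiener-increment convention. Undriven neurons therefore receive no noise.

## Synapses

Synaptic conductances follow a peak-normalized beta function
(`beta_conductance()`): a difference of exponentials with separate rise and
decay time constants, divided by its analytic peak so that a weight of 1.0
produces a maximum conductance of exactly 1 nS regardless of the time
constants. When $\tau_{rise} = \tau_{decay}$ the alpha-function limit
$W(s/\tau)e^{1-s/\tau}$ is used (the engine nudges exactly-equal constants
by a relative $10^{-6}$ because its two-state recursion requires distinct
rates; the curve is contract-identical to that precision). Weights are drawn
per synapse from a normal distribution (clipped at 0), each ordered neuron
pair is connected independently with the projection's probability, at most
one synapse per pair, no autapses, and a uniform 1 ms conduction delay is
the default.

The engine maintains the two-state linear recursion of the kernel per
(neuron, kinetics class), so the per-step cost is independent of synapse
count, and the summed conductance sampled on the step grid equals the
closed-form kernel exactly (verified against a pure-R integration in the
test suite).

## The healthy network

The shipped configuration (`inst/extdata/healthy_network.yaml`, loaded by
`healthy_network()`) is the single source of truth for the healthy model:

* **Rhythm generators.** Flexor (RG-F) and extensor (RG-E) populations of 60
  neurons, 4:1 excitatory:inhibitory, 30% bursting neurons on the flexor
  side and 10% on the extensor side. The flexor RG bursts rhythmically when
  isolated; the extensor RG fires tonically (the flexor-driven
  architecture). `isolate_rgs()` reduces the config to this two-population
  system for exactly that check.
* **Mutual inhibition.** RG-F excites V2b, which inhibits RG-E; RG-E
  excites V1RG, which inhibits RG-F. V1RG is V1-derived and degenerates;
  V2b does not. Loss of V1RG inhibition is what lets the flexor rhythm
  accelerate as disease progresses.
* **Output chains.** RG-F → V2a-F → MNP-F and RG-E → V2a-E → MNP-E.
* **Reciprocal Ia inhibition.** Each Ia population is named after the
  motoneuron pool it inhibits: Ia-F receives RG-E excitation plus a tonic
  drive and inhibits MNP-F (and symmetrically for Ia-E). The naming-by-
  target convention keeps every flexor-side synapse carrying an `_F`
  suffix, which is what the side-restricted slow-dynamics intervention
  operates on.
* **Recurrent inhibition.** MNP → RC → MNP on each side.
* **Cholinergic drive.** V0c populations under tonic drive excite their
  motoneuron pool.
* **Drives.** Populations receiving descending or tonic drive (both RGs,
  both Ia pools, both V0c pools, both MNPs) draw per-neuron biases from a
  normal distribution with the population mean and an SD of 25% of that
  mean. Which populations are driven is not enumerable from the source
  material's text; this set is the package's documented interpretation.

Two asymmetries are deliberate and carry the disease phenotype. First, V1
inhibition of the flexor motoneuron pool (Ia-F, RC-F) is several-fold
stronger than of the extensor pool, consistent with reports of stronger V1
connectivity to flexor motoneurons; in health it exactly cancels the tonic
excitation (descending + V0c) of MNP-F, holding the flexor's inter-burst
baseline near zero. Second, the extensor pool's tonic drive sustains a
moderate firing "tail" between its release bursts. Halving V1 connectivity
then releases a large flexor baseline while barely moving the extensor
tail — which is precisely the flexor-biased, flexor-dominated phenotype.

## Disease stages and interventions

`apply_stage()` transforms the healthy config declaratively: population
counts are reduced to `round(survival * n)` (which cells die is left to the
trial's wiring realization, so survival holds in expectation), every
V1-presynaptic projection's connection probability is multiplied by 0.5
from P45 onward (the printed 28% → 14% rule), and the V0c → MNP weights are
multiplied by 1.5 at P112. Descending drives never change. The survival
table (`inst/extdata/stages.yaml`) is editable; the shipped fractions are
directionally faithful — V1 populations affected earliest and deepest, V2a
and motoneurons lost only at P112 — not transcriptions of measured counts,
because the per-population counts exist only in figure form in the source
literature.

`apply_intervention()` composes on top of a stage: `stabilize_v1`
multiplies surviving V1 weights (shipped factor 3, tuned so stabilization
approximately restores the healthy V1 inhibition product across stages);
`spare_v2a` / `spare_mn` reset those populations' counts to healthy;
`rescue_v1` restores V1 cells and probabilities (mutually exclusive with
stabilization, optionally combined with the V0c boost); `slow_dynamics`
doubles the rise and decay constants of the RC→MNP and Ia→MNP inhibitory
and MNP→RC excitatory projections on the flexor side, extensor side, or
both. Because the beta kernel is peak-normalized, slower kinetics deliver
more charge per event at the same peak conductance — which is why flexor-
side slow dynamics plus stabilization over-inhibits the flexor pool and
flips the network to extensor-biased activity, the model's argument for
timing the intervention after synaptic dynamics have recovered.

`condition_matrix()` enumerates the 19 named conditions (healthy plus the
18 disease x intervention panels) and `build_condition()` materializes any
of them.

## Output metrics

`trial_metrics()` computes, per simulation:

* **Rate traces** (`smoothed_rate()`): pooled population spikes convolved
  with a 20 ms Gaussian on the simulation grid, then the whole trace
  multiplied by (maximum instantaneous rate / raw convolved peak), where
  the maximum instantaneous rate is the per-neuron $1000/\min(\mathrm{ISI})$
  maximized over neurons (a pooled-ISI variant is switchable). A raw peak
  of 50 against a 100 Hz instantaneous maximum multiplies the trace by 2.
  The first second of each record is discarded before smoothing
  (`settle_ms = 1000` in `trial_metrics()`): every neuron starts at rest
  with zero adaptation, so the onset volley is unrepresentatively strong
  and would otherwise set the trace maximum that everything else is scaled
  against.
* **Peaks** (`detect_peaks()`): local maxima at least 40% of the trace
  maximum, with prominence at least 0.1 on the max-normalized trace, and a
  minimum peak spacing of 250 ms (higher peak wins). The spacing floor must
  lie above the burst-width scale (~150-250 ms, so a double-humped burst
  counts once) and below the shortest cycle the model produces (333 ms at
  3 Hz); within that admissible range the value was fixed at 250 ms because
  it makes flexor and extensor frequency estimates agree within a
  condition, as they should for a shared rhythm.
* **Frequency**: the mean of successive peak intervals, inverted.
* **Burst durations** (`burst_segments()`): crossings of the flexor and
  extensor traces (linearly interpolated between grid points) delimit
  bursts; flexor bursts are intervals with flexor above extensor; partial
  bursts at the record edges are discarded; durations are averaged per side
  within the trial. No offset is applied to either trace before
  intersection, accepting the known sensitivity of this estimator when the
  two traces run close to each other.
* **Phase difference** (`phase_difference()`): per flexor-midpoint pair
  with an extensor burst between, $360(m_E - m_{F1})/(m_{F2} - m_{F1})$
  degrees folded into $[0, 180]$, averaged over cycles. The formula assumes
  one burst per side per cycle; because crossing-based segmentation can
  emit spurious sub-bursts, the trial pipeline anchors flexor midpoints on
  segments containing a detected rhythm peak and takes the extensor
  midpoint between the crossings bounding the inter-burst interval. Note a
  geometric property of this estimator: for perfectly regular alternation
  it returns exactly 180 degrees regardless of duty cycle, and deviations
  below 180 measure cycle-to-cycle burst-width jitter. At this network
  scale the healthy rhythm is very regular (trial SD near 1.5 degrees), so
  rank tests on phase resolve even few-degree systematic differences that
  a larger, noisier network would not.

Missing metrics (no peaks, no crossings) are reported as `NA` with a flag,
never silently dropped.

## Trial batteries and statistics

`run_battery()` runs one wiring realization + simulation + metrics pass per
seed (default seeds 1-25, 10 s of simulated time, the same ordered seed
list for every condition in a comparison — comparisons refuse to run
otherwise). Outliers beyond 3 SDs of a metric's mean (single pass, within
condition and side) are excluded per metric; a trial can be excluded for
one metric and kept for another, with trial-level exclusion available as a
switch.

Flexor-versus-extensor contrasts use a two-sided Wilcoxon signed-rank test
with Pratt handling of zero differences and a tie-corrected normal
approximation; across-condition contrasts use the Kruskal-Wallis H-test
with Dunn's z post hoc against the control group, unadjusted by default
(Holm available). Stars follow the printed thresholds: `***` at
$p \le 0.001$, `**` at $p \le 0.01$, `*` at $p \le 0.05$, otherwise `ns`.

## What the simulations do and do not show

All inputs are generated internally; there is no external data. The
simulated conditions emulate staged circuit degeneration — cell loss,
halved V1 connectivity, cholinergic compensation, slowed synaptic
kinetics — under constant descending drive. They do not include afferent or
muscle feedback, commissural (left-right) circuitry, or continuous-time
degeneration (stages are discrete snapshots), so passing batteries
demonstrate circuit-level consequences of the modeled changes, not
behavioral predictions about muscle output.

Problem sizes were chosen for desk-scale reproducibility: ~520 neurons,
10 s per trial, 25 trials per condition (a 3-seed `--reduced` smoke mode
exists in the CLI). The scale of the published model is larger; weights,
probabilities and drives here were tuned from scratch against the same
qualitative surface (2-3 Hz rhythm, sub-100 Hz motoneuron rates,
extensor-dominated healthy step cycle, isolated-RG behavior, staged
flexor bias and its interventions), so individual parameter values are
this package's own and not transcriptions.

## Numerical choices

* Forward Euler at 0.1 ms; determinism is bit-exact for identical
  (config, seed, dt, duration).
* Synaptic delays round to integer steps (minimum one step).
* Gaussian kernel truncated at ±4 SD; no edge reflection.
* Weight draws clipped at zero rather than resampled.
* Bursting/tonic mode is assigned to the first `round(fraction * n)`
  neurons of a population (neurons are exchangeable a priori).
* The engine records spikes at the end of the step in which the threshold
  was crossed; inter-spike intervals therefore never fall below
  $t_{ref}$.
* All-zero paired differences in the signed-rank test return $p = 1$
  ("ns" by convention).
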