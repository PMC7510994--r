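---
title: "Modeling neurodegeneration in spiking cortical microcircuits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling neurodegeneration in spiking cortical microcircuits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(izhinet)
```

## The model

`izhinet` simulates isolated cortical microcircuits as networks of
Izhikevich integrate-and-fire neurons and asks how their population
dynamics — mean firing rate, spike-timing irregularity, and transient
population oscillations — respond to progressive neurodegeneration and to
subsequent rewiring by spike-timing-dependent plasticity (STDP).

Each neuron carries two state variables, the membrane potential $v$ (mV)
and a recovery variable $u$, evolving as

$$v' = 0.04 v^2 + 5v + 140 - u + I, \qquad u' = a(bv - u),$$

with the threshold rule: if $v \ge 30$ mV, a spike is recorded and
$v \leftarrow c$, $u \leftarrow u + d$. Excitatory neurons use the
regular-spiking parameterization $(a, b, c, d) = (0.02, 0.2, -65, 8)$ and
inhibitory neurons the fast-spiking one $(0.1, 0.2, -65, 2)$; each neuron's
parameters are jittered by a uniform $\pm 5\%$ so the population is
heterogeneous. Integration is forward Euler at a fixed $\Delta t = 0.2$ ms,
with both right-hand sides evaluated at the pre-step state and the reset
applied within the crossing step.

### Substrate

A network of $n$ neurons (default 1000; 80% excitatory, sweepable
0.65–0.95) is placed uniformly on the unit sphere — a boundary-free domain
that avoids edge effects. Connectivity is Erdős–Rényi-like: each neuron
draws an out-degree from $\mathcal{N}(50, 5^2)$ (so total in + out degree
averages 100 with ~10% relative spread) and targets that many distinct
random neurons, no self-edges. Conduction delays are proportional to
great-circle arclength, capped at 8 ms, and rounded **up** to the timestep
grid so no delay is zero (a zero delay would break event ordering).

Excitatory weights are seeded on $[0, 4]$ from a symmetric bimodal mixture
(two Beta(2, 8) lobes, one reflected), anticipating the bimodal fixed point
of additive STDP; inhibitory weights are seeded on $[-14, 0]$ from a normal
distribution ($\sigma$ = 10% of the unit seeding interval, i.e. 0.05 before
scaling). The "10% variance" of the source description is read as a
coefficient of variation both for degrees and for inhibitory weights, and
the 100-connection figure as *total* (in + out) degree; both readings are
configurable.

### Synapses, desensitization, background drive

Spikes deliver their weight, after the axonal delay, into the target's
excitatory or inhibitory drive accumulator; accumulators decay
exponentially with $\tau = 5$ ms (fast AMPA / GABA$_A$ kinetics; slow NMDA
/ GABA$_B$ currents are out of scope). The total current is simply
$I = g_\mathrm{exc} + g_\mathrm{inh} + I_\mathrm{background}$ — a
current-based (not conductance-based) synapse model. A neuron that has just
spiked attenuates its subsequent inputs by 40% (factor 0.6, reset on every
spike, non-cumulative), relaxing back to 1 with $\tau = 150$ ms; we read
"attenuated at 40%" as attenuated *by* 40%, and the alternative (to 40%)
remains a one-line configuration change.

Background drive is a per-neuron Poisson process (1 Hz) of current events
with amplitudes $15 \times \Gamma(k{=}2, \theta{=}0.5)$. The event is
injected into the decaying excitatory accumulator (default
`stimulus_model(mode = "decay")`): a mean-amplitude event then fires a
resting regular-spiking neuron in ~3 ms, satisfying the requirement that
background events be suprathreshold. We also provide a one-timestep impulse
mode, but note that a single-step impulse of amplitude 15 depolarizes a
resting neuron by only ~3 mV and can never fire it, which is why the
decaying injection is the default.

### Plasticity

STDP follows the additive Song rule at excitatory→excitatory synapses only:

$$\Delta w = \begin{cases} A_+ \, e^{-\Delta t/\tau} & \Delta t > 0 \\
 -A_- \, e^{-|\Delta t|/\tau} & \Delta t \le 0 \end{cases},
 \qquad \Delta t = t_\mathrm{post} - t_\mathrm{pre},\ \tau = 20\ \text{ms},$$

with hard clipping to $[0, 4]$. The increment magnitudes are not part of
the published parameterization; we adopt the canonical Song values
$A_+ = 0.005\,w_\mathrm{max}$ and $A_- = 1.05\,A_+$ (slight depression
dominance), both configurable. Interactions are all-pairs, implemented
online with exponentially decaying pre- and post-synaptic eligibility
traces; the test suite proves the trace scheme equal to brute-force
all-pairs summation to $10^{-9}$. Pairing uses spike *emission* times
(coincident spikes fall on the depression branch); arrival-time pairing is
a recognized alternative that is not implemented. Additive updates with
hard bounds were chosen over multiplicative ones because their known
bimodal fixed-point distribution matches the bimodal seeding; after tens of
simulated minutes the mid-range weight mass indeed collapses toward the
bounds (a property test watches this).

### Per-step order of operations

Within each 0.2 ms step: decay plasticity traces; decay accumulators;
deliver due queued spikes (scaled by the target's desensitization factor);
inject background events; Euler-update all neurons and record threshold
crossings (spike time = step start); apply STDP (potentiation of incoming
synapses of post-spikers before bumping traces, so same-step pairs
depress); enqueue outgoing spikes at $t + \mathrm{delay}$ with the weight
current at emission; update desensitization. The delay queue is a ring
buffer of $\mathrm{max\_delay}/\Delta t$ slots (O(1) per event); in-flight
spikes crossing a simulation-block boundary are carried in the returned
state and delivered when the simulation continues.

## Measuring activity

Five metrics summarize each (default 5-minute) measurement window:

* **firing rate** — spikes per second per surviving neuron, averaged over
  the population (silent neurons included);
* **CoV ISI** — per-neuron SD/mean of inter-spike intervals (neurons with
  fewer than two spikes skipped), averaged;
* **oscillation frequency, magnitude, width** — from the count of spikes
  in a 10-ms window slid at the timestep stride. Local maxima with
  topographic prominence ≥ 1 spike are oscillation events; magnitude is the
  peak count (also expressed as a fraction of surviving network size) and
  width is the full width at half maximum.

Three detector conventions are not fixed by the published description and
are our choices: the stride (one timestep), the half-maximum reference
(half of the prominence-referenced height rather than half of the absolute
peak, because absolute-height FWHM is undefined when background activity
exceeds half the peak; a switch selects the alternative), and a minimum
separation of 10 ms between accepted peaks (one window) to avoid
double-counting a single volley. The prominence threshold is read in units
of spikes per window; fraction-of-network units would be the other reading.

For oscillation-phase analyses, each event's interval is $1.4 \times$ FWHM
centered on the peak, split into deciles (or quintiles for figure-level
summaries); a group's firing likelihood per bin is its share of in-interval
spikes (the per-neuron-probability alternative is selectable). The
**neuron-connectivity index** is
$(\sum |w_\mathrm{in}| - \sum |w_\mathrm{out}|)/(\sum |w|)$, in $[-1, 1]$,
undefined for isolated neurons. We evaluate its correlation with firing
rate over the excitatory population: the index is an excitatory-focused
construct, and inhibitory neurons — whose strong *output* weights drive
their own rates up through network feedback — sit on a different branch of
the relation and dilute a pooled correlation.

## Protocols

`run_protocol()` reproduces the experiment: build → settle with STDP →
measure baseline → for each injury condition: copy, delete, measure 5
minutes with **frozen** weights, recover with STDP, measure again. Settling
simulates 5-minute blocks until firing rate and oscillation frequency both
change by under 1% between consecutive blocks (cap 4 simulated hours);
recovery uses the same rule. Injuries delete `round(fraction * n)` neurons
of the *settled* network in one step (independent copies per level, not
cumulative): randomly at a fixed 4:1 excitatory:inhibitory ratio, focally
(nearest-k to a random lesion center, kind-agnostic), or by baseline firing
rate (LFR/HFR, excitatory only, seeded tie-breaking). When no oscillation
survives an injury the oscillation metrics are reported missing, not zero.
One master seed spawns per-replicate, per-stage child streams, so a
replicate's conditions share one settled network and the whole protocol is
bit-reproducible. Group comparisons use one-way ANOVA with Tukey–Kramer
post hoc tests (`anova_tukey()`) and Welch t-tests with Bonferroni
correction (`ttest_bonferroni()`), at $\alpha = 0.05$ by default.

`ei_sweep()` runs the baseline-only protocol across excitatory fractions
(0.65–0.95), normalizing group means to the 80% reference network and
tracking quintile phase occupancy per composition.

## Scales, runtimes, and what the tests show

Two documented profiles exist. The full-scale profile
(`protocol_config()`: 1000 neurons, 4-hour settling caps, 5-minute windows,
10 replicates) matches the study conditions and runs for hours per
replicate on one CPU; `scripts/full_scale_baseline.R` measures its baseline
metrics and writes them with a run manifest. The desk profile
(`desk_config()`: 300 neurons, 60-s blocks, 20-minute settling cap, 60-s
windows, 5 replicates) is used by the test suite. It deliberately keeps the
full-scale *per-neuron connection count* (mean total degree 100) instead of
scaling the degree with $n$: each neuron's recurrent input, not the
network-wide edge density, sets the dynamical regime, and with only ~30
connections per neuron a small network is dominated by the 1-Hz background
drive — firing pinned near 1 Hz, injury responses flat — which would make
every directional comparison vacuous. With the input count preserved, the
reduced network fires at ~5 Hz, oscillates, develops the index–rate
correlation (r ≈ 0.9 over excitatory neurons), loses rate and oscillation
frequency under 40% random deletion, regains rate with STDP recovery, and
is hurt more by low-firing-rate than by high-firing-rate targeted deletion
at 10% — the directional fingerprint of the full model.

The synthetic substrate emulates the stated construction (sizes, ratios,
degrees, weight scales, delays) but not features of real cortical tissue
that the model itself abstracts away: no distance-dependent connection
preference (a hook exists but only the random topology is built), no
conductance-based or slow synapses, no inhibitory plasticity, no
cell-type diversity beyond RS/FS. Passing tests therefore certify the
simulation and analysis machinery and the model's internal directional
logic, not quantitative agreement with any particular biological
recording.

Known limitations: absolute oscillation statistics are sensitive to the
detector conventions above (a 1-spike prominence threshold counts many
small inter-volley ripples, so detected event rates run well above the
rate of large coherent volleys); the A± magnitudes are conventions, and
longer settling slowly raises mean rate as weights polarize. These affect
level comparisons against published summary numbers, not the within-model
contrasts the protocols are built around.

## A short session

```{r example, eval = FALSE}
net <- build_network(n = 300, mean_degree = 100, seed = 1)
cfg <- desk_config()
st <- settle(net, cfg, seed = 2)
base <- simulate_network(st$network, 60000, stim = cfg$stim,
                         stdp = cfg$stdp, state = st$state, seed = 3)
summarize_metrics(base$raster, st$network$neurons$id)

rates <- firing_rate(base$raster, ids = st$network$neurons$id)$per_neuron
inj <- injure(base$network, 0.4, "random", seed = 4)
post <- simulate_network(inj$network, 60000, stim = cfg$stim, seed = 5)
summarize_metrics(post$raster, inj$network$neurons$id)
```
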