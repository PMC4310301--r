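---
title: "Error-driven learning of short-term plasticity: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Error-driven learning of short-term plasticity: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stpnet)
```

## The model

`stpnet` simulates recurrent networks of conductance-based
integrate-and-fire neurons in which every synapse carries three coupled
plasticity processes:

1. **Short-term plasticity (STP)** in the Tsodyks–Markram form. Each
   synapse $j \to i$ has a depression variable $r_{ij}$ (available
   resources) and a facilitation variable $u_{ij}$ (release probability).
   Between spikes $r$ recovers toward 1 with time constant
   $\tau_{rec}$ and $u$ relaxes toward the utilization $U$ with time
   constant $\tau_{facil}$; a presynaptic spike facilitates
   ($u \mathrel{+}= U(1-u)$), releases $r\,u$ and depletes $r$ by the
   released amount.
2. **Triplet spike-timing-dependent plasticity (STDP)** with hard bounds,
   acting on the maximum strength $A_{ij} \in [10^{-3}, 1]$. Each neuron
   carries two presynaptic traces ($m^1$, fast; $m^2$, slow) and two
   postsynaptic traces ($o^1$, $o^2$); a spike of neuron $i$ potentiates
   its incoming synapses by $\gamma\, m^1_j (A_2^+ + A_3^+ o^2_i)$ and
   depresses its outgoing synapses by $\gamma\, o^1_k (A_2^- + A_3^-
   m^2_i)$, the slow traces read just before the triggering spike's own
   increment. The triplet term makes potentiation frequency dependent:
   at high rates neurons that fire together wire together, at low rates
   the pair-like balance combined with a temporally ordered drive favors
   unidirectional connections.
3. **Error-driven STP learning.** Each population carries a target rate
   $\nu_{targ}$; per-neuron rates are estimated by an exponential moving
   average with $\tau_\nu = 1$ s and averaged within the population.
   When neuron $i$ spikes, its *incoming* synapses descend the gradient
   of $E = ((\nu_{targ} - \langle\nu\rangle)/\nu_{lim})^2$ through
   mean-field surrogate rate relations ($\langle\nu\rangle \le
   A/\tau_{rec} + I_{ext}$ and its $U$- and $\tau_{facil}$-analogues),
   giving per-spike updates for $\tau_{rec}$, $U$, $\tau_{facil}$ and an
   STP-dependent update for $A$ that adds to the STDP change. Learning is
   therefore *target specific*: what a synapse becomes depends on the
   population of its postsynaptic neuron.

The effective efficacy transmitted by a spike is $w_{ij} = r_{ij} u_{ij}
A_{ij}$; conductances decay with $\tau_g = 10$ ms and drive the membrane
through $\dot V_i = -g_L V_i + \sum_j g_{ij}(E_{rev} - V_i)$ with a 1 mV
threshold, reset to 0 and a 10 ms refractory period, which caps rates at
$\nu_{lim} = 100$ Hz.

The mean-field module (`meanfield_rhs()`, `fixed_point_F()`,
`rate_bound()`) implements the population-level equations the learning
rules are derived from. It serves as an analytic validation surface: the
test suite checks that each implemented learning rule has the sign of the
corresponding surrogate gradient by finite differences, and that the
high-rate limit of the fixed-point relation equals $A/\tau_{rec} +
I_{ext}$. The gain constants `a` and `theta` are only used here, never in
the network simulation.

## Stimulus and architectures

Input neurons receive a **sequential wave**: suprathreshold 2 mV pulses
cycling through the input population with lag $t_{delay} =
1/(\nu_{in} N_{in})$ at $\nu_{in} = 10$ Hz per neuron, jittered by a
Gaussian of SD $0.1\,t_{delay}$; draws that would invert the firing order
are resampled, so the wave order is always preserved. Input neurons can
fire above, but never below, the stimulus rate.

Two published architectures are built by `network_spec()`:

* **single** — 40 neurons all-to-all (30 input + 10 output), one shared
  target alternating low (5 Hz) / high (30 Hz) in four 500 s phases,
  $\gamma = 2$ in low and $1$ in high phases;
* **double** — two mirrored 40-neuron branches (80 neurons) with fixed
  branch targets 30 Hz and 5 Hz, $\gamma = 2$; cross connections between
  functionally different populations are absent and lateral homologous
  connections start weak ($A \in [10^{-3}, 10^{-1}]$).

Parameters initialize uniformly: $U \in [0.05, 0.95]$,
$\tau_{rec} \in [100, 900]$ ms, $\tau_{facil} \in [1, 900]$ ms,
$A \in [10^{-3}, 1]$, with $r = 1$, $u = U$.

## Units and the two calibration constants

The membrane equation as printed equates conductance·voltage with
voltage/time, so conductances are treated numerically as rates (1/ms) —
the convention of the source single-neuron model. This leaves one genuine
free scale: how strongly one released quantum drives the membrane. We
use a size-normalized coupling, injecting $w_{ij}\,\kappa/N$ per spike
(the mean-field normalization that makes total recurrent drive
independent of network size), with a single dimensionless constant
$\kappa$ shared by both architectures.

$\kappa$ was calibrated once, before any quantitative comparison, against
three qualitative conditions the experiments require: (i) both output
populations can hold their targets in both architectures; (ii) the 30 Hz
target is reachable only with facilitated synapses — a network whose
recovery time constants are frozen saturates well below it, which is the
premise behind the minimal model and the reported failure of the
$(U, A)$-only scheme; (iii) input populations stay near the 10 Hz wave
floor in low-target phases, preserving the temporal order that the STDP
motif mechanism needs. This gives $\kappa = 0.27$ (`coupling` in
`default_params()`).

The second free scale is the magnitude of the per-spike learning updates
(the paper's update rules carry no units). Internally rates are in Hz and
time constants in seconds, which makes a single update of order 1 ms for
$\tau_{rec}$ and $10^{-3}$ for $U$; a global factor `learn_scale`
(default 5) was set so that the low-target branch survives the initial
transient and parameter convergence completes within a few hundred
simulated seconds, matching the reported phase-resolved dynamics. Both
constants are ordinary config fields and were frozen before the
acceptance measurements; they are not per-experiment dials.

## Numerical choices

* Explicit Euler for the membrane at $dt = 1$ ms (the printed
  discretization); conductance, trace, rate-EMA and STP relaxations use
  exact per-step exponential factors (stabler than Euler when
  $\tau_{facil}$ approaches $dt$), with per-synapse factors cached and
  refreshed when learning changes a time constant.
* Per-step order: stimulus pulses → continuous decays → membrane step
  (refractory neurons clamped at $V = 0$) → threshold detection →
  presynaptic STP release and conductance injection → STDP (all traces
  read at pre-increment values, so simultaneous spikes interact only
  through past activity) → trace increments → error-driven updates of the
  spikers' incoming synapses → a single clipped update of $A$ per step
  (STDP and STP contributions summed first) → rate EMA and population
  means → recording. Spikes therefore affect targets from the following
  step, the one-step transmission delay implied by the discretization.
* The rate EMA adds a unit impulse (+1 Hz) per spike so steady firing at
  $f$ Hz estimates $f$ Hz; estimates are capped at $\nu_{lim}$. A
  literal per-step indicator would estimate $f/1000$ and could never be
  compared with targets in Hz.
* STP parameters are clipped to their bounds after every update; $A$ is
  clipped once per step after summing both contributions. Synapses
  excluded by the architecture mask stay exactly 0 and never enter
  learning.
* On a presynaptic spike the facilitation increment is applied before
  release (the standard Tsodyks–Markram convention; the pre-increment
  variant is available as `facil_first = FALSE`). Single-synapse traces
  (`synapse_trace()`) follow the paired-pulse measurement convention of a
  fully rested synapse, $u_0 = 0$, so the first amplitude is exactly $U$
  and facilitation appears as a rising train; inside the network $u$
  rests at $U$.
* Stimulus pulses arriving during a target's refractory period are
  absorbed (the membrane stays clamped); at 10 Hz against a 10 ms
  refractory period this is rare. By default synaptic conductances do
  accumulate during refractoriness (`refrac_gate = FALSE` keeps the
  published reading; the gate exists as a sensitivity switch).
* The inner loop is compiled (Rcpp); a plain-R reference implementation
  of the identical step order lives in the test suite and the two are
  asserted equal to $10^{-10}$ on a 400-step run, including identical
  spike rasters.

## What the simulations do and do not show

The simulator *is* the data generator here — there is no external data.
The canonical problem sizes are the published ones: four 500 s phases for
the single-population experiment and 300 s for the double-population
runs (rates converge within ~50 s, parameter group means within
~200 s), with three to five replicate seeds per quantity. All
randomness is confined to three separable streams (initialization,
stimulus jitter, analysis nulls), so every run is exactly reproducible
from its seeds.

Known limitations, measured honestly by the acceptance checks rather
than smoothed over:

* In the **double** scenario the two output populations differentiate as
  published: facilitating synapses and near-reciprocal motifs onto the
  30 Hz target, depressing synapses and unidirectional motifs onto the
  5 Hz target. In the **single** scenario the low-phase output population
  in this implementation either fires in synchronized volleys (driving
  all output–output weights to the upper bound, symmetry index ≈ 1) or
  falls silent; the intermediate spread-phase regime that carves the
  published low-phase symmetry value never appears. The high-phase
  symmetry result is reproduced.
* The $(U, A)$-only scheme is bistable across seeds: the high-target
  population either plateaus near half its target (the published failure
  mode) or goes silent during the initial transient. Averages over seeds
  sit below the published plateau.
* There is no membrane noise, so a silent population with sub-threshold
  drive is an absorbing state; real circuits (and models with background
  noise) can escape it.
* Inhibitory neurons, non-deterministic release, and figure-for-figure
  graphics are out of scope.

## Reading results

`run_simulation()` returns per-second traces (population rates, output
symmetry, projection-group parameter means), per-phase parameter
snapshots and optionally the full raster. `group_summary()` reproduces
the projection-group table of the double scenario, mapping the pooled
and source-resolved groups onto the facilitation-dominated (E1, with
subtypes E1a/E1b) and depression-dominated (E2, E2a/E2b) synaptic
classes. `symmetry_index()` and `symmetry_p_value()` quantify motif
structure against the iid-uniform null, whose mean
$2 - 2\ln 2 \approx 0.614$ is available in closed form as a sampler
cross-check; p-values use the Monte-Carlo null moments with a normal
approximation, reproducing order-of-magnitude verdicts rather than exact
published tail values (the analytic null variance lives in companion
work and is not reprinted).
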