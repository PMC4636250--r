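---
title: "Voltage-based STDP with fast BCM-like metaplasticity in a compartmental granule cell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voltage-based STDP with fast BCM-like metaplasticity in a compartmental granule cell}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Dentate gyrus granule cells in vivo show an unusual form of synaptic
plasticity: high-frequency stimulation (HFS) of the medial perforant path
(MPP) induces long-term potentiation (LTP) of the tetanized synapses and,
at the same time, long-term depression (LTD) of the *non-tetanized* lateral
perforant path (LPP) synapses.  The effect depends strongly on the temporal
pattern of stimulation: 400 Hz delta-burst stimulation (400-DBS) is highly
effective, a 400 Hz theta-burst variant (400-TBS) less so, and the standard
100 Hz theta-burst protocol (100-TBS) — normally an efficient LTP protocol
in vitro — produces only weak changes.

`dentatestdp` simulates a mechanistic account of this pattern: a
spike-timing-dependent plasticity (STDP) rule whose postsynaptic event is a
*local dendritic voltage threshold crossing* (sometimes called ETDP),
combined with a fast Bienenstock–Cooper–Munro (BCM)-like homeostatic
scaling of the plasticity amplitudes, all embedded in a reduced-morphology
multicompartment granule cell that receives ongoing spontaneous afferent
activity on every synapse.

## The model

### Cell

The cell follows the reduced granule-cell morphology of Aradi & Holmes
(1998) as adapted by Santhakumar et al. (2005): a soma (16.8 um) and two
symmetric dendritic branches, each a chain of granule-cell-layer (50 um),
inner, middle and outer molecular layer sections (150 um each).  The
default discretisation has 125 compartments; a 9-compartment reduced mode
(one per section) is used for parameter scans and batch work.  150 medial
path synapses are placed uniformly at random on the MML sections and 150
lateral path synapses on the OML sections.  Each synapse is a
double-exponential conductance (rise 0.2 ms, decay 2.5 ms, reversal 0 mV)
whose waveform is normalized so a single afferent spike peaks exactly at
the synaptic weight (the peak conductance, in uS).

Membrane mechanisms are parameter data kept in a JSON registry, one file
per named source.  The default source, `fallback-hh`, is a simplified set
authored and calibrated for this package: Na and fast delayed-rectifier K
everywhere, plus a generic high-threshold Ca channel and an SK-type
Ca-activated K channel.  A second source, `modeldb-51781`, carries a
best-effort transcription of the published granule-cell densities (ModelDB
accession 51781); it is provided for completeness, but all packaged tests
run on `fallback-hh`.  The calibration targets of the fallback set are
behaviours, not channel-level data: a stable rest near −78 mV; somatic
action potentials that cross 0 mV; active back-propagation that carries the
spike above the −37 mV plasticity threshold in the OML; failure of the
passively conducted spike to reach −37 mV in the OML when dendritic Na/Ca
channels are blocked; a refractoriness that yields only 2–5 somatic spikes
per 10-pulse 400 Hz burst while following discrete 100 Hz pulses almost
one-to-one; and a slow (Ca pool tau = 120 ms) SK-mediated adaptation that
keeps the between-burst background firing near its baseline rate during
stimulation trains.  The last point matters for the science: the
homeostatic signal integrates *all* somatic spikes, so uncontrolled
background firing during trains would overstate the homeostatic response.

### Plasticity rule

Each synapse keeps a weight `w` updated multiplicatively,
`w <- w (1 + dw_p − dw_d)`, under a presynaptically centered
nearest-neighbour pairing: each presynaptic spike is paired with at most
two postsynaptic events — the latest one before it (depression,
`dw_d = A_d exp(dt/tau_d)`, `dt = t_post − t_pre < 0`) and the earliest one
after it (potentiation, `dw_p = A_p exp(−dt/tau_p)`, `dt > 0`).
Postsynaptic events are not consumed by pairing.  A simultaneous pair
(`dt = 0`) contributes to neither window.  The postsynaptic event is a
rising crossing of −37 mV by the membrane potential at the synapse's own
compartment; somatic spikes (0 mV crossings) feed a separate, global
detector.

The amplitudes slide homeostatically with the exponentially weighted
average somatic spike count:

    <c>(t) = (alpha/tau) * integral c(t') exp(-(t-t')/tau) dt',
    A_p(t) = A_p(0) / <c>,    A_d(t) = A_d(0) * <c>

implemented as the exact one-step recursion
`<c> <- <c> exp(−dt/tau) + (alpha/tau) dt [spike]`.  High average firing
therefore shrinks prospective LTP and enlarges prospective LTD, and their
product is conserved.  For constant-rate firing the steady state is
`alpha * dt * rate`; with the defaults (`alpha = 2500` at `dt = 0.2` ms,
i.e. `alpha * dt` held at 500 ms) a 2 Hz somatic rate gives `<c> = 1`, so
the amplitudes sit at their initial values at baseline.

Default parameters: `A_p(0) = 0.003`, `A_d(0) = 0.001` (3:1),
`tau_p = 20` ms, `tau_d = 70` ms, `tau_c = 60` s, dendritic threshold
−37 mV, somatic threshold 0 mV, hard ±100 % bound on the weight relative
to its baseline.

### Afferent drive

Every synapse receives an independent quasi-periodic spontaneous train:
inter-spike intervals are drawn as
`ISI = (1 − noise) ISI0 + Exponential(mean = noise * ISI0)` with
`ISI0 = 125` ms and `noise = 0.05`, i.e. a lightly jittered 8 Hz train
(fully periodic at `noise = 0`, Poisson at `noise = 1`).  The HFS protocols
are deterministic nested pulse trains (400-DBS: 10 pulses at 400 Hz x 5
bursts at 1 Hz x 10 repeats at 1 min, 500 pulses; 100-TBS: 4 x 100 Hz x 10
bursts at 5 Hz x 8 repeats at 10 s, 320 pulses; 400-TBS: the same with
400 Hz intra-burst frequency).  Protocol pulses are superimposed on the
spontaneous trains of a seeded random subset of medial synapses (the
tetanized fraction, 60 % by default); spontaneous activity continues
throughout.

What the generator emulates: the mean rate, the quasi-periodicity and the
per-synapse independence of perforant-path spontaneous activity, and the
superposition of stimulation on top of it.  What it does not emulate:
slow rate modulation (theta/behavioural state), correlations between
afferents beyond the shared mean period, HFS-evoked changes in presynaptic
firing, and synaptic failures or short-term plasticity.  Note also that
with independent jitter the afferent phases drift apart, so trains that
start synchronized are effectively desynchronized after the first minute
or two of simulated time; passing tests therefore speak to the
steady-state regime, not to transient volley-locked firing.

## Numerical choices

* **Integrator.** Backward-Euler cable solve on the branched tree (a Hines
  elimination, parents ordered before children) with staggered
  exponential-Euler gate updates; synaptic conductances advance by exact
  exponential decay with event increments.  An implicit scheme is required
  by the stiffness of active membrane; explicit schemes were rejected.
  `dt = 0.2` ms is the working default, `dt = 0.1` ms the convergence
  check; halving `dt` moves somatic spike times by well under 1 ms.
* **Event detection.** Rising threshold crossings, linearly interpolated
  between samples.  After a crossing, no new event at the same compartment
  for 5 ms (one action-potential width), so one depolarization is counted
  once.  The same debounce applies to the somatic detector.
* **Update timing.** `<c>` and the amplitudes advance every step; an event
  inside a step uses the amplitudes current at that step's end (the step
  index is the authoritative clock, so the closed-loop engine and the
  standalone event-driven evaluator agree exactly).  The depression term
  of a presynaptic spike applies immediately (its preceding event is
  known); the potentiation term applies when the next postsynaptic event
  arrives, or lapses after `5 tau_p` without one.  The depression window
  needs no explicit lapse: its exponential is negligible beyond `5 tau_d`.
* **Degenerate inputs.** `<c>` is floored at 1e-3 so `A_p` stays finite at
  start-up; weight updates are disabled during a warm-up of one
  integration period (`tau_c`) while `<c>` (initialized at its baseline
  steady state of 1) equilibrates to the cell's actual rate.  Updates that
  overshoot the ±100 % bound are clamped, not rejected; the lower clamp is
  symmetric to the published upper bound (the source only states the upper
  one) and keeps weights strictly positive.  Spikes landing within one
  integration step at one synapse merge into a single spike.
* **Baseline weights.** Not published; a seeded bisection calibrates the
  uniform peak conductance so that 8 Hz spontaneous drive at all 300
  synapses yields a ~2 Hz somatic rate, which makes baseline `<c> = 1`
  and flat amplitudes.  The calibrated value is recorded in every run
  manifest.

## Study conditions and problem sizes

The packaged experiments run at: 9-compartment reduced morphology,
`fallback-hh` mechanisms, one `tau_c` (60 s) of warm-up, 2 min of baseline,
the full protocol, and 10 min of post-stimulation time; pathway changes
are measured as the per-synapse percent change from the weight at protocol
onset, averaged over the last 2 min, then summarised as mean ± SD over
runs (3 runs by default, 10 for the robustness scans, as in the source
experiments).  The test suite exercises these full-length conditions for
the headline properties (protocol ordering, the lateral-silencing control,
the temporal order of LTP and LTD onsets) and uses shorter baselines and
post periods for mechanics-level checks; the 125-compartment mode is
reserved for the morphology and back-propagation tests.

## What the simplified biophysics can and cannot claim

With the calibrated `fallback-hh` set the package reproduces the
qualitative pattern that is the point of the model: robust medial LTP with
concurrent lateral LTD under 400-DBS, intermediate changes under 400-TBS,
weak changes under 100-TBS (with strong homeostatic braking of `A_p`
during 100-TBS), loss of lateral LTD when lateral spontaneous activity is
silenced, persistence of medial LTP but loss of lateral LTD when dendritic
Na/Ca channels are blocked, and LTP onset preceding LTD onset.  The
printed quantitative magnitudes of the original study are tied to the full
ModelDB-51781 biophysics; with the simplified channel set the simulated
magnitudes are of the same sign and ordering but systematically smaller
(roughly half), and the `summarize_scenarios()` comparison table
accordingly marks all rows "conditional" unless that mechanism source is
in use.

## Known limitations

* The `modeldb-51781` registry entry is a best-effort density
  transcription onto this package's channel forms, not the verbatim
  kinetics of the accession; quantitative work against the published
  magnitudes should treat it as approximate.
* No short-term plasticity, receptor saturation, stochastic gating,
  temperature dependence, or network feedback (each out of scope for the
  model being implemented).
* One plasticity threshold serves both LTP and LTD, and metaplasticity is
  cell-wide; local or pathway-specific metaplasticity is not modelled.

## A minimal session

```{r example}
library(dentatestdp)

b <- run_experiment(experiment_spec("400-DBS", tetanized_fraction = 0.6,
                                    n_runs = 3))
measure_pathway_change(b)
autoplot(b)                      # Weight evolution, both pathways
autoplot(b[[1]], "homeostasis")  # <c>, A_p, A_d
weight_vs_distance(b[[1]])$correlations

# the full scenario registry
scenario_catalog()
run_scenario("fig3", overrides = list(n_runs = 3))
```
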