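---
title: "Models and methods behind mmnsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mmnsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`mmnsim` simulates auditory novelty detection — the phenomenon underlying
the mismatch negativity (MMN) — in a spiking network of leaky
integrate-and-fire (LIF) neurons, and probes how cellular alterations
associated with schizophrenia degrade it. This vignette explains the
models, every tunable constant that matters, the choices made where the
design was genuinely open, and the limits of what the simulations
establish. It states no empirical result that the test suite or the
acceptance script does not itself compute.

## 1. The simulation engine

Neurons are single-compartment LIF units integrated by exponential Euler
at a fixed step (`dt = 0.1` ms by default):

$$C_m \frac{dV}{dt} = -g_L (V - E_L) - \sum_s g_s(t)\,B_s(V)\,(V - E_s)
  + I_\text{pulse}(t) + I_\text{noise}(t).$$

Within a step the conductances are held constant for the membrane update
and decayed exponentially afterwards; a neuron whose voltage reaches
threshold is reset and clamped for the refractory period, with the spike
timestamped at the end of the crossing step. The engine aggregates all
synapses of a neuron into one AMPA, one NMDA and one GABA channel, so
decay constants and reversal potentials are per-network constants
(`kinetics_config()`): AMPA $\tau = 2$ ms, NMDA $\tau = 100$ ms with the
standard sigmoidal magnesium block
$B(V) = 1/(1 + [\mathrm{Mg}]/3.57\,e^{-0.062V})$, GABA $\tau = 10$ ms,
$E_\text{exc} = 0$ mV, $E_\text{inh} = -80$ mV. These kinetics are not
given in the main text of the underlying study; they are conventional
cortical values, and the grid search defines which combinations of the
*fitted* parameters work on top of them.

Noise is white Gaussian current per neuron. Its amplitude is quoted as
the per-step standard deviation at the 0.1-ms reference step and rescaled
by $\sqrt{0.1/dt}$ for other steps, so membrane-voltage statistics are
comparable across step sizes. All randomness is driven by explicit
integer seeds through a platform-independent generator; identical
`(network, inputs, dt, seed)` reproduce a simulation bit for bit.
Halving `dt` moves the spike times of the analytic single-neuron case by
less than one step (tested).

Short-term depression follows the release-fraction model: the fraction
of releasable vesicles obeys
$dD/dt = -p_v D \sum_j \delta(t - t_j^-) + (1 - D)/\tau_D$, handled
event-driven with the exact closed form between spikes. A presynaptic
spike transmits $w \cdot D$ (evaluated just before release); whether the
efficacy should additionally carry the factor $p_v$ is not specified in
the source model, so the transmitted conductance uses $w\,D$ alone — the
choice only rescales the fitted conductances.

## 2. The novelty-detection network

`build_mmn_network()` assembles nine populations of 40 neurons:
tone-tuned excitatory/inhibitory pairs for the standard (ES, IS) and the
deviant frequency (ED, ID); delayed-activating populations (ESD, EDD)
identical except for a larger membrane capacitance, which makes them
charge too slowly to fire within a 50-ms tone but fast enough within a
100-ms tone; two pacemaker-driven populations phase-locked to the 2-Hz
presentation rhythm (EP at the tone phase, EP2 50 ms earlier, aligned
with the first half of long tones); and the output population EO. The
six excitatory populations project to EO with depressing AMPA+NMDA
synapses; IS/ID inhibit EP and EP2 without depression; connection
probability is 0.5 throughout, and per-neuron capacitances carry 30%
heterogeneity.

Detection mechanisms, protocol by protocol:

* **Frequency deviant** — repeated standards depress ES→EO; a deviant
  tone recruits the fresh ED→EO synapses.
* **Omission** — EP charges under its pacemaker pulse at every expected
  onset but is clamped by tone-driven inhibition a few milliseconds into
  each tone; only when the tone is absent does EP fire and drive EO.
* **Duration deviant** — the long tone (which starts 50 ms before the
  nominal onset and ends with the short tone) is the only stimulus that
  activates the slow ESD population.
* **Inverse duration deviant** — during long standards the early tone
  segment inhibits EP2; a short deviant leaves EP2's early pulse
  unopposed.

### Protocol structure

Oddball protocols place one deviant after every four standards and
repeat the cycle four times, preceded by four *burn-in* standards that
drive the depression variables to their steady state and are excluded
from standard-trial averaging — the analogue of discarding the first
trials of a recording session. Without burn-in the very first tone,
delivered to fresh synapses, would dominate the standard mean and make
the deviant/standard ratio meaningless. The roving variant concatenates
runs of five identical tones realizing each of the 12 ordered
transitions between the four tone types exactly once (an Eulerian
circuit), plus one omission per tone type.

### Fitted parameters and calibration

Eight parameters are fitted by grid search (5·5·5·7·2·6·2·2 = 42,000
combinations, `default_grid_spec()`): stimulus amplitude, the three
output-bound conductances (tone, pacemaker, delayed), the NMDA/AMPA
ratio, the inhibitory conductance, the depression strength $p_v$, and
the capacitance of the delayed populations. The underlying study reports
its parameter ranges only in supplementary material, so the ranges here
were chosen by the same procedure the study describes: coarse
pre-calibration until the qualitative mechanism battery held
(all four protocols detected at sizes 20, 40 and 60; omission detection
destroyed by a 5-ms synaptic delay but not by 1–2 ms; the
ablation matrix reproduced). The shipped defaults (`mmn_params()`) are
one grid point; `co_fit_mmn_params()` is a second accepted grid point
whose larger residual standard response is needed by the cortical relay
(section 4).

Constants that are *not* grid axes but shape the timing race of omission
detection: the inhibitory populations receive the tone pulse amplified
2.5-fold (inhibitory neurons respond faster than pyramidal cells), the
pacemaker pulse is 2.5× the tone amplitude with a 2-ms onset lag and
50-ms width, and $\tau_D = 10$ s. The long $\tau_D$ keeps the
recovery floor over one 500-ms period (≈5%) far below the recovery over
the 2.5-s deviant spacing (≈22%), which is what lets the same per-synapse
conductances separate standards from deviants at population sizes 20–60.
Multi-second adaptation recovery is consistent with stimulus-specific
adaptation timescales reported in auditory cortex.

### Metrics

`deviance_index()` counts output spikes in half-open windows
$[t_\text{onset} - 150, t_\text{onset} + 350)$ ms (index window) or
$[-50, +450)$ (response-total window), divides by 0.5 s, averages within
trial class and reports $f_{dd} = f_\text{deviant} - f_\text{standard}$.
Trials whose window precedes the recording are excluded with a warning.
`acceptance_test()` accepts a model when at least 80% of the output
neurons fire for the deviant *and* the deviant spike count is at least
six times the mean standard count — both thresholds inclusive.
`group_compare()` is the two-sided rank-sum test (normal approximation,
tie- and continuity-corrected) with Bonferroni correction over the four
protocols.

## 3. Synfire chain and STDP entrainment

The chain is a base population plus 70 populations of 50 neurons,
feedforward-connected with probability 0.5 and a 5-ms transmission
delay; every excitatory population has an inhibitory partner population
that terminates its burst. Feedback synapses from each chain population
to the base population follow the standard pair-based STDP rule: traces
$A_\text{pre} > 0$, $A_\text{post} < 0$ decay with $\tau_A = 20$ ms; a
presynaptic spike adds $A_+$ to the presynaptic trace and the (negative)
postsynaptic trace to the weight; a postsynaptic spike adds $A_-$ to the
postsynaptic trace and the presynaptic trace to the weight; weights are
clipped to 0–2400 pS after every update, and start at the (weak) value
of $A_+$. Simultaneous pre/post events resolve pre-before-post.

Numerical choices: the excitatory synapses of *this* network decay with
$\tau = 6$ ms rather than 2 ms. The hop latency of a marginally
propagating chain is pinned near (delay + kernel width); with 2-ms
kinetics no conductance reaches the ≈8.6 ms/hop that makes one stimulus
sweep 70 populations in ≈600 ms — the sweep saturates near 490 ms and
then fails abruptly. With 6-ms kinetics the calibrated conductance
(`g_ff = 1.25` nS, see `calibrate_synfire()`) yields a stable ≈590-ms
sweep. The feedback connection probability is 0.45: denser feedback lets
weakly potentiated early populations trigger the base prematurely, which
accelerates the intrinsic cycle shortening until the post-cessation
rhythm collapses; sparser feedback fails to sustain it.

Under 12 s of 2-Hz stimulation with the optimized learning rates
($A_+ = 0.029$ nS, $A_- = -1.2 A_+$), populations ≈51–59 — those that
fire just before the next stimulus — are strongly potentiated, while the
populations firing just after the base (1–3 and 60–62) are depressed,
and the network keeps firing rhythmically after stimulus cessation. A
gradual shortening of the cycle (tens of ms over 5 cycles) is present
and reported, not treated as failure. Entrainment is scored two ways
(`score_entrainment()`): *relative* burst-timing criteria (next burst
begins ≥450 ms and ends ≤550 ms after the previous burst's last spike at
2 Hz, scaled as 0.9–1.1 periods at other rates; any burst over 75 ms
aborts the run) and *absolute* fixed windows (±60 ms around each
expected post-cessation time, ≥5 spikes per hit; 60–440 ms after as
"unexpected" activity). Poisson-timed stimulation at the same mean rate
produces no entrainment.

In our calibration the boundaries of the learning-rate phase diagram
shift somewhat relative to the source study (the inhibitory partner
populations, whose parameters the source reports only in supplementary
material, move them): insufficient potentiation and no post-cessation
activity occur at the small-$A_+$ corner ($A_+ = 0.020$, $\alpha \le
-3$) rather than already at $A_+ = 0.024$, and the overexcitable corner
(large $A_+$, $\alpha$ near $-0.7$) manifests as double activations
late in the entrainment phase followed by collapse of the
post-cessation rhythm rather than sustained inter-cycle spiking.

## 4. Excitability, capacitance and disease perturbations

`fi_curve()` measures LIF firing rates for somatic currents 0–1 nA in
0.1-nA steps (16-s injections scored over the final 15.5 s) and
summarizes excitability as the trapezoidal area under the curve (AUC).
Two routes map a subject's AUC onto the LIF membrane capacitance:
the *ratio* method multiplies $C_m$ by
$(\overline{AUC}/AUC_i)$ — the linear exponent is the default because it
reproduces the reported mappings (−6.7% AUC → +7.2% $C_m$, −16.1% →
+19.2%); a squared exponent is exposed as an option. The *fit* method
searches the capacitance whose simulated AUC equals the target exactly;
with a 3-ms refractory period the relationship is slightly super-linear,
so fitted capacitances exceed the ratio-based ones (the −6.7% fit lands
at ≈631 pF from the 580-pF reference — the value the source study also
reports).

Disease perturbations (`apply_perturbation()`): scaling the capacitance
of all excitatory populations (reduced intrinsic excitability via ion
channel expression), or scaling the excitatory conductances onto
excitatory populations by 0.81 (19% spine loss). Under the *subcortical*
interpretation only the cortical output population CO is perturbed.

`attach_cortical_output()` adds CO: 40 neurons with 580 pF / 4 nS
(membrane time constant 145 ms), 30% heterogeneity, strong white noise
(1.75 nA per-step SD) producing spontaneous fluctuations, and static
AMPA input from EO. The reported input strength, 3 µS, is interpreted as
the *summed* EO conductance expected per CO neuron (per-synapse weight
$g/(p N_{EO})$ = 150 nS): a single 3-µS synapse would saturate any
conductance-based point neuron. At this saturating drive CO essentially
relays EO activity, and its burst-following is capped by its refractory
period; 5 ms (a free constant) places the deviant-window rate of the
fitted configuration near 20 spikes/s while scattered standard-trial EO
spikes and noise give ≈8 spikes/s. Because the relay saturates, the
disease-related capacitance increase has only a small effect on it —
largest in the omission protocol, whose weaker output volleys leave the
relay least saturated.
`fit_cortical_output()` reproduces the original fitting procedure as a
grid search over (summed conductance, noise SD) against target rates.

`synthesize_subject_aucs()` replaces the cohort-derived subject table
(which cannot be redistributed) with a synthetic stand-in: control AUCs
drawn from a positive normal distribution (15% dispersion — a typical
inter-subject spread for excitability measures), normalized to control
mean exactly 1, and case groups with the mean reduced by 6.7%
(prefrontal-like) or 16.1% (cingulate-like). It emulates group means and
dispersion only; it carries no gene-level structure, no covariates and
no correlation between regions, so a green group-comparison test
establishes the *pipeline*, not any biological claim about real cohorts.

## 5. What the synthetic world does and does not establish

The stimulus generator produces idealized square-pulse drive with exact
onsets; real auditory input has cochlear and subcortical preprocessing,
adaptation upstream of the modelled populations, and amplitude
variability. The pacemaker inputs are *assumed* (their plausibility is
what the synfire module argues); a green omission-detection test
establishes that the mechanism works given phase-locked drive, not that
such drive exists. Acceptance tests at one fixed connectivity seed
establish parameter effects, not robustness over anatomical
realizations (the seed policy is overridable).

Known limitations:

* ±20 ms pacemaker phase jitter *impairs* omission detection here
  (deviance index down ~25–30%) but does not push it below the 80% / 6×
  acceptance thresholds, whereas the source study reports near-complete
  loss. With 0.5-s counting windows and an output membrane integrating
  over 20 ms, a ±20-ms dispersal of the pacemaker volley still delivers
  suprathreshold drive; breaking it would need a faster output membrane
  (contradicting the shared membrane parameters) or size-dependent
  conductance rescaling. The corresponding acceptance check is
  implemented faithfully and is expected to fail.
* The ISD/IDD populations named in the source's abbreviation table have
  no described projections and are not built (the roster follows the
  nine wired populations).
* Whether the delayed-activating populations receive tone input directly
  or via ES/ED is unspecified; they are driven directly.
* No homeostasis corrects the post-cessation cycle drift of the
  entrained chain; runs longer than a few seconds after cessation
  accumulate phase error by construction.
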