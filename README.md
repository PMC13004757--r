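# mmnsim

Spiking network simulation of auditory novelty detection (mismatch
negativity, MMN) and of its impairment under schizophrenia-associated
cellular alterations.

The auditory system responds more strongly to rare, novel sounds than to
repeated ones — the EEG signature of this is the mismatch negativity.
`mmnsim` implements a leaky integrate-and-fire (LIF) network in which this
behaviour emerges from two mechanisms: **short-term synaptic depression**
of the projections onto an output population (stimulus-specific
adaptation), and **pacemaker inputs phase-locked to the stimulus rhythm**,
which let the network detect even the *omission* of an expected tone. A
companion synfire-chain model shows how such phase-locked activity can be
learned from rhythmic stimulation through spike-timing-dependent
plasticity (STDP) in feedback synapses.

The package is aimed at computational neuroscientists who want a tested,
scriptable implementation of these models: every network, protocol and
metric is a plain R object, and the heavy lifting runs in compiled code.

## The model in brief

Neurons are single-compartment LIF units,

```
Cm dV/dt = -g_L (V - E_L) - sum_s g_s(t) B_s(V) (V - E_s) + I_pulse(t) + I_noise(t),
```

with conductance-based AMPA, NMDA (magnesium-blocked) and GABA synapses,
threshold-reset spiking and absolute refractoriness. Excitatory
projections onto the output population depress presynaptically: the
releasable fraction `D` obeys

```
dD/dt = -p_v D sum_j delta(t - t_j) + (1 - D) / tau_D,
```

so each presynaptic spike transmits `w * D` and multiplies `D` by
`(1 - p_v)`. Novelty is quantified per protocol by the deviance-detection
index

```
f_dd = f_deviant - f_standard,
```

the difference of the output population's firing rates in fixed 0.5-s
peristimulus windows, and a parameter set counts as *accepted* when at
least 80% of the output neurons fire for the deviant and the deviant
response is at least six times the mean standard response.

The synfire module implements pair-based STDP with exponentially decaying
pre- and postsynaptic traces (`tau_A` = 20 ms, additive updates clipped to
0–2400 pS) in the feedback synapses of a 70 x 50-neuron chain; 12 s of
2-Hz stimulation entrains the chain so that it keeps firing rhythmically
after the stimulus stops.

## Worked example

```r
library(mmnsim)

net  <- build_mmn_network(mmn_params(), seed = 1)   # 9 populations x 40 neurons
prot <- make_stimulus_sequence("frequency_deviant") # oddball: 4 standards : 1 deviant
rec  <- run_protocol(net, prot, seed = 1)
rec
#> <spike_record> 23093 spikes over 12500 ms
#>   per population: ED=490 EDD=24 EO=2228 EP=318 EP2=7678 ES=2594 ESD=225 ID=1567 IS=7969

deviance_index(rec, prot)
#> <deviance_result> f_deviant = 381.50, f_standard = 3.50, f_dd = 378.00 spikes/s (population, 4/16 trials)

acc <- acceptance_test(rec, prot)
#> accepted: TRUE   fraction firing: 1   deviant/standard ratio: 109
```

The output population fires vigorously inside the deviant windows
(381.5 spikes/s summed over the population, i.e. roughly 190 spikes per
0.5-s window) and is nearly silent for late standards (3.5 spikes/s), so
the set passes both acceptance thresholds. The same network loses
omission detection when a 5-ms synaptic delay is added
(`run_protocol(net, prot, extra_delay = 5)`) but tolerates 1–2 ms, and an
`ablate = "EP2"` network loses exactly the inverse-duration deviant.

Other entry points:

```r
run_grid(default_grid_spec(), set_ids = 1:100)        # acceptance-filtered search
ent <- run_entrainment(synfire_config(),
                       stdp_params(A_plus = 0.029, alpha = -1.2))
score_entrainment(ent$record, ent$cessation_time)     # post-cessation cycles
apply_perturbation(net, "excitatory_conductance_scale", 0.81)  # -19% spines
attach_cortical_output(net)                           # fitted cortical relay
fi_curve(neuron_params(Cm = 580, g_leak = 4))         # excitability (AUC)
```

A command-line launcher is installed at
`system.file("scripts", "mmn", package = "mmnsim")` with subcommands
`protocol`, `run`, `entrain` and `report`.

## Documentation

The methods vignette (`vignettes/mmnsim-methods.Rmd`) describes the model
assumptions, the calibration of all constants that the underlying study
reports only in supplementary material, what the synthetic experiments do
and do not establish, and known limitations.
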