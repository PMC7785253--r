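# spikewm — embodied working memory in a plastic spiking network

`spikewm` is a desk-scale simulator for studying how working memory —
stimulus content maintained as reverberating neural activity after the
stimulus is gone — interacts with ongoing input streams. It implements a
500-unit network of adaptive exponential integrate-and-fire (aEIF) neurons
with Tsodyks–Markram short-term plasticity, nearest-neighbour
multiplicative STDP, and structural plasticity, driven by bimodal Gaussian
input currents and a frozen 10 Hz Poisson background. Population spike
counts, binned at 40 ms, are decoded into the wheel speeds of a virtual
differential-drive agent, so every memory state has a direct behavioural
readout: which way the agent turns.

The network: below threshold each unit follows

    C_m dV/dt = -g_L (V - E_L) + g_L Δ_T exp((V - V_T)/Δ_T) - w + I_syn + I_ext
    τ_w dw/dt = a_w (V - E_L) - w

with reset V → E_L, w → w + b_w on a spike. Each presynaptic unit carries
short-term plasticity variables (u, x) that facilitate and depress
transmission, and every synapse follows the asymmetric STDP window
ΔJ = λ₊(1−J)^μ e^(−Δt/τ₊) for post-after-pre pairings and
ΔJ = −λ₋ α J^μ e^(Δt/τ₋) otherwise, evaluated continuously while a pairing
holds. Pairs without a synapse form one when an update fires, so the
initially 20%-sparse wiring densifies over a session. All parameter
defaults are the published values (Cm = 281 pF, gL = 30 nS, EL = −70.6 mV,
VT = −50.4 mV, ΔT = 2 mV, τw = 144 ms, aw = 4 nS, bw = 0.0805 nA,
τsyn = 5 ms; τf = 100 ms, τd = 900 ms, U = 0.8; τ₊ = 20 ms, τ₋ = 50 ms,
λ₊ = 5e−5, λ₋ = 25e−5, μ = 1, α = 2; 400 E / 100 I units, c = 0.2,
J_EE = 0.65, J_II = −1; R_b = 0.5, R_p = 2.5, R_n = 1.0 nA, σ = 35).

Six protocols probe the memory: (1) single learning and recall,
(2) incremental learning, (3) task switching, (4) resistance to a brief
interferer, (5) submission to the same interferer after an extended
washout, (6) resistance to an equal-duration distractor at one-third
intensity. Each has a machine-evaluated success criterion based on which
subpopulation dominates the recall activity.

## Worked example

```r
library(spikewm)

# build the default network: 400 E + 100 I units, 49,900 synapses
st <- build_network(network_params(), seed = 1)
connection_stats(st)[c("n_connections", "density")]
#> $n_connections
#> [1] 49900
#> $density
#> [1] 0.2

# the clockwise stimulus peaks at unit 125 with ~3 nA
I <- bimodal_input("RIGHT", stimulus_params())
which.max(I); round(I[125], 3)
#> [1] 125
#> [1] 3

# run the single learning-and-recall protocol (20 s cue + 10 s recall)
res <- run_experiment("exp1", seed = 42)
res
#> <wm_experiment> exp1, seed 42: pass
#>       event rate_left rate_right    dominance
#> 1 STIM_LEFT   47.8560    83.0048 RIGHT_SUBPOP
#> 2  STIM_OFF   15.9024    21.4000 RIGHT_SUBPOP

# structural plasticity has densified the 20%-sparse wiring
connection_stats(res$final_state)[c("n_connections", "n_dale_violations")]
#> $n_connections
#> [1] 250000
#> $n_dale_violations
#> [1] 40030
```

The LEFT cue drives the subpopulation preferring unit 375 (the agent's
right wheel); during recall the stimulus is off, yet the same
subpopulation keeps the higher rate — the persistent-activity bump — so
the agent keeps turning the same way. `save_run(res, "results/exp1")`
writes spikes, the mean-efficacy trace, the decoded trajectory, weight
snapshots and a `metrics.json`; `report("results/exp1")` re-derives the
verdict from the stored files.

A command-line front-end covers the same surface:

```sh
inst/exec/spikewm run --experiment exp1 --seed 42 --out results/exp1
inst/exec/spikewm report results/exp1
inst/exec/spikewm validate-config my-config.yaml
```

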