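---
title: "An embodied working-memory network: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An embodied working-memory network: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikewm)
```

`spikewm` simulates a 500-unit spiking network whose population activity is
decoded into the wheel speeds of a virtual two-wheeled agent, and exercises
it through six working-memory protocols: a cue is learned during evoked
("stimulus ON") activity, maintained as a localized activity bump during
spontaneous ("stimulus OFF") activity, and then refined, overwritten, or
defended as new inputs arrive. This vignette explains the model and the
choices behind every tunable default.

## The model

**Membrane dynamics.** Each unit is an adaptive exponential
integrate-and-fire (aEIF) neuron,

$$C_m \dot V_i = -g_L (V_i - E_L) + g_L \Delta_T
  e^{(V_i - V_T)/\Delta_T} - w_i + I_i^{syn} + I_i^{ext},
\qquad
\tau_w \dot w_i = a_w (V_i - E_L) - w_i,$$

with a spike recorded when $V_i > V_T$ after an update, followed by the
reset $V_i \to E_L$ and $w_i \to w_i + b_w$. The parameters are the
standard regular-spiking cortical set ($C_m = 281$ pF, $g_L = 30$ nS,
$E_L = -70.6$ mV, $V_T = -50.4$ mV, $\Delta_T = 2$ mV, $\tau_w = 144$ ms,
$a_w = 4$ nS, $b_w = 80.5$ pA, $\tau_{syn} = 5$ ms). There is no refractory
period, and the spike value $V_{peak} = 20$ mV is cosmetic — recorded, never
integrated. Integration is forward Euler at $dt = 0.1$ ms; the argument of
the exponential is clamped at $+20$ so a suprathreshold excursion cannot
overflow inside a step. The test suite checks Euler convergence under
step-halving, the subthreshold fixed point against a numeric nullcline
solver, and the step response against the analytic linear two-variable
solution with the exponential term cancelled.

**Short-term plasticity.** Each presynaptic unit $j$ carries one release
probability $u_j$ (baseline $U = 0.8$, facilitation constant
$\tau_f = 100$ ms) and one resource variable $x_j$ (recovery constant
$\tau_d = 900$ ms), shared across all of its efferent synapses, as the
per-unit subscripts of the governing equations indicate. On a presynaptic
spike, $u_j \to u_j + U(1-u_j)$ first, then the release $u_j' x_j$ is
transmitted and $x_j \to (1-u_j')x_j$. The update order matters and the
sources leave it ambiguous; applying the facilitation jump before the
resource decrement is the reading consistent with a decrement of $-u_j x_j$
evaluated at the updated $u_j$. With these constants the synapse is
depression-dominated: sustained firing collapses $x$ and throttles
transmission, which is the main rate-stabilizing mechanism of the network.
Between spikes both variables relax exponentially; the implementation uses
the exact exponential update, so the decay is correct for any step size.

**Long-term plasticity.** Synapses follow a pair-based, nearest-neighbour
STDP rule with multiplicative soft bounds:

$$\Delta J_{ij} =
\begin{cases}
\lambda_+ (1 - J_{ij})^\mu \, e^{-\Delta t / \tau_+} & \Delta t > 0\\[2pt]
-\lambda_- \alpha \, J_{ij}^\mu \, e^{\Delta t / \tau_-} & \Delta t \le 0
\end{cases}
\qquad \Delta t = t_i^{last} - t_j^{last},$$

with $\tau_+ = 20$ ms, $\tau_- = 50$ ms, $\lambda_+ = 5\times10^{-5}$,
$\lambda_- = 25\times10^{-5}$, $\mu = 1$, $\alpha = 2$. Depression dominates
by design ($\alpha \lambda_-/\lambda_+ = 10$), which keeps runaway
potentiation in check. Because the rule is multiplicative, excitatory
weights started in $[0,1]$ stay there without clipping; inhibitory weights
(initialized at $-1$) see a *positive* update from both branches, so under
sustained pairing they drift monotonically toward zero and across it — the
documented erosion of Dale's law, which this package reproduces rather than
prevents. Structural plasticity falls out of the same rule: when an update
fires for a pair with no synapse, the connection is created at $J = 0$
before the update applies, so the 20%-sparse initial wiring densifies
toward full connectivity, self-connections included (a switch
`allow_self_connections` permits ablating this).

**Evaluation mode of the STDP rule.** The rule above can be applied in two
inequivalent ways, and the choice changes the science. In *event* mode each
pre/post pairing contributes once, at the spike that completes it. In
*continuous* mode the rule is re-evaluated at every evaluation instant
while a pairing holds, so a pairing's contribution scales with how long it
remains the most recent one. We implement both (`stdp_mode`) and default to
**continuous**, for two reasons. First, it matches the description of the
rule as continuously re-evaluating the nearest spike-time difference at
each time instance. Second, it is the reading under which transitions
between net LTP and net LTD are controlled by the postsynaptic emission
rate — the mechanism the original study names — because the fraction of
time a synapse spends in the LTP state is $\rho_{post}/(\rho_{post} +
\rho_{pre})$. Empirically, event mode makes long-term plasticity roughly an
order of magnitude too slow for the protocols: a task switch barely
overwrites and a washout never completes within desk-scale durations.

Continuous mode is computed exactly, not by brute force: between spikes of
a pair, $\Delta t$ is constant and the per-evaluation update is a linear
recurrence, so the accrual over $n$ evaluations has the closed form
$(1-J) \mapsto (1-J)(1-\lambda_+ K)^n$ (LTP state) and
$J \mapsto J (1-\lambda_- \alpha K')^n$ (LTD state). The closed form is
exact only for $\mu = 1$ (the published exponent); the implementation
refuses continuous mode otherwise. A test verifies the closed form against
a literal per-step brute-force replay on a small network.

The evaluation interval `stdp_eval_dt` is a free parameter of the artifact:
the published learning rates are per evaluation, so this interval sets the
absolute speed of long-term plasticity (halving it doubles every learning
and forgetting rate). The source does not state its simulation step; we
fix the interval once at the value where the six protocols' relative
durations (a brief interferer versus a full cue versus an extended washout)
fall into the regimes the protocols demand, and document it below.

**Synaptic transmission.** The current injected into target $i$ by one
spike of presynaptic unit $j$ is $g \cdot J_{ij} \cdot u_j' x_j$ (sign
carried by $J$), added instantaneously to $I_i^{syn}$, which otherwise
decays exponentially with $\tau_{syn} = 5$ ms. A literal reading of the
total-efficacy equation would inject the sum over *all* synapses on every
spike; we interpret the sum as bookkeeping notation for the assembled
postsynaptic current, since the per-spike current is explicitly described
as triggered by the activation of presynaptic unit $j$. The conversion
$g$ (`g_scale`) from dimensionless efficacy to current is not given by the
source and is a calibration of this artifact; see below.

**Inputs.** Evoked input is a bimodal mixture of Gaussians on the ring of
unit indices: baseline $R_b = 0.5$ nA everywhere, a higher peak
$R_p = 2.5$ nA at the preferred unit (125 for the clockwise configuration,
375 for the counter-clockwise one), and a lower peak $R_n = 1.0$ nA half a
ring away, both with width $\sigma = 35$. Indices are treated modulo $N$:
the second peak of the clockwise configuration would otherwise fall outside
$[1, N]$, and the two configurations are exact ring-swap images of each
other with identical mean intensity (asserted to $10^{-12}$ in the tests).
Each unit also receives an independent homogeneous Poisson background train
at 10 Hz, drawn once per run and frozen — the same realization drives
evoked and spontaneous phases. Background spikes are routed through the
unit's efferent synapses (they drive its STP state and deliver current) but
do not advance the STDP pairing clock by default
(`background_drives_stdp = FALSE`), keeping long-term learning driven by
emitted somatic spikes; the stronger reading of "frozen spatiotemporal
pattern" — one fixed realization, not merely fixed statistics — is
implemented because it makes runs exactly reproducible from the seed.

**Architecture.** 500 units; 400 excitatory and 100 inhibitory, assigned
uniformly at random and independently of ring position (the source states
random choice and no spatial rule). Exactly
$\mathrm{round}(c \, N (N{-}1)) = 49{,}900$ ordered off-diagonal pairs are
wired at $c = 0.2$ — a fixed count rather than independent Bernoulli draws,
so the stated 20% density is exact and testable. Initial efficacies follow
the presynaptic class: $J_{EE} = J_{IE} = 0.65$, $J_{II} = J_{EI} = -1$.
Subpopulation 1 is units 1–250 (preferred unit 125), subpopulation 2 is
units 251–500 (preferred unit 375).

**Embodiment.** Spike counts in consecutive non-overlapping 40 ms bins
(half-open, anchored at $t = 0$) are converted to wheel speeds:
subpopulation 1 drives the left wheel and subpopulation 2 the right wheel,
the unique assignment under which a bump at unit 125 produces clockwise
turning. The pose integrates standard differential-drive kinematics with
exact arcs inside each constant-speed bin. The speed gain (0.5 mm/s per
spike) and wheelbase (48 mm) only set the physical scale of trajectories;
no verdict depends on them. The behavioural readout behind every verdict is
`dominance()`: the subpopulation with the strictly larger spike count in an
analysis window, with a 5% tie band and a 20-spike floor below which the
readout is `NONE` (a near-silent network does not move the agent
meaningfully).

## Calibration of the free parameters

Two quantities are genuinely unconstrained by the printed parameter set and
had to be fixed as artifact calibrations, once, with the following
rationale.

*Efficacy-to-current conversion* (`g_scale`). Under the depression-dominated
STDP rule the network's operating efficacies settle far below the initial
0.65 (multiplicative LTP/LTD balance puts active synapses near
$J^* \approx 0.1$). Anchoring the conversion so that a handful of
coincident excitatory spikes at *operating* efficacy is suprathreshold from
rest — rather than at the initial efficacy, which would leave the entire
delay period silent — gives $g \approx 2000$ pA per unit efficacy·release:
at $J \approx 0.1$ and release $\approx 0.96$, three to four coincident
spikes cross the ~606 pA rheobase. With this value the delay period shows
sustained, spatially biased activity, which is the phenomenon the package
exists to study.

*Plasticity speed* (`stdp_eval_dt`). Chosen so that (i) a full-length cue
(~20 s) reaches its learned structure, and (ii) a brief (~4 s) opposite
interferer cannot overwrite an intact memory. These place the
structure-formation time constant at roughly ten seconds of evoked
activity; the default evaluation interval is 4 ms. Faster settings (1–2 ms)
let the brief interferer overwrite intact memories, destroying the
interference-resistance protocol; the event-wise mode at the other extreme
is an order of magnitude too slow for task switching.

## The six protocols and their verdicts

Schedules replace the original interactive keypresses with deterministic
event lists; all durations are configuration, since the original sessions
were operator-driven. Defaults: cue 20 s, recall 10 s, interferer 4 s,
60 s washout for the submission protocol, distractor at 1/3 intensity and
cue-equal duration. With the structure-formation time constant near ten
seconds, a 20 s cue reaches most of its learned structure — shorter cues
were found to leave the task-switching overwrite inside the tie band —
while keeping each protocol inside a few minutes of desk time. Verdicts are computed from the last 25% of each
phase (onset transients excluded) and are pure functions of the stored
per-phase metrics, so a results directory can be re-judged offline
(`report()`).

Because single runs are stochastic in their seed, the shipped acceptance
battery requires each protocol's criterion on at least 2 of the 3 fixed
seeds 41–43, mirroring the robustness one expects from the single embodied
sessions of the original study.

**A known limitation: the washout of the submission protocol.** Protocol 5
gates its verdict on a precondition — after the extended delay, neither
subpopulation may dominate (the memory has washed out) — before asking
whether the brief interferer then overwrites. Under the default wiring this
precondition is not reachable: as the learned structure erodes at baseline
rates, the surviving rate bias keeps regenerating it, and the subpopulation
margin settles at a floor of roughly 11% — above the 5% tie band — no
matter how long the delay (measured out to 400 s across a wide range of
gains and plasticity speeds). The protocol therefore returns
`"inconclusive"` (precondition unmet), which is deliberately distinct from
`"fail"`: the overwrite question is never posed. The alternative wiring
`background_drives_stdp = TRUE`, under which the frozen background trains
also advance the presynaptic STDP clock, erodes structure at a constant
rate independent of network activity; with it the washout genuinely
completes — the margin falls below 5% within ~140 s and activity fades to
silence by ~170 s, the fade-out-to-baseline behaviour described for long
delays — but the same flat erosion thins the recall margins of the
task-switching and distraction protocols to the edge of the tie band. We
ship the default wiring, which makes the first four protocols robust, and
expose the switch for users who want the washout regime; this trade-off
appears to be a real property of the printed parameter set rather than an
implementation artifact.

**A second limitation: the margin after an equal-duration distractor.** In
protocol 6 the distractor runs as long as the cue at one third of its
intensity. Across the calibration space we explored, the post-distraction
recall consistently leaves the cued subpopulation *ahead* — the direction
the original study reports — but with its margin roughly halved, which
lands inside the 5% tie band on some seeds. The shipped battery therefore
shows this protocol passing on a minority of its seeds. Extending the
post-distraction recall does not recover the margin: the distractor has
genuinely overwritten about half of the learned structure, so there is no
force that re-separates the subpopulations afterwards. Users who want to
study the resistant regime can shorten the distractor or lower its
intensity further in the schedule configuration.

## What the synthetic conditions do and do not show

The generator reproduces the study's *conditions* — parameter values,
population sizes, input shapes, noise rate — not real sensory data. Passing
protocols show that the implemented mechanisms interact as described:
bump formation under bimodal drive, rate-controlled LTP/LTD transitions,
palimpsest overwriting, context-dependent interference. They do not show
robustness to parameter variation away from the printed set, to
non-Gaussian stimuli, or to physical-robot effects (wheel slip, sensor
noise, real-time jitter), all of which are outside the model. The Dale's-law
erosion and self-connection growth are reproduced as documented properties
of the rule, not as biological claims.

## Numerical choices and degenerate inputs

* Forward Euler at $dt = 0.1$ ms; step-halving changes a subthreshold
  voltage trace by well under 0.05 mV over 200 ms (asserted in tests).
* STP and synaptic-current decays use exact exponentials, valid for any
  step.
* Spike times are quantized to the step; inter-spike-interval comparisons
  in tests allow one-step jitter.
* $\Delta t = 0$ pairings fall in the LTD branch, exactly as the rule's
  $\le$ states; simultaneous spikers each trigger their own evaluation.
* A unit that has never spiked has no pairing time and contributes no STDP
  updates.
* Weights are clamped to $[-1, 1]$ as a guard; the multiplicative rule
  cannot leave the interval from default initial conditions.
* The simulation clock advances additively ($t \mathrel{+}= dt$), matching
  the R reference functions bit for bit; the compiled core and the R
  implementations of every update rule are cross-checked on a small network
  step by step in the test suite.

## Problem sizes

The shipped defaults keep every protocol within minutes of a single CPU:
500 units at $dt = 0.1$ ms, horizons between 30 s (single learning/recall)
and a few minutes (the washout protocol). These sizes are the package's
choice of desk-scale study conditions; the dynamics at these sizes display
every qualitative regime the protocols probe.
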