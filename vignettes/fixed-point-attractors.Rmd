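---
title: "Fixed-point attractors link circuit structure to locomotor function"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fixed-point attractors link circuit structure to locomotor function}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormcircuit)
```

## The model

Interneurons of *C. elegans* signal with graded potentials, not spikes.
`wormcircuit` models a circuit of $n$ such neurons by the membrane potential
vector $x$ (relative to rest, dimensionless — the data never fix a millivolt
scale, so none is imposed):

$$\tau \dot x = (G - L - E)\,x + W\,\sigma(x - \theta) + B u,$$

where $W_{ij}$ is the chemical weight from presynaptic $j$ onto postsynaptic
$i$ (positive excitatory, negative inhibitory), $G$ the symmetric
gap-junction conductance matrix with Laplacian degree matrix
$L = \mathrm{diag}(\sum_k g_{k1}, \dots, \sum_k g_{kn})$, $E$ the identity
(leak), $\sigma(v) = 1/(1+e^{-kv})$ the synaptic sigmoid, and $Bu$ external
drive. All neurons share the time constant $\tau$, threshold $\theta$ and
slope $k$; this simplification is deliberate (the circuits analysed are
composed of same-type command interneurons) and per-neuron overrides are
rejected rather than silently averaged.

Equilibria solve $(G - L - E)x + W\sigma(x-\theta) = 0$; $\tau$ cancels, so
it never affects *which* states exist, only how fast they are approached.
The working parameter point throughout is $\tau = 1$, $\theta = 0.5$,
$k = 20$. Two consequences of that choice drive everything else:

* because $\sigma(-k\theta) = \sigma(-10) \approx 4.5\times10^{-5}$, the
  near-zero "quiescent" state is always an equilibrium, for any $W$ and $G$
  of moderate size — it is the resting/sleep-like state;
* because $k$ is large, $\sigma$ is switch-like near $\theta$, so circuits
  with enough recurrent excitation hold themselves above threshold:
  bistability.

## Finding and classifying fixed points

`find_fixed_points()` runs damped Newton iteration with the analytic
Jacobian
$J = \tfrac{1}{\tau}\left[(G - L - E) + W\,\mathrm{diag}(k\sigma_j(1-\sigma_j))\right]$
from a deterministic multi-start set: the origin, the box corners, the 0/1
activation patterns, and a seeded latin-hypercube sample (default 500
starts; all reproducible from one seed). Roots are accepted at residual
$<10^{-9}$ (infinity norm), merged within $10^{-3}$, and classified by the
real parts of the Jacobian eigenvalues (stable / unstable / saddle;
$|\mathrm{Re}| < 10^{-9}$ is flagged marginal and resolved by a simulation
probe). The default box is $[-3, 3]$ per dimension, which comfortably
contains every state the shipped circuits produce. The steepness $k = 20$
makes the equilibrium system stiff near threshold, so trajectories are
integrated with an adaptive stiff-capable scheme (`deSolve`, lsoda family,
tolerances $10^{-8}$) with an equilibration stop at
$\lVert\dot x\rVert_\infty < 10^{-7}$.

A counting convention worth being explicit about: any circuit with several
attractors necessarily also has saddle points on the boundaries between
their basins (at this parameter point the quiescent root is provably
linearly stable, and a Brouwer-degree argument then forces at least two
additional mixed-sign roots whenever two more attractors exist). The solver
returns and labels *all* roots. For the one- and two-neuron motifs, "number
of fixed points" means all distinct roots — one, or three with the
intermediate one unstable, which is exactly the fold structure
`bifurcation_sweep()` traces as the connection weight grows. For
circuit-level survival tables, states are *attractors*: `stable_points()`
filters the saddles, and the command-circuit analyses count three states,
not three roots.

## The command circuit

`command_circuit_fixture()` ships a ten-neuron model of the
forward–backward command circuit (AVBL/R, PVCL/R, AVAL/R, AVDL/R, AVEL/R).
Its synaptic count matrices (`inst/extdata/*_synthetic.csv`) are synthetic:
pair-level counts documented in the anatomical literature are used as
printed, the remaining entries are invented to be qualitatively consistent
with the known wiring. Counts become weights under `adjustment_rules()`:

* chemical synapses within a functional section (forward = AVB + PVC,
  backward = AVA + AVD + AVE) are excitatory, between sections inhibitory;
* magnitudes are monotone in synapse count, capped at $\pm 1$, with 1–2
  synapse contacts mapped to $\approx 0.1$ — present but not load-bearing;
* gap junctions inside a left/right pair get conductance in $[1, 2]$ (they
  synchronise the pair), other intra-section gaps are moderate, and
  cross-section gaps are weak regardless of contact count (anatomical
  contact number is a poor proxy for electrical coupling strength — the
  AVA–PVC contact is the canonical example of many contacts, little
  coupling);
* chemical synapses inside a *bistable* pair are raised to the strong
  reciprocal weight (default 0.9). This override matters: at the forward
  state only AVBL/R are above threshold, and a gap junction between two
  equally active partners carries no current, so the pair's chemical drive
  alone must hold it up. A literal reading of the weak-count rule (AVB's
  reciprocal counts are 3 and 1) would make the forward state impossible.

The packaged weights are a manual adjustment within these constraints
(count-to-strength maps are genuinely underdetermined, and the analysis
needs one concrete realisation); a unit test pins the fixture's sign and
support pattern to the rule-derived one. One tuning choice deserves its
rationale here: the AVA pair's reciprocal chemical weight is 0.35 — below
threshold — although its synapse counts are the largest in the circuit.
With a saturated weight the AVA pair would sustain itself alone, and the
backward state would survive AVE ablation; with 0.35 the backward state
exists only through the AVA–AVE positive feedback loop, which is what makes
ablation of either pair abolish it while AVD or PVC ablation and complete
gap-junction removal leave all three states intact. Within the fixture the
three attractors are: forward (AVB $\approx 0.9$, everything else
non-positive), backward (AVA $\approx 1.2$, AVE $\approx 1.3$, AVD mildly
positive but sub-threshold, AVB/PVC inhibited), quiescent (all zeros to one
decimal).

## Motifs and the positive-feedback condition

`scan_bistability_motifs()` counts the four recurrent classes capable of
bistability (chemical self-loops, with/without an electrical counterpart;
reciprocal chemical pairs, with/without a shared gap junction), as nested
classes — the "also electrical" hits are subsets, and exclusive counts
follow by subtraction. `check_sufficiency()` expresses the structural
condition for multistability as a predicate: at least one simple positive
feedback loop dominated by excitatory chemical synapses, with weights
adjustable without changing any synapse's character (the second clause is
reported as a note, not checked numerically — it is about what an
adjustment *could* do). "Dominated by excitatory" is read strictly by
default (every chemical edge in the witness loop excitatory), since every
worked example of the condition is of that form; whether a mutual-inhibition
loop (net sign $+$) should qualify is genuinely ambiguous, so the lenient
reading is available behind `strict = FALSE` rather than guessed. Loop
enumeration is a bounded-length DFS over the signed edge set (gap junctions
contribute two opposed positive directed edges; a pure-gap two-cycle would
reuse the same junction twice and is excluded); the test suite checks it
against an exhaustive permutation oracle.

## State machine and basins

Stable fixed points become the states of a finite state machine; stimulus
protocols become its transitions. Activation tables are modelled as
initial-condition protocols: targeted neurons start at the stimulus
amplitude (default 1 — the tables specify 0/1 patterns without stimulus
physics, so amplitude is an explicit parameter rather than a hidden
assumption), untargeted neurons at the protocol baseline, and the circuit
relaxes with no input. With the default zero baseline such a protocol
resets the whole circuit, so its outcome is the same from every state —
that is what makes the machine's transition table reproduce the activation
experiments; a `baseline = "start"` variant perturbs the current state
instead, and sustained-input protocols (drive through $B$ for a duration,
then release) always act on the state they interrupt. Terminal states are
matched to attractors within 0.05 in the infinity norm — half the 0.1
reporting precision used in the survival tables; unmatched runs are
reported as unresolved, never silently assigned.

`estimate_attraction_domains()` estimates basin sizes by uniform seeded
sampling of initial conditions, simulation to equilibrium, and
nearest-attractor labelling under the same radius. Fractions plus the
unresolved remainder sum to one by construction. In one dimension the
labelled samples bracket the unstable intermediate root, and on the
mutually excitatory pair the active state's basin grows with the coupling
weight — the structural reading of "stronger interconnection, longer-held
state". No noise is injected during protocol runs: switching is analysed
deterministically, with stochastic drift left out of scope.

## Ablation screens

`ablate_neurons()` deletes rows and columns (laser ablation removes the
cell; clamping to zero would be a different experiment and would leave the
gap Laplacian wrong), and `ablation_screen()` re-solves each condition with
shared settings. Because coordinates shift under ablation, baseline states
are matched to perturbed states by their supra-threshold activation
pattern restricted to the surviving neurons, not by position; a baseline
state whose active neurons were all removed, or whose restricted pattern no
perturbed attractor reproduces, is impaired. The quiescent state survives
every condition — a structural fact, not a tuning outcome.

## The locomotion module

`synthesize_speed_trace()` emulates tracked centroid-speed recordings as a
semi-Markov process: exponential dwell times per state, next-state
probabilities proportional to target occupancy, per-frame speed = state
mean + Gaussian noise. Given target occupancies, the configured dwell means
are rescaled so the realised occupancy matches in expectation while keeping
the configured overall time scale. Defaults encode the two-state
local-search statistics the analyses are calibrated against: forward
$\mu = 259.8$, $\delta = 77.79$ µm/s at 93.36% of time; backward
$\mu = -308.03$, $\delta = 62.79$ µm/s at 6.64%; forward dwell 28.1 s with
the backward dwell following from the occupancy ratio ($\approx 2$ s —
"backward events last seconds"), and a 10 Hz frame rate. Dwell times,
frame rate and the exponential dwell law are modelling choices (the source
statistics report means and fractions, not distributions or sampling
rates); they are parameters, chosen once and documented, not fitted.

What the generator deliberately does not emulate: speed autocorrelation
within a state, turning behaviour coupled to reversals, tracking artefacts,
and any pause state by default (its mass is too small to separate by sign).
Passing tests therefore show that the segmentation/fit pipeline inverts
*this* generative model at the stated sample sizes — not that real traces
are two-component Gaussian.

`segment_locomotion()` classifies frames by sign around a dead band
(default 0: classification by sign, with the pause band available when
wanted) and merges runs. `fit_speed_distribution()` defaults to sign-split
Gaussian maximum likelihood — matching how separate forward/backward
$(\mu, \delta)$ pairs are conventionally reported, and exactly invertible
against the generator — with a two-component EM mixture behind
`method = "em"` for when the mixture interpretation is preferred; both are
deterministic given the data. With one-signed input the fit degrades to a
single Gaussian with a warning instead of fabricating a second component.

## Problem sizes and numerical defaults

The shipped analyses and tests use: 500 multi-starts for the ten-neuron
circuit (solve time a few seconds; the full eight-condition ablation screen
under half a minute), 100–300 starts for one- and two-neuron motifs,
250–1200 Monte-Carlo basin samples, and $10^5$-frame synthetic traces for
the behavioural recovery checks (occupancy recovers within one percentage
point, component centres within a few µm/s at that size). All randomness —
start sets, basin samples, trace generation — flows from explicit seed
arguments; rerunning with the same seed reproduces results exactly.

## Limitations

* Fixed points only: limit cycles and oscillatory attractors are out of
  scope, as is any spiking dynamics.
* The fixture's weights are one defensible realisation of underdetermined
  rules; analyses should rely on its sign structure and state pattern, not
  on individual decimals.
* Basin fractions are Monte-Carlo estimates of volume within a box, not a
  geometric characterisation of the basins.
* The sufficiency predicate is one-directional: satisfying it does not
  guarantee multistability at given weights (condition (ii) is about
  adjustability), and the strict/lenient ambiguity for mixed loops is
  surfaced, not resolved.
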