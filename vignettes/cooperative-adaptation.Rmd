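---
title: "Modelling cooperative adaptive responses in gene regulatory networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cooperative adaptive responses in gene regulatory networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`coopadapt` studies how adaptive responses — a transient change in gene
expression followed by a return toward the pre-stimulus level — emerge
across *many* genes when selection only rewards the adaptation of a single
target gene.

Expression of gene $i$ in an $N$-gene network follows the smoothed
Glass-type kinetics

$$\frac{dx_i}{dt} = \frac{1}{1 + e^{-\beta (z_i - \theta)}} - x_i + \delta,
\qquad
z_i = \frac{1}{s_i} \sum_j J_{ij}\, x_j + I\,[i = \mathrm{input}],$$

with expression levels $x_i \in [0, 1 + \delta]$ and time measured in
units of the protein degradation time. The ternary matrix
$J_{ij} \in \{-1, 0, +1\}$ encodes inhibition, absence or activation of
gene $i$ by gene $j$; it is the only thing evolution may change. The
target gene has no outgoing edges, so its own adaptation cannot drive the
rest of the network. The normalizer $s_i$ keeps the regulatory field
comparable to the threshold $\theta$ regardless of network size; the
package supports $s_i = \sqrt{N}$ (default) and
$s_i = \sqrt{\max(1, k_i^{\mathrm{in}})}$, selectable because published
descriptions of this scaling are ambiguous between the two readings.

### Parameters and defaults

| parameter | default | meaning |
|---|---|---|
| `beta` | 10 | sigmoid gain; Hill-coefficient analogue. Above ~20 the on/off switching becomes so sharp that intermediate (partial-adaptation) levels are hard to hold. |
| `theta` | 0.5 | expression threshold, mid-range. |
| `delta` | 0.001 | basal leak; shifts the ceiling to $1+\delta$ and keeps the off state slightly above zero. |
| `I0`, `I1` | 0, 1 | pre-/post-switch signal on the input gene; the step must clear the threshold so the input gene responds regardless of other incoming edges. |
| `dt` | 0.01 | fixed RK4 step. The dynamics are smooth and non-stiff; fitted steady states computed at `dt` = 0.1 and 0.01 agree to ~1e-9, which is why the large-scale experiments below use 0.1. |
| `t_max` | 1000 | relaxation cap per phase. Evolved networks commonly hold long response plateaus, so short caps truncate the return phase and distort $\Delta_{stat}$. |
| `ss_tol` | 1e-8 | fixed point declared when $\max_i |dx_i/dt|$ falls below this. |
| `avg_window` | 100 | final-state averaging window when the dynamics do not converge (small-amplitude oscillation). |
| `osc_tol` | 0.01 | two successive window means agreeing to this tolerance flag a stationary oscillation. The value is set above the ~3e-3 beating residual that a genuine short-period limit cycle leaves in 100-unit window means (measured on a driven repressilator ring), and below the drift of a slowly relaxing transient. |

These defaults are reconstructions: the primary description of this model
family leaves several constants inside figures, and the text only brackets
them ("an appropriate range", $\theta$ mid-range, $\delta$ small, $\beta$
below the sharp-switching regime). All are exposed through
`grn_dynamics()` and a run's effective configuration is echoed into its
outputs.

### The response protocol and the fitness

Every evaluation uses one protocol (`step_response()`): all genes start
off, relax under $I_0$ to the pre-stimulus baseline, then the signal
switches to $I_1$ and the post-switch dynamics run to their new steady
state. Per gene, `gene_response_metrics()` reduces the response to

* $\Delta_{max}$ — the largest $|x_i(t) - x_i^{base}|$,
* $\Delta_{stat}$ — $|\bar{x}_i - x_i^{base}|$ with $\bar{x}_i$ the
  time-averaged final level,
* adaptiveness $f_i = \Delta_{max} - \Delta_{stat} \in [0, 1 + \delta]$.

$f_i$ is zero both for silent genes and for monotone responders, and
maximal for a full pulse that returns exactly to baseline (perfect
adaptation). $\Delta_{stat}$ uses the deviation *of the mean level* (not
the mean absolute deviation), which is what guarantees
$f_i \ge 0$. The fitness of a network is $f$ of the target gene alone;
the *average adaptiveness* $\bar{A}$ is the mean of $f_i$ over all genes
except the input (which always responds monotonically) and the target
(whose adaptation is forced by selection). $\bar{A}$ near 1 is the
cooperative regime in which essentially every gene adapts although
nothing selects for it.

Partial adaptation is reported as $\Delta_{stat}/\Delta_{max} \in [0,1]$
(0 = perfect). Response classes use two thresholds, `eps_resp = 0.1`
(a gene must move at least this much to count as responding) and
`eps_adapt = 0.05` (minimum $f$ to count as adaptive); the underlying
description is qualitative, so both thresholds are exposed and echoed in
reports.

An important structural fact about this protocol: with $I_0 = 0$ and the
all-off initial state, the baseline of *every* network is the all-off
state — a gene can only ignite if its field exceeds $\theta$, which is
impossible when all $x_j \approx \delta$. Consequently no gene, the
target included, can respond *downward* from baseline under the canonical
protocol. The alternative initial state (`initial_state = "on"`) exists
precisely to probe regimes where genes start high.

## The genetic algorithm

`evolve()` implements truncation selection: evaluate $M$ networks, keep
the $M_s$ fittest, let each survivor produce $M/M_s$ mutants
(per-entry mutation probability `mu`; a mutated entry takes one of the
other two ternary values, equiprobably), and repeat. The new generation
consists solely of mutants — there is no elitism, so the recorded best
fitness can dip transiently, and histories record it faithfully.
`selection_noise` optionally lets random non-survivors fill survivor
slots. Defaults ($M = 100$, $M_s = 10$, $\mu = 0.003$, initial edge
density 0.3) are again reconstructions; $\mu$ sits below the error
threshold discussed below, and the initial density gives typical in-degrees
of ~6, enough for the collective ignition the cooperative state relies on.

All randomness — initial population, mutation, selection noise, Langevin
noise — draws from R's RNG in a fixed order, so a seed reproduces a run
bit for bit. Deterministic fitness evaluations are memoised on the matrix
contents; at small `mu` roughly a third of offspring are unmutated copies
of their parent, and survivors recur, so this saves roughly a third of the
integration work without changing any result.

## What the analyses compute

* `ffl_census()` classifies feed-forward loops on (input, middle, target)
  by their sign triple. Two incoherent patterns are flagged *minimal
  adaptive*: `(+,-,+)` (fast activation, delayed inhibition — an upward
  pulse) and `(+,+,-)` (fast inhibition, delayed activation — a downward
  pulse, which requires a non-floor baseline and is therefore unreachable
  under the canonical protocol; see above).
* `triad_census()` canonicalizes every induced signed 3-gene subgraph
  (lexicographically smallest adjacency over the 6 node permutations,
  self-loops excluded) and annotates classes with the structures of
  interest: feed-forward loops, negative feedback 3-cycles, mutually
  activating and mutually inhibiting pairs. Using canonical matrices as
  class labels avoids any external motif dictionary.
* `random_motif_baseline()` gives the null expectation for censuses under
  i.i.d. ternary entries, both sampled and (for FFL patterns) in closed
  form.
* `group_interaction_fractions()` quantifies the two-group structure of
  cooperative networks — target-activating genes activating each other
  and inhibiting the target-inhibiting group, and vice versa.
* `edge_deletion_fitness()` and `noisy_fitness()` probe robustness to
  single-edge knockouts and to additive Gaussian expression noise
  (Euler–Maruyama with per-step clipping to $[0, 1+\delta]$; both phases
  of the protocol are run with noise, with window-averaged baseline and
  final levels). `parameter_sweep()` re-runs evolution across grids of
  network size, mutation rate, expression-noise level or gain, and
  re-evaluates evolved networks across input levels.

## Numerical choices

* **Integrator.** Fixed-step classical RK4. The right-hand side is smooth
  and bounded with Jacobian norm of order $\beta/4 \cdot \sqrt{N}/s_i$,
  well inside RK4's stability region at the steps used. A determinism
  requirement (bit-identical trajectories for identical inputs) rules out
  adaptive solvers with heuristic step control; the suite nevertheless
  cross-checks trajectories against an adaptive stiff solver (`deSolve`)
  and checks steady-state agreement across halved steps.
* **Steady-state detection.** The derivative max-norm is tested at every
  step (the first RK4 stage is the derivative, so this is free). If the
  cap `t_max` is reached, the final `avg_window` mean is used as the
  representative state, and the run is flagged oscillatory when two
  successive window means agree to `osc_tol`.
* **Saturation.** Sigmoid exponents are clamped so no evaluation can
  overflow, and entries outside ±40 (where the logistic is 1 within
  4e-18) skip the `exp` call entirely — population evaluation spends most
  of its time in saturated regimes.
* **Degenerate inputs.** Zero-edge networks, empty censuses and zero-FFL
  networks are reported with explicit zero-total flags rather than NaN
  fractions; mutation and enumeration treat the target's outgoing column
  as immutable by construction.

## Desk-scale experiment sizes

The package's own reproduction experiments (in `scripts/acceptance.R` and
the acceptance tests) are scaled to a single CPU. Choices, made once:

* evolution runs use `dt = 0.1` and default `t_max = 1000`;
* the mutation-rate sweep runs $N = 20$, $M = 60$ at
  $\mu \in \{0.001, 0.003, 0.01, 0.03, 0.1\}$, 3 replicate runs of 400
  generations each, and reports the error threshold as the last grid
  point before the median evolved $\bar{A}$ first drops by more than the
  replicate noise (the pooled median absolute deviation of the replicate
  values) — below the threshold the desk-scale medians are statistically
  tied, so a peak location would be decided by seed noise, while the
  decline that defines the threshold is far larger than the noise;
* the noise-robustness experiment collects generation-best networks
  (fitness ≥ 0.8) at 25-generation checkpoints from 6 runs of
  900 generations, bins them by $\bar{A}$ (width 0.04), and locates the
  bin with maximal mean fitness under expression noise of amplitude
  0.05;
* the exhaustive 3-gene search enumerates all 81 ternary networks
  (self-loops excluded; with them the universe is 729 and the top
  networks contain no feed-forward loop at all) at high gain
  $\beta = 40$ and censuses FFL patterns in the top fitness tier.

At these scales the qualitative phenomena — the target reaching
near-maximal fitness within a few hundred generations, the slow
subsequent growth of $\bar{A}$, the two-group differentiation, the
collapse of $\bar{A}$ at high mutation rates — all appear, but $\bar{A}$
itself grows roughly logarithmically in generations and desk-scale runs
reach $\bar{A} \approx 0.3$–0.4 rather than the near-unity values that
long runs attain. Quantities tied to the *location* of features on the
$\bar{A}$ axis (such as the noise-robustness optimum) are therefore
compressed toward lower $\bar{A}$ at this scale.

## What the synthetic data do and do not show

All inputs are simulated: random ternary networks, hand-built motif
fixtures (`iffl_fixture()`, `two_group_network()`) and exhaustively
enumerated small networks. They emulate the model's own universe, not
transcriptomes: there is no mRNA/protein distinction (the fast mRNA
stage is adiabatically eliminated), no stochastic bursting, no
distributed thresholds or graded interaction strengths, and expression is
a single normalized level per gene. Passing tests therefore validate the
simulator, the metrics and the evolutionary procedure — they do not by
themselves establish that any particular biological network adapts
cooperatively.

## Known limitations

* The canonical protocol cannot produce downward responses from baseline
  (all-off initial state, $I_0 = 0$), so analyses of downward-adaptive
  receivers require embedding in larger networks or the `"on"` initial
  state.
* $\bar{A}$ growth is slow (roughly logarithmic in generations);
  experiments that need networks spanning the full $[0, 1]$ adaptiveness
  range need commensurately long runs.
* Motif names used in the field for specific sign patterns vary; the
  census reports canonical adjacencies and structural annotations rather
  than relying on any one naming convention.
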